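# Synthetic multi-subject, multi-scan cohort generator with a known
# between-/within-subject variance decomposition, so the intraclass
# correlation of every connection is analytically known.

#' Configure a synthetic test-retest cohort
#'
#' The generative model works per off-diagonal connection (i, j), subject s,
#' scan t, in Fisher-z space:
#'
#'   z_ijst = mu_ij + b_ijs + w_ijst,
#'   b ~ Normal(0, sigma_b^2),  w ~ Normal(0, sigma_w^2),
#'
#' and correlations are `tanh(z)`, so they never leave (-1, 1). `b` is the
#' stable subject effect shared by all scans; `w` is scan-to-scan noise. The
#' theoretical intraclass correlation of each connection is therefore
#' `sigma_b^2 / (sigma_b^2 + sigma_w^2)` in z-space, exactly.
#'
#' @param n_subjects,n_scans,n_rois cohort dimensions (>= 2, >= 2, >= 3).
#' @param ts_length timepoints per scan; 0 (default) means matrix mode where
#'   correlation matrices are drawn directly from the generative model.
#'   Positive values switch to time-series mode: the per-scan correlation
#'   target is projected to the nearest positive-semidefinite correlation
#'   matrix and `ts_length` samples of a zero-mean multivariate Gaussian are
#'   drawn from it.
#' @param mu population mean connectivity in Fisher-z units: a scalar or an
#'   N x N symmetric matrix with zero diagonal.
#' @param sigma_b,sigma_w between-subject and within-subject (between-scan)
#'   standard deviations in z units; scalar or per-connection matrix, >= 0.
#' @param seed integer master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects, n_scans, n_rois, ts_length = 0,
                          mu = 0, sigma_b = 0.3, sigma_w = 0.3, seed = 1L) {
  stopifnot(n_subjects >= 2, n_scans >= 2, n_rois >= 3, ts_length >= 0)
  expand <- function(x, name) {
    if (length(x) == 1) {
      m <- matrix(x, n_rois, n_rois)
      diag(m) <- 0
      m
    } else {
      m <- as.matrix(x)
      if (!is_square_numeric(m) || nrow(m) != n_rois) {
        stop(name, " must be a scalar or ", n_rois, "x", n_rois, " matrix")
      }
      if (max(abs(m - t(m))) > 1e-12) stop(name, " must be symmetric")
      m
    }
  }
  mu <- expand(mu, "mu")
  if (any(abs(diag(mu)) > 1e-12)) stop("mu must have zero diagonal")
  sigma_b <- expand(sigma_b, "sigma_b")
  sigma_w <- expand(sigma_w, "sigma_w")
  if (any(sigma_b < 0) || any(sigma_w < 0)) {
    stop("sigma_b and sigma_w must be >= 0")
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_scans = as.integer(n_scans),
         n_rois = as.integer(n_rois), ts_length = as.integer(ts_length),
         mu = mu, sigma_b = sigma_b, sigma_w = sigma_w,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Theoretical per-connection intraclass correlation of a cohort config
#'
#' Returns the z-space ground truth `sigma_b^2 / (sigma_b^2 + sigma_w^2)`
#' per connection (0/0 defined as 0); symmetric, in \[0, 1\], zero diagonal.
#'
#' @param config a [cohort_config()] (matrix mode).
#' @return N x N matrix of theoretical ICC values.
#' @export
ground_truth_icc <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  vb <- config$sigma_b^2
  vw <- config$sigma_w^2
  tot <- vb + vw
  icc <- ifelse(tot == 0, 0, vb / tot)
  diag(icc) <- 0
  icc
}

# Nearest positive-semidefinite correlation matrix by eigenvalue clipping at
# a small floor followed by re-normalization to unit diagonal, iterated to
# convergence.
#' @keywords internal
nearest_psd_corr <- function(m, floor = 1e-8, max_iter = 100, tol = 1e-10) {
  out <- m
  for (it in seq_len(max_iter)) {
    eig <- eigen(out, symmetric = TRUE)
    if (min(eig$values) >= floor - tol) {
      d <- sqrt(diag(out))
      out <- out / tcrossprod(d)
      diag(out) <- 1
      if (min(eigen(out, symmetric = TRUE, only.values = TRUE)$values) >=
          -tol) {
        return((out + t(out)) / 2)
      }
    } else {
      vals <- pmax(eig$values, floor)
      out <- eig$vectors %*% diag(vals) %*% t(eig$vectors)
      d <- sqrt(diag(out))
      out <- out / tcrossprod(d)
      diag(out) <- 1
      out <- (out + t(out)) / 2
    }
  }
  stop("nearest-PSD projection did not converge after ", max_iter,
       " iterations")
}

#' Generate a synthetic test-retest cohort
#'
#' Draws per-subject latent connectivity and per-scan realizations from the
#' model described in [cohort_config()]. Matrix mode returns the tanh-mapped
#' matrices directly (no positive-definiteness required downstream);
#' time-series mode additionally draws multivariate Gaussian series whose
#' population correlation is the nearest positive-semidefinite repair of the
#' per-scan matrix, and returns their empirical Pearson matrices.
#'
#' Deterministic given the config seed: each (subject, scan) cell uses a
#' seed derived from the master seed by counters, so results do not depend
#' on generation order.
#'
#' @param config a [cohort_config()].
#' @return A `synthetic_cohort` list with elements `matrices` (list of
#'   subjects, each a list of scans), `true_subject_matrices` (scan-free
#'   latent correlation per subject), `series` and `target_matrices`
#'   (time-series mode only: the generated series and the PSD-repaired
#'   population correlation each series was drawn from), and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_rois
  labs <- paste0("roi", seq_len(n))
  ut <- upper.tri(matrix(0, n, n))
  mu_u <- config$mu[ut]
  sb_u <- config$sigma_b[ut]
  sw_u <- config$sigma_w[ut]
  n_edges <- length(mu_u)

  matrices <- vector("list", config$n_subjects)
  true_mats <- vector("list", config$n_subjects)
  series <- if (config$ts_length > 0) vector("list", config$n_subjects) else NULL
  targets <- if (config$ts_length > 0) vector("list", config$n_subjects) else NULL

  for (s in seq_len(config$n_subjects)) {
    set.seed(derive_seed(config$seed, 1L, s))
    b <- stats::rnorm(n_edges, 0, sb_u)
    z_subj <- mu_u + b
    tm <- sym_from_upper(fisher_z_inv(z_subj), n)
    dimnames(tm) <- list(labs, labs)
    true_mats[[s]] <- tm

    scans <- vector("list", config$n_scans)
    sub_series <- if (config$ts_length > 0) vector("list", config$n_scans)
    sub_targets <- if (config$ts_length > 0) vector("list", config$n_scans)
    for (t in seq_len(config$n_scans)) {
      set.seed(derive_seed(config$seed, 2L, s, t))
      w <- stats::rnorm(n_edges, 0, sw_u)
      r_scan <- sym_from_upper(fisher_z_inv(z_subj + w), n)
      dimnames(r_scan) <- list(labs, labs)
      if (config$ts_length > 0) {
        target <- tryCatch(
          nearest_psd_corr(r_scan),
          error = function(e) stop(sprintf(
            "PSD projection failed for subject %d scan %d: %s",
            s, t, conditionMessage(e)), call. = FALSE)
        )
        sub_targets[[t]] <- target
        x <- MASS::mvrnorm(config$ts_length, mu = rep(0, n), Sigma = target)
        colnames(x) <- labs
        ts <- time_series_matrix(x, labs, subject_id = sprintf("sub-%02d", s),
                                 scan_id = sprintf("scan-%d", t))
        sub_series[[t]] <- ts
        r_scan <- correlation_matrix(ts)
      } else {
        attr(r_scan, "subject_id") <- sprintf("sub-%02d", s)
        attr(r_scan, "scan_id") <- sprintf("scan-%d", t)
      }
      scans[[t]] <- r_scan
    }
    names(scans) <- sprintf("scan-%d", seq_len(config$n_scans))
    matrices[[s]] <- scans
    if (config$ts_length > 0) {
      names(sub_series) <- names(scans)
      names(sub_targets) <- names(scans)
      series[[s]] <- sub_series
      targets[[s]] <- sub_targets
    }
  }
  names(matrices) <- sprintf("sub-%02d", seq_len(config$n_subjects))
  names(true_mats) <- names(matrices)
  if (!is.null(series)) {
    names(series) <- names(matrices)
    names(targets) <- names(matrices)
  }

  structure(
    list(matrices = matrices, true_subject_matrices = true_mats,
         series = series, target_matrices = targets, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<synthetic_cohort> %d subjects x %d scans, %d ROIs, %s mode, seed %d\n",
    cfg$n_subjects, cfg$n_scans, cfg$n_rois,
    if (cfg$ts_length > 0) sprintf("time-series (T=%d)", cfg$ts_length)
    else "matrix", cfg$seed))
  invisible(x)
}

#' Extract one scan condition of a cohort as a list of matrices
#'
#' Convenience accessor: returns the per-subject correlation matrices of one
#' scan, or the Fisher-z average of several scans per subject (used to build
#' the long-term condition from scans 2 and 3).
#'
#' @param cohort a `synthetic_cohort`.
#' @param scans integer scan indices; more than one means z-space averaging.
#' @return Named list (one correlation matrix per subject).
#' @export
cohort_scans <- function(cohort, scans) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  lapply(cohort$matrices, function(subj) {
    if (length(scans) == 1) subj[[scans]] else average_matrices(subj[scans])
  })
}

#' Write a cohort to disk as plain-text matrices
#'
#' One square TSV per subject-scan (`sub-<s>_scan-<t>.tsv`, leading label
#' row/column) plus a `manifest.json` recording the configuration and seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  for (s in seq_len(cfg$n_subjects)) {
    for (t in seq_len(cfg$n_scans)) {
      path <- file.path(dir, sprintf("sub-%02d_scan-%d.tsv", s, t))
      write_matrix_tsv(cohort$matrices[[s]][[t]], path)
    }
  }
  manifest <- list(
    n_subjects = cfg$n_subjects, n_scans = cfg$n_scans, n_rois = cfg$n_rois,
    ts_length = cfg$ts_length, seed = cfg$seed,
    sigma_b = cfg$sigma_b[upper.tri(cfg$sigma_b)][1],
    sigma_w = cfg$sigma_w[upper.tri(cfg$sigma_w)][1]
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
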