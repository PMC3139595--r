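# Test-retest reliability: one-way random-effects intraclass correlation
# (ICC), its F-statistic relation, qualitative grading, AUC summarization
# of metric-sparsity curves, edgewise connectivity reliability, and the
# correlation-based consistency checks.

#' One-way random-effects intraclass correlation
#'
#' Splits the total sum of squares of an n x k table (rows = subjects,
#' columns = repeated scans) into between-subject and within-subject parts
#' by a one-way ANOVA with random subject effects, and returns
#'
#'   ICC = (MS_b - MS_w) / (MS_b + (k - 1) MS_w),
#'
#' the ICC(1,1) single-measurement form. Negative values are returned as
#' computed (not truncated). The ANOVA F = MS_b / MS_w is also returned;
#' the two are linked by `ICC = (F - 1) / (F + k - 1)`.
#'
#' @param values numeric matrix, subjects x repeated observations (k >= 2);
#'   rows with missing values are dropped listwise.
#' @return An `icc_result` list: `icc`, `f_value`, `ms_between`,
#'   `ms_within`, `grade`, `n`, `k`. All-identical tables (zero total
#'   variance) yield a flagged NA icc.
#' @examples
#' icc(cbind(c(1, 3, 5, 7), c(2, 3, 4, 8)))
#' @export
icc <- function(values) {
  values <- as.matrix(values)
  values <- values[stats::complete.cases(values), , drop = FALSE]
  n <- nrow(values)
  k <- ncol(values)
  if (k < 2) stop("need at least 2 repeated observations per subject")
  if (n < 3) stop("need at least 3 subjects")
  row_means <- rowMeans(values)
  grand <- mean(values)
  ss_b <- k * sum((row_means - grand)^2)
  ss_w <- sum((values - row_means)^2)
  ms_b <- ss_b / (n - 1)
  ms_w <- ss_w / (n * (k - 1))
  if (ms_b == 0 && ms_w == 0) {
    return(structure(list(icc = NA_real_, f_value = NA_real_,
                          ms_between = 0, ms_within = 0,
                          grade = NA_character_, n = n, k = k),
                     class = "icc_result"))
  }
  icc_val <- (ms_b - ms_w) / (ms_b + (k - 1) * ms_w)
  f_val <- if (ms_w > 0) ms_b / ms_w else Inf
  structure(list(icc = icc_val, f_value = f_val,
                 ms_between = ms_b, ms_within = ms_w,
                 grade = grade_icc(icc_val), n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC = %.4f (%s), F = %.3f, n = %d, k = %d\n",
              x$icc, x$grade, x$f_value, x$n, x$k))
  invisible(x)
}

#' ICC from the one-way ANOVA F statistic
#'
#' `ICC = (F - 1) / (F + k - 1)`; exactly consistent with [icc()] for any
#' complete table.
#'
#' @param f_value ANOVA F (MS_between / MS_within), > 0.
#' @param k repeated observations per subject, >= 2.
#' @return scalar ICC.
#' @export
icc_from_f <- function(f_value, k) {
  stopifnot(f_value > 0, k >= 2)
  (f_value - 1) / (f_value + k - 1)
}

#' Qualitative reliability grade of an ICC value
#'
#' Bands: below 0.25 poor; 0.25-0.4 low; 0.4-0.6 fair; 0.6-0.75 good;
#' 0.75-1.0 excellent. Lower bounds are inclusive; negative values grade
#' as poor.
#'
#' @param icc numeric ICC values (vectorized), <= 1.
#' @return character vector of grades.
#' @export
grade_icc <- function(icc) {
  if (any(icc > 1 + 1e-12, na.rm = TRUE)) stop("ICC cannot exceed 1")
  breaks <- c(-Inf, 0.25, 0.4, 0.6, 0.75, Inf)
  labels <- c("poor", "low", "fair", "good", "excellent")
  as.character(cut(icc, breaks = breaks, labels = labels, right = FALSE))
}

#' Area under a metric-sparsity curve
#'
#' Trapezoidal integral of metric values over the sparsity grid — the
#' threshold-independent per-subject summary fed into the ICC. Grid points
#' with undefined (NA) values are pruned together with their values.
#'
#' @param grid sparsity levels (strictly increasing).
#' @param values metric values at each grid point.
#' @return scalar AUC.
#' @export
auc <- function(grid, values) {
  grid <- as.numeric(grid)
  stopifnot(length(grid) == length(values))
  ok <- !is.na(values)
  grid <- grid[ok]
  values <- values[ok]
  if (length(grid) < 2) stop("AUC needs at least 2 usable grid points")
  stopifnot(all(diff(grid) > 0))
  pracma::trapz(grid, values)
}

#' Edgewise connectivity reliability between two scan conditions
#'
#' For every connection (strict upper-triangle entry) the per-subject
#' values of the two conditions form an n x 2 table whose ICC is computed.
#' By default values are Fisher-z transformed first, matching the scale on
#' which the synthetic generator's ground truth is defined and on which
#' correlations are averaged.
#'
#' @param a,b named lists of correlation matrices, one per subject, in
#'   matching subject order (e.g. from [cohort_scans()]).
#' @param space `"z"` (default) or `"r"`.
#' @return list with `icc` (N x N symmetric matrix, NA diagonal),
#'   `mean_icc`, `grade_counts` (table over the five bands), and `n_edges`.
#' @export
edgewise_reliability <- function(a, b, space = c("z", "r")) {
  space <- match.arg(space)
  stopifnot(is.list(a), is.list(b), length(a) == length(b))
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b))) {
    stop("subject sets of the two conditions do not match")
  }
  n_sub <- length(a)
  if (n_sub < 3) stop("need at least 3 subjects")
  n <- nrow(a[[1]])
  xform <- if (space == "z") {
    function(u) fisher_z(pmin(pmax(u, -1 + 1e-12), 1 - 1e-12))
  } else identity
  ua <- vapply(a, function(m) xform(upper_tri_values(m)),
               numeric(n * (n - 1) / 2))
  ub <- vapply(b, function(m) xform(upper_tri_values(m)),
               numeric(n * (n - 1) / 2))
  n_edges <- nrow(ua)
  icc_vals <- numeric(n_edges)
  for (e in seq_len(n_edges)) {
    icc_vals[e] <- icc(cbind(ua[e, ], ub[e, ]))$icc
  }
  icc_mat <- sym_from_upper(icc_vals, n, diag_value = NA_real_)
  labs <- roi_labels_of(a[[1]])
  dimnames(icc_mat) <- list(labs, labs)
  grades <- factor(grade_icc(icc_vals),
                   levels = c("poor", "low", "fair", "good", "excellent"))
  list(icc = icc_mat, mean_icc = mean(icc_vals, na.rm = TRUE),
       grade_counts = table(grades), n_edges = n_edges)
}

#' Metric reliability between two scan conditions
#'
#' Given long-format metric tables for two conditions (as produced by
#' [metrics_over_grid()] over the same subjects and grid), computes the ICC
#' per measure either at every sparsity level (`mode = "per_threshold"`) or
#' on the per-subject AUC over the grid (`mode = "auc"`, the
#' threshold-independent scalar). Subjects with an undefined value for a
#' measure are dropped listwise for that measure; under AUC mode undefined
#' values are pruned from the curve before integration.
#'
#' @param tab_a,tab_b metric tables for conditions A and B.
#' @param mode `"auc"` or `"per_threshold"`.
#' @return data frame: metric, node (NA for global), sparsity (`"AUC"` or
#'   the level), icc, f, grade, n_used.
#' @export
metric_reliability <- function(tab_a, tab_b,
                               mode = c("auc", "per_threshold")) {
  mode <- match.arg(mode)
  grid_a <- sort(unique(tab_a$sparsity))
  grid_b <- sort(unique(tab_b$sparsity))
  if (!isTRUE(all.equal(grid_a, grid_b))) {
    stop("sparsity grids of the two conditions differ")
  }
  subjects <- sort(unique(tab_a$subject))
  if (!identical(subjects, sort(unique(tab_b$subject)))) {
    stop("subject sets of the two conditions do not match")
  }
  measures <- unique(tab_a[, c("metric", "node")])
  rows <- vector("list", 0L)
  for (i in seq_len(nrow(measures))) {
    met <- measures$metric[i]
    node <- measures$node[i]
    sel <- function(tab) {
      keep <- tab$metric == met &
        (if (is.na(node)) is.na(tab$node) else !is.na(tab$node) &
           tab$node == node)
      tab[keep, c("subject", "sparsity", "value")]
    }
    va <- sel(tab_a)
    vb <- sel(tab_b)
    if (mode == "auc") {
      auc_of <- function(v) {
        vapply(subjects, function(su) {
          d <- v[v$subject == su, ]
          d <- d[order(d$sparsity), ]
          if (sum(!is.na(d$value)) < 2) NA_real_ else auc(d$sparsity, d$value)
        }, numeric(1))
      }
      pm <- cbind(auc_of(va), auc_of(vb))
      res <- tryCatch(icc(pm), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, node = node, sparsity = "AUC",
        icc = if (is.null(res)) NA_real_ else res$icc,
        f = if (is.null(res)) NA_real_ else res$f_value,
        grade = if (is.null(res)) NA_character_ else res$grade,
        n_used = if (is.null(res)) 0L else res$n,
        stringsAsFactors = FALSE)
    } else {
      for (s in grid_a) {
        pm <- cbind(
          va$value[match(paste(subjects, s), paste(va$subject, va$sparsity))],
          vb$value[match(paste(subjects, s), paste(vb$subject, vb$sparsity))])
        res <- tryCatch(icc(pm), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = met, node = node, sparsity = as.character(s),
          icc = if (is.null(res)) NA_real_ else res$icc,
          f = if (is.null(res)) NA_real_ else res$f_value,
          grade = if (is.null(res)) NA_character_ else res$grade,
          n_used = if (is.null(res)) 0L else res$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Connection strength versus reliability
#'
#' Least-squares fit of edgewise ICC on mean connectivity strength,
#' separately for positive and negative connections — do stronger
#' connections tend to be more reliable?
#'
#' @param mean_strength per-edge mean connectivity (upper-triangle vector
#'   or matrix).
#' @param icc_values per-edge ICC, same layout.
#' @param sign `"positive"` or `"negative"`: which connections to fit.
#' @return list with `r`, `p`, `r_squared`, `slope`, `intercept`,
#'   `n_edges`. Degenerate inputs (zero ICC variance) flag `r` as NA.
#' @export
strength_vs_reliability <- function(mean_strength, icc_values,
                                    sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (is.matrix(mean_strength)) mean_strength <- upper_tri_values(mean_strength)
  if (is.matrix(icc_values)) icc_values <- upper_tri_values(icc_values)
  stopifnot(length(mean_strength) == length(icc_values))
  keep <- if (sign == "positive") mean_strength > 0 else mean_strength < 0
  keep <- keep & !is.na(icc_values)
  if (sum(keep) < 3) stop("fewer than 3 ", sign, " connections")
  x <- mean_strength[keep]
  y <- icc_values[keep]
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    return(list(r = NA_real_, p = NA_real_, r_squared = NA_real_,
                slope = NA_real_, intercept = NA_real_, n_edges = sum(keep)))
  }
  ct <- stats::cor.test(x, y)
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r = unname(ct$estimate), p = ct$p.value,
       r_squared = unname(ct$estimate)^2,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]), n_edges = sum(keep))
}

#' Paired t-test and inter-scan Pearson correlation
#'
#' Thin wrappers used for the post-hoc comparisons and the ICC-vs-Pearson
#' consistency check; degenerate inputs (zero variance of differences, or
#' of either sample) are flagged rather than erroring.
#'
#' @param a,b matched numeric vectors (length >= 3).
#' @return `paired_t`: list(t, df, p); `pearson_r`: list(r, p). Flagged
#'   values are NA.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(a) - 1L, p = NA_real_,
                flag = "zero-variance differences"))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' @rdname paired_t
#' @export
pearson_r <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    return(list(r = NA_real_, p = NA_real_, flag = "zero variance"))
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value)
}
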