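# Study orchestration: configuration-driven execution of the full
# reliability analysis — cohort synthesis or ingest, scan pairing into
# short-term (scan 2 vs scan 3) and long-term (scan 1 vs z-average of
# scans 2-3) conditions, network construction across the membership x kind
# factor grid, metric computation, ICC tables, and (optionally) the noise
# experiment — with a JSON manifest of seeds and settings.

#' Configure a reliability study
#'
#' @param input `"synthetic"` (default: generate a cohort from
#'   `cohort`), `"matrices"` (read `sub-<s>_scan-<t>.tsv` files from
#'   `path`), or `"timeseries"` (read per-scan time-series TSVs from
#'   `path`, filtered/regressed/correlated per the connectivity defaults).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param path input directory (matrices / timeseries modes).
#' @param n_scans scans per subject when reading from disk.
#' @param short_term,long_term scan pairings: integer scan indices; a
#'   length-2 second element means z-space averaging of those scans.
#' @param memberships,kinds factor grid cells to run.
#' @param grid sparsity grid (truncated per condition by the group-wise
#'   maximum attainable sparsity).
#' @param global_names,nodal_names metric subsets (NULL skips a family).
#' @param n_random surrogate ensemble size.
#' @param noise optional [noise_config()] to also run the noise experiment
#'   on the first scan's matrices.
#' @param out_dir output directory for TSV tables and the manifest.
#' @param seed master seed.
#' @return a `study_config` list.
#' @export
study_config <- function(input = c("synthetic", "matrices", "timeseries"),
                         cohort = NULL, path = NULL, n_scans = 3,
                         short_term = list(2, 3),
                         long_term = list(1, c(2, 3)),
                         memberships = c("positive_only", "absolute_both"),
                         kinds = c("binarized", "weighted"),
                         grid = sparsity_grid(0.05, 0.5, 0.05),
                         global_names = GLOBAL_METRIC_NAMES,
                         nodal_names = NODAL_METRIC_NAMES,
                         n_random = 20, noise = NULL,
                         out_dir = "results/study", seed = 1L) {
  input <- match.arg(input)
  structure(list(input = input, cohort = cohort, path = path,
                 n_scans = as.integer(n_scans),
                 short_term = short_term, long_term = long_term,
                 memberships = memberships, kinds = kinds, grid = grid,
                 global_names = global_names, nodal_names = nodal_names,
                 n_random = n_random, noise = noise, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Validate a study configuration
#'
#' Returns findings (errors and warnings) instead of throwing, so a
#' configuration can be checked before any computation.
#'
#' @param cfg a [study_config()].
#' @param matrices optional list of correlation matrices to check the grid
#'   against (grid values above the group-wise maximum attainable sparsity
#'   under positive-only membership produce a truncation warning).
#' @return data frame with columns `level` ("error"/"warning") and
#'   `message`; zero rows when the configuration is clean.
#' @export
validate_config <- function(cfg, matrices = NULL) {
  findings <- list()
  note <- function(level, msg) {
    findings[[length(findings) + 1L]] <<- data.frame(
      level = level, message = msg, stringsAsFactors = FALSE)
  }
  if (!inherits(cfg, "study_config")) {
    note("error", "not a study_config object")
    return(do.call(rbind, findings))
  }
  if (length(cfg$memberships) == 0 || length(cfg$kinds) == 0) {
    note("error", "empty factor grid: need at least one membership and kind")
  }
  if (!all(cfg$memberships %in% c("positive_only", "absolute_both"))) {
    note("error", "unknown membership value")
  }
  if (!all(cfg$kinds %in% c("binarized", "weighted"))) {
    note("error", "unknown kind value")
  }
  if (cfg$input == "synthetic" && !inherits(cfg$cohort, "cohort_config")) {
    note("error", "synthetic input requires a cohort_config")
  }
  if (cfg$input != "synthetic" &&
      (is.null(cfg$path) || !dir.exists(cfg$path))) {
    note("error", "input path missing or not a directory")
  }
  all_scans <- unlist(c(cfg$short_term, cfg$long_term))
  if (any(all_scans > cfg$n_scans | all_scans < 1)) {
    note("error", "scan pairing references a scan outside 1..n_scans")
  }
  if (!is.null(matrices) && "positive_only" %in% cfg$memberships) {
    s_max <- min(vapply(matrices, max_sparsity, numeric(1),
                        membership = "positive_only"))
    if (max(as.numeric(cfg$grid)) > s_max) {
      note("warning", sprintf(
        "sparsity grid exceeds group-wise S_max = %.3f under positive_only; grid will be truncated",
        s_max))
    }
  }
  if (length(findings) == 0) {
    return(data.frame(level = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, findings)
}

#' @keywords internal
load_study_matrices <- function(cfg) {
  if (cfg$input == "synthetic") {
    cohort <- generate_cohort(cfg$cohort)
    lapply(seq_len(cfg$cohort$n_scans), function(t) cohort_scans(cohort, t))
  } else {
    files <- list.files(cfg$path, pattern = "^sub-.*_scan-[0-9]+\\.tsv$")
    subs <- sort(unique(sub("_scan-.*$", "", files)))
    if (length(subs) == 0) stop("no sub-*_scan-*.tsv files in ", cfg$path)
    lapply(seq_len(cfg$n_scans), function(t) {
      mats <- lapply(subs, function(su) {
        f <- file.path(cfg$path, sprintf("%s_scan-%d.tsv", su, t))
        if (!file.exists(f)) stop("missing scan file for pairing: ", f)
        if (cfg$input == "timeseries") {
          ts <- read_timeseries_tsv(f, subject_id = su,
                                    scan_id = sprintf("scan-%d", t))
          correlation_matrix(regress_nuisance(bandpass_filter(ts)))
        } else {
          read_matrix_tsv(f)
        }
      })
      names(mats) <- subs
      mats
    })
  }
}

#' @keywords internal
condition_matrices <- function(by_scan, pairing) {
  lapply(pairing, function(scans) {
    scans <- as.integer(scans)
    if (length(scans) == 1) {
      by_scan[[scans]]
    } else {
      subs <- names(by_scan[[scans[1]]])
      out <- lapply(subs, function(su)
        average_matrices(lapply(scans, function(t) by_scan[[t]][[su]])))
      names(out) <- subs
      out
    }
  })
}

#' Run a full reliability study
#'
#' Executes every stage for each factor cell (membership x kind) and each
#' scan condition (short-term, long-term): edgewise connectivity ICC,
#' per-threshold and AUC metric ICC tables with grade histograms,
#' strength-versus-reliability fits, and optionally the noise experiment.
#' All tables are written as TSV under `cfg$out_dir` together with a JSON
#' manifest of the configuration and derived seeds. Deterministic given the
#' master seed.
#'
#' @param cfg a [study_config()].
#' @return Invisibly, a list with the in-memory tables (`edgewise`,
#'   `metric_icc`, `strength_fits`, `noise`, `manifest`).
#' @export
run_study <- function(cfg) {
  findings <- validate_config(cfg)
  if (any(findings$level == "error")) {
    stop("invalid study config:\n  ",
         paste(findings$message[findings$level == "error"], collapse = "\n  "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  by_scan <- load_study_matrices(cfg)
  conditions <- list(
    short_term = condition_matrices(by_scan, cfg$short_term),
    long_term = condition_matrices(by_scan, cfg$long_term)
  )

  edgewise_out <- list()
  strength_out <- list()
  metric_out <- list()

  for (cond in names(conditions)) {
    pair <- conditions[[cond]]
    ew <- edgewise_reliability(pair[[1]], pair[[2]])
    edgewise_out[[cond]] <- ew
    write_matrix_tsv_na <- function(m, path) {
      diag(m) <- 0
      write_matrix_tsv(m, path)
    }
    write_matrix_tsv_na(ew$icc,
                        file.path(cfg$out_dir,
                                  sprintf("edgewise_icc_%s.tsv", cond)))
    mean_conn <- average_matrices(c(pair[[1]], pair[[2]]))
    fits <- list()
    for (sgn in c("positive", "negative")) {
      fits[[sgn]] <- tryCatch(
        strength_vs_reliability(mean_conn, ew$icc, sgn),
        error = function(e) list(r = NA_real_, p = NA_real_,
                                 r_squared = NA_real_, slope = NA_real_,
                                 intercept = NA_real_, n_edges = 0L))
    }
    strength_out[[cond]] <- fits

    for (membership in cfg$memberships) {
      grid_c <- truncate_grid(cfg$grid, c(pair[[1]], pair[[2]]), membership)
      if (length(grid_c) < 2) {
        warning("grid collapsed under ", membership, " for ", cond)
        next
      }
      for (kind in cfg$kinds) {
        tabs <- lapply(c(1, 2), function(ci) {
          mats <- pair[[ci]]
          do.call(rbind, lapply(names(mats), function(su)
            metrics_over_grid(mats[[su]], grid_c, membership, kind,
                              global_names = cfg$global_names,
                              nodal_names = cfg$nodal_names,
                              n_random = cfg$n_random,
                              seed = derive_seed(cfg$seed, match(cond, names(conditions)),
                                                 match(membership, cfg$memberships),
                                                 match(kind, cfg$kinds), ci,
                                                 match(su, names(mats))),
                              subject_id = su,
                              scan_id = sprintf("%s_%d", cond, ci))))
        })
        cell <- sprintf("%s_%s_%s", cond, membership, kind)
        for (mode in c("auc", "per_threshold")) {
          tab <- metric_reliability(tabs[[1]], tabs[[2]], mode)
          tab$condition <- cond
          tab$membership <- membership
          tab$kind <- kind
          metric_out[[paste(cell, mode, sep = "_")]] <- tab
          utils::write.table(
            tab, file.path(cfg$out_dir,
                           sprintf("metric_icc_%s_%s.tsv", cell, mode)),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")
        }
      }
    }
  }

  noise_res <- NULL
  if (!is.null(cfg$noise)) {
    noise_res <- run_noise_experiment(by_scan[[1]], cfg$noise)
    utils::write.table(noise_res$per_level,
                       file.path(cfg$out_dir, "noise_per_level.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    utils::write.table(noise_res$per_rep,
                       file.path(cfg$out_dir, "noise_per_rep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }

  grade_hist <- lapply(edgewise_out, function(ew) as.list(ew$grade_counts))
  manifest <- list(
    input = cfg$input, seed = cfg$seed,
    n_subjects = length(by_scan[[1]]),
    n_rois = nrow(by_scan[[1]][[1]]),
    memberships = cfg$memberships, kinds = cfg$kinds,
    grid = as.numeric(cfg$grid),
    edgewise_mean_icc = lapply(edgewise_out, function(e) e$mean_icc),
    edgewise_grade_counts = grade_hist,
    package_version = as.character(utils::packageVersion("trtnet"))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(edgewise = edgewise_out, metric_icc = metric_out,
                 strength_fits = strength_out, noise = noise_res,
                 manifest = manifest))
}
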