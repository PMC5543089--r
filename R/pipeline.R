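# End-to-end orchestration: validate a configuration, run extraction and the
# requested statistics per volume of interest, rank subjects, compare
# regions, and write a machine-readable result bundle with every seed used.

#' Pipeline configuration
#'
#' Validates paths and analysis switches before any computation; a missing
#' events file or model matrix fails here, not mid-run.
#'
#' @param data_dir Dataset directory (layout of [write_dataset()]).
#' @param model Path to a model similarity CSV, or a `similarity_matrix`;
#'   default: `model.csv` inside `data_dir`.
#' @param masks Optional named list of `voi_mask` objects or mask TSV/NIfTI
#'   paths; `NULL` analyses all voxels as a single region `"all"`.
#' @param statistics Which statistics to run.
#' @param n_perm Permutations per test (>= 1).
#' @param seed Master seed; all per-subject and per-statistic seeds derive
#'   from it.
#' @param window,substep BOLD integration window and grid step.
#' @param cell fMRI matrix cell definition (see [fmri_similarity_matrix()]).
#' @param regress Apply nuisance regression (intercept + drift) first.
#' @param out_dir Output directory (`NULL` = no files written).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(data_dir, model = NULL, masks = NULL,
                            statistics = c("rsa", "identity", "location"),
                            n_perm = 10000, seed = 1L, window = c(2, 8),
                            substep = 0.1,
                            cell = c("trial_pairs", "entity_average"),
                            regress = FALSE, out_dir = NULL) {
  if (!dir.exists(data_dir)) stopf("data directory '%s' does not exist", data_dir)
  events <- file.path(data_dir, "events.tsv")
  if (!file.exists(events)) stopf("missing events file '%s'", events)
  if (is.null(model)) model <- file.path(data_dir, "model.csv")
  if (is.character(model) && !file.exists(model)) {
    stopf("missing model matrix '%s'", model)
  }
  if (!is.null(masks)) {
    for (m in masks) {
      if (is.character(m) && !file.exists(m)) stopf("missing mask file '%s'", m)
    }
  }
  if (n_perm < 1) stopf("n_perm must be >= 1")
  structure(
    list(data_dir = data_dir, model = model, masks = masks,
         statistics = match.arg(statistics, several.ok = TRUE),
         n_perm = as.integer(n_perm), seed = as.integer(seed),
         window = window, substep = substep, cell = match.arg(cell),
         regress = isTRUE(regress), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Reads the dataset, then per region: per-subject response patterns and
#' similarity matrices, the group-average matrix, the requested permutation
#' statistics, per-subject ranks, across-subject diagnostics; finally
#' pairwise between-region rank comparisons (one-tailed signed rank) for
#' each statistic. Results are returned as a bundle and, when `out_dir` is
#' set, written as CSV/JSON with a manifest recording every seed.
#'
#' @param cfg A `pipeline_config`.
#' @return A `pipeline_result`: list with `regions` (per-region results),
#'   `comparisons`, and `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  ds <- read_dataset(cfg$data_dir)
  model <- if (is.character(cfg$model)) {
    read_similarity_csv(cfg$model, source = "model")
  } else cfg$model
  masks <- cfg$masks
  if (!is.null(masks)) {
    masks <- lapply(masks, function(m) {
      if (inherits(m, "voi_mask")) return(m)
      if (grepl("\\.nii(\\.gz)?$", m)) read_mask_nifti(m) else read_mask_tsv(m)
    })
    if (is.null(names(masks))) {
      names(masks) <- vapply(masks, `[[`, "", "name")
    }
  } else {
    masks <- list(all = NULL)
  }
  subjects <- unique(ds$trials$subject)
  region_seeds <- split_seed(cfg$seed, length(masks))
  regions <- vector("list", length(masks))
  names(regions) <- names(masks)
  for (v in seq_along(masks)) {
    regions[[v]] <- analyze_region(ds, masks[[v]], model, cfg,
                                   seed = region_seeds[v])
  }
  comparisons <- region_comparisons(regions, cfg$statistics)
  manifest <- list(
    package_version = as.character(utils::packageVersion("voxrsa")),
    data_dir = cfg$data_dir, statistics = cfg$statistics,
    n_perm = cfg$n_perm, master_seed = cfg$seed,
    region_seeds = stats::setNames(as.list(region_seeds), names(masks)),
    window = cfg$window, substep = cfg$substep, cell = cfg$cell,
    n_subjects = length(subjects), regions = names(masks)
  )
  res <- structure(list(regions = regions, comparisons = comparisons,
                        manifest = manifest), class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_result(res, cfg$out_dir)
  res
}

# Single-region computation; stage errors are annotated with the region.
analyze_region <- function(ds, mask, model, cfg, seed) {
  region <- if (is.null(mask)) "all" else mask$name
  seeds <- split_seed(seed, 4L)
  subjects <- unique(ds$trials$subject)
  tryCatch({
    patterns <- lapply(subjects, function(s) {
      tt_s <- ds$trials[ds$trials$subject == s, , drop = FALSE]
      class(tt_s) <- class(ds$trials)
      ts_list <- ds$timeseries[[s]]
      if (!is.null(mask)) {
        keep <- mask$indices[, 1]        # flat-layout data: x-axis index
        ts_list <- lapply(ts_list, function(ts) {
          voxel_timeseries(ts$values[, keep, drop = FALSE], tr = ts$tr,
                           run = ts$run, voxel_ids = keep)
        })
      }
      if (cfg$regress) ts_list <- lapply(ts_list, nuisance_regress)
      extract_patterns(ts_list, tt_s, window = cfg$window,
                       substep = cfg$substep)
    })
    names(patterns) <- subjects
    out <- list(region = region)
    if ("rsa" %in% cfg$statistics) {
      out$subject_matrices <- lapply(patterns, fmri_similarity_matrix,
                                     cell = cfg$cell)
      out$group_matrix <- group_average_matrix(out$subject_matrices)
      out$rsa <- rsa_test(out$group_matrix, model, n_perm = cfg$n_perm,
                          seed = seeds[1])
      subj <- rsa_subject_tests(out$subject_matrices, model,
                                n_perm = cfg$n_perm, seed = seeds[2])
      out$rsa_subject <- subj
      if (cfg$n_perm >= 100) {
        out$rsa_ranks <- subject_rank(subj$observed, subj$nulls)
      }
      if (length(subjects) >= 3 && stats::sd(subj$observed) > 0) {
        out$diagnostics <- subjectwise_diagnostics(subj$observed, subj$p)
      }
    }
    if ("identity" %in% cfg$statistics) {
      out$identity <- identity_statistic(patterns, n_perm = cfg$n_perm,
                                         seed = seeds[3])
      if (cfg$n_perm >= 100) {
        out$identity_ranks <- subject_rank(out$identity$per_subject$observed,
                                           out$identity$per_subject$nulls)
      }
    }
    if ("location" %in% cfg$statistics) {
      out$location <- location_statistic(patterns, n_perm = cfg$n_perm,
                                         seed = seeds[4])
      if (cfg$n_perm >= 100) {
        out$location_ranks <- subject_rank(out$location$per_subject$observed,
                                           out$location$per_subject$nulls)
      }
    }
    out
  }, error = function(e) {
    stopf("region '%s': %s", region, conditionMessage(e))
  })
}

# Pairwise one-tailed signed-rank comparisons of subject ranks between
# regions, per statistic.
region_comparisons <- function(regions, statistics) {
  rank_field <- c(rsa = "rsa_ranks", identity = "identity_ranks",
                  location = "location_ranks")
  rows <- list()
  nms <- names(regions)
  for (st in statistics) {
    f <- rank_field[[st]]
    for (i in seq_along(regions)) {
      for (j in seq_along(regions)) {
        if (i == j) next
        ra <- regions[[i]][[f]]; rb <- regions[[j]][[f]]
        if (is.null(ra) || is.null(rb)) next
        cmp <- compare_conditions(ra$rank, rb$rank, paired = TRUE, tail = "one")
        rows[[length(rows) + 1L]] <- data.frame(
          statistic = st, region_a = nms[i], region_b = nms[j],
          p = cmp$p, method = cmp$method
        )
      }
    }
  }
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Write a pipeline result bundle to disk
#'
#' Per region: subject matrix CSVs, the group matrix CSV, one JSON record
#' per statistic (plus null-sample CSVs), rank tables; at top level the
#' comparison table and the run manifest.
#'
#' @param res A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rg in res$regions) {
    rdir <- file.path(dir, rg$region)
    dir.create(rdir, showWarnings = FALSE)
    if (!is.null(rg$group_matrix)) {
      write_similarity_csv(rg$group_matrix, file.path(rdir, "group_matrix.csv"))
      for (s in names(rg$subject_matrices)) {
        write_similarity_csv(rg$subject_matrices[[s]],
                             file.path(rdir, sprintf("matrix_%s.csv", s)))
      }
    }
    for (st in c("rsa", "identity", "location")) {
      if (!is.null(rg[[st]])) {
        write_perm_result(rg[[st]], file.path(rdir, paste0(st, ".json")),
                          null_csv = file.path(rdir, paste0(st, "_null.csv")))
      }
      rk <- rg[[paste0(st, "_ranks")]]
      if (!is.null(rk)) {
        utils::write.csv(rk, file.path(rdir, paste0(st, "_ranks.csv")),
                         row.names = FALSE)
      }
    }
    if (!is.null(rg$diagnostics)) {
      d <- rg$diagnostics
      jsonlite::write_json(d[setdiff(names(d), "z")],
                           file.path(rdir, "diagnostics.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(res$comparisons)) {
    utils::write.csv(res$comparisons, file.path(dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d region(s): %s\n", length(x$regions),
              paste(names(x$regions), collapse = ", ")))
  for (rg in x$regions) {
    for (st in c("rsa", "identity", "location")) {
      if (!is.null(rg[[st]])) {
        cat(sprintf("  %s / %s: observed = %.5g, p = %.4g\n", rg$region, st,
                    rg[[st]]$observed, rg[[st]]$p))
      }
    }
  }
  invisible(x)
}
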