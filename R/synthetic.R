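# Synthetic event-related dataset generator. Emulates the passive-viewing
# design the pipeline targets: 24 entities shown once per run at one of 4
# quadrant locations, 12 runs, TR 2 s, one stimulus every 8.5 s, with
# controllable semantic / identity / location representational structure and
# a canonical double-gamma hemodynamic response.

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response minus undershoot), normalized
#' to peak 1. With the defaults the response peaks near 5-6 s and the
#' undershoot near 15 s.
#'
#' @param t Time points in seconds (values < 0 return 0).
#' @param peak Shape of the response gamma (default 6).
#' @param undershoot Shape of the undershoot gamma (default 16).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @return Numeric vector of HRF values.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1/6) {
  h <- ifelse(t <= 0, 0,
              stats::dgamma(t, shape = peak, rate = 1) -
                ratio * stats::dgamma(t, shape = undershoot, rate = 1))
  tg <- seq(0, 32, by = 0.05)
  hmax <- max(stats::dgamma(tg, shape = peak, rate = 1) -
                ratio * stats::dgamma(tg, shape = undershoot, rate = 1))
  h / hmax
}

#' Synthetic concept-feature matrix
#'
#' Binary entity x feature applicability matrix with category block
#' structure, emulating feature-generation norms: entities of a category
#' share elevated applicability probability on that category's feature block,
#' so within-category semantic similarity exceeds between-category
#' similarity. Every entity is guaranteed at least one applicable feature.
#'
#' @param n_entities Number of entities (default 24).
#' @param n_features Number of features (default 64).
#' @param n_categories Number of equal-sized categories (default 2).
#' @param p_within,p_between Applicability probabilities for own-category vs
#'   other-category feature blocks.
#' @param seed Integer seed.
#' @return Binary matrix with entity rownames and feature colnames.
#' @export
synthetic_concept_features <- function(n_entities = 24, n_features = 64,
                                       n_categories = 2, p_within = 0.45,
                                       p_between = 0.15, seed = 1L) {
  with_seed(seed, {
    ent <- sprintf("ent%02d", seq_len(n_entities))
    feat <- sprintf("feat%03d", seq_len(n_features))
    cat_of_ent <- rep(seq_len(n_categories), length.out = n_entities)
    cat_of_feat <- rep(seq_len(n_categories), length.out = n_features)
    p <- ifelse(outer(cat_of_ent, cat_of_feat, `==`), p_within, p_between)
    m <- matrix(stats::rbinom(length(p), 1, p), n_entities,
                dimnames = list(ent, feat))
    for (i in which(rowSums(m) == 0)) m[i, sample.int(n_features, 1)] <- 1
    m
  })
}

#' Generator configuration
#'
#' Holds the stated experimental design (defaults: 12 runs of 24 entities,
#' one presentation each, 4 counterbalanced quadrant locations, TR 2 s, one
#' stimulus every 8.5 s emulating cue + 150 ms stimulus + 8,050 ms
#' intertrial interval) plus the knobs that control representational
#' structure: pattern-amplitude gains for semantic structure, object
#' identity, and location, and the noise levels.
#'
#' @param n_subjects Number of subjects (default 31, the main-experiment
#'   cohort size).
#' @param n_runs Runs per subject (default 12); must be a multiple of
#'   `n_locations` for exact counterbalancing.
#' @param n_entities Entities (default 24).
#' @param n_locations Stimulus locations (default 4 quadrants).
#' @param n_voxels Voxels in the simulated region (default 200, a typical
#'   volume-of-interest size).
#' @param tr Repetition time in seconds (default 2).
#' @param isi Onset-to-onset interval in seconds (default 8.5).
#' @param model Target `similarity_matrix` over the entities whose geometry
#'   the semantic patterns embed; default: semantic similarity of a
#'   seed-derived synthetic concept-feature matrix.
#' @param semantic_gain,identity_gain,location_gain Pattern amplitude
#'   multipliers (>= 0). Semantic patterns share the model matrix geometry;
#'   identity patterns are entity-unique; location patterns are
#'   location-unique and add to every trial at that location.
#' @param noise_sd Trial-unique amplitude noise SD.
#' @param temporal_noise_sd Scan-level noise SD (default `0.5 * noise_sd`).
#' @param ar1_phi AR(1) coefficient of the temporal noise (default 0.3).
#' @param hrf_peak,hrf_undershoot,hrf_ratio Double-gamma response parameters.
#' @param mirror_half Generate the mirrored-presentation metadata flag on
#'   half of each entity's trials (no signal contribution).
#' @param seed Master seed; the dataset is a deterministic function of the
#'   config.
#' @return A validated `generator_config`.
#' @export
generator_config <- function(n_subjects = 31, n_runs = 12, n_entities = 24,
                             n_locations = 4, n_voxels = 200, tr = 2,
                             isi = 8.5, model = NULL,
                             semantic_gain = 1, identity_gain = 0,
                             location_gain = 0, noise_sd = 1,
                             temporal_noise_sd = NULL, ar1_phi = 0.3,
                             hrf_peak = 6, hrf_undershoot = 16,
                             hrf_ratio = 1/6, mirror_half = FALSE,
                             seed = 1L) {
  counts <- c(n_subjects = n_subjects, n_runs = n_runs,
              n_entities = n_entities, n_locations = n_locations,
              n_voxels = n_voxels)
  if (any(counts < 1)) stopf("all design counts must be >= 1")
  if (tr <= 0) stopf("TR must be > 0")
  if (isi < tr) stopf("stimulus interval %.3g s too short for TR %.3g s", isi, tr)
  gains <- c(semantic_gain, identity_gain, location_gain, noise_sd)
  if (any(gains < 0)) stopf("gains and noise_sd must be >= 0")
  if (n_runs %% n_locations != 0) {
    stopf("n_runs (%d) must be a multiple of n_locations (%d) for exact counterbalancing",
          n_runs, n_locations)
  }
  if (is.null(model)) {
    model <- semantic_similarity_matrix(
      synthetic_concept_features(n_entities, seed = seed + 1000L)
    )
  }
  stopifnot(inherits(model, "similarity_matrix"))
  if (length(model$labels) != n_entities) {
    stopf("model matrix has %d labels but n_entities = %d",
          length(model$labels), n_entities)
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_runs = as.integer(n_runs),
         n_entities = as.integer(n_entities),
         n_locations = as.integer(n_locations),
         n_voxels = as.integer(n_voxels), tr = tr, isi = isi, model = model,
         semantic_gain = semantic_gain, identity_gain = identity_gain,
         location_gain = location_gain, noise_sd = noise_sd,
         temporal_noise_sd = temporal_noise_sd %||% (0.5 * noise_sd),
         ar1_phi = ar1_phi, hrf_peak = hrf_peak,
         hrf_undershoot = hrf_undershoot, hrf_ratio = hrf_ratio,
         mirror_half = isTRUE(mirror_half), seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Entity patterns realizing a target similarity geometry
#'
#' Draws an entity x voxel pattern matrix `gain * L %*% Z` where `L` is a
#' symmetric square root of the model similarity matrix (eigendecomposition;
#' small negative eigenvalues from rounding are clipped at zero) and `Z` is
#' standard normal. The expected pattern Gram matrix is then proportional to
#' the model matrix, so the similarity structure the RSA stage tests for is
#' true by construction.
#'
#' @param model A positive semi-definite `similarity_matrix`.
#' @param n_voxels Number of voxels.
#' @param gain Amplitude multiplier (>= 0); 0 yields the zero matrix.
#' @param seed Integer seed.
#' @return Entity x voxel matrix with the model's labels as rownames.
#' @export
make_entity_patterns <- function(model, n_voxels, gain = 1, seed = 1L) {
  stopifnot(inherits(model, "similarity_matrix"))
  eig <- eigen(model$values, symmetric = TRUE)
  tol <- 1e-6 * max(abs(eig$values), 1)
  if (min(eig$values) < -tol) {
    stopf("model matrix is not positive semi-definite (min eigenvalue %.3g); project it to the nearest PSD matrix first",
          min(eig$values))
  }
  lam <- pmax(eig$values, 0)
  L <- eig$vectors %*% (sqrt(lam) * t(eig$vectors))
  n <- length(model$labels)
  Z <- with_seed(seed, matrix(stats::rnorm(n * n_voxels), n, n_voxels))
  out <- gain * (L %*% Z)
  rownames(out) <- model$labels
  out
}

# Counterbalanced location assignment: each entity sees every location
# exactly n_runs / n_locations times, in random run order.
counterbalanced_locations <- function(n_runs, n_entities, n_locations) {
  vapply(seq_len(n_entities), function(e) {
    sample(rep(seq_len(n_locations), n_runs / n_locations))
  }, integer(n_runs))                              # run x entity
}

#' Generate a multi-subject event-related dataset
#'
#' Per trial, the amplitude vector is the entity's semantic pattern plus its
#' identity pattern plus the location pattern plus trial-unique white noise;
#' amplitudes are convolved with the double-gamma response on the scan grid,
#' and AR(1) temporal noise is added. Entity order is randomized per run;
#' locations are counterbalanced across runs per entity. The dataset is a
#' deterministic function of `cfg` (bit-identical regeneration under the
#' same seed).
#'
#' @param cfg A `generator_config`.
#' @return List with `timeseries` (per subject, a list of per-run
#'   `voxel_timeseries`), `trials` (one `trial_table` covering all
#'   subjects), and `truth` (per-subject ground-truth patterns and the
#'   realized pattern-similarity matrix).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  lead_in <- 2
  tail_pad <- 10
  last_onset <- lead_in + (cfg$n_entities - 1) * cfg$isi
  n_scans <- ceiling((last_onset + tail_pad) / cfg$tr) + 1L
  frame_t <- (seq_len(n_scans) - 1) * cfg$tr
  onsets <- lead_in + (seq_len(cfg$n_entities) - 1) * cfg$isi
  # onsets are identical in every run, so the convolution design is shared
  X <- vapply(onsets, function(o) {
    hrf_double_gamma(frame_t - o, peak = cfg$hrf_peak,
                     undershoot = cfg$hrf_undershoot, ratio = cfg$hrf_ratio)
  }, numeric(n_scans))
  seeds <- split_seed(cfg$seed, cfg$n_subjects + 1L)
  entities <- cfg$model$labels
  categories <- stats::setNames(
    rep(c("instruments", "vehicles"), length.out = cfg$n_entities), entities)

  timeseries <- vector("list", cfg$n_subjects)
  truth <- vector("list", cfg$n_subjects)
  trial_rows <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    sub_id <- sprintf("sub%02d", s)
    sub <- with_seed(seeds[s], {
      E_sem <- make_entity_patterns(cfg$model, cfg$n_voxels,
                                    gain = cfg$semantic_gain,
                                    seed = sample.int(.Machine$integer.max, 1))
      E_id <- cfg$identity_gain *
        matrix(stats::rnorm(cfg$n_entities * cfg$n_voxels), cfg$n_entities,
               dimnames = list(entities, NULL))
      P_loc <- cfg$location_gain *
        matrix(stats::rnorm(cfg$n_locations * cfg$n_voxels), cfg$n_locations)
      loc_assign <- counterbalanced_locations(cfg$n_runs, cfg$n_entities,
                                              cfg$n_locations)
      runs <- vector("list", cfg$n_runs)
      rows <- vector("list", cfg$n_runs)
      for (r in seq_len(cfg$n_runs)) {
        ord <- sample.int(cfg$n_entities)           # entity order in this run
        loc <- loc_assign[r, ord]
        amp <- E_sem[ord, , drop = FALSE] + E_id[ord, , drop = FALSE] +
          P_loc[loc, , drop = FALSE] +
          cfg$noise_sd * matrix(stats::rnorm(cfg$n_entities * cfg$n_voxels),
                                cfg$n_entities)
        Y <- X %*% amp
        if (cfg$temporal_noise_sd > 0) {
          eps <- matrix(stats::rnorm(n_scans * cfg$n_voxels), n_scans)
          if (cfg$ar1_phi > 0) {
            eps <- matrix(stats::filter(eps * sqrt(1 - cfg$ar1_phi^2),
                                        cfg$ar1_phi, method = "recursive"),
                          n_scans)
          }
          Y <- Y + cfg$temporal_noise_sd * eps
        }
        runs[[r]] <- voxel_timeseries(Y, tr = cfg$tr, run = r)
        rows[[r]] <- data.frame(
          subject = sub_id, run = r, onset = onsets,
          entity = entities[ord], category = categories[entities[ord]],
          location = loc,
          size = ((r - 1L) %% 3L) + 1L,
          mirrored = if (cfg$mirror_half) (r %% 2L) == 0L else FALSE
        )
      }
      E_total <- E_sem + E_id
      realized <- if (any(E_total != 0)) {
        cosine_similarity_matrix(E_total,
                                 meta = list(source = "ground_truth"))
      } else NULL
      list(runs = runs, rows = do.call(rbind, rows),
           truth = list(entity_patterns = E_total,
                        semantic_patterns = E_sem,
                        identity_patterns = E_id,
                        location_patterns = P_loc,
                        realized = realized, seed = seeds[s]))
    })
    timeseries[[s]] <- sub$runs
    truth[[s]] <- sub$truth
    trial_rows[[s]] <- sub$rows
  }
  names(timeseries) <- names(truth) <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  list(timeseries = timeseries,
       trials = trial_table(do.call(rbind, trial_rows),
                            locations = seq_len(cfg$n_locations)),
       truth = truth,
       config = cfg)
}

#' Run the full analysis on a generated (or equivalent) dataset
#'
#' Convenience core shared by the pipeline, the power/recovery report and
#' the tests: extracts BOLD-integral patterns per subject, builds per-subject
#' and group similarity matrices, and computes the requested statistics.
#'
#' @param ds A dataset as returned by [generate_dataset()].
#' @param model Model `similarity_matrix` for the RSA stage (default: the
#'   generator's target matrix).
#' @param statistics Subset of `c("rsa", "identity", "location")`.
#' @param n_perm Permutations per test.
#' @param seed Master analysis seed.
#' @param window,substep Passed to [extract_patterns()].
#' @param regress Apply [nuisance_regress()] (intercept + drift) before
#'   integration (default FALSE; the generator adds no drift).
#' @return List with `patterns` (per-subject `response_patterns`),
#'   `subject_matrices`, `group_matrix`, and one `perm_result` per requested
#'   statistic.
#' @export
analyze_dataset <- function(ds, model = NULL,
                            statistics = c("rsa", "identity", "location"),
                            n_perm = 1000, seed = 1L, window = c(2, 8),
                            substep = 0.1, regress = FALSE) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  model <- model %||% ds$config$model
  subjects <- unique(ds$trials$subject)
  seeds <- split_seed(seed, 3L)
  patterns <- lapply(seq_along(subjects), function(s) {
    tt_s <- ds$trials[ds$trials$subject == subjects[s], , drop = FALSE]
    class(tt_s) <- class(ds$trials)
    ts_list <- ds$timeseries[[s]]
    if (regress) ts_list <- lapply(ts_list, nuisance_regress)
    extract_patterns(ts_list, tt_s, window = window, substep = substep)
  })
  names(patterns) <- subjects
  out <- list(patterns = patterns)
  if ("rsa" %in% statistics) {
    out$subject_matrices <- lapply(patterns, fmri_similarity_matrix)
    out$group_matrix <- group_average_matrix(out$subject_matrices)
    out$rsa <- rsa_test(out$group_matrix, model, n_perm = n_perm,
                        seed = seeds[1])
  }
  if ("identity" %in% statistics) {
    out$identity <- identity_statistic(patterns, n_perm = n_perm,
                                       seed = seeds[2])
  }
  if ("location" %in% statistics) {
    out$location <- location_statistic(patterns, n_perm = n_perm,
                                       seed = seeds[3])
  }
  out
}

#' Power / parameter-recovery report over an effect-size grid
#'
#' Runs the full generate-extract-test pipeline repeatedly per effect-size
#' level and reports one-tailed rejection rates at alpha for each requested
#' statistic, plus the mean observed statistic.
#'
#' @param gains Numeric vector of effect-size levels (>= 2 values).
#' @param gain_field Which gain the grid varies: `"semantic_gain"`,
#'   `"identity_gain"` or `"location_gain"`.
#' @param n_replicates Replicates per level (>= 20 for a stable rate).
#' @param cfg_base `generator_config` providing all other parameters.
#' @param statistics Statistics to evaluate.
#' @param n_perm Permutations per test.
#' @param alpha Rejection threshold (default 0.05).
#' @param seed Master seed (split per level and replicate).
#' @return Data frame: `gain`, `statistic`, `rejection_rate`,
#'   `mean_observed`, `n_replicates`.
#' @export
recovery_report <- function(gains, gain_field = "semantic_gain",
                            n_replicates = 20, cfg_base = generator_config(),
                            statistics = c("rsa", "identity", "location"),
                            n_perm = 200, alpha = 0.05, seed = 1L) {
  if (length(gains) < 2L) stopf("need at least 2 effect-size levels")
  if (n_replicates < 20L) stopf("need at least 20 replicates per level")
  gain_field <- match.arg(gain_field,
                          c("semantic_gain", "identity_gain", "location_gain"))
  statistics <- match.arg(statistics, several.ok = TRUE)
  seeds <- matrix(split_seed(seed, length(gains) * n_replicates),
                  n_replicates)
  rows <- list()
  for (g in seq_along(gains)) {
    p_mat <- matrix(NA_real_, n_replicates, length(statistics),
                    dimnames = list(NULL, statistics))
    obs_mat <- p_mat
    for (rep_i in seq_len(n_replicates)) {
      cfg_args <- unclass(cfg_base)
      cfg_args[[gain_field]] <- gains[g]
      cfg_args$temporal_noise_sd <- cfg_base$temporal_noise_sd
      cfg_args$seed <- seeds[rep_i, g]
      cfg <- do.call(generator_config, cfg_args[names(cfg_args) %in%
                                                  names(formals(generator_config))])
      ds <- generate_dataset(cfg)
      an <- analyze_dataset(ds, statistics = statistics, n_perm = n_perm,
                            seed = seeds[rep_i, g] + 1L)
      for (st in statistics) {
        p_mat[rep_i, st] <- an[[st]]$p
        obs_mat[rep_i, st] <- an[[st]]$observed
      }
    }
    rows[[g]] <- data.frame(
      gain = gains[g], statistic = statistics,
      rejection_rate = colMeans(p_mat < alpha),
      mean_observed = colMeans(obs_mat),
      n_replicates = n_replicates, row.names = NULL
    )
  }
  do.call(rbind, rows)
}
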