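# Readers and writers for the package's plain-text interfaces: similarity
# matrices (CSV), events tables (BIDS-style TSV), concept-feature matrices,
# transcriptions, encoder-layer sets, and mask index lists. All round-trip
# losslessly within documented precision.

#' Write a similarity matrix as labeled CSV
#'
#' Labels appear as both header and first column; values are written with 10
#' significant digits.
#'
#' @param x A `similarity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_similarity_csv <- function(x, path) {
  stopifnot(inherits(x, "similarity_matrix"))
  df <- data.frame(label = x$labels,
                   signif(x$values, 10), check.names = FALSE)
  colnames(df) <- c("label", x$labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a similarity matrix written by [write_similarity_csv()]
#'
#' @param path CSV path (labels as header and first column).
#' @param source Provenance tag stored in `meta$source`.
#' @return A `similarity_matrix`.
#' @export
read_similarity_csv <- function(path, source = "file") {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(vals), labels)) {
    stopf("'%s': header labels do not match first-column labels", path)
  }
  storage.mode(vals) <- "double"
  similarity_matrix(vals, labels, meta = list(source = source, path = path))
}

#' Write an events table as BIDS-style TSV
#'
#' @param tt A `trial_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(tt, path) {
  stopifnot(inherits(tt, "trial_table"))
  utils::write.table(as.data.frame(tt), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read and validate an events TSV
#'
#' Columns `subject`, `run`, `onset`, `entity`, `location` are required
#' (`category`, `size`, `mirrored` optional). Malformed rows are reported
#' with their line numbers; the trial-table invariants (strictly increasing
#' onsets, one presentation of each entity per run, declared locations) are
#' enforced.
#'
#' @param path TSV path.
#' @param locations Declared location set (default `1:4`).
#' @return A `trial_table`.
#' @export
read_events_tsv <- function(path, locations = 1:4) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  bad <- which(is.na(suppressWarnings(as.numeric(df$onset))))
  if (length(bad)) {
    stopf("'%s': malformed onset at line(s) %s", path,
          paste(bad + 1L, collapse = ", "))
  }
  trial_table(df, locations = locations)
}

#' Read a concept-feature matrix CSV
#'
#' First column = entity label, header row = feature labels, cells numeric.
#'
#' @param path CSV path.
#' @return Numeric entity x feature matrix.
#' @export
read_concept_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read phonetic transcriptions from a 2-column TSV
#'
#' @param path TSV path: label, transcription (UTF-8, one symbol per code
#'   point).
#' @return Named character vector.
#' @export
read_transcriptions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stopf("'%s': expected 2 columns (label, transcription)", path)
  stats::setNames(df[[2]], df[[1]])
}

#' Read an encoder layer set via an ordered manifest
#'
#' The manifest is a 2-column TSV (layer name, CSV path relative to the
#' manifest) listing layers in order; each CSV has the stimulus label in its
#' first column.
#'
#' @param manifest Manifest TSV path.
#' @return Named list of stimulus x dimension matrices, in manifest order.
#' @export
read_layer_set <- function(manifest) {
  mf <- utils::read.delim(manifest, stringsAsFactors = FALSE, header = TRUE)
  if (ncol(mf) < 2L) stopf("'%s': expected columns (layer, path)", manifest)
  base <- dirname(manifest)
  layers <- lapply(mf[[2]], function(p) {
    df <- utils::read.csv(file.path(base, p), check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE]); storage.mode(m) <- "double"
    rownames(m) <- as.character(df[[1]])
    m
  })
  stats::setNames(layers, mf[[1]])
}

#' Write a mask as a voxel index list TSV
#'
#' Header comment lines carry the grid dimensions and affine; body rows are
#' 0-based `i j k` indices (file convention; in-memory indices are 1-based).
#'
#' @param mask A `voi_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask_tsv <- function(mask, path) {
  stopifnot(inherits(mask, "voi_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# name: %s", mask$name),
    sprintf("# dim: %s", paste(mask$grid$dim, collapse = " ")),
    sprintf("# affine: %s",
            paste(format(t(mask$grid$affine), digits = 17), collapse = " ")),
    "i\tj\tk"
  ), con)
  utils::write.table(mask$indices - 1L, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a mask index list written by [write_mask_tsv()]
#'
#' @param path TSV path.
#' @return A `voi_mask`.
#' @export
read_mask_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stopf("'%s': missing '# %s:' header", path, key)
    sub(paste0("^# ", key, ": *"), "", ln[1])
  }
  dim_ <- as.integer(strsplit(get_field("dim"), " +")[[1]])
  aff <- matrix(as.numeric(strsplit(get_field("affine"), " +")[[1]]),
                4, 4, byrow = TRUE)
  body <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]))
  voi_mask(as.matrix(body) + 1L, voi_grid(dim_, affine = aff),
           name = get_field("name"), provenance = list(kind = "file",
                                                       path = path))
}

#' Write a mask as a binary NIfTI volume
#'
#' @param mask A `voi_mask`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_nifti <- function(mask, path) {
  vol <- array(0L, mask$grid$dim)
  vol[mask$indices] <- 1L
  write_nifti(vol, path, affine = mask$grid$affine, datatype = "uint8")
  invisible(path)
}

#' Read a binary NIfTI volume as a mask
#'
#' Nonzero voxels become the mask; the sform affine defines the grid.
#'
#' @param path NIfTI path.
#' @param name Mask name.
#' @return A `voi_mask`.
#' @export
read_mask_nifti <- function(path, name = basename(path)) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L) stopf("'%s': mask must be 3D", path)
  idx <- which(nii$data != 0, arr.ind = TRUE)
  voi_mask(idx, voi_grid(dim(nii$data), affine = nii$affine), name = name,
           provenance = list(kind = "file", path = path))
}

#' Write one run's voxel time series as a 4D NIfTI
#'
#' Voxels are laid out along the first axis (n_voxels x 1 x 1 x time), the
#' standard flat layout for masked data; TR is stored in pixdim.
#'
#' @param ts A `voxel_timeseries`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_timeseries_nifti <- function(ts, path) {
  stopifnot(inherits(ts, "voxel_timeseries"))
  vol <- array(t(ts$values), c(ncol(ts$values), 1L, 1L, nrow(ts$values)))
  write_nifti(vol, path, tr = ts$tr, datatype = "float64")
  invisible(path)
}

#' Read a 4D NIfTI written by [write_timeseries_nifti()]
#'
#' @param path NIfTI path.
#' @param run Run identifier to attach.
#' @return A `voxel_timeseries`.
#' @export
read_timeseries_nifti <- function(path, run = 1L) {
  nii <- read_nifti(path)
  d <- dim(nii$data)
  if (length(d) != 4L) stopf("'%s': expected a 4D time series", path)
  vals <- t(matrix(nii$data, prod(d[1:3]), d[4]))
  voxel_timeseries(vals, tr = nii$tr, run = run)
}

#' Write a generated dataset through the public file interfaces
#'
#' Produces a directory with one events TSV covering all subjects, the model
#' similarity matrix CSV, per-subject/run 4D NIfTI time series, ground-truth
#' CSVs, and a JSON manifest of generator parameters and seed.
#'
#' @param ds Dataset from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_events_tsv(ds$trials, file.path(dir, "events.tsv"))
  write_similarity_csv(ds$config$model, file.path(dir, "model.csv"))
  for (s in names(ds$timeseries)) {
    sdir <- file.path(dir, s)
    dir.create(sdir, showWarnings = FALSE)
    for (ts in ds$timeseries[[s]]) {
      write_timeseries_nifti(ts, file.path(sdir, sprintf("run%02d.nii.gz",
                                                         as.integer(ts$run))))
    }
    truth <- ds$truth[[s]]
    utils::write.csv(truth$entity_patterns,
                     file.path(sdir, "truth_entity_patterns.csv"))
    utils::write.csv(truth$location_patterns,
                     file.path(sdir, "truth_location_patterns.csv"),
                     row.names = FALSE)
  }
  cfg <- ds$config
  manifest <- list(
    n_subjects = cfg$n_subjects, n_runs = cfg$n_runs,
    n_entities = cfg$n_entities, n_locations = cfg$n_locations,
    n_voxels = cfg$n_voxels, tr = cfg$tr, isi = cfg$isi,
    semantic_gain = cfg$semantic_gain, identity_gain = cfg$identity_gain,
    location_gain = cfg$location_gain, noise_sd = cfg$noise_sd,
    temporal_noise_sd = cfg$temporal_noise_sd, ar1_phi = cfg$ar1_phi,
    seed = cfg$seed
  )
  jsonlite::write_json(manifest, file.path(dir, "generator.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List with `trials`, `timeseries`, `model`, and the generator
#'   manifest as `config` (list form).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "generator.json"),
                                  simplifyVector = TRUE)
  trials <- read_events_tsv(file.path(dir, "events.tsv"),
                            locations = seq_len(manifest$n_locations))
  model <- read_similarity_csv(file.path(dir, "model.csv"), source = "model")
  subjects <- unique(trials$subject)
  timeseries <- lapply(subjects, function(s) {
    files <- sort(list.files(file.path(dir, s), pattern = "^run.*\\.nii",
                             full.names = TRUE))
    lapply(files, function(f) {
      read_timeseries_nifti(f, run = as.integer(gsub("\\D", "", basename(f))))
    })
  })
  names(timeseries) <- subjects
  list(trials = trials, timeseries = timeseries, model = model,
       config = manifest)
}
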