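#' Trial/events table
#'
#' One row per stimulus presentation with the design factors of an
#' event-related run: subject, run, onset (seconds from run start), entity
#' (the concept shown), category, location (screen quadrant 1..4 by default),
#' size code, and mirrored flag.
#'
#' Validated invariants: onsets strictly increasing within each (subject,
#' run); each (subject, run, entity) occurs at most once (one presentation of
#' each entity per run); locations drawn from the declared set.
#'
#' @param df Data frame with columns `subject`, `run`, `onset`, `entity`,
#'   `category`, `location`, `size`, `mirrored` (the last three optional,
#'   defaulted).
#' @param locations Declared location set (default `1:4`, the quadrants).
#' @return A validated `trial_table` (a data.frame subclass).
#' @export
trial_table <- function(df, locations = 1:4) {
  df <- as.data.frame(df)
  needed <- c("subject", "run", "onset", "entity", "location")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stopf("events table lacks column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$category)) df$category <- "unspecified"
  if (is.null(df$size)) df$size <- 1L
  if (is.null(df$mirrored)) df$mirrored <- FALSE
  df$subject <- as.character(df$subject)
  df$run <- as.integer(df$run)
  df$onset <- as.numeric(df$onset)
  df$entity <- as.character(df$entity)
  df$category <- as.character(df$category)
  df$location <- as.integer(df$location)
  df$mirrored <- as.logical(df$mirrored)
  if (any(is.na(df$onset)) || any(is.na(df$location))) {
    stopf("events table contains missing onsets or locations")
  }
  bad_loc <- !df$location %in% locations
  if (any(bad_loc)) {
    stopf("location outside declared set {%s} at row(s) %s",
          paste(locations, collapse = ","),
          paste(which(bad_loc), collapse = ", "))
  }
  for (key in split(seq_len(nrow(df)), paste(df$subject, df$run))) {
    on <- df$onset[key]
    if (is.unsorted(on, strictly = TRUE)) {
      stopf("onsets not strictly increasing within subject %s run %d",
            df$subject[key[1]], df$run[key[1]])
    }
    dup <- duplicated(df$entity[key])
    if (any(dup)) {
      stopf("entity '%s' repeated within subject %s run %d",
            df$entity[key][dup][1], df$subject[key[1]], df$run[key[1]])
    }
  }
  rownames(df) <- NULL
  attr(df, "locations") <- locations
  class(df) <- c("trial_table", "data.frame")
  df
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> %d trials, %d subject(s), %d run(s), %d entities\n",
              nrow(x), length(unique(x$subject)), length(unique(x$run)),
              length(unique(x$entity))))
  NextMethod()
}
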