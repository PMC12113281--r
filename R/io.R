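# Trial-table interchange: plain tab-separated text with a header, one row
# per trial. No domain-standard container exists for trial-wise spike
# counts at this granularity, so delimited text is the interchange format.

TRIAL_COLUMNS <- c("unit_id", "region", "subject", "experiment", "pose",
                   "part", "body_orientation", "head_orientation",
                   "anchor_angle", "centering", "inversion", "trial_index",
                   "baseline100_count", "baseline200_count",
                   "response_count")

#' Validate a trial table
#'
#' Checks the schema used throughout the package: required columns present,
#' counts nonnegative integers, orientations on the 45-degree grid (or
#' missing, per part), parts/centerings/inversions from their vocabularies,
#' and uniqueness of (unit, condition, trial_index). Errors name the first
#' offending row and column.
#'
#' @param trials data frame to validate.
#' @return the validated table, invisibly.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- function(which, col) {
    if (any(which)) {
      stop(sprintf("invalid value in column '%s' at row %d", col,
                   utils::head(base::which(which), 1)))
    }
  }
  for (col in c("baseline100_count", "baseline200_count", "response_count",
                "trial_index")) {
    x <- trials[[col]]
    bad(is.na(x) | x < 0 | x != round(x), col)
  }
  bad(!trials$part %in% c("monkey", "head", "body"), "part")
  bad(!trials$centering %in% c("MC", "HC"), "centering")
  bad(!trials$inversion %in% c("upright", "inverted"), "inversion")
  for (col in c("body_orientation", "head_orientation")) {
    x <- trials[[col]]
    bad(!is.na(x) & !(x %% 45 == 0 & x >= 0 & x < 360), col)
  }
  bad(trials$part == "monkey" &
        (is.na(trials$body_orientation) | is.na(trials$head_orientation)),
      "body_orientation")
  bad(trials$part == "head" & !is.na(trials$body_orientation),
      "body_orientation")
  bad(trials$part == "body" & !is.na(trials$head_orientation),
      "head_orientation")
  key <- paste(trials$unit_id, condition_key(trials), trials$trial_index)
  if (anyDuplicated(key)) {
    stop("duplicated (unit, condition, trial_index) at row ",
         which(duplicated(key))[1])
  }
  invisible(trials)
}

#' Read a trial table from tab-separated text
#'
#' @param path file path.
#' @return validated trial table (unknown columns are preserved).
#' @export
read_trials <- function(path) {
  tr <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA", check.names = FALSE)
  for (col in c("body_orientation", "head_orientation", "anchor_angle",
                "angle")) {
    if (col %in% names(tr)) tr[[col]] <- as.integer(tr[[col]])
  }
  validate_trials(tr)
  tr
}

#' Write a trial table to tab-separated text
#'
#' @param trials trial table (validated before writing).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
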