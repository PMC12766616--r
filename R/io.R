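#' Write a cohort to delimited text tables
#'
#' Persists a [simulate_cohort()] result (or an equivalent list) as
#' comma-delimited UTF-8 tables with header rows: `participants.csv`,
#' `strain.csv` (long format), `outcomes.csv`, `ledger.csv`, plus the
#' generator configuration as `config.json` (seed included).
#'
#' @param cohort A `strain_cohort` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(cohort$participants, file.path(dir, "participants.csv"))
  readr::write_csv(cohort$strain, file.path(dir, "strain.csv"))
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"))
  if (!is.null(cohort$ledger))
    readr::write_csv(cohort$ledger, file.path(dir, "ledger.csv"))
  if (!is.null(cohort$config))
    jsonlite::write_json(unclass(cohort$config),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read cohort tables from delimited text
#'
#' Loads the participant/covariate table, the strain table and (optionally)
#' the outcome table. The strain table is accepted in long dialect
#' (`participant_id, direction, segment, value`) or wide dialect
#' (`participant_id` plus 16 columns per direction named like
#' `longitudinal_1` .. `radial_16`), auto-detected. Unparseable numeric
#' cells become missing with a logged count.
#'
#' @param participants_path,strain_path,outcomes_path CSV file paths
#'   (`outcomes_path` optional).
#' @return A `strain_cohort` list with tibbles `participants`, `strain`
#'   and (when supplied) `outcomes`.
#' @export
read_cohort_tables <- function(participants_path, strain_path,
                               outcomes_path = NULL) {
  read_checked <- function(path) {
    x <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
    prob <- readr::problems(x)
    if (nrow(prob) > 0)
      message(nrow(prob), " malformed cell(s) in ", basename(path),
              " read as missing")
    x
  }
  participants <- read_checked(participants_path)
  if (!"participant_id" %in% names(participants))
    abort("participants table lacks mandatory column `participant_id`")
  strain_raw <- read_checked(strain_path)
  strain <- normalize_strain_table(strain_raw)
  dup <- strain %>%
    dplyr::count(.data$participant_id, .data$direction, .data$segment) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort("duplicate participant-direction-segment rows in strain table")
  out <- list(participants = participants, strain = strain)
  if (!is.null(outcomes_path)) {
    outcomes <- read_checked(outcomes_path)
    need <- c("participant_id", "endpoint", "time", "event", "prevalent")
    missing_cols <- setdiff(need, names(outcomes))
    if (length(missing_cols))
      abort(paste0("outcomes table lacks mandatory column(s): ",
                   paste(missing_cols, collapse = ", ")))
    out$outcomes <- outcomes %>%
      mutate(event = as.logical(.data$event),
             prevalent = as.logical(.data$prevalent))
  }
  structure(out, class = "strain_cohort")
}

# accept long (participant_id, direction, segment, value) or wide
# (participant_id + <direction>_<segment> columns) strain dialects
normalize_strain_table <- function(strain) {
  to_num <- function(v) {
    if (is.numeric(v)) return(v)
    num <- suppressWarnings(as.numeric(v))
    n_bad <- sum(is.na(num) & !is.na(v) & v != "")
    if (n_bad > 0)
      message(n_bad, " malformed strain cell(s) read as missing")
    num
  }
  long_cols <- c("participant_id", "direction", "segment", "value")
  if (all(long_cols %in% names(strain))) {
    return(strain %>%
             select(dplyr::all_of(long_cols)) %>%
             mutate(segment = as.integer(.data$segment),
                    value = to_num(.data$value)))
  }
  wide_pat <- "^(longitudinal|circumferential|radial)_([1-9]|1[0-6])$"
  wide_cols <- grep(wide_pat, names(strain), value = TRUE)
  if (!"participant_id" %in% names(strain) || length(wide_cols) == 0)
    abort(paste0("strain table is neither long (needs columns ",
                 paste(long_cols, collapse = ", "),
                 ") nor wide (needs participant_id + direction_segment ",
                 "columns)"))
  strain %>%
    select("participant_id", dplyr::all_of(wide_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(wide_cols),
                        names_to = c("direction", "segment"),
                        names_pattern = "^(.*)_([0-9]+)$",
                        values_to = "value") %>%
    mutate(segment = as.integer(.data$segment),
           value = to_num(.data$value)) %>%
    arrange(.data$participant_id, .data$direction, .data$segment)
}
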