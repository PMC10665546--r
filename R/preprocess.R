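## Preprocessing rules of the interview design: "or"-rule combination of
## parent and child reports, exclusion of heavy-missingness subjects, removal
## of incomplete subject-weeks, and delimited-text round trips for all tables.

#' Combine parent and child symptom reports by the "or" rule
#'
#' Element-wise: a symptom is marked at the more severe of the two informants'
#' ratings (present if either endorses it). When the interviewer judges one
#' informant uninformed (e.g., the child was away), `override` privileges the
#' other informant and that informant's rating is taken as-is. A rating
#' missing on one side falls back to the other side; both missing yields
#' missing.
#'
#' @param parent,child integer vectors of ratings in 1..3 (NA = missing).
#' @param override `"none"` (default, maximum-severity rule), `"parent"` or
#'   `"child"` (take that informant's rating, falling back to the other only
#'   if it is missing).
#' @return integer vector of combined ratings.
#' @export
#' @examples
#' combine_informant_reports(c(2, 3, 1), c(1, 1, 1))           # or-rule
#' combine_informant_reports(3, 1, override = "child")         # summer camp
combine_informant_reports <- function(parent, child,
                                      override = c("none", "parent", "child")) {
  override <- match.arg(override)
  ok <- function(x) all(is.na(x) | (x %in% 1:3))
  if (!ok(parent) || !ok(child))
    stop("ratings must be in 1..3 or NA", call. = FALSE)
  out <- switch(override,
    none = pmax(parent, child, na.rm = TRUE),
    parent = ifelse(is.na(parent), child, parent),
    child = ifelse(is.na(child), parent, child))
  out[is.na(parent) & is.na(child)] <- NA
  as.integer(out)
}

#' Apply the study's missingness exclusions to a panel
#'
#' Two-stage filter: (1) subjects with strictly more than
#' `subject_missing_threshold` of their subject-weeks missing (a week counts
#' as missing when any rating in it is missing) are dropped entirely;
#' (2) remaining subject-weeks with any missing rating are removed. Week
#' indices of retained rows are kept, so removal creates gaps in the weekly
#' time base that the likelihood bridges.
#'
#' @param panel panel tibble (`subject_id`, `week`, rating columns).
#' @param subject_missing_threshold proportion in (0, 1\]; default 0.8.
#' @return list with `panel` (filtered tibble) and `report` (tibble:
#'   `subject_id`, `n_weeks`, `n_missing_weeks`, `excluded`), plus counts
#'   `n_rows_dropped` of incomplete rows removed from retained subjects.
#' @export
apply_exclusions <- function(panel, subject_missing_threshold = 0.8) {
  stopifnot(subject_missing_threshold > 0, subject_missing_threshold <= 1)
  sym_cols <- setdiff(names(panel), c("subject_id", "week"))
  row_missing <- rowSums(is.na(panel[sym_cols])) > 0

  report <- panel |>
    dplyr::mutate(.missing = row_missing) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(n_weeks = dplyr::n(),
                     n_missing_weeks = sum(.data$.missing),
                     .groups = "drop") |>
    dplyr::mutate(excluded =
      .data$n_missing_weeks / .data$n_weeks > subject_missing_threshold)

  keep_subjects <- report$subject_id[!report$excluded]
  kept <- panel[!row_missing & panel$subject_id %in% keep_subjects, ]
  n_rows_dropped <- sum(!row_missing & !(panel$subject_id %in% keep_subjects)) +
    sum(row_missing & panel$subject_id %in% keep_subjects)
  if (nrow(kept) == 0)
    stop("exclusion filtering removed every observation; ",
         "check the missingness pattern and threshold", call. = FALSE)
  list(panel = kept, report = report, n_rows_dropped = n_rows_dropped)
}

#' Validate a panel table against the rating schema
#' @noRd
validate_panel <- function(panel) {
  need <- c("subject_id", "week")
  if (!all(need %in% names(panel)))
    stop("panel must have subject_id and week columns", call. = FALSE)
  sym_cols <- setdiff(names(panel), need)
  if (!length(sym_cols)) stop("panel has no rating columns", call. = FALSE)
  for (col in sym_cols) {
    v <- panel[[col]]
    bad <- which(!is.na(v) & !(v %in% 1:3))
    if (length(bad))
      stop("invalid rating in column '", col, "', rows ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": ratings must be 1, 2, 3 or missing", call. = FALSE)
  }
  weeks_ok <- panel |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$week, strictly = TRUE),
                     .groups = "drop")
  if (!all(weeks_ok$ok))
    stop("weeks must be strictly increasing within subject: ",
         paste(weeks_ok$subject_id[!weeks_ok$ok], collapse = ", "),
         call. = FALSE)
  invisible(panel)
}

#' Read / write panel and companion tables as comma-separated text
#'
#' Missing ratings are written as empty fields. `read_panel()` validates the
#' schema (ratings in 1..3 or missing, weeks strictly increasing per subject)
#' and reports offending rows.
#'
#' @param path file path.
#' @param x tibble to write.
#' @return `read_panel` returns a validated tibble.
#' @export
read_panel <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  x$subject_id <- as.character(x$subject_id)
  validate_panel(x)
  x$week <- as.integer(x$week)
  for (col in setdiff(names(x), c("subject_id", "week")))
    x[[col]] <- as.integer(x[[col]])
  x
}

#' @rdname read_panel
#' @export
write_panel <- function(x, path) {
  validate_panel(x)
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname read_panel
#' @export
read_covariates <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "female", "age", "ethnoracial_minority")
  if (!all(need %in% names(x)))
    stop("covariate table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(duplicated(x$subject_id)))
    stop("covariate table must have one row per subject", call. = FALSE)
  if (any(x$age <= 0)) stop("age must be positive", call. = FALSE)
  if (!all(x$female %in% 0:1) || !all(x$ethnoracial_minority %in% 0:1))
    stop("female and ethnoracial_minority must be 0/1", call. = FALSE)
  x$subject_id <- as.character(x$subject_id)
  x
}

#' @rdname read_panel
#' @export
read_comorbidity <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "week", "disorder", "severity")
  if (!all(need %in% names(x)))
    stop("comorbidity table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(!is.na(x$severity) & !(x$severity %in% 1:6))
  if (length(bad))
    stop("severity outside 1..6 at rows ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  x$subject_id <- as.character(x$subject_id)
  x
}

#' @rdname read_panel
#' @export
write_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}
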