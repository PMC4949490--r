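# Cohort data: long-format trial records, validation, and CSV round-trip.

.group_levels <- c("entity", "incremental")

#' Construct and validate a performance cohort
#'
#' A cohort is a long-format tibble of repeated-trial performance records:
#' one row per individual and trial, with a fixed binary group label per
#' individual ("entity" or "incremental"). Performance scores are on the
#' task's percentage-of-budgeted-hours scale (norm near 100). Every
#' individual must have a score for every trial `1..T`, with `T >= 4` so at
#' least one spiral cut-point is admissible (spirals may not begin in the
#' last two trials).
#'
#' @param data A data frame with columns `individual`, `group`, `trial`,
#'   `score`.
#' @return A validated tibble with class `spiral_cohort`, ordered by
#'   individual then trial.
#' @examples
#' cohort <- as_cohort(tibble::tibble(
#'   individual = rep(1:2, each = 4),
#'   group = rep(c("entity", "incremental"), each = 4),
#'   trial = rep(1:4, 2),
#'   score = 100 + rnorm(8)
#' ))
#' cohort_dims(cohort)
#' @export
as_cohort <- function(data) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c("individual", "group", "trial", "score"),
                          names(data))
  if (length(missing_cols) > 0) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  out$individual <- as.character(out$individual)
  out$group <- as.character(out$group)
  bad_group <- setdiff(unique(out$group), .group_levels)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         "; expected 'entity' or 'incremental'", call. = FALSE)
  }
  if (!all(is.finite(out$score))) {
    stop("all scores must be finite", call. = FALSE)
  }
  out$trial <- as.integer(out$trial)
  n_trials <- max(out$trial)
  if (n_trials < 4) stop("need T >= 4 trials", call. = FALSE)

  # dense 1..T grid per individual
  grid <- dplyr::summarise(
    dplyr::group_by(out, .data$individual),
    missing = list(setdiff(seq_len(n_trials), .data$trial)),
    n_dup = sum(duplicated(.data$trial)),
    n_groups = dplyr::n_distinct(.data$group),
    .groups = "drop"
  )
  gaps <- tidyr::unnest(grid[c("individual", "missing")], "missing")
  if (nrow(gaps) > 0) {
    msg <- paste(sprintf("(%s, trial %d)", gaps$individual, gaps$missing),
                 collapse = ", ")
    stop("missing trials: ", msg, call. = FALSE)
  }
  if (any(grid$n_dup > 0)) {
    stop("duplicated trials for individual(s): ",
         paste(grid$individual[grid$n_dup > 0], collapse = ", "),
         call. = FALSE)
  }
  if (any(grid$n_groups != 1)) {
    stop("group label must be constant within individual", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$individual, .data$trial)
  class(out) <- c("spiral_cohort", class(out))
  out
}

#' Cohort dimensions
#'
#' @param cohort A cohort tibble (see [as_cohort()]).
#' @return A list with `J` (individuals), `T` (trials), `ids` and per-individual
#'   `group` labels (named character vector).
#' @export
cohort_dims <- function(cohort) {
  ids <- unique(cohort$individual)
  groups <- vapply(split(cohort$group, cohort$individual)[ids],
                   function(g) g[[1]], character(1))
  list(J = length(ids), T = max(cohort$trial), ids = ids, group = groups)
}

# J x T score matrix (rows = individuals in id order)
cohort_matrix <- function(cohort) {
  d <- cohort_dims(cohort)
  y <- matrix(NA_real_, d$J, d$T, dimnames = list(d$ids, NULL))
  y[cbind(match(cohort$individual, d$ids), cohort$trial)] <- cohort$score
  y
}

#' Read / write a cohort CSV
#'
#' Long-format CSV with header `individual,group,trial,score`; UTF-8.
#' `write_cohort()` then `read_cohort()` reproduces the cohort exactly.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated cohort tibble.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(
    individual = readr::col_character(),
    group = readr::col_character(),
    trial = readr::col_integer(),
    score = readr::col_double()
  ))
  as_cohort(raw)
}

#' @param cohort A cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort[c("individual", "group", "trial", "score")], path)
  invisible(path)
}

#' Score an 8-item implicit-theory-of-ability (ITA) questionnaire
#'
#' Items are Likert responses in 1..6 (1 = strongly agree, 6 = strongly
#' disagree), four worded as entity-type statements and four as
#' incremental-type. Incremental items are reverse scored (`v -> 7 - v`) and
#' the eight values averaged, so higher scores indicate a stronger
#' incremental theory of ability. The raw sum is reported alongside.
#'
#' @param items Data frame with one row per respondent-item: columns
#'   `individual`, `item` (1..8), `value` (1..6) and `polarity`
#'   (`"entity"` or `"incremental"`).
#' @return Tibble with one row per individual: `individual`, `ita_score`
#'   (mean of the reversed items, in 1..6) and `ita_sum`.
#' @export
score_ita <- function(items) {
  stopifnot(all(c("individual", "value", "polarity") %in% names(items)))
  bad <- which(!(items$value %in% 1:6))
  if (length(bad) > 0) {
    stop("ITA item value out of 1..6 range at row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(items$polarity %in% c("entity", "incremental"))) {
    stop("ITA polarity must be 'entity' or 'incremental'", call. = FALSE)
  }
  counts <- dplyr::count(tibble::as_tibble(items),
                         .data$individual, .data$polarity)
  ok <- dplyr::summarise(
    dplyr::group_by(counts, .data$individual),
    valid = dplyr::n() == 2 && all(.data$n == 4), .groups = "drop"
  )
  if (!all(ok$valid)) {
    stop("each respondent needs exactly 4 entity and 4 incremental items; ",
         "violated for: ",
         paste(ok$individual[!ok$valid], collapse = ", "), call. = FALSE)
  }
  scored <- dplyr::mutate(
    tibble::as_tibble(items),
    scored = ifelse(.data$polarity == "incremental",
                    7 - .data$value, .data$value)
  )
  dplyr::summarise(dplyr::group_by(scored, .data$individual),
                   ita_score = mean(.data$scored),
                   ita_sum = sum(.data$scored),
                   .groups = "drop")
}

#' Median-split ITA classification
#'
#' Individuals strictly below the median scale score are classified as
#' entity theorists, strictly above as incremental theorists. Individuals
#' exactly at the median are assigned to the entity (lower) group; the
#' number of such ties is recorded in the `n_ties` attribute and in the
#' `at_median` column. With an even number of distinct scores the split is
#' balanced (e.g. 28 distinct scores give 14/14).
#'
#' @param scores Tibble with columns `individual` and `ita_score`, or a bare
#'   numeric vector.
#' @return Tibble `individual`, `ita_score`, `label`, `at_median`, with
#'   attribute `n_ties`.
#' @export
median_split <- function(scores) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(individual = as.character(seq_along(scores)),
                             ita_score = as.numeric(scores))
  }
  stopifnot(all(c("individual", "ita_score") %in% names(scores)))
  if (nrow(scores) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (length(unique(scores$ita_score)) == 1) {
    stop("all ITA scores identical; median split undefined", call. = FALSE)
  }
  med <- stats::median(scores$ita_score)
  out <- dplyr::mutate(
    tibble::as_tibble(scores),
    at_median = .data$ita_score == med,
    label = ifelse(.data$ita_score > med, "incremental", "entity")
  )
  out <- out[c("individual", "ita_score", "label", "at_median")]
  attr(out, "n_ties") <- sum(out$at_median)
  attr(out, "median") <- med
  out
}
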