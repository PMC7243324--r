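#' Read participant records from CSV
#'
#' Expected columns: `participant_id`, `role` (`regulator`/`seller`),
#' `price_group` (`100k`/`1`), reservation prices `x1..x5`, price offers
#' `y1..y5`, and logical `screening_correct`, `comprehension_correct`.
#' Prices are given in the native display unit of the participant's frame
#' (thousand-$ for the 100k group, payoff-$ for the 1$ group) and are
#' normalised to the internal thousand-$ scale on ingestion. Records with
#' missing values are rejected: the experiment forced complete responses,
#' so a hole is a data error, not a skip.
#'
#' @param path CSV file path.
#' @param config A [game_config()]; used for frame normalisation and bounds.
#' @return A tibble of participant records on the internal scale.
#' @export
read_participants <- function(path, config = game_config()) {
  cohort <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_participants(cohort, config, normalized = FALSE)
  normalize_participants(cohort, config)
}

participant_columns <- function() {
  c("participant_id", "role", "price_group",
    paste0("x", 1:5), paste0("y", 1:5),
    "screening_correct", "comprehension_correct")
}

normalize_participants <- function(cohort, config) {
  cohort <- tibble::as_tibble(cohort)[participant_columns()]
  for (col in c(paste0("x", 1:5), paste0("y", 1:5))) {
    cohort[[col]] <- price_to_internal(cohort[[col]], cohort$price_group, config)
  }
  cohort$screening_correct <- as.logical(cohort$screening_correct)
  cohort$comprehension_correct <- as.logical(cohort$comprehension_correct)
  cohort
}

validate_participants <- function(cohort, config = game_config(),
                                  normalized = TRUE) {
  missing_cols <- setdiff(participant_columns(), names(cohort))
  if (length(missing_cols) > 0) {
    stop("participant data is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  price_cols <- c(paste0("x", 1:5), paste0("y", 1:5))
  bad <- which(!stats::complete.cases(cohort[participant_columns()]))
  if (length(bad) > 0) {
    stop("participant data has missing values in record(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "", call. = FALSE)
  }
  if (!all(cohort$role %in% c("regulator", "seller"))) {
    stop("role must be \"regulator\" or \"seller\"", call. = FALSE)
  }
  if (!all(cohort$price_group %in% c("100k", "1"))) {
    stop("price_group must be \"100k\" or \"1\"", call. = FALSE)
  }
  if (anyDuplicated(cohort$participant_id)) {
    stop("duplicated participant_id values", call. = FALSE)
  }
  prices <- as.matrix(cohort[price_cols])
  if (!normalized) {
    prices <- prices * ifelse(cohort$price_group == "1", payoff_scale(config), 1)
  }
  out <- which(prices < config$price_min | prices > config$price_max,
               arr.ind = TRUE)
  if (nrow(out) > 0) {
    rows <- sort(unique(out[, 1]))
    stop("prices outside the admissible range in record(s) ",
         paste(utils::head(rows, 10), collapse = ", "),
         if (length(rows) > 10) " ..." else "", call. = FALSE)
  }
  invisible(cohort)
}

#' Write participant records to CSV in native frame units
#'
#' Inverse of [read_participants()]: internal thousand-$ prices are scaled
#' back to each participant's display unit before writing.
#'
#' @param cohort Participant tibble on the internal scale.
#' @param path Output CSV path.
#' @param config A [game_config()].
#' @return `path`, invisibly.
#' @export
write_participants <- function(cohort, path, config = game_config()) {
  out <- cohort[participant_columns()]
  scale <- ifelse(out$price_group == "1", payoff_scale(config), 1)
  for (col in c(paste0("x", 1:5), paste0("y", 1:5))) {
    out[[col]] <- round(out[[col]] / scale, 2)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Strict monotonicity of a reservation-price profile
#'
#' A participant has strict monotone preferences for incremental patient
#' benefit when the five reservation prices increase strictly from round 1
#' to 5.
#'
#' @param reservation_prices Numeric vector of length 5, or a matrix with 5
#'   columns (one row per participant).
#' @return Logical scalar (vector input) or vector (matrix input).
#' @export
classify_monotone <- function(reservation_prices) {
  if (is.matrix(reservation_prices)) {
    if (ncol(reservation_prices) != 5) {
      stop("classify_monotone: expected 5 rounds per participant", call. = FALSE)
    }
    d <- reservation_prices[, -1, drop = FALSE] -
      reservation_prices[, -5, drop = FALSE]
    return(rowSums(d > 0) == 4)
  }
  if (length(reservation_prices) != 5) {
    stop("classify_monotone: expected a reservation vector of length 5",
         call. = FALSE)
  }
  all(diff(reservation_prices) > 0)
}

#' Offer consistency with the private reservation price
#'
#' A consistent price offer must not cross the decider's own reservation
#' price: sellers may only offer at or above their willingness to accept
#' (`y >= x`), regulators at or below their willingness to pay (`y <= x`).
#' Equality (a zero-margin offer) is consistent.
#'
#' @param role `"regulator"`/`"seller"` (recycled against x, y).
#' @param reservation_x,offer_y Prices on a common scale.
#' @return Logical vector.
#' @export
offer_consistent <- function(role, reservation_x, offer_y) {
  check_role(role)
  ifelse(role == "seller", offer_y >= reservation_x, offer_y <= reservation_x)
}

check_role <- function(role) {
  if (!all(role %in% c("regulator", "seller"))) {
    stop("role must be \"regulator\" or \"seller\"", call. = FALSE)
  }
  invisible(role)
}

#' Margin claimed by a decider
#'
#' The role-signed gap between reservation price and offer — the potential
#' bonus of a successful agreement: `x - y` for regulators, `y - x` for
#' sellers. Non-negative exactly when the offer is consistent; a negative
#' value flags an inconsistent offer, which the caller decides how to
#' handle (`check = TRUE` warns).
#'
#' @inheritParams offer_consistent
#' @param check Warn if any margin is negative (inconsistent offer).
#' @return Numeric vector of margins, same scale as the inputs.
#' @export
margin <- function(role, reservation_x, offer_y, check = FALSE) {
  check_role(role)
  m <- ifelse(role == "seller",
              offer_y - reservation_x,
              reservation_x - offer_y)
  if (check && any(m < 0)) {
    warning(sum(m < 0), " inconsistent offer(s) produced negative margins",
            call. = FALSE)
  }
  m
}

#' Per-round classification flags for a cohort
#'
#' Adds `monotone_strict`, per-round consistency flags
#' `consistent_r1..consistent_r5` and their conjunction `consistent_all`.
#'
#' @param cohort Participant tibble (internal scale).
#' @return The cohort with classification columns appended.
#' @export
classify_cohort <- function(cohort) {
  x <- as.matrix(cohort[paste0("x", 1:5)])
  y <- as.matrix(cohort[paste0("y", 1:5)])
  cohort$monotone_strict <- classify_monotone(x)
  for (r in 1:5) {
    cohort[[paste0("consistent_r", r)]] <-
      offer_consistent(cohort$role, x[, r], y[, r])
  }
  cohort$consistent_all <-
    rowSums(as.matrix(cohort[paste0("consistent_r", 1:5)])) == 5
  cohort
}

#' Long (participant x round) view of a cohort
#'
#' One row per participant and round with reservation price `x`, offer `y`,
#' consistency flag, and the signed margin on both the internal and the
#' payoff scale.
#'
#' @inheritParams classify_cohort
#' @param config A [game_config()] for the payoff-scale conversion.
#' @return A long tibble.
#' @export
cohort_long <- function(cohort, config = game_config()) {
  keep <- c("participant_id", "role", "price_group",
            intersect("monotone_strict", names(cohort)))
  long_x <- tidyr::pivot_longer(cohort[c(keep, paste0("x", 1:5))],
                                cols = dplyr::all_of(paste0("x", 1:5)),
                                names_to = "round", names_prefix = "x",
                                values_to = "x")
  long_y <- tidyr::pivot_longer(cohort[c("participant_id", paste0("y", 1:5))],
                                cols = dplyr::all_of(paste0("y", 1:5)),
                                names_to = "round", names_prefix = "y",
                                values_to = "y")
  long <- dplyr::left_join(long_x, long_y, by = c("participant_id", "round"))
  long$round <- as.integer(long$round)
  long$consistent <- offer_consistent(long$role, long$x, long$y)
  long$margin <- margin(long$role, long$x, long$y)
  long$x_payoff <- internal_to_payoff(long$x, config)
  long$y_payoff <- internal_to_payoff(long$y, config)
  long$margin_payoff <- internal_to_payoff(long$margin, config)
  long
}

#' Apply the study's inclusion filters
#'
#' Filters a cohort down to the analysable population and returns it in
#' long (participant x round) form. Filters, in order: attention screening
#' and comprehension flags (whole participant), strict monotone preferences
#' (whole participant), and offer consistency in one of two first-class
#' modes — `per_round` drops only the inconsistent player-rounds,
#' `all_rounds` drops every round of any player with one or more
#' inconsistent offers, `none` keeps everything.
#'
#' @param cohort Participant tibble (internal scale).
#' @param monotone_only Keep only strictly monotone participants.
#' @param consistency `"per_round"`, `"all_rounds"` or `"none"`.
#' @param screening,comprehension Require the respective control flag.
#' @param config A [game_config()].
#' @return Long tibble of eligible player-rounds (see [cohort_long()]) with
#'   a `filter_counts` attribute tabulating removals per criterion. An
#'   empty result warns rather than errors.
#' @export
filter_population <- function(cohort,
                              monotone_only = TRUE,
                              consistency = c("per_round", "all_rounds", "none"),
                              screening = FALSE,
                              comprehension = FALSE,
                              config = game_config()) {
  consistency <- match.arg(consistency)
  cohort <- classify_cohort(cohort)
  counts <- list()

  if (screening) {
    drop <- !cohort$screening_correct
    counts$screening <- sum(drop)
    cohort <- cohort[!drop, ]
  }
  if (comprehension) {
    drop <- !cohort$comprehension_correct
    counts$comprehension <- sum(drop)
    cohort <- cohort[!drop, ]
  }
  if (monotone_only) {
    drop <- !cohort$monotone_strict
    counts$non_monotone <- sum(drop)
    cohort <- cohort[!drop, ]
  }
  if (consistency == "all_rounds") {
    drop <- !cohort$consistent_all
    counts$inconsistent_player <- sum(drop)
    cohort <- cohort[!drop, ]
  }

  long <- cohort_long(cohort, config)
  if (consistency == "per_round") {
    counts$inconsistent_round <- sum(!long$consistent)
    long <- long[long$consistent, ]
  }

  if (nrow(long) == 0) {
    warning("filter_population: no player-rounds survive the filters",
            call. = FALSE)
  }
  attr(long, "filter_counts") <- tibble::tibble(
    criterion = names(counts),
    n_removed = unlist(counts, use.names = FALSE)
  )
  attr(long, "consistency_mode") <- consistency
  long
}
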