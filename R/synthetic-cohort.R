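#' Specification of a synthetic participant cohort
#'
#' Describes the statistical structure of a generated cohort: four
#' treatment groups (role x price frame), strictly increasing reservation
#' prices over the five rounds, and an offer process that mixes zero-margin
#' offers (players forgoing their bonus in favour of an agreement),
#' positive role-signed margins, and a controlled rate of inconsistent
#' offers, plus a rate of non-monotone preference profiles. All price
#' parameters are in payoff-$ (the common scale of the two frames);
#' generated prices land on the 0.01 payoff-$ grid and inside the
#' configured price bounds.
#'
#' The default group sizes are the experiment's cell sizes (97/101/105/101).
#' The default zero-margin structure matches the reported pattern that 15%
#' of players never claimed a margin and 47% forwent it at least once: a
#' persistent always-zero share of 0.15 plus a per-round zero probability
#' of 0.09 among the rest. Base reservation means place regulators lower in
#' the 100k frame and sellers below regulators in the 1$ frame.
#'
#' @param n_per_group Named counts for `regulator_100k`, `seller_100k`,
#'   `regulator_1`, `seller_1`.
#' @param base_price_mean Named round-1 reservation-price means (payoff-$),
#'   same names as `n_per_group`.
#' @param base_price_sd Standard deviation of the (truncated normal)
#'   round-1 reservation price.
#' @param increment_mean Mean of the positive per-round reservation-price
#'   increment (exponential family), enforcing strict monotonicity.
#' @param zero_margin_prob Per-player-round probability of a zero margin
#'   (`y = x`), applied to non-persistent players on consistent rounds.
#' @param persistent_zero_prob Share of players who claim no margin in any
#'   round.
#' @param positive_margin_mean Mean of the positive margin draw
#'   (exponential, floored at one grid step).
#' @param inconsistency_prob Per-player-round probability of an offer on
#'   the wrong side of the reservation price.
#' @param non_monotone_prob Probability that a participant's reservation
#'   profile is corrupted to a non-strictly-monotone one.
#' @param screening_correct_prob,comprehension_correct_prob Pass rates of
#'   the two control questions.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_per_group = c(regulator_100k = 97, seller_100k = 101,
                    regulator_1 = 105, seller_1 = 101),
    base_price_mean = c(regulator_100k = 1.5, seller_100k = 1.7,
                        regulator_1 = 1.9, seller_1 = 1.6),
    base_price_sd = 0.6,
    increment_mean = 0.15,
    zero_margin_prob = 0.09,
    persistent_zero_prob = 0.15,
    positive_margin_mean = 0.2,
    inconsistency_prob = 0.10,
    non_monotone_prob = 0.25,
    screening_correct_prob = 0.88,
    comprehension_correct_prob = 0.85) {
  groups <- c("regulator_100k", "seller_100k", "regulator_1", "seller_1")
  n_per_group <- n_per_group[groups]
  base_price_mean <- base_price_mean[groups]
  if (any(is.na(n_per_group)) || any(is.na(base_price_mean))) {
    stop("cohort_spec: n_per_group and base_price_mean must name all of ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  probs <- c(zero_margin_prob, persistent_zero_prob, inconsistency_prob,
             non_monotone_prob, screening_correct_prob,
             comprehension_correct_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("cohort_spec: probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (base_price_sd <= 0 || increment_mean <= 0 || positive_margin_mean <= 0) {
    stop("cohort_spec: scale parameters must be positive", call. = FALSE)
  }
  structure(list(
    n_per_group = n_per_group,
    base_price_mean = base_price_mean,
    base_price_sd = base_price_sd,
    increment_mean = increment_mean,
    zero_margin_prob = zero_margin_prob,
    persistent_zero_prob = persistent_zero_prob,
    positive_margin_mean = positive_margin_mean,
    inconsistency_prob = inconsistency_prob,
    non_monotone_prob = non_monotone_prob,
    screening_correct_prob = screening_correct_prob,
    comprehension_correct_prob = comprehension_correct_prob
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
                         collapse = ", "), "\n")
  cat(sprintf("  zero margin: %.2f/round + %.2f persistent; inconsistent %.2f; non-monotone %.2f\n",
              x$zero_margin_prob, x$persistent_zero_prob,
              x$inconsistency_prob, x$non_monotone_prob))
  invisible(x)
}

#' Read / write a cohort spec as JSON or YAML
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_cohort_spec()` returns a [cohort_spec()].
#' @export
read_cohort_spec <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  raw$n_per_group <- unlist(raw$n_per_group)
  raw$base_price_mean <- unlist(raw$base_price_mean)
  do.call(cohort_spec, raw)
}

#' @rdname read_cohort_spec
#' @param spec A [cohort_spec()] to serialise.
#' @export
write_cohort_spec <- function(spec, path) {
  out <- unclass(spec)
  out$n_per_group <- as.list(out$n_per_group)
  out$base_price_mean <- as.list(out$base_price_mean)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(out, path)
  else jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}

# grid step on the payoff scale: 0.01 payoff-$ = 1 thousand-$
payoff_grid <- 0.01

round_to_grid <- function(x) round(x / payoff_grid) * payoff_grid

# truncated-normal draw by rejection, vectorised
rtruncnorm_vec <- function(n, mean, sd, lower, upper) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) > 0) {
    out[bad] <- stats::rnorm(length(bad), if (length(mean) > 1) mean[bad] else mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1
    if (guard > 1000) stop("truncated-normal rejection failed; check bounds",
                           call. = FALSE)
  }
  out
}

#' Generate a synthetic participant cohort
#'
#' Draws the four treatment groups of a [cohort_spec()]: round-1
#' reservation prices from a truncated normal per group, strictly positive
#' grid increments for rounds 2-5 (increment vectors that would push round
#' 5 beyond the price ceiling are resampled, not clipped, so strict
#' monotonicity survives), non-monotone corruptions and inconsistent,
#' zero-margin or positive-margin offers injected at the specified rates.
#' Fully reproducible under `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param config A [game_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A participant tibble on the internal scale, as returned by
#'   [read_participants()].
#' @export
generate_cohort <- function(spec = cohort_spec(), config = game_config(),
                            seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  pmin_ <- internal_to_payoff(config$price_min, config)
  pmax_ <- internal_to_payoff(config$price_max, config)

  groups <- names(spec$n_per_group)
  pieces <- vector("list", length(groups))
  id0 <- 0
  for (g in seq_along(groups)) {
    n <- spec$n_per_group[[g]]
    role <- sub("_(100k|1)$", "", groups[g])
    frame <- sub("^(regulator|seller)_", "", groups[g])
    x <- generate_reservations(n, spec$base_price_mean[[g]], spec, pmin_, pmax_)
    x <- inject_non_monotone(x, spec, pmin_)
    y <- generate_offers(x, role, spec, pmin_, pmax_)
    pieces[[g]] <- tibble::tibble(
      participant_id = sprintf("P%04d", id0 + seq_len(n)),
      role = role,
      price_group = frame,
      x1 = x[, 1], x2 = x[, 2], x3 = x[, 3], x4 = x[, 4], x5 = x[, 5],
      y1 = y[, 1], y2 = y[, 2], y3 = y[, 3], y4 = y[, 4], y5 = y[, 5],
      screening_correct = stats::runif(n) < spec$screening_correct_prob,
      comprehension_correct = stats::runif(n) < spec$comprehension_correct_prob
    )
    id0 <- id0 + n
  }
  cohort <- dplyr::bind_rows(pieces)
  # payoff-$ -> internal thousand-$ (exact: grid values are integer there)
  for (col in c(paste0("x", 1:5), paste0("y", 1:5))) {
    cohort[[col]] <- round(cohort[[col]] * payoff_scale(config))
  }
  validate_participants(cohort, config, normalized = TRUE)
  cohort
}

# strictly increasing reservation matrix (n x 5) on the payoff grid
generate_reservations <- function(n, base_mean, spec, pmin_, pmax_) {
  # leave room for the four minimal increments above the base price
  head_max <- pmax_ - 4 * payoff_grid
  base <- round_to_grid(rtruncnorm_vec(n, base_mean, spec$base_price_sd,
                                       pmin_, head_max))
  x <- matrix(0, n, 5)
  x[, 1] <- base
  todo <- seq_len(n)
  guard <- 0
  while (length(todo) > 0) {
    inc <- matrix(stats::rexp(4 * length(todo), rate = 1 / spec$increment_mean),
                  ncol = 4)
    inc <- pmax(round_to_grid(inc), payoff_grid)
    cand <- x[todo, 1] + t(apply(inc, 1, cumsum))
    if (length(todo) == 1) cand <- matrix(cand, nrow = 1)
    ok <- cand[, 4] <= pmax_
    x[todo[ok], 2:5] <- cand[ok, , drop = FALSE]
    todo <- todo[!ok]
    guard <- guard + 1
    if (guard > 200) {
      stop("generate_cohort: increments repeatedly exceed the price ceiling; ",
           "the spec is infeasible (base prices too close to price_max ",
           "for increment_mean = ", spec$increment_mean, ")", call. = FALSE)
    }
  }
  round_to_grid(x)
}

# corrupt a share of profiles so they are not strictly increasing
inject_non_monotone <- function(x, spec, pmin_) {
  n <- nrow(x)
  hit <- which(stats::runif(n) < spec$non_monotone_prob)
  if (length(hit) == 0) return(x)
  k <- sample(2:5, length(hit), replace = TRUE)
  drop <- round_to_grid(stats::rexp(length(hit), rate = 1 / spec$increment_mean))
  x[cbind(hit, k)] <- pmax(pmin_, x[cbind(hit, k - 1)] - drop)
  x
}

# offers per round: persistent zero-margin players, else a per-round
# mixture of inconsistent / zero-margin / positive-margin offers
generate_offers <- function(x, role, spec, pmin_, pmax_) {
  n <- nrow(x)
  sign <- if (role == "seller") 1 else -1
  y <- x
  persistent <- stats::runif(n) < spec$persistent_zero_prob
  free <- which(!persistent)
  if (length(free) == 0) return(y)
  for (r in 1:5) {
    u <- stats::runif(length(free))
    d <- pmax(round_to_grid(stats::rexp(length(free),
                                        rate = 1 / spec$positive_margin_mean)),
              payoff_grid)
    inconsistent <- u < spec$inconsistency_prob
    zero <- !inconsistent &
      u < spec$inconsistency_prob +
        (1 - spec$inconsistency_prob) * spec$zero_margin_prob
    off <- ifelse(inconsistent, -sign * d, ifelse(zero, 0, sign * d))
    y[free, r] <- pmin(pmax(x[free, r] + off, pmin_), pmax_)
  }
  round_to_grid(y)
}

#' Moment estimates of a cohort's generative parameters
#'
#' Estimates, with binomial / normal standard errors, the observable rates
#' a generated cohort carries: the non-monotone participant share, the
#' inconsistent player-round share, the zero-margin share among consistent
#' player-rounds, the share of players claiming no margin in all five
#' rounds, and the mean positive margin (payoff-$). With
#' `persistent_zero_prob = 0` the first three estimate
#' `non_monotone_prob`, `inconsistency_prob` and `zero_margin_prob` of the
#' generating [cohort_spec()] directly; a persistent zero-margin mass mixes
#' into the inconsistency and zero-margin rates (persistent players are
#' never inconsistent).
#'
#' @param cohort Participant tibble (internal scale).
#' @param config A [game_config()].
#' @return A tibble with columns `parameter`, `estimate`, `se`, `n`.
#' @export
recover_parameters <- function(cohort, config = game_config()) {
  cohort <- classify_cohort(cohort)
  long <- cohort_long(cohort, config)

  p_se <- function(p, n) sqrt(p * (1 - p) / n)
  n_part <- nrow(cohort)
  n_rounds <- nrow(long)

  p_nm <- mean(!cohort$monotone_strict)
  p_inc <- mean(!long$consistent)
  cons <- long[long$consistent, ]
  p_zero <- mean(cons$margin == 0)
  all_zero <- dplyr::summarise(
    dplyr::group_by(long, .data$participant_id),
    az = all(.data$margin == 0), .groups = "drop")
  p_all_zero <- mean(all_zero$az)
  pos <- cons$margin_payoff[cons$margin > 0]
  mean_pos <- if (length(pos) > 0) mean(pos) else NA_real_
  se_pos <- if (length(pos) > 1) stats::sd(pos) / sqrt(length(pos)) else NA_real_

  tibble::tibble(
    parameter = c("non_monotone_rate", "inconsistency_rate",
                  "zero_margin_rate", "all_rounds_zero_rate",
                  "mean_positive_margin"),
    estimate = c(p_nm, p_inc, p_zero, p_all_zero, mean_pos),
    se = c(p_se(p_nm, n_part), p_se(p_inc, n_rounds),
           p_se(p_zero, nrow(cons)), p_se(p_all_zero, n_part), se_pos),
    n = c(n_part, n_rounds, nrow(cons), n_part, length(pos))
  )
}
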