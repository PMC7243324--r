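# Classical test battery over cohort margins and simulation output.
#
# All results come back as one tidy tibble (one row per hypothesis x
# grouping x test) so they can be bound, filtered and exported uniformly.
# No multiple-testing correction is applied -- results are reported
# per round as in the underlying design -- but every battery run records
# the number of tests so readers can correct afterwards.

test_result_row <- function(hypothesis_id, test_name, statistic, p_value,
                            n1, n2 = NA_integer_, estimate = NA_real_,
                            round = NA_integer_, frame = NA_character_,
                            role = NA_character_, grouping = NA_character_,
                            usable = TRUE, note = NA_character_) {
  tibble::tibble(
    hypothesis_id = hypothesis_id, round = round, frame = frame, role = role,
    grouping = grouping, test_name = test_name,
    statistic = statistic, p_value = p_value, estimate = estimate,
    n1 = n1, n2 = n2, usable = usable, note = note
  )
}

# one-sample t of `v` against 0, robust to zero-variance groups:
# exactly-constant-at-zero data gives t = 0, p = 1 (nothing to reject);
# constant nonzero data has no finite statistic and is flagged unusable.
safe_one_sample_t <- function(v, alternative = "two.sided") {
  n <- length(v)
  if (n < 2) {
    return(list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                note = "group size < 2"))
  }
  if (stats::sd(v) == 0) {
    if (mean(v) == 0) {
      return(list(statistic = 0, p = 1, usable = TRUE,
                  note = "zero variance, zero mean"))
    }
    return(list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                note = "zero variance, nonzero mean"))
  }
  ht <- stats::t.test(v, mu = 0, alternative = alternative)
  list(statistic = unname(ht$statistic), p = ht$p.value, usable = TRUE,
       note = NA_character_)
}

safe_two_sample_t <- function(a, b, alternative = "two.sided",
                              paired = FALSE) {
  if (length(a) < 2 || length(b) < 2 ||
      (paired && length(a) != length(b))) {
    return(list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                note = "group size < 2"))
  }
  if (paired) return(safe_one_sample_t(a - b, alternative))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(statistic = 0, p = 1, usable = TRUE,
                  note = "zero variance, equal means"))
    }
    return(list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                note = "zero variance, unequal means"))
  }
  ht <- stats::t.test(a, b, alternative = alternative, var.equal = FALSE)
  list(statistic = unname(ht$statistic), p = ht$p.value, usable = TRUE,
       note = NA_character_)
}

# Mann-Whitney U: exact enumeration for small tie-free samples, normal
# approximation with tie correction (and continuity correction) otherwise
safe_mann_whitney <- function(a, b, exact_max = 20) {
  if (length(a) < 2 || length(b) < 2) {
    return(list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                note = "group size < 2"))
  }
  exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)
  )
  list(statistic = unname(ht$statistic), p = ht$p.value, usable = TRUE,
       note = NA_character_)
}

#' Margins against zero (offers versus reservation prices)
#'
#' Per role x frame x round, a paired t-test of price offers against
#' reservation prices (equivalently a one-sample t of the signed margin
#' against zero): do deciders claim margins at all, or do they offer their
#' reservation price?
#'
#' @param population Long tibble of consistent player-rounds from
#'   [filter_population()].
#' @return A tidy tibble of test results (payoff-scale mean margin as
#'   `estimate`).
#' @export
test_margin_vs_zero <- function(population) {
  groups <- split(population,
                  list(role = population$role, frame = population$price_group,
                       round = population$round), drop = TRUE)
  purrr::list_rbind(purrr::map(groups, function(g) {
    res <- safe_one_sample_t(g$margin_payoff)
    test_result_row(
      "H0-I", "t_paired", res$statistic, res$p,
      n1 = nrow(g), estimate = mean(g$margin_payoff),
      round = g$round[1], frame = g$price_group[1], role = g$role[1],
      grouping = "offer vs reservation price",
      usable = res$usable, note = res$note
    )
  }))
}

#' Frame and role contrasts of claimed margins
#'
#' Margins are compared on the common payoff scale: per round and role, the
#' 100k frame against the 1$ frame (price-framing contrast); per round and
#' frame, regulators against sellers (role contrast). Each contrast runs an
#' independent-samples Welch t-test and a Mann-Whitney U test.
#'
#' @inheritParams test_margin_vs_zero
#' @return A tidy tibble of test results; `estimate` is the difference of
#'   group mean margins (first minus second group).
#' @export
test_frame_and_role_contrasts <- function(population) {
  contrast <- function(a, b, id, grouping, round, frame, role) {
    tt <- safe_two_sample_t(a, b)
    mw <- safe_mann_whitney(a, b)
    est <- mean(a) - mean(b)
    dplyr::bind_rows(
      test_result_row(id, "t_independent", tt$statistic, tt$p,
                      n1 = length(a), n2 = length(b), estimate = est,
                      round = round, frame = frame, role = role,
                      grouping = grouping, usable = tt$usable, note = tt$note),
      test_result_row(id, "mann_whitney_u", mw$statistic, mw$p,
                      n1 = length(a), n2 = length(b), estimate = est,
                      round = round, frame = frame, role = role,
                      grouping = grouping, usable = mw$usable, note = mw$note)
    )
  }
  out <- list()
  for (r in sort(unique(population$round))) {
    pr <- population[population$round == r, ]
    for (role in unique(pr$role)) {
      a <- pr$margin_payoff[pr$role == role & pr$price_group == "100k"]
      b <- pr$margin_payoff[pr$role == role & pr$price_group == "1"]
      if (length(a) > 0 && length(b) > 0) {
        out[[length(out) + 1]] <-
          contrast(a, b, "H0-II", "margin: 100k vs 1$ frame", r,
                   NA_character_, role)
      }
    }
    for (frame in unique(pr$price_group)) {
      a <- pr$margin_payoff[pr$price_group == frame & pr$role == "regulator"]
      b <- pr$margin_payoff[pr$price_group == frame & pr$role == "seller"]
      if (length(a) > 0 && length(b) > 0) {
        out[[length(out) + 1]] <-
          contrast(a, b, "H0-III", "margin: regulator vs seller", r,
                   frame, NA_character_)
      }
    }
  }
  purrr::list_rbind(out)
}

#' Agreement feasibility: weak and strong forms
#'
#' Weak form: per round x frame, a one-tailed independent t-test of seller
#' offers being above regulator offers; rejection means the average
#' negotiators could not close (`mean(y_S) > mean(y_R)`). Strong form
#' (requires `states`): per round x frame, a paired one-tailed t-test
#' across iterations of trades possible against trades successful — the
#' loss of agreements between overlapping preferences and closing offers.
#'
#' @inheritParams test_margin_vs_zero
#' @param states Optional market states from [simulate_markets()].
#' @return A tidy tibble of test results.
#' @export
test_agreement_feasibility <- function(population, states = NULL) {
  out <- list()
  combos <- unique(population[c("round", "price_group")])
  for (i in seq_len(nrow(combos))) {
    r <- combos$round[i]
    f <- combos$price_group[i]
    cell <- population[population$round == r & population$price_group == f, ]
    ys <- cell$y_payoff[cell$role == "seller"]
    yr <- cell$y_payoff[cell$role == "regulator"]
    tt <- safe_two_sample_t(ys, yr, alternative = "greater")
    out[[length(out) + 1]] <- test_result_row(
      "H0-IV-weak", "t_one_tailed", tt$statistic, tt$p,
      n1 = length(ys), n2 = length(yr), estimate = mean(ys) - mean(yr),
      round = r, frame = f, grouping = "seller vs regulator offers",
      usable = tt$usable, note = tt$note
    )
  }
  if (!is.null(states)) {
    cells <- split(states[states$n_pairs > 0, ],
                   list(round = states$round[states$n_pairs > 0],
                        frame = states$frame[states$n_pairs > 0]),
                   drop = TRUE)
    for (cell in cells) {
      tt <- safe_two_sample_t(cell$n_trades_possible,
                              cell$n_trades_successful,
                              alternative = "greater", paired = TRUE)
      out[[length(out) + 1]] <- test_result_row(
        "H0-IV-strong", "t_paired", tt$statistic, tt$p,
        n1 = nrow(cell),
        estimate = mean(cell$n_trades_possible - cell$n_trades_successful),
        round = cell$round[1], frame = cell$frame[1],
        grouping = "trades possible vs successful (per iteration)",
        usable = tt$usable, note = tt$note
      )
    }
  }
  purrr::list_rbind(out)
}

#' Margin break-point tests along the reservation price
#'
#' Splits player-rounds by reservation price at fixed break points
#' (defaults: 1.2 payoff-$, the funders' equality point; 2.5, the mean of
#' the price range; 2.75, the mean of the slider range) or at the
#' reservation-price quartiles, and runs a one-sample t-test of the mean
#' margin against zero on each side, per role x frame. A shared assumption
#' about the opponent's likely offer would show up as a side with margins
#' collapsing to zero.
#'
#' @inheritParams test_margin_vs_zero
#' @param breakpoints Break points on the payoff scale.
#' @param quartile_mode Use the per-group reservation-price quartiles as
#'   relative break points instead.
#' @return A tidy tibble of test results; empty strata are flagged
#'   unusable.
#' @export
test_breakpoints <- function(population, breakpoints = c(1.2, 2.5, 2.75),
                             quartile_mode = FALSE) {
  out <- list()
  groups <- split(population,
                  list(role = population$role,
                       frame = population$price_group), drop = TRUE)
  for (g in groups) {
    if (quartile_mode) {
      qs <- stats::quantile(g$x_payoff, c(0.25, 0.5, 0.75), names = FALSE)
      strata <- cut(g$x_payoff,
                    breaks = c(-Inf, qs, Inf),
                    labels = paste0("Q", 1:4))
      for (lev in levels(strata)) {
        v <- g$margin_payoff[strata == lev]
        res <- safe_one_sample_t(v)
        out[[length(out) + 1]] <- test_result_row(
          "breakpoint", "t_one_sample", res$statistic, res$p,
          n1 = length(v), estimate = if (length(v)) mean(v) else NA_real_,
          frame = g$price_group[1], role = g$role[1],
          grouping = paste0("margin vs 0, reservation quartile ", lev),
          usable = res$usable && length(v) > 0,
          note = if (length(v) == 0) "empty stratum" else res$note
        )
      }
    } else {
      for (bp in breakpoints) {
        for (side in c("below", "above")) {
          v <- if (side == "below") g$margin_payoff[g$x_payoff <= bp]
               else g$margin_payoff[g$x_payoff > bp]
          res <- if (length(v) == 0) {
            list(statistic = NA_real_, p = NA_real_, usable = FALSE,
                 note = "empty stratum")
          } else safe_one_sample_t(v)
          out[[length(out) + 1]] <- test_result_row(
            "breakpoint", "t_one_sample", res$statistic, res$p,
            n1 = length(v), estimate = if (length(v)) mean(v) else NA_real_,
            frame = g$price_group[1], role = g$role[1],
            grouping = sprintf("margin vs 0, reservation %s %.2f$", side, bp),
            usable = res$usable, note = res$note
          )
        }
      }
    }
  }
  purrr::list_rbind(out)
}

#' Run the full hypothesis-test battery
#'
#' Binds [test_margin_vs_zero()], [test_frame_and_role_contrasts()],
#' [test_agreement_feasibility()] and [test_breakpoints()] into one tidy
#' table. Raw p-values are reported without multiplicity correction; the
#' `n_tests` attribute carries the battery size so corrections can be
#' applied downstream.
#'
#' @inheritParams test_agreement_feasibility
#' @param breakpoints Passed to [test_breakpoints()].
#' @return A tidy tibble of all test results with attribute `n_tests`.
#' @export
run_test_battery <- function(population, states = NULL,
                             breakpoints = c(1.2, 2.5, 2.75)) {
  res <- dplyr::bind_rows(
    test_margin_vs_zero(population),
    test_frame_and_role_contrasts(population),
    test_agreement_feasibility(population, states),
    test_breakpoints(population, breakpoints),
    test_breakpoints(population, quartile_mode = TRUE)
  )
  attr(res, "n_tests") <- nrow(res)
  res
}
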