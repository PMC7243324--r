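#' Randomly pair regulators with sellers
#'
#' Draws a uniform random bijection between equal-size subsamples of the
#' two sides: `m = min(n_regulators, n_sellers)` participants are sampled
#' without replacement from each side and matched one-to-one; surplus
#' participants of the larger side stay unmatched for this draw.
#'
#' @param regulators,sellers Tibbles with at least `participant_id`, `x`,
#'   `y` (internal scale), one row per participant.
#' @return A tibble of pairs with columns suffixed `_R` / `_S`.
#' @export
pair_randomly <- function(regulators, sellers) {
  if (nrow(regulators) == 0 || nrow(sellers) == 0) {
    stop("pair_randomly: both sides must be non-empty", call. = FALSE)
  }
  m <- min(nrow(regulators), nrow(sellers))
  ri <- sample(nrow(regulators), m)
  si <- sample(nrow(sellers), m)
  tibble::tibble(
    regulator_id = regulators$participant_id[ri],
    seller_id = sellers$participant_id[si],
    x_R = regulators$x[ri], y_R = regulators$y[ri],
    x_S = sellers$x[si], y_S = sellers$y[si]
  )
}

#' Evaluate matched negotiation pairs
#'
#' A trade is *possible* when the reservation prices overlap
#' (`x_S <= x_R`, WTA below WTP) and *successful* when the submitted offers
#' close (`y_S <= y_R`, equality trades). On success the transaction price
#' follows `price_rule` and each decider earns their own margin as bonus
#' (`x_R - y_R` for the regulator, `y_S - x_S` for the seller); unsuccessful
#' pairs carry zero bonuses and no price.
#'
#' @param pairs Tibble with columns `x_R`, `y_R`, `x_S`, `y_S` (internal
#'   scale), e.g. from [pair_randomly()].
#' @param config A [game_config()].
#' @param price_rule Whose offer is the reimbursed price: the seller's
#'   (default, the seller-sets-price reading), the regulator's, or their
#'   midpoint.
#' @return `pairs` with `trade_possible`, `trade_successful`,
#'   `transaction_price` (internal scale, `NA` when unsuccessful),
#'   `regulator_bonus`, `seller_bonus` appended.
#' @export
evaluate_pairs <- function(pairs, config = game_config(),
                           price_rule = c("seller_offer", "regulator_offer",
                                          "midpoint")) {
  price_rule <- match.arg(price_rule)
  pairs$trade_possible <- pairs$x_S <= pairs$x_R
  pairs$trade_successful <- pairs$y_S <= pairs$y_R
  price <- switch(price_rule,
    seller_offer = pairs$y_S,
    regulator_offer = pairs$y_R,
    midpoint = (pairs$y_S + pairs$y_R) / 2
  )
  pairs$transaction_price <- ifelse(pairs$trade_successful, price, NA_real_)
  pairs$regulator_bonus <- ifelse(pairs$trade_successful,
                                  pairs$x_R - pairs$y_R, 0)
  pairs$seller_bonus <- ifelse(pairs$trade_successful,
                               pairs$y_S - pairs$x_S, 0)
  pairs
}

# aggregate one iteration of one (round, frame) cell into a market state
market_state_row <- function(pairs, config) {
  pool <- premium_pool(config)
  suc <- pairs[pairs$trade_successful, ]
  pos_r <- suc$regulator_bonus[suc$regulator_bonus > 0]
  pos_s <- suc$seller_bonus[suc$seller_bonus > 0]
  mean_or_na <- function(v) if (length(v) > 0) mean(v) else NA_real_
  tibble::tibble(
    n_pairs = nrow(pairs),
    n_trades_possible = sum(pairs$trade_possible),
    n_trades_successful = sum(pairs$trade_successful),
    pct_possible = sum(pairs$trade_possible) / nrow(pairs),
    pct_successful = sum(pairs$trade_successful) / nrow(pairs),
    n_regulator_bonus = length(pos_r),
    mean_regulator_bonus = internal_to_payoff(mean_or_na(pos_r), config),
    n_seller_bonus = length(pos_s),
    mean_seller_bonus = internal_to_payoff(mean_or_na(pos_s), config),
    mean_bonus = internal_to_payoff(mean_or_na(c(pos_r, pos_s)), config),
    mean_price = internal_to_payoff(mean_or_na(suc$transaction_price), config),
    payer_share = mean_or_na((pool - suc$transaction_price) / pool),
    investor_share = mean_or_na(suc$transaction_price / pool)
  )
}

#' Monte-Carlo market simulation by repeated random pairing
#'
#' For every iteration ("state of the society"), round and price frame,
#' eligible regulators and sellers are paired at random
#' ([pair_randomly()]), the pairs evaluated ([evaluate_pairs()]) and
#' aggregated into one market state. The default plan — 500 iterations over
#' 5 rounds and 2 frames — yields 5000 market states. Iterations are
#' independent resamples; all randomness flows from `seed`.
#'
#' Bonuses, prices and funder shares are reported on the payoff-$ scale so
#' the two frames are directly comparable; a cell with an empty side is
#' recorded with `n_pairs = 0` and excluded from summaries.
#'
#' @param population Long tibble of eligible player-rounds from
#'   [filter_population()] (columns `participant_id`, `role`,
#'   `price_group`, `round`, `x`, `y`).
#' @param iterations Number of pairing iterations per cell.
#' @param config A [game_config()].
#' @param price_rule Passed to [evaluate_pairs()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return A tibble of market states: one row per iteration x round x
#'   frame.
#' @export
simulate_markets <- function(population, iterations = 500,
                             config = game_config(),
                             price_rule = c("seller_offer", "regulator_offer",
                                            "midpoint"),
                             seed = NULL) {
  price_rule <- match.arg(price_rule)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(iterations >= 1)
  cells <- split(
    population,
    list(round = population$round, frame = population$price_group),
    drop = TRUE
  )
  out <- vector("list", length(cells))
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    round_i <- cell$round[1]
    frame_i <- cell$price_group[1]
    regs <- cell[cell$role == "regulator", ]
    sels <- cell[cell$role == "seller", ]
    if (nrow(regs) == 0 || nrow(sels) == 0) {
      warning("no pairs possible in round ", round_i, ", frame ", frame_i,
              "; cell recorded as empty", call. = FALSE)
      out[[ci]] <- tibble::tibble(
        iteration = seq_len(iterations), round = round_i, frame = frame_i,
        n_pairs = 0L
      )
      next
    }
    states <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      pairs <- evaluate_pairs(pair_randomly(regs, sels), config, price_rule)
      states[[it]] <- market_state_row(pairs, config)
    }
    states <- dplyr::bind_rows(states)
    states <- dplyr::mutate(states, iteration = dplyr::row_number(),
                            round = round_i, frame = frame_i,
                            .before = 1)
    out[[ci]] <- states
  }
  states <- dplyr::bind_rows(out)
  dplyr::arrange(states, .data$frame, .data$round, .data$iteration)
}

state_metric_cols <- function() {
  c("n_pairs", "n_trades_possible", "n_trades_successful",
    "pct_possible", "pct_successful",
    "n_regulator_bonus", "mean_regulator_bonus",
    "n_seller_bonus", "mean_seller_bonus", "mean_bonus",
    "mean_price", "payer_share", "investor_share")
}

#' Summarise market states across iterations
#'
#' Per round x frame cell: the mean of every market-state metric across
#' iterations with a normal-approximation 95% confidence interval
#' (`mean +/- 1.96 * sd / sqrt(n)`), plus grand averages over all non-empty
#' states (the weighted mean of the cells, weights = state counts) and the
#' success rate among possible trades.
#'
#' @param states Market states from [simulate_markets()].
#' @return A list of class `market_summary` with elements `cells` (tibble,
#'   columns `<metric>_mean`, `<metric>_lo`, `<metric>_hi`), `grand`
#'   (one-row tibble of overall means) and `n_iterations`.
#' @export
summarize_markets <- function(states) {
  if (nrow(states) == 0) stop("summarize_markets: no states", call. = FALSE)
  states <- states[states$n_pairs > 0, ]
  metrics <- intersect(state_metric_cols(), names(states))
  ci <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    if (n == 0) return(c(mean = NA_real_, lo = NA_real_, hi = NA_real_))
    m <- mean(v)
    half <- if (n > 1) 1.96 * stats::sd(v) / sqrt(n) else 0
    c(mean = m, lo = m - half, hi = m + half)
  }
  cells <- dplyr::summarise(
    dplyr::group_by(states, .data$round, .data$frame),
    n_states = dplyr::n(),
    dplyr::across(dplyr::all_of(metrics),
                  list(mean = ~ ci(.x)[["mean"]],
                       lo = ~ ci(.x)[["lo"]],
                       hi = ~ ci(.x)[["hi"]])),
    .groups = "drop"
  )
  grand <- dplyr::summarise(
    states,
    n_states = dplyr::n(),
    dplyr::across(dplyr::all_of(metrics), ~ mean(.x, na.rm = TRUE),
                  .names = "{.col}_mean")
  )
  grand$pct_successful_of_possible <-
    grand$n_trades_successful_mean / grand$n_trades_possible_mean
  structure(list(cells = cells, grand = grand,
                 n_iterations = max(states$iteration)),
            class = "market_summary")
}

#' @export
print.market_summary <- function(x, ...) {
  cat("<market_summary> ", nrow(x$cells), " cells, ",
      x$n_iterations, " iterations\n", sep = "")
  cat(sprintf("  grand averages: %.1f pairs, %.1f%% trades possible, %.1f%% successful (%.1f%% of possible)\n",
              x$grand$n_pairs_mean, 100 * x$grand$pct_possible_mean,
              100 * x$grand$pct_successful_mean,
              100 * x$grand$pct_successful_of_possible))
  invisible(x)
}

#' Funder redistribution over the innovation cycles
#'
#' Each round the payers fund a fresh premium pool (2.4 payoff-$ under the
#' default configuration); among successful pairs the mean transaction
#' price fixes how the pool splits between payers (pool minus price) and
#' investors (price). The trajectory accumulates these allocations on top
#' of the initial assets (4.8 payoff-$: 1.2 per funder). Because the
#' caption-level accounting can also be read as a single payoff round, the
#' totals are additionally reported for that variant (one pool only,
#' total assets 7.2), together with the division by ten applied for the
#' final payout.
#'
#' @param states Market states from [simulate_markets()].
#' @param config A [game_config()].
#' @return A list of class `redistribution` with `trajectory` (per round x
#'   frame: mean shares, pool allocations and cumulative assets, payoff-$),
#'   `totals` (per frame: final assets, net shift of the pool allocations
#'   from payers to investors relative to an even split, that shift as a
#'   share of initial assets, totals under both accounting variants, final
#'   payout) and `flagged` (cells where no pair ever succeeded, whose share
#'   is undefined).
#' @export
redistribution_trajectory <- function(states, config = game_config()) {
  ps <- payoff_scale(config)
  pool <- premium_pool(config) / ps
  init <- initial_assets(config) / ps

  per_cell <- dplyr::summarise(
    dplyr::group_by(states[states$n_pairs > 0, ], .data$frame, .data$round),
    n_states_with_trades = sum(!is.na(.data$investor_share)),
    investor_share = mean(.data$investor_share, na.rm = TRUE),
    payer_share = mean(.data$payer_share, na.rm = TRUE),
    .groups = "drop"
  )
  flagged <- per_cell[per_cell$n_states_with_trades == 0, c("frame", "round")]
  per_cell$investor_alloc <- pool * per_cell$investor_share
  per_cell$payer_alloc <- pool * per_cell$payer_share

  traj <- dplyr::mutate(
    dplyr::group_by(dplyr::arrange(per_cell, .data$frame, .data$round),
                    .data$frame),
    payer_assets_cum = init / 2 + cumsum(dplyr::coalesce(.data$payer_alloc, 0)),
    investor_assets_cum = init / 2 +
      cumsum(dplyr::coalesce(.data$investor_alloc, 0))
  )
  traj <- dplyr::ungroup(traj)

  totals <- dplyr::summarise(
    dplyr::group_by(traj, .data$frame),
    n_rounds = dplyr::n(),
    payer_final = init / 2 + sum(.data$payer_alloc, na.rm = TRUE),
    investor_final = init / 2 + sum(.data$investor_alloc, na.rm = TRUE),
    net_shift = sum(.data$investor_alloc - pool / 2, na.rm = TRUE),
    mean_investor_share = mean(.data$investor_share, na.rm = TRUE),
    .groups = "drop"
  )
  totals$total_assets <- totals$payer_final + totals$investor_final
  totals$net_shift_share_of_initial <- totals$net_shift / init
  # single-payoff-round reading: one pool on top of the initial assets
  totals$total_assets_single_round <- init + pool
  totals$investor_single_round <- init / 2 + pool * totals$mean_investor_share
  totals$final_payout <- totals$total_assets / config$payoff_divisor

  structure(list(trajectory = traj, totals = totals, flagged = flagged,
                 pool = pool, initial_assets = init),
            class = "redistribution")
}

#' Choose an iteration count by run-to-run stability
#'
#' Doubles the iteration count until two independent simulation runs agree,
#' in every round x frame cell, to within `tolerance` percentage points on
#' both the mean share of trades possible and the mean share of trades
#' successful. Deterministic given `seed` (each level derives its own
#' sub-seeds).
#'
#' @param population Eligible player-rounds from [filter_population()].
#' @param config A [game_config()].
#' @param tolerance Maximum allowed between-run difference, in percentage
#'   points (> 0).
#' @param initial,max_iterations Starting and maximum iteration counts.
#' @param price_rule Passed to [simulate_markets()].
#' @param seed Integer seed.
#' @return A list with `iterations` (chosen count), `converged` (logical),
#'   and `deltas` (per-cell achieved differences, percentage points, at the
#'   final level). If the cap is exceeded the best effort is returned with
#'   a warning.
#' @export
converge_iterations <- function(population, config = game_config(),
                                tolerance = 0.1, initial = 50,
                                max_iterations = 6400,
                                price_rule = "seller_offer", seed = 1) {
  stopifnot(tolerance > 0, initial >= 1)
  n <- initial
  level <- 0
  repeat {
    level <- level + 1
    a <- simulate_markets(population, n, config, price_rule,
                          seed = seed + 2 * level - 1)
    b <- simulate_markets(population, n, config, price_rule,
                          seed = seed + 2 * level)
    cell_means <- function(s) dplyr::summarise(
      dplyr::group_by(s[s$n_pairs > 0, ], .data$round, .data$frame),
      pct_possible = mean(.data$pct_possible),
      pct_successful = mean(.data$pct_successful),
      .groups = "drop")
    ma <- cell_means(a)
    mb <- cell_means(b)
    deltas <- dplyr::mutate(
      dplyr::inner_join(ma, mb, by = c("round", "frame"),
                        suffix = c("_a", "_b")),
      delta_possible = 100 * abs(.data$pct_possible_a - .data$pct_possible_b),
      delta_successful = 100 * abs(.data$pct_successful_a - .data$pct_successful_b)
    )
    worst <- max(deltas$delta_possible, deltas$delta_successful)
    if (worst <= tolerance) {
      return(list(iterations = n, converged = TRUE,
                  deltas = deltas[c("round", "frame",
                                    "delta_possible", "delta_successful")]))
    }
    if (n >= max_iterations) {
      warning("converge_iterations: cap of ", max_iterations,
              " iterations reached with worst delta ",
              sprintf("%.3f", worst), " pp", call. = FALSE)
      return(list(iterations = n, converged = FALSE,
                  deltas = deltas[c("round", "frame",
                                    "delta_possible", "delta_successful")]))
    }
    n <- min(2 * n, max_iterations)
  }
}
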