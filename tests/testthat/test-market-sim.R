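toy_sides <- function(nr, ns, seed = 1) {
  set.seed(seed)
  list(
    regs = tibble::tibble(participant_id = sprintf("R%02d", 1:nr),
                          x = sample(100:400, nr), y = sample(100:400, nr)),
    sels = tibble::tibble(participant_id = sprintf("S%02d", 1:ns),
                          x = sample(100:400, ns), y = sample(100:400, ns))
  )
}

test_that("random pairing is a bijection on the smaller side's size", {
  s <- toy_sides(3, 3)
  set.seed(2)
  p <- pair_randomly(s$regs, s$sels)
  expect_equal(nrow(p), 3)
  expect_setequal(p$regulator_id, s$regs$participant_id)
  expect_setequal(p$seller_id, s$sels$participant_id)

  s2 <- toy_sides(5, 3)
  p2 <- pair_randomly(s2$regs, s2$sels)
  expect_equal(nrow(p2), 3)
  expect_false(anyDuplicated(p2$regulator_id) > 0)

  set.seed(7); a <- pair_randomly(s$regs, s$sels)
  set.seed(7); b <- pair_randomly(s$regs, s$sels)
  expect_identical(a, b)
  expect_error(pair_randomly(s$regs[0, ], s$sels), "non-empty")
})

test_that("pair evaluation applies the agreement and bonus rules", {
  pairs <- tibble::tibble(
    x_R = c(250, 250, 150), y_R = c(200, 200, 140),
    x_S = c(150, 150, 150), y_S = c(200, 201, 180)
  )
  ev <- evaluate_pairs(pairs)
  # equality trades; one price unit above does not
  expect_identical(ev$trade_successful, c(TRUE, FALSE, FALSE))
  # possible (x_S <= x_R) is independent of the offers closing
  expect_identical(ev$trade_possible, c(TRUE, TRUE, TRUE))
  expect_equal(ev$regulator_bonus, c(50, 0, 0))
  expect_equal(ev$seller_bonus, c(50, 0, 0))
  expect_identical(is.na(ev$transaction_price), c(FALSE, TRUE, TRUE))
  expect_equal(ev$transaction_price[1], 200)  # seller sets the price

  expect_equal(evaluate_pairs(pairs, price_rule = "regulator_offer")$transaction_price[1], 200)
  mid <- evaluate_pairs(tibble::tibble(x_R = 300, y_R = 260, x_S = 100, y_S = 200),
                        price_rule = "midpoint")
  expect_equal(mid$transaction_price, 230)
})

test_that("successful trades are a subset of possible ones for consistent offers", {
  cohort <- generate_cohort(seed = 21)
  pop <- filter_population(cohort, consistency = "per_round")
  states <- simulate_markets(pop, iterations = 10, seed = 22)
  expect_true(all(states$n_trades_successful <= states$n_trades_possible))
  expect_true(all(states$n_trades_possible <= states$n_pairs))
  expect_true(all(states$pct_successful <= states$pct_possible))
})

test_that("funder conservation holds in every successful pair", {
  s <- toy_sides(40, 40, seed = 23)
  set.seed(24)
  ev <- evaluate_pairs(pair_randomly(s$regs, s$sels))
  suc <- ev[ev$trade_successful, ]
  fb <- funder_benefits(suc$transaction_price)
  expect_true(all(fb$payer_total + fb$investor_total == 240))
  # unsuccessful pairs carry no bonuses
  expect_true(all(ev$regulator_bonus[!ev$trade_successful] == 0))
  expect_true(all(ev$seller_bonus[!ev$trade_successful] == 0))
})

test_that("simulation is deterministic under seed and shaped iterations x cells", {
  cohort <- generate_cohort(
    cohort_spec(n_per_group = c(regulator_100k = 25, seller_100k = 25,
                                regulator_1 = 25, seller_1 = 25)),
    seed = 25)
  pop <- filter_population(cohort)
  a <- simulate_markets(pop, iterations = 7, seed = 26)
  b <- simulate_markets(pop, iterations = 7, seed = 26)
  expect_identical(a, b)
  expect_equal(nrow(a), 7 * 5 * 2)
  expect_setequal(unique(a$round), 1:5)
  expect_setequal(unique(a$frame), c("1", "100k"))
})

test_that("a population whose sellers always overbid never trades", {
  pop <- make_population(reg_x = rep(200, 10), reg_y = rep(150, 10),
                         sell_x = rep(250, 10), sell_y = rep(300, 10))
  states <- simulate_markets(pop, iterations = 5, seed = 27)
  expect_true(all(states$pct_successful == 0))
  expect_true(all(is.na(states$mean_price)))
})

test_that("cells with an empty side are recorded empty and excluded from summaries", {
  pop <- make_population(reg_x = rep(200, 5), reg_y = rep(180, 5),
                         sell_x = numeric(0), sell_y = numeric(0))
  pop2 <- make_population(reg_x = rep(200, 5), reg_y = rep(180, 5),
                          sell_x = rep(150, 5), sell_y = rep(170, 5),
                          round = 2L)
  expect_warning(
    states <- simulate_markets(dplyr::bind_rows(pop, pop2), iterations = 4,
                               seed = 28),
    "empty"
  )
  expect_true(all(states$n_pairs[states$round == 1] == 0))
  sm <- summarize_markets(states)
  expect_equal(nrow(sm$cells), 1)
  expect_equal(sm$cells$round, 2)
})

test_that("frame invariance: relabelled frames simulate identically", {
  set.seed(30)
  pop1 <- make_population(reg_x = sample(100:400, 30),
                          reg_y = sample(100:400, 30),
                          sell_x = sample(100:400, 30),
                          sell_y = sample(100:400, 30), frame = "1")
  pop100k <- pop1
  pop100k$price_group <- "100k"
  a <- simulate_markets(pop1, iterations = 6, seed = 31)
  b <- simulate_markets(pop100k, iterations = 6, seed = 31)
  expect_identical(a[setdiff(names(a), "frame")],
                   b[setdiff(names(b), "frame")])
})

test_that("summaries average states and shrink CIs with more iterations", {
  pop <- make_population(reg_x = seq(150, 295, 5), reg_y = seq(140, 285, 5),
                         sell_x = seq(100, 245, 5), sell_y = seq(120, 265, 5))
  one <- simulate_markets(pop, iterations = 1, seed = 32)
  sm1 <- summarize_markets(one)
  expect_equal(sm1$cells$pct_possible_mean, one$pct_possible)
  expect_equal(sm1$cells$pct_possible_lo, sm1$cells$pct_possible_hi)

  many <- simulate_markets(pop, iterations = 40, seed = 33)
  dup <- dplyr::mutate(dplyr::bind_rows(many, many),
                       iteration = dplyr::row_number())
  sm_many <- summarize_markets(many)
  sm_dup <- summarize_markets(dup)
  expect_equal(sm_dup$cells$pct_possible_mean, sm_many$cells$pct_possible_mean)
  width <- function(s) s$cells$pct_possible_hi - s$cells$pct_possible_lo
  expect_lt(width(sm_dup), width(sm_many))

  # grand averages are the state-weighted means of the cells
  states <- simulate_markets(
    dplyr::bind_rows(pop, dplyr::mutate(pop, round = 2L)),
    iterations = 15, seed = 34)
  sm <- summarize_markets(states)
  expect_equal(sm$grand$pct_possible_mean, mean(states$pct_possible))
  expect_equal(
    sm$grand$pct_possible_mean,
    weighted.mean(sm$cells$pct_possible_mean, sm$cells$n_states))
})

test_that("redistribution splits the round pool by the transaction price", {
  # every transaction at 120 -> the funders' equality point, 50:50
  pop <- make_population(reg_x = rep(200, 8), reg_y = rep(120, 8),
                         sell_x = rep(100, 8), sell_y = rep(120, 8))
  states <- simulate_markets(pop, iterations = 5, seed = 35)
  red <- redistribution_trajectory(states)
  expect_equal(red$trajectory$payer_share, 0.5)
  expect_equal(red$trajectory$investor_share, 0.5)
  expect_equal(red$totals$net_shift, 0)

  # price at the pool maximum -> payers keep nothing
  pop_max <- make_population(reg_x = rep(300, 8), reg_y = rep(240, 8),
                             sell_x = rep(100, 8), sell_y = rep(240, 8))
  red_max <- redistribution_trajectory(
    simulate_markets(pop_max, iterations = 5, seed = 36))
  expect_equal(red_max$trajectory$payer_share, 0)

  # fixed price 154 -> investor share 154/240
  pop_154 <- make_population(reg_x = rep(300, 8), reg_y = rep(154, 8),
                             sell_x = rep(100, 8), sell_y = rep(154, 8))
  red_154 <- redistribution_trajectory(
    simulate_markets(pop_154, iterations = 5, seed = 37))
  expect_equal(red_154$trajectory$investor_share, 154 / 240)
})

test_that("redistribution accumulates assets under both accounting readings", {
  pops <- purrr::map(1:5, function(r) {
    make_population(reg_x = rep(300, 8), reg_y = rep(120, 8),
                    sell_x = rep(100, 8), sell_y = rep(120, 8),
                    round = r)
  })
  states <- simulate_markets(dplyr::bind_rows(pops), iterations = 3, seed = 38)
  red <- redistribution_trajectory(states)
  # even split every round: each side climbs from 2.4 by 1.2 per round
  expect_equal(red$trajectory$payer_assets_cum, 2.4 + 1.2 * (1:5))
  expect_equal(red$totals$total_assets, 4.8 + 5 * 2.4)
  expect_equal(red$totals$total_assets_single_round, 7.2)
  expect_equal(red$totals$final_payout, (4.8 + 5 * 2.4) / 10)

  # a round with no successful pairs is flagged, not silently averaged
  no_trade <- make_population(reg_x = rep(200, 8), reg_y = rep(100, 8),
                              sell_x = rep(150, 8), sell_y = rep(300, 8),
                              round = 3L)
  states2 <- simulate_markets(
    dplyr::bind_rows(pops[[1]], no_trade), iterations = 3, seed = 39)
  red2 <- redistribution_trajectory(states2)
  expect_equal(red2$flagged$round, 3)
})

test_that("Monte-Carlo cell means agree with exhaustive pairing enumeration", {
  set.seed(40)
  nr <- 5
  regs_x <- sample(150:350, nr); regs_y <- regs_x - sample(0:60, nr, TRUE)
  sels_x <- sample(100:300, nr); sels_y <- sels_x + sample(0:60, nr, TRUE)
  pop <- make_population(regs_x, regs_y, sels_x, sels_y)

  perms <- all_permutations(nr)
  enum_poss <- enum_succ <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    enum_poss[i] <- mean(sels_x[p] <= regs_x)
    enum_succ[i] <- mean(sels_y[p] <= regs_y)
  }
  states <- simulate_markets(pop, iterations = 400, seed = 41)
  mc_se <- function(v) max(sd(v) / sqrt(length(v)), 1e-9)
  expect_lt(abs(mean(states$pct_possible) - mean(enum_poss)),
            3 * mc_se(states$pct_possible))
  expect_lt(abs(mean(states$pct_successful) - mean(enum_succ)),
            3 * mc_se(states$pct_successful))
})

test_that("iteration convergence is deterministic and immediate for degenerate markets", {
  # one pair possible -> both runs identical at the minimum count
  pop <- make_population(reg_x = 200, reg_y = 180, sell_x = 150, sell_y = 170)
  res <- converge_iterations(pop, tolerance = 0.1, initial = 10, seed = 42)
  expect_true(res$converged)
  expect_equal(res$iterations, 10)
  res2 <- converge_iterations(pop, tolerance = 0.1, initial = 10, seed = 42)
  expect_identical(res, res2)
})

test_that("iteration convergence reports best effort when capped", {
  set.seed(43)
  pop <- make_population(reg_x = sample(100:400, 12),
                         reg_y = sample(100:400, 12),
                         sell_x = sample(100:400, 12),
                         sell_y = sample(100:400, 12))
  expect_warning(
    res <- converge_iterations(pop, tolerance = 0.001, initial = 10,
                               max_iterations = 40, seed = 44),
    "cap"
  )
  expect_false(res$converged)
  expect_equal(res$iterations, 40)
})
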