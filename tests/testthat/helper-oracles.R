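# Independent textbook-formula oracles and small fixture builders.
# These deliberately avoid the package's own code paths (and stats::t.test /
# stats::wilcox.test where they are what the package calls), so they can
# serve as cross-checks.

oracle_one_sample_t <- function(v, mu = 0, alternative = "two.sided") {
  n <- length(v)
  t <- (mean(v) - mu) / (sd(v) / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t), df),
    greater = pt(t, df, lower.tail = FALSE),
    less = pt(t, df)
  )
  list(statistic = t, p = p, df = df)
}

oracle_welch_t <- function(a, b, alternative = "two.sided") {
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a) / n1; v2 <- var(b) / n2
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(t), df),
    greater = pt(t, df, lower.tail = FALSE),
    less = pt(t, df)
  )
  list(statistic = t, p = p, df = df)
}

# Mann-Whitney U, normal approximation with tie correction and continuity
# correction (two-sided)
oracle_mann_whitney_normal <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  z <- W - n1 * n2 / 2
  ties <- table(r)
  sigma <- sqrt((n1 * n2 / 12) *
                ((n1 + n2 + 1) - sum(ties^3 - ties) /
                   ((n1 + n2) * (n1 + n2 - 1))))
  z <- (z - sign(z) * 0.5) / sigma
  p <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
  list(statistic = W, p = min(p, 1))
}

# exact two-sided Mann-Whitney for tie-free samples via the U distribution
oracle_mann_whitney_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  stopifnot(!any(duplicated(c(a, b))))
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  p <- if (W > n1 * n2 / 2) pwilcox(W - 1, n1, n2, lower.tail = FALSE)
       else pwilcox(W, n1, n2)
  list(statistic = W, p = min(2 * p, 1))
}

# all permutations of 1..n (n small), one per row
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1
    }
  }
  out
}

# long eligible-population tibble straight from price vectors
# (internal thousand-$ scale), bypassing cohort construction
make_population <- function(reg_x, reg_y, sell_x, sell_y,
                            round = 1L, frame = "1") {
  stopifnot(length(reg_x) == length(reg_y),
            length(sell_x) == length(sell_y))
  n_r <- length(reg_x); n_s <- length(sell_x)
  pop <- tibble::tibble(
    participant_id = c(sprintf("R%03d", seq_len(n_r)),
                       sprintf("S%03d", seq_len(n_s))),
    role = c(rep("regulator", n_r), rep("seller", n_s)),
    price_group = frame,
    round = as.integer(round),
    x = c(reg_x, sell_x),
    y = c(reg_y, sell_y)
  )
  pop$consistent <- offer_consistent(pop$role, pop$x, pop$y)
  pop$margin <- margin(pop$role, pop$x, pop$y)
  pop$x_payoff <- pop$x / 100
  pop$y_payoff <- pop$y / 100
  pop$margin_payoff <- pop$margin / 100
  pop
}

# small wide cohort from per-participant reservation/offer matrices
# (internal scale); flags default to all-correct
make_cohort <- function(role, frame, x, y,
                        screening = TRUE, comprehension = TRUE) {
  x <- matrix(x, ncol = 5, byrow = TRUE)
  y <- matrix(y, ncol = 5, byrow = TRUE)
  n <- nrow(x)
  tibble::tibble(
    participant_id = sprintf("T%03d", seq_len(n)),
    role = rep_len(role, n),
    price_group = rep_len(frame, n),
    x1 = x[, 1], x2 = x[, 2], x3 = x[, 3], x4 = x[, 4], x5 = x[, 5],
    y1 = y[, 1], y2 = y[, 2], y3 = y[, 3], y4 = y[, 4], y5 = y[, 5],
    screening_correct = rep_len(screening, n),
    comprehension_correct = rep_len(comprehension, n)
  )
}
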