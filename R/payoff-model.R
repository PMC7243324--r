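#' Round states of the negotiation game
#'
#' The game is played over five product rounds preceded by two reference
#' states: the "no product" state (no treatment at all) and the standard of
#' care (SoC), the already-reimbursed comparator. Each state carries the
#' patient's survival in months and quality of life as a work-ability
#' fraction. Survival increases strictly from the SoC through round 5.
#'
#' @return A tibble with columns `index` (-1 = no product, 0 = SoC,
#'   1..5 = product rounds), `state` (label), `survival_m` (months) and
#'   `quality_q` (fraction in \[0, 1\]).
#' @export
default_round_states <- function() {
  tibble::tibble(
    index      = -1:5,
    state      = c("no_product", "soc", paste0("product_", 1:5)),
    survival_m = c(0, 5, 8, 10, 12, 15, 17),
    quality_q  = rep(0.5, 7)
  )
}

#' Economic configuration of the negotiation game
#'
#' Bundles every economic parameter of the reimbursement game: admissible
#' price range, the healthy full-time salary that monetises quality of life,
#' the deciders' fixed salary, the premium pool funded by the payers, the
#' investors compensated by the reimbursed price, and the conversion between
#' game currency and final payoff dollars.
#'
#' All money fields are stored in thousand-$ of the "real world" (100k)
#' price frame; 1$-frame inputs are up-scaled on ingestion so that a single
#' numeric scale runs through the whole pipeline. One payoff-$ corresponds
#' to 100,000 game-$, i.e. 100 internal units.
#'
#' @param price_min,price_max Admissible price range (thousand-$). The floor
#'   is the price of the standard of care.
#' @param monthly_salary_healthy Full-time monthly salary of a healthy
#'   person (thousand-$); quality of life equals work ability as a fraction
#'   of this salary.
#' @param decider_fixed_salary Fixed per-round salary of regulator and
#'   seller (thousand-$).
#' @param payer_premium_per_payer Premium each payer contributes per round
#'   (thousand-$). The premium pool per round is `n_payers` times this.
#' @param n_payers,n_investors Number of premium payers / investors.
#' @param initial_asset_per_funder Starting asset of each funder
#'   (thousand-$).
#' @param conversion_factor Game-$ per payoff-$ (100,000 by default).
#' @param payoff_divisor Final payoff division applied after the experiment.
#' @param rounds Tibble of round states, see [default_round_states()].
#'
#' @return An object of class `game_config` (a validated list).
#' @examples
#' cfg <- game_config()
#' premium_pool(cfg)     # 240 thousand-$ = 2.4 payoff-$
#' initial_assets(cfg)   # 480 thousand-$ = 4.8 payoff-$
#' @export
game_config <- function(price_min = 50,
                        price_max = 500,
                        monthly_salary_healthy = 10,
                        decider_fixed_salary = 120,
                        payer_premium_per_payer = 120,
                        n_payers = 2,
                        n_investors = 2,
                        initial_asset_per_funder = 120,
                        conversion_factor = 1e5,
                        payoff_divisor = 10,
                        rounds = default_round_states()) {
  cfg <- list(
    price_min = price_min,
    price_max = price_max,
    monthly_salary_healthy = monthly_salary_healthy,
    decider_fixed_salary = decider_fixed_salary,
    payer_premium_per_payer = payer_premium_per_payer,
    n_payers = n_payers,
    n_investors = n_investors,
    initial_asset_per_funder = initial_asset_per_funder,
    conversion_factor = conversion_factor,
    payoff_divisor = payoff_divisor,
    rounds = tibble::as_tibble(rounds)
  )
  validate_game_config(cfg)
  structure(cfg, class = "game_config")
}

validate_game_config <- function(cfg) {
  money <- c("price_min", "price_max", "monthly_salary_healthy",
             "decider_fixed_salary", "payer_premium_per_payer",
             "initial_asset_per_funder")
  for (f in money) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("game_config: `", f, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (cfg$price_min >= cfg$price_max) {
    stop("game_config: price_min must be below price_max", call. = FALSE)
  }
  r <- cfg$rounds
  need <- c("index", "survival_m", "quality_q")
  if (!all(need %in% names(r))) {
    stop("game_config: rounds must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(r$index, strictly = TRUE)) {
    stop("game_config: round indices must be strictly ordered", call. = FALSE)
  }
  if (any(r$survival_m < 0) || any(r$quality_q < 0 | r$quality_q > 1)) {
    stop("game_config: survival must be >= 0 and quality within [0, 1]",
         call. = FALSE)
  }
  main <- r[r$index >= 0, ]
  if (nrow(main) > 1 && is.unsorted(main$survival_m, strictly = TRUE)) {
    stop("game_config: survival must increase strictly from the SoC onwards",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config>\n")
  cat(sprintf("  price range: %g - %g thousand-$ (%.2f - %.2f payoff-$)\n",
              x$price_min, x$price_max,
              x$price_min / payoff_scale(x), x$price_max / payoff_scale(x)))
  cat(sprintf("  premium pool / round: %g (%.2f payoff-$), initial assets: %g (%.2f payoff-$)\n",
              premium_pool(x), premium_pool(x) / payoff_scale(x),
              initial_assets(x), initial_assets(x) / payoff_scale(x)))
  cat(sprintf("  deciders: fixed salary %g; funders: %d payers, %d investors\n",
              x$decider_fixed_salary, x$n_payers, x$n_investors))
  cat(sprintf("  rounds: %d states (survival %g-%g months)\n",
              nrow(x$rounds), min(x$rounds$survival_m), max(x$rounds$survival_m)))
  invisible(x)
}

# internal thousand-$ per payoff-$ (100 under the default conversion)
payoff_scale <- function(config) config$conversion_factor / 1000

#' Premium pool and initial funder assets
#'
#' `premium_pool()` is the total premium available per round
#' (`n_payers * payer_premium_per_payer`); `initial_assets()` is the total
#' starting asset across all funders. Both in thousand-$.
#'
#' @param config A [game_config()].
#' @return A single number (thousand-$).
#' @export
premium_pool <- function(config) config$n_payers * config$payer_premium_per_payer

#' @rdname premium_pool
#' @export
initial_assets <- function(config) {
  (config$n_payers + config$n_investors) * config$initial_asset_per_funder
}

#' Monetised patient benefit of a health state
#'
#' The patient's outcome converts to an economic benefit: quality of life
#' equals work ability in percent of a healthy full-time salary, so the
#' benefit of a state is `survival_m * quality_q * monthly_salary`. Linear
#' and monotone non-decreasing in every argument.
#'
#' @param survival_m Survival in months (>= 0).
#' @param quality_q Quality of life as a fraction in \[0, 1\].
#' @param monthly_salary Healthy monthly salary (thousand-$), default 10.
#' @return Benefit in thousand-$ (vectorised).
#' @examples
#' patient_benefit(5, 0.5)   # SoC state: 25
#' patient_benefit(17, 0.5)  # round 5: 85
#' @export
patient_benefit <- function(survival_m, quality_q, monthly_salary = 10) {
  if (any(!is.finite(survival_m)) || any(survival_m < 0)) {
    stop("patient_benefit: survival_m must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(quality_q)) || any(quality_q < 0 | quality_q > 1)) {
    stop("patient_benefit: quality_q must lie in [0, 1]", call. = FALSE)
  }
  if (any(monthly_salary <= 0)) {
    stop("patient_benefit: monthly_salary must be positive", call. = FALSE)
  }
  survival_m * quality_q * monthly_salary
}

#' Funder benefits at a transaction price
#'
#' Splits the consequences of a reimbursed price between the two funder
#' groups: the payers keep whatever the premium pool leaves after paying the
#' price, the investors receive the price. Per-capita amounts are equal
#' splits. Conservation holds for every price: payer total plus investor
#' total equals the premium pool.
#'
#' @param transaction_price Reimbursed price (thousand-$), vectorised.
#' @param config A [game_config()].
#' @return A tibble with columns `transaction_price`, `payer_total`,
#'   `investor_total`, `payer_per_capita`, `investor_per_capita`
#'   (thousand-$).
#' @examples
#' funder_benefits(120)  # equality point: 120 / 120
#' @export
funder_benefits <- function(transaction_price, config = game_config()) {
  if (any(!is.finite(transaction_price))) {
    stop("funder_benefits: transaction_price must be finite", call. = FALSE)
  }
  if (any(transaction_price < config$price_min |
          transaction_price > config$price_max)) {
    stop("funder_benefits: transaction_price outside the admissible range [",
         config$price_min, ", ", config$price_max, "]", call. = FALSE)
  }
  pool <- premium_pool(config)
  tibble::tibble(
    transaction_price = transaction_price,
    payer_total = pool - transaction_price,
    investor_total = transaction_price,
    payer_per_capita = (pool - transaction_price) / config$n_payers,
    investor_per_capita = transaction_price / config$n_investors
  )
}

#' Decider payoff (fixed salary plus bonus)
#'
#' Regulator and seller receive the fixed salary in every round. In the
#' offer game a successful agreement additionally pays the decider the
#' margin between their private reservation price and their offer:
#' `x - y` for the regulator, `y - x` for the seller. The reservation game
#' carries no bonus.
#'
#' @param role `"regulator"` or `"seller"`.
#' @param reservation_x,offer_y Reservation price and price offer
#'   (thousand-$), within the configured price bounds.
#' @param agreement Logical: did the matched pair close (`y_S <= y_R`)?
#' @param game `"offer"` (bonus applies) or `"reservation"` (no bonus).
#' @param config A [game_config()].
#' @return Payoff in thousand-$ (vectorised over x, y, agreement).
#' @export
decider_payoff <- function(role, reservation_x, offer_y, agreement,
                           game = c("offer", "reservation"),
                           config = game_config()) {
  role <- match.arg(role, c("regulator", "seller"))
  game <- match.arg(game)
  for (v in list(reservation_x, offer_y)) {
    if (any(v < config$price_min | v > config$price_max)) {
      stop("decider_payoff: prices must lie within [", config$price_min,
           ", ", config$price_max, "]", call. = FALSE)
    }
  }
  bonus <- if (game == "offer") {
    ifelse(agreement,
           if (role == "regulator") reservation_x - offer_y
           else offer_y - reservation_x,
           0)
  } else {
    0
  }
  config$decider_fixed_salary + bonus
}

#' Convert money between price frames and the payoff scale
#'
#' The 100k-frame groups negotiated in fictive "real world" magnitudes that
#' convert at 100,000 game-$ = 1 payoff-$ (displayed in thousand-$, hence
#' divided by 100); the 1$-frame groups negotiated directly in payoff
#' dollars. `convert_price()` maps an amount from its frame to the payoff
#' scale; the mapping is exact linear scaling and round-trips at the
#' declared precision.
#'
#' @param amount Numeric amount(s), finite.
#' @param from_frame `"100k"` or `"1"`.
#' @param unit For the 100k frame, whether `amount` is in `"thousand"`
#'   game-$ (the display unit, default) or raw `"dollar"` game-$. Ignored
#'   for the 1$ frame, whose display unit is already the payoff dollar.
#' @param config A [game_config()] supplying the conversion factor.
#' @return Amount(s) in payoff-$.
#' @examples
#' convert_price(120, "100k")             # 1.2 payoff-$
#' convert_price(1e5, "100k", "dollar")   # 1 payoff-$
#' @export
convert_price <- function(amount, from_frame, unit = c("thousand", "dollar"),
                          config = game_config()) {
  if (any(!is.finite(amount))) {
    stop("convert_price: amount must be finite", call. = FALSE)
  }
  if (length(from_frame) != 1 || !from_frame %in% c("100k", "1")) {
    stop("convert_price: unknown price frame `", paste(from_frame, collapse = ","),
         "`; expected \"100k\" or \"1\"", call. = FALSE)
  }
  unit <- match.arg(unit)
  if (from_frame == "1") return(amount)
  if (unit == "dollar") amount / config$conversion_factor
  else amount / payoff_scale(config)
}

# native display unit -> internal thousand-$ of the 100k frame
price_to_internal <- function(amount, frame, config = game_config()) {
  if (!all(frame %in% c("100k", "1"))) {
    stop("unknown price frame; expected \"100k\" or \"1\"", call. = FALSE)
  }
  ifelse(frame == "1", amount * payoff_scale(config), amount)
}

# internal thousand-$ -> payoff-$
internal_to_payoff <- function(amount, config = game_config()) {
  amount / payoff_scale(config)
}

#' Read / write a game configuration as JSON or YAML
#'
#' The shipped default (`system.file("extdata", "default_config.json",
#' package = "bargainsim")`) reproduces the experiment's parameterisation.
#'
#' @param path File path; format decided by extension (`.json`, `.yaml`/`.yml`).
#' @return `read_game_config()` returns a [game_config()];
#'   `write_game_config()` returns `path` invisibly.
#' @export
read_game_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::fromJSON(path)
  rounds <- tibble::as_tibble(raw$rounds)
  raw$rounds <- NULL
  do.call(game_config, c(raw, list(rounds = rounds)))
}

#' @rdname read_game_config
#' @param config A [game_config()] to serialise.
#' @export
write_game_config <- function(config, path) {
  out <- unclass(config)
  out$rounds <- as.data.frame(out$rounds)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(out, path)
  } else {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}
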