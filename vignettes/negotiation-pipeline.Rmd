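---
title: "Modelling bilateral reimbursement negotiations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling bilateral reimbursement negotiations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bargainsim)
```

## The setting

`bargainsim` analyses a stylised price negotiation for a new
life-extending pharmaceutical. Two deciders bargain: a **regulator**
(the buyer, whose reservation price is a willingness to pay, WTP) and a
**seller** (whose reservation price is a willingness to accept, WTA).
Five more stakeholders absorb the consequences: a patient whose survival
and quality of life improve with each successive product round, two
premium payers who fund reimbursement from a fixed premium pool, and two
investors who receive the reimbursed price. Deciders first state private
reservation prices ($x$) over five rounds of increasing patient benefit,
then submit incentivised price offers ($y$). A matched pair agrees when
the seller's offer does not exceed the regulator's ($y_S \le y_R$); a
pair *could* have agreed whenever the reservation prices overlap
($x_S \le x_R$).

Two price framings are compared: a "real world" frame (prices of
50,000–500,000 game-\$, converted at 100,000 game-\$ = 1 payoff-\$) and a
direct payoff frame (0.50–5.00 \$). The package stores all money in
thousand-\$ of the real-world frame — one payoff-\$ is 100 internal
units — and up-scales payoff-frame inputs on ingestion, so a single
exact integer grid (1 thousand-\$ = 0.01 payoff-\$) runs through the
pipeline and money comparisons need no epsilon.

## The payoff model

The patient's outcome is monetised through work ability: a state with
survival $m$ months and quality of life $q$ is worth
$m \cdot q \cdot s$ with $s$ the healthy monthly salary (10 thousand-\$).
The seven states (no product; standard of care with $m = 5$; five
product rounds with $m = 8, 10, 12, 15, 17$, all at $q = 50\%$) are
therefore worth 0, 25, 40, 50, 60, 75 and 85 thousand-\$:

```{r}
states <- default_round_states()
patient_benefit(states$survival_m, states$quality_q)
```

Per round the two payers contribute a premium pool of 240 thousand-\$
(2.4 payoff-\$). A reimbursed price $y$ splits it: payers keep
$240 - y$, investors receive $y$ — conserved identically for every
admissible price, with equality at 120 thousand-\$ (1.2 payoff-\$).
Deciders earn a fixed round salary of 120; in the offer game a
successful agreement additionally pays each decider their own margin,
$x_R - y_R$ for the regulator and $y_S - x_S$ for the seller. Every
funder starts with assets of 1.2 payoff-\$ (4.8 in total).

## Participant records and inclusion filters

A participant record carries role, price frame, five reservation prices,
five offers and two control flags (attention screening, comprehension).
Three filters define the analysis population:

* **strict monotone preferences** — reservation prices strictly
  increasing over rounds (more patient benefit must be worth strictly
  more);
* **offer consistency** — an offer must not cross the decider's own
  reservation price ($y_S \ge x_S$, $y_R \le x_R$; equality allowed).
  Both reported modes are first-class: `per_round` drops only the
  offending player-rounds, `all_rounds` drops every round of a player
  with any inconsistent offer;
* **screening/comprehension** — optional whole-participant flags.

The signed **margin** ($x_R - y_R$ or $y_S - x_S$) is non-negative
exactly when the offer is consistent, a property the test suite checks
over randomised cases. Records with missing values are rejected at
ingestion because the experiment forced complete responses — a hole in
the data is an error, not a missing-at-random observation.

## The synthetic cohort generator

The generator exists so every downstream stage is testable without the
deposited participant data. It emulates the *structure* the analysis
assumes, not the empirical distributions of any particular sample:

* four treatment groups with the experiment's cell sizes
  (97/101/105/101);
* round-1 reservation prices from a truncated normal per group,
  strictly positive per-round increments (exponential, floored at one
  grid step). Increment vectors that would push round 5 beyond the price
  ceiling are **resampled, not clipped**, so strict monotonicity is
  preserved exactly;
* offers built from a mixture: a persistent share of players who never
  claim a margin (default 0.15), a per-round zero-margin probability for
  the rest (default 0.09), otherwise a positive exponential margin
  (mean 0.20 payoff-\$) on the role-appropriate side. The two
  zero-margin defaults were calibrated once so that the implied shares
  of "never claims a margin" (15%) and "forgoes the margin at least
  once" ($0.15 + 0.85\,(1-(1-0.09)^5) \approx 47\%$) match the pattern
  the experiment reported;
* defects injected at fixed rates: inconsistent offers (wrong side of
  the reservation price, default 0.10 per player-round) and
  non-monotone reservation profiles (default 0.25 per participant).
  Neither rate is reported for the original sample; both were chosen
  once as realistic for an online crowd-sourced cohort (where roughly
  nine in ten players managed at least one consistent offer) and are
  configuration, not constants.
* base-price means (1.5/1.7 payoff-\$ for 100k-frame regulators/sellers,
  1.9/1.6 for the payoff frame) place regulators lower in the
  real-world frame and create a negative role gap in the payoff frame —
  the two directional findings the design is meant to reproduce
  qualitatively. The exact values are conventional choices.

`recover_parameters()` reports the *observable* rates (inconsistent
player-round share, zero-margin share among consistent rounds, share of
players with all-zero margins, mean positive margin). With a persistent
zero-margin mass these are mixtures of the generator parameters —
persistent players can never be inconsistent — so parameter-recovery
validation uses `persistent_zero_prob = 0`, where the mapping is the
identity. Everything is reproducible under a single integer seed.

What passing tests on synthetic cohorts do **not** show: that real
participants follow truncated-normal prices, exponential margins, or
independent per-round defects. They show that the pipeline's filters,
matching, accounting and tests are correct conditional on data of the
declared structure.

## The market simulation

The headline computation matches regulators and sellers at random,
separately per round and price frame. One *market state* is the
aggregate of one random pairing of one cell: `min(n_R, n_S)`
participants are sampled without replacement from each side and joined
by a uniform random bijection; surplus players on the larger side sit
out that draw. The default plan — 500 iterations × 5 rounds × 2
frames — yields 5000 market states. Iterations are independent
resamples.

For consistent offers the chain $x_S \le y_S \le y_R \le x_R$ makes
successful trades a subset of possible ones in every pair, hence
`pct_successful <= pct_possible` in every state. Bonuses are
non-negative and zero in unsuccessful pairs. Because the expectation of
a cell mean over a uniform random bijection equals the all-pairs mean,
the Monte-Carlo means are checked in the test suite against brute-force
enumeration of *all* bijections on small populations (within three
Monte-Carlo standard errors), and against the closed-form limit
$P(Y_S \le Y_R) = 1/2$ for i.i.d. continuous offers.

The transaction price of a successful pair is not attributed by the
game's bookkeeping (each decider sees their own offer), so it is
configurable: the seller's offer (default, following the
seller-proposes-a-price narrative), the regulator's offer, or the
midpoint.

**Iteration convergence.** `converge_iterations()` doubles the
iteration count until two independent runs agree in every cell on mean
trades-possible and trades-successful shares within a tolerance
(default 0.1 percentage points). The between-run difference of a cell
mean has standard deviation $\approx \sqrt{2\,p(1-p)/m/n_{iter}}$ for
$m$ pairs per cell, so tight tolerances are only reachable when $m$ is
large; the test suite exercises the 0.1-pp tolerance on a
two-cell cohort with roughly two thousand pairs per cell, where the
formula puts convergence at a few thousand iterations.

## Funder redistribution

Per round, the mean transaction price among successful pairs splits the
2.4-\$ pool into a payer share ($1 - \bar y / 2.4$) and an investor
share ($\bar y / 2.4$). The trajectory accumulates these allocations on
top of the initial 4.8 \$: with a fresh pool each round (premiums accrue
per round), total assets across funders are $4.8 + 5 \times 2.4 = 16.8$
payoff-\$. Since the game's payout description also supports a
single-payoff-round reading (one pool, total $7.2$), both totals are
reported, along with the net shift of pool allocations from payers to
investors relative to an even split (as a share of initial assets) and
the final division by ten. Rounds in which no pair succeeded have an
undefined share and are flagged rather than averaged over.

## The statistical battery

All tests call the classical implementations in `stats` and return one
tidy row per hypothesis × grouping × test:

* offers vs reservation prices (margins vs zero): paired / one-sample
  $t$ per role × frame × round;
* frame contrasts (margins on the common payoff scale, 100k vs 1\$
  frame, within role and round) and role contrasts (within frame and
  round): Welch two-sample $t$ plus Mann–Whitney $U$;
* agreement feasibility, weak form: one-tailed Welch $t$ of seller
  offers exceeding regulator offers per round × frame; strong form:
  one-tailed paired $t$ across simulation iterations of trades possible
  vs trades successful;
* break points: one-sample $t$ of margins against zero on each side of
  fixed break points (1.2 \$, the funders' equality point; 2.5 \$ and
  2.75 \$, two readings of the mid price) and, alternatively, of the
  per-group reservation-price quartiles.

Design choices: Welch rather than pooled-variance $t$ for independent
contrasts (the modern default; the paired and one-sample tests use the
classic formulas); one-tailed tests only where the scientific question
is directional; Mann–Whitney by exact enumeration for tie-free samples
up to $n = 20$ per side, otherwise the normal approximation with tie
and continuity correction; **no multiple-testing correction** — results
are reported per round, and the battery records its own size
(`attr(, "n_tests")`) so corrections can be applied downstream.
Degenerate zero-variance groups are handled explicitly: identically
zero margins give $t = 0$, $p = 1$ (nothing to reject); zero variance
around a nonzero mean has no finite $t$ and is flagged unusable rather
than fabricated. Every flavour is cross-checked in the test suite
against independent textbook-formula oracles to six decimals, and the
battery's type-I error under a null cohort is verified to sit within
three binomial standard errors of $\alpha = 0.05$ over 1000 replicates.

## Numerical and interface choices

* Prices live on an exact integer grid (1 thousand-\$, i.e. 0.01
  payoff-\$); all money comparisons are exact.
* One integer seed drives everything; the pipeline derives sub-seeds
  for generation and simulation, and run manifests (config hash, cohort
  source, simulation parameters, package version) make outputs
  byte-for-byte reproducible.
* Problem sizes in the shipped test suite were chosen from the
  variance formulas above: parameter recovery at 2000 participants per
  group (three-standard-error bands), enumeration oracles at 5–6
  players per side (where all bijections are enumerable), the
  convergence check on ~2000 pairs per cell, and 500-iteration default
  simulations.
* `run_pipeline()` ties the stages together; a thin command-line
  wrapper (`inst/cli/bargainsim.R`, subcommands `generate`, `simulate`,
  `report`, `converge`) exposes the same functions to shell users.

## Known limitations

* Offers are fixed inputs: there are no strategic agents, no learning
  across iterations, and no renegotiation.
* The generator does not attempt to fit any deposited dataset's
  empirical distributions; quantitative market outcomes on synthetic
  cohorts are properties of the chosen generative defaults, not
  estimates of the original experiment's numbers.
* The abstract-level "share of assets redistributed" depends on which
  accounting reading one adopts; the package reports the ingredients of
  both rather than privileging one.
* Confidence intervals across iterations use the normal approximation;
  with 500 iterations this is innocuous, but single-digit iteration
  counts should not be summarised.

```{r example, eval = FALSE}
# a complete run, written to disk
res <- run_pipeline(iterations = 500, seed = 1, out_dir = "run1")
res$summary
res$redistribution$totals
```
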