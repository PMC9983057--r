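test_that("multiplicative shift evaluates the shifted distribution", {
  expect_equal(mult_shift_q(0.3, 1, 0, 0.5), 0.35)
  expect_equal(mult_shift_q(0.3, 1, 1, 0.5), 0.65)
  # delta = 1: intervention coincides with the observed process
  f <- runif(20)
  expect_equal(mult_shift_q(f, 1, 1, 1), f)
  expect_equal(mult_shift_q(f, 0, 1, 1), f)
  # delta = 0 always treats the indicated
  expect_equal(mult_shift_q(0.2, 1, 1, 0), 1)
  # no indication: observed process untouched for any delta
  expect_equal(mult_shift_q(f, 0, 1, 0.3), f)
  expect_equal(mult_shift_q(f, 0, 0, 0.3), 1 - f)
})

test_that("odds shift multiplies the propensity odds", {
  expect_equal(odds_shift_q(0.5, 1, 2), 2 / 3)
  f <- runif(20)
  expect_equal(odds_shift_q(f, 1, 1), f)
  expect_equal(odds_shift_q(0, 1, 5), 0)
})

test_that("both families are proper distributions and respect domains", {
  set.seed(41)
  f1 <- runif(10000); l <- rbinom(10000, 1, 0.5)
  gaps_m <- vapply(seq_along(f1), function(i) {
    d <- runif(1)
    mult_shift_q(f1[i], l[i], 0, d) + mult_shift_q(f1[i], l[i], 1, d) - 1
  }, 0)
  gaps_o <- vapply(seq_along(f1), function(i) {
    d <- rexp(1) + 1e-3
    odds_shift_q(f1[i], 0, d) + odds_shift_q(f1[i], 1, d) - 1
  }, 0)
  expect_lt(max(abs(gaps_m)), 1e-12)
  expect_lt(max(abs(gaps_o)), 1e-12)
  # q(1) non-increasing in delta under the multiplicative shift
  ds <- seq(0, 1, by = 0.05)
  q1 <- vapply(ds, function(d) mult_shift_q(0.3, 1, 1, d), 0)
  expect_true(all(diff(q1) <= 1e-12))
  expect_error(mult_shift(1.2), "delta")
  expect_error(mult_shift_q(0.3, 1, 1, -0.1), "delta")
  expect_error(odds_shift(0), "delta")
  expect_error(odds_shift_q(0.3, 1, 0), "delta")
})

test_that("canonical form carries the intervention constants", {
  s <- mult_shift(0.5)
  expect_equal(s$c1, 0.5)
  expect_equal(s$c2, 1)
  expect_equal(s$c3, 0)
  fr <- data.frame(lstar = c(1, 0))
  expect_equal(s$h1(fr), c(1, 0))
  expect_equal(s$h2(fr), c(0.5, 1))
  # delta = 1: c1 = 0, h2 = 1, so q = f
  s1 <- mult_shift(1)
  expect_equal(s1$c1, 0)
  expect_equal(s1$h2(fr), c(1, 1))
  # static regime is the degenerate distribution
  st <- static_regime(1)
  fr2 <- data.frame(lstar = c(1, 0, 1))
  expect_equal(q_eval(st, c(.2, .5, .9), fr2, 1), c(1, 1, 1))
  expect_equal(q_eval(st, c(.2, .5, .9), fr2, 0), c(0, 0, 0))
  # q_eval through the canonical terms matches the closed form
  f1 <- runif(5); l <- rbinom(5, 1, .5)
  fr3 <- data.frame(lstar = l)
  expect_equal(q_eval(s, f1, fr3, 1), mult_shift_q(f1, l, 1, 0.5))
  # odds shift carries no canonical representation
  os <- odds_shift(2)
  expect_false(os$canonical)
  expect_error(tj_update(os, fr, 0.5, 0.5), "canonical")
  # h3 without p_star is rejected
  expect_error(custom_intervention(c3 = 1, h3 = function(fr) fr$lstar),
               "p_star|h3")
})

test_that("positivity diagnostic flags unsupported intervention mass", {
  p <- fixture_panel(400, seed = 5)
  tf <- suppressWarnings(fit_treatment(p, fix_sat$treatment))
  # delta = 1: q = f, nothing to flag
  r1 <- positivity_check(mult_shift(1), p, tf, epsilon = 1e-3)
  expect_equal(sum(r1$flags), 0)
  # indication never present: observed process untouched regardless of f
  p0 <- p
  for (j in 1:2) p0$L$lstar[!is.na(p0$L$lstar[, j]), j] <- 0
  tf0 <- suppressWarnings(fit_treatment(p0, list(~ 1, ~ A_prev)))
  r0 <- positivity_check(mult_shift(0.3), p0, tf0, epsilon = 0.9)
  expect_equal(sum(r0$flags), 0)
  # constructed near-violation: f-hat(1) ~ 0 for an indicated history
  tf$pi[[1]][p$L$lstar[, 1] == 1] <- 1e-5
  r <- positivity_check(mult_shift(0.5), p, tf, epsilon = 1e-3)
  expect_gt(r$flags[1], 0)
})
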