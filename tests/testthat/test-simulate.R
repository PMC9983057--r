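test_that("the discrete process matches its stated marginals and hazards", {
  n <- 1e5
  p <- simulate_study1(n, seed = 301)
  # baseline: L1_0 ~ Ber(expit(-1))
  m <- mean(p$L$L1[, 1])
  tgt <- plogis(-1)
  expect_lt(abs(m - tgt), 3 * sqrt(tgt * (1 - tgt) / n))
  # conditional survival among the treated, cell by cell at interval 1
  fr <- interval_frame(p, 1)
  on <- at_risk(p, 1) & !is.na(p$C[, 3]) & p$C[, 3] == 0 & fr$A == 1
  for (ls in 0:1) for (l1 in 0:1) {
    rows <- which(on & fr$lstar == ls & fr$L1 == l1 & fr$L2 == 1)
    if (length(rows) < 50) next
    ph <- plogis(1 + 3 - 2 * ls + l1 - 1)
    expect_lt(abs(mean(p$Y[rows, 3]) - ph),
              3 * sqrt(ph * (1 - ph) / length(rows)) + 1e-12)
  }
  # generated panels satisfy the monotone validity structure by construction
  expect_s3_class(p, "panel_data")
  expect_true(all(diff(vapply(0:4, function(j) sum(at_risk(p, j)), 0)) <= 0))
})

test_that("the continuous process has absorbing treatment and stated baseline", {
  n <- 1e5
  p <- simulate_study2(n, seed = 302)
  expect_lt(abs(mean(p$L$L1[, 1]) - 2.5), 3 * sqrt(2 / n))
  for (j in 1:4) {
    fr <- interval_frame(p, j)
    started <- which(at_risk(p, j) & fr$A_prev == 1)
    expect_true(all(p$A[started, j + 1] == 1))
  }
})

test_that("simulation is bitwise reproducible under a seed", {
  a <- simulate_study1(500, seed = 99)
  b <- simulate_study1(500, seed = 99)
  expect_identical(a, b)
  c2 <- simulate_study2(500, seed = 99)
  d2 <- simulate_study2(500, seed = 99)
  expect_identical(c2, d2)
})

test_that("exact enumeration reproduces hand-computed g-formula sums", {
  # J = 1, L ~ Ber(0.5), m(1, l) = 0.9, m(0, l) = 0.5, f(1 | l) = 0.4,
  # everyone indicated, delta = 0.5 -> psi = 0.9 * 0.7 + 0.5 * 0.3 = 0.78
  law <- discrete_law(
    J = 1, l_levels = data.frame(lstar = c(0, 1)),
    p_l = function(j, l, lbar, abar) 0.5,
    f = function(j, lbar, abar) 0.4,
    surv = function(j, lbar, abar) ifelse(abar[1] == 1, 0.9, 0.5))
  law$l_levels <- data.frame(lstar = c(1, 1)) # indicated in both rows
  expect_equal(exact_gformula(law, mult_shift(0.5)), 0.78)
  # delta = 1 reduces to the observational survival of the law
  expect_equal(exact_gformula(law, mult_shift(1)), 0.4 * 0.9 + 0.6 * 0.5)
  # static always-treat: sum_l m(1, l) p(l)
  expect_equal(exact_gformula(law, static_regime(1)), 0.9)
  # unnormalized covariate table is rejected
  bad <- law; bad$p_l <- function(j, l, lbar, abar) 0.3
  expect_error(exact_gformula(bad, mult_shift(1)), "sums to")
  # the J = 2 fixture law: enumeration equals the independent summation
  for (d in c(0.25, 0.7, 1))
    expect_equal(exact_gformula(fixture_law(), mult_shift(d)),
                 fixture_truth(d), tolerance = 1e-12)
})

test_that("Monte-Carlo truths agree with enumeration and order in delta", {
  # test-side Monte Carlo under the intervention for the fixture law,
  # checked against the package's exact enumeration
  d <- 0.5
  set.seed(305)
  n <- 2e5
  par <- fix_par
  rb <- function(p) rbinom(length(p), 1L, p)
  qm <- function(f1, l) (1 - d) * l + (l * d + 1 - l) * f1
  l0 <- rb(rep(par$pl0, n))
  a0 <- rb(qm(par$a0(l0), l0))
  y1 <- rb(par$y1(l0, a0))
  al <- y1 == 1
  l1 <- rb(par$l1(l0[al], a0[al]))
  a1 <- rb(qm(par$a1(l0[al], a0[al], l1), l1))
  y2 <- rb(par$y2(l0[al], a0[al], l1, a1))
  psi_mc <- sum(y2) / n
  psi_exact <- exact_gformula(fixture_law(), mult_shift(d))
  expect_lt(abs(psi_mc - psi_exact),
            3 * sqrt(psi_exact * (1 - psi_exact) / n))
  # the built-in truth: delta = 1 equals the no-censoring observational
  # survival of the same process under the same seed stream
  t1 <- monte_carlo_truth("study1", delta = 1, n_mc = 5e4, seed = 17)
  t2 <- monte_carlo_truth("study1", delta = 1, n_mc = 5e4, seed = 17)
  expect_identical(t1$psi, t2$psi)
  # smaller delta (more initiation) improves survival
  ts <- vapply(c(0.25, 0.5, 0.75), function(dd)
    monte_carlo_truth("study1", delta = dd, n_mc = 3e5, seed = 19)$psi, 0)
  expect_true(all(diff(ts) < 0))
})

test_that("scenario formulas encode the stated misspecifications", {
  f <- misspecified_formulas("all_correct")
  expect_true(all(c("lstar", "A_prev") %in% all.vars(f$treatment)))
  expect_true("A" %in% all.vars(f$outcome))
  # outcome-correct scenario: treatment drops the previous treatment and
  # the weighting ignores the censoring process
  f2 <- misspecified_formulas("outcome_only")
  expect_false("A_prev" %in% all.vars(f2$treatment))
  expect_null(f2$censoring)
  expect_identical(deparse(f2$outcome), deparse(f$outcome))
  # treatment-correct scenario: outcome drops the pairwise interactions
  f3 <- misspecified_formulas("treatment_only")
  tl <- attr(terms(f3$outcome), "order")
  expect_true(all(tl == 1))
  expect_identical(deparse(f3$treatment), deparse(f$treatment))
  expect_error(misspecified_formulas("bogus"))
})
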