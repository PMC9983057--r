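test_that("cumulative weights cancel at delta = 1 and zero out the censored", {
  p <- fixture_panel(400, seed = 51, censor = TRUE)
  tf <- suppressWarnings(fit_treatment(p, fix_sat$treatment))
  cf <- fit_censoring(p, ~ lstar)
  w1 <- cumulative_weights(p, mult_shift(1), tf, j = 1)
  on1 <- at_risk(p, 1)
  expect_equal(w1[on1], rep(1, sum(on1)))
  expect_true(all(w1[!at_risk(p, 0)] == 0))
  # censored at time 1: zero weight from that interval onward
  wc <- cumulative_weights(p, mult_shift(0.5), tf, cf, j = 1)
  cens1 <- !is.na(p$C[, 2]) & p$C[, 2] == 1
  expect_true(all(wc[cens1] == 0))
  # hand product for one always-treated, always-indicated subject
  i <- which(p$L$lstar[, 1] == 1 & p$L$lstar[, 2] == 1 &
               p$A[, 1] == 1 & p$A[, 2] == 1 & at_risk(p, 1) &
               p$C[, 3] == 0)[1]
  expect_false(is.na(i))
  d <- 0.5
  hand <- prod(vapply(1:2, function(k) {
    pik <- tf$pi[[k]][i]
    q1 <- (1 - d) + d * pik              # q(1 | l* = 1)
    (q1 / pik) / (1 - cf$hazard[[k]][i])
  }, 0))
  expect_equal(cumulative_weights(p, mult_shift(d), tf, cf, j = 1)[i],
               hand, tolerance = 1e-12)
})

test_that("saturated sequential regressions reproduce the plug-in g-formula", {
  for (seed in c(101, 102)) {
    df <- sim_fixture_long(500, seed = seed)
    p <- panel_data(df, covariates = "lstar")
    for (d in c(1, 0.5)) {
      s <- mult_shift(d)
      plug <- plugin_gformula(df, d)
      f_ice <- ice(p, s, outcome = fix_sat$outcome)
      f_wice <- wice(p, s, treatment = fix_sat$treatment,
                     outcome = fix_sat$outcome, se = FALSE)
      expect_equal(f_ice$psi, plug, tolerance = 1e-10)
      expect_equal(f_wice$psi, plug, tolerance = 1e-10)
    }
  }
})

test_that("the J = 1 estimate is the covariate-standardized identity", {
  df <- sim_fixture_long(400, seed = 103)
  w0 <- df[df$time == 0, ]
  p1 <- panel_data(w0, covariates = "lstar")
  d <- 0.3
  f <- ice(p1, mult_shift(d), outcome = ~ A * lstar)
  # psi-hat = sum_l p(l) sum_a m(a, l) q(a | l) with empirical tables
  psi <- 0
  for (l in 0:1) {
    il <- w0$lstar == l
    fl <- mean(w0$A[il])
    for (a in 0:1) {
      m <- mean(w0$Y[il & w0$A == a])
      q <- (1 - d) * l * a +
        (l * d + 1 - l) * (a * fl + (1 - a) * (1 - fl))
      psi <- psi + mean(il) * m * q
    }
  }
  expect_equal(f$psi, psi, tolerance = 1e-10)
})

test_that("IPW equals weighted ICE with intercept-only outcome models", {
  for (k in 1:50) {
    df <- sim_fixture_long(120, seed = 500 + k, censor = (k %% 2 == 0))
    p <- panel_data(df, covariates = "lstar")
    d <- runif(1, 0.2, 1)
    s <- mult_shift(d)
    cn <- if (k %% 2 == 0) ~ lstar
    a <- ipw(p, s, treatment = fix_sat$treatment, censoring = cn)
    b <- wice(p, s, treatment = fix_sat$treatment, outcome = ~ 1,
              censoring = cn, se = FALSE)
    expect_equal(a$psi, b$psi, tolerance = 1e-10)
  }
})

test_that("degenerate panels give boundary estimates", {
  # every subject survives: psi = 1 for ICE/WICE, and trivially for IPW
  n <- 60
  df <- rbind(
    data.frame(id = 1:n, time = 0, lstar = rbinom(n, 1, .5),
               A = rbinom(n, 1, .5), C = 0, Y = 1),
    data.frame(id = 1:n, time = 1, lstar = rbinom(n, 1, .5),
               A = rbinom(n, 1, .5), C = 0, Y = 1))
  p <- panel_data(df, covariates = "lstar")
  s <- mult_shift(0.5)
  expect_equal(ice(p, s, outcome = ~ lstar)$psi, 1, tolerance = 1e-9)
  expect_equal(ipw(p, s, treatment = ~ lstar)$psi, 1, tolerance = 1e-9)
})

test_that("estimates are sample bounded on many random panels", {
  set.seed(61)
  ok <- TRUE
  for (k in 1:250) {
    df <- sim_fixture_long(40, seed = 700 + k)
    p <- panel_data(df, covariates = "lstar")
    d <- runif(1)
    psis <- c(
      tryCatch(ice(p, mult_shift(d), outcome = ~ A + lstar)$psi,
               error = function(e) NA),
      tryCatch(wice(p, mult_shift(d), treatment = ~ lstar,
                    outcome = ~ A + lstar, se = FALSE)$psi,
               error = function(e) NA))
    psis <- psis[!is.na(psis)]
    ok <- ok && all(psis >= 0 & psis <= 1)
  }
  expect_true(ok)
})

test_that("weighted ICE is consistent whenever models are correct from some
           interval on (J + 1 robustness at J = 2)", {
  d <- 0.3
  s <- mult_shift(d)
  truth <- fixture_truth(d)
  # saturated full-history models are correct; intercept/short models are not
  wrong_q <- list(~ A, ~ A)
  wrong_t <- list(~ 1, ~ 1)
  configs <- list(
    k0 = list(t = wrong_t, q = fix_sat$outcome),          # all Q correct
    k1 = list(t = list(fix_sat$treatment[[1]], ~ 1),      # split at k = 1
              q = list(wrong_q[[1]], fix_sat$outcome[[2]])),
    k2 = list(t = fix_sat$treatment, q = wrong_q))        # all pi correct
  reps <- 60; n <- 4000
  est <- matrix(NA_real_, reps, length(configs) + 1L)
  for (r in seq_len(reps)) {
    p <- fixture_panel(n, seed = 900 + r)
    for (ci in seq_along(configs)) {
      cfg <- configs[[ci]]
      est[r, ci] <- wice(p, s, treatment = cfg$t, outcome = cfg$q,
                         se = FALSE)$psi
    }
    # negative control: nothing correct anywhere
    est[r, 4] <- wice(p, s, treatment = wrong_t, outcome = wrong_q,
                      se = FALSE)$psi
  }
  for (ci in 1:3) {
    bias <- mean(est[, ci]) - truth
    mcse <- sd(est[, ci]) / sqrt(reps)
    expect_lt(abs(bias), 3 * mcse)
  }
  bias4 <- mean(est[, 4]) - truth
  expect_gt(abs(bias4), 3 * sd(est[, 4]) / sqrt(reps))
})
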