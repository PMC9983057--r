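test_that("fractional logistic closed forms hold for intercept fits", {
  y <- c(1, 0, 0, 0)
  f <- frac_logit(matrix(1, 4), y)
  expect_equal(f$coef, qlogis(0.25), tolerance = 1e-9)
  w <- c(3, 1, 2, 5)
  fw <- frac_logit(matrix(1, 4), y, weights = w)
  expect_equal(plogis(fw$coef), weighted.mean(y, w), tolerance = 1e-9)
  expect_error(frac_logit(matrix(1, 3), c(0.2, 1.4, 0.5)), "\\[0, 1\\]")
  expect_error(frac_logit(matrix(1, 2), c(0, 1), weights = c(0, 0)),
               "weights")
})

test_that("offset-only fluctuation matches a bisection root of the score", {
  y <- c(0.9, 0.2, 0.55, 0.7, 0.1)
  off <- c(0.5, -1, 0, 1.2, -0.4)
  w <- c(1, 2, 1, 0.5, 3)
  f <- frac_logit(matrix(1, 5), y, weights = w, offset = off)
  # independent bisection on the scalar score
  sc <- function(g) sum(w * (y - plogis(off + g)))
  lo <- -10; hi <- 10
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sc(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(f$coef, (lo + hi) / 2, tolerance = 1e-8)
})

test_that("binary-response fits equal the logistic MLE and solve the score", {
  set.seed(71)
  for (i in 1:100) {
    n <- 80
    x <- cbind(1, rnorm(n), rbinom(n, 1, 0.5))
    y <- rbinom(n, 1, plogis(drop(x %*% c(-0.2, 0.7, -0.5))))
    w <- if (i %% 2) NULL else rexp(n) + 0.1
    yy <- if (i %% 3) y else runif(n)      # fractional every third case
    f <- frac_logit(x, yy, weights = w)
    expect_lt(f$score, 1e-8)
    if (is.null(w) && all(yy %in% 0:1)) {
      th <- newton_logit(x, yy)
      expect_equal(f$coef, th, tolerance = 1e-6, ignore_attr = TRUE)
    }
  }
})

test_that("per-interval treatment and censoring fits recover the study-1 law", {
  p <- simulate_study1(1e5, seed = 202)
  tf <- fit_treatment(p, ~ lstar + L1 + L2 + A_prev)
  co <- tf$fits[[2]]$fit$coef            # interval 1, named by column
  # A_j ~ expit(-1 - 2 lstar - L1 + L2 + 2 A_prev): recover the lstar slope
  risk <- sum(at_risk(p, 1))
  expect_lt(abs(co[2] - (-2)), 3 * sqrt(4 / risk) + 0.15)
  cf <- fit_censoring(p, ~ L1 + L2)
  cc <- cf$fits[[1]]$fit$coef            # hazard ~ expit(-2 + L1 - L2)
  expect_lt(abs(cc[2] - 1), 3 * sqrt(4 / p$n) + 0.15)
  # predictions live on the risk set only, inside (0, 1)
  pi1 <- tf$pi[[3]]
  expect_true(all(is.na(pi1[!at_risk(p, 2)])))
  expect_true(all(pi1[at_risk(p, 2)] > 0 & pi1[at_risk(p, 2)] < 1))
})

test_that("degenerate fits are handled: no events, single class, empty sets", {
  p <- fixture_panel(200, seed = 31, censor = FALSE)
  cf <- fit_censoring(p, ~ lstar)
  expect_true(all(cf$hazard[[1]][at_risk(p, 0)] == 0))
  w <- cumulative_weights(p, mult_shift(1),
                          suppressWarnings(fit_treatment(p, fix_sat$treatment)),
                          cf, j = 1)
  expect_equal(w[at_risk(p, 1)], rep(1, sum(at_risk(p, 1))))
  # absorbing treatment: prior initiators are deterministic, not modeled
  p2 <- simulate_study2(400, seed = 8)
  tf2 <- suppressWarnings(fit_treatment(p2, ~ lstar + L1, absorbing = TRUE))
  fr <- interval_frame(p2, 2)
  started <- at_risk(p2, 2) & fr$A_prev == 1
  expect_true(all(tf2$pi[[3]][started] == 1))
})

test_that("cross-validated stacking returns proper convex weights", {
  set.seed(55)
  # candidate weights are convex across many random problems
  for (i in 1:100) {
    n <- 60
    d <- data.frame(x = rnorm(n))
    y <- rbinom(n, 1, plogis(0.8 * d$x))
    st <- cv_stack(list(lrn_glm(), lrn_mean()), d, y, v = 2)
    expect_true(all(st$weights >= 0))
    expect_equal(sum(st$weights), 1, tolerance = 1e-10)
  }
  # the true-model candidate dominates the constant predictor at n large
  n <- 5000
  d <- data.frame(x = rnorm(n))
  y <- rbinom(n, 1, plogis(1.2 * d$x - 0.3))
  st <- cv_stack(list(lrn_glm(), lrn_mean()), d, y, v = 2)
  expect_gt(st$weights[1], 0.95)
  # identical candidates: predictions invariant to the weight split
  st2 <- cv_stack(list(lrn_glm(), lrn_glm()), d, y, v = 2)
  expect_equal(predict_stack(st2, d[1:50, , drop = FALSE]),
               predict(glm(y ~ x, data = d, family = binomial()),
                       d[1:50, , drop = FALSE], type = "response"),
               tolerance = 1e-6, ignore_attr = TRUE)
  # single learner short-circuits
  st3 <- cv_stack(list(lrn_mean()), d, y)
  expect_equal(st3$weights, 1)
})
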