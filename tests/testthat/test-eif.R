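test_that("the backward response update evaluates the canonical terms", {
  s <- mult_shift(0.5)
  fr <- data.frame(lstar = 1)
  expect_equal(tj_update(s, fr, Q_obs = 0.8, Q_star = 0.9),
               0.5 * 0.9 + 0.8 * 0.5)                  # 0.85
  fr0 <- data.frame(lstar = 0)
  expect_equal(tj_update(s, fr0, Q_obs = 0.8, Q_star = 0.9), 0.8)
  st <- static_regime(1)
  expect_equal(tj_update(st, fr, Q_obs = 0.8, Q_star = 0.9), 0.9)
  expect_error(tj_update(s, fr, Q_obs = 0.8), "a\\*")
})

test_that("at J = 1 and delta = 1 the EIF collapses to Y - psi", {
  p1 <- fixture_panel1(300, seed = 21)
  s1 <- mult_shift(1)
  f <- wice(p1, s1, treatment = ~ lstar, outcome = ~ A * lstar,
            store = TRUE)
  U <- eif_values(f)
  expect_equal(U, p1$Y[, 2] - f$psi, tolerance = 1e-8)
})

test_that("the J = 1 EIF matches the direct point-treatment expression", {
  # general delta: q/f (Y - m) + m(A,L)(L* d + 1 - L*) + m(1,L) L*(1-d) - psi
  delta <- 0.4
  p1 <- fixture_panel1(500, seed = 22)
  s <- mult_shift(delta)
  f <- wice(p1, s, treatment = ~ lstar, outcome = ~ A * lstar,
            store = TRUE)
  U <- eif_values(f)
  # independent transcription of the point-treatment formula
  l <- p1$L$lstar[, 1]; a <- p1$A[, 1]; y <- p1$Y[, 2]
  pi1 <- f$components$pi[[1]]
  m_obs <- f$components$Q[[1]]
  m_star <- f$components$Qstar[[1]]
  qf <- ((1 - delta) * l * a +
           (l * delta + 1 - l) * (a * pi1 + (1 - a) * (1 - pi1))) /
    (a * pi1 + (1 - a) * (1 - pi1))
  U_direct <- qf * (y - m_obs) + m_obs * (l * delta + 1 - l) +
    m_star * l * (1 - delta) - f$psi
  expect_equal(U, U_direct, tolerance = 1e-10)
  # and via the linear-combination representation evaluator on the same fits
  U_pt <- point_treatment_eif(y, a, a_star = 1, c1 = 1, c2 = 1 - delta,
                              h1 = y * (l * delta + 1 - l),
                              h2_factor = l, h2_factor_star = l,
                              m_obs = m_obs, m_star = m_star,
                              f_obs = a * pi1 + (1 - a) * (1 - pi1),
                              psi = f$psi)
  expect_equal(U_pt, U_direct, tolerance = 1e-10)
})

test_that("the static point-treatment EIF is the AIPW influence function", {
  set.seed(23)
  n <- 50
  y <- rbinom(n, 1, 0.6); a <- rbinom(n, 1, 0.5)
  m_obs <- runif(n); m_star <- runif(n); f_obs <- runif(n, .2, .8)
  psi <- 0.5
  U <- point_treatment_eif(y, a, a_star = 1, c1 = 0, c2 = 1,
                           h1 = rep(0, n), h2_factor = rep(1, n),
                           h2_factor_star = rep(1, n),
                           m_obs = m_obs, m_star = m_star,
                           f_obs = f_obs, psi = psi)
  expect_equal(U, (a == 1) / f_obs * (y - m_obs) + m_star - psi)
})

test_that("population EIF mean vanishes when either nuisance is correct", {
  # 2x2 discrete point-treatment law, exact enumeration
  delta <- 0.5
  pl <- 0.4                               # P(L = 1); L = L*
  f_true <- function(l) ifelse(l == 1, 0.3, 0.6)
  m_true <- function(a, l) plogis(-0.5 + 1.2 * a - 0.8 * l)
  q <- function(a, l, f) (1 - delta) * l * a +
    (l * delta + 1 - l) * (a * f + (1 - a) * (1 - f))
  psi_true <- sum(vapply(0:1, function(l) {
    pL <- ifelse(l == 1, pl, 1 - pl)
    pL * sum(vapply(0:1, function(a)
      q(a, l, f_true(l)) * m_true(a, l), 0))
  }, 0))
  EU <- function(m_fn, f_fn) {
    tot <- 0
    for (l in 0:1) for (a in 0:1) for (y in 0:1) {
      pLAY <- ifelse(l == 1, pl, 1 - pl) *
        (a * f_true(l) + (1 - a) * (1 - f_true(l))) *
        (y * m_true(a, l) + (1 - y) * (1 - m_true(a, l)))
      if (pLAY == 0) next
      fa <- a * f_fn(l) + (1 - a) * (1 - f_fn(l))
      U <- q(a, l, f_fn(l)) / fa * (y - m_fn(a, l)) +
        m_fn(a, l) * (l * delta + 1 - l) +
        m_fn(1, l) * l * (1 - delta) - psi_true
      tot <- tot + pLAY * U
    }
    tot
  }
  m_bad <- function(a, l) plogis(0.3 + 0.2 * a)       # wrong outcome model
  f_bad <- function(l) ifelse(l == 1, 0.7, 0.2)       # wrong propensity
  expect_lt(abs(EU(m_true, f_bad)), 1e-12)            # m right, f wrong
  expect_lt(abs(EU(m_bad, f_true)), 1e-12)            # f right, m wrong
  expect_gt(abs(EU(m_bad, f_bad)), 1e-3)              # both wrong: biased
})

test_that("the recursion with a static regime gives longitudinal AIPW", {
  p <- fixture_panel(600, seed = 24)
  st <- static_regime(1)
  f <- wice(p, st, treatment = fix_sat$treatment,
            outcome = fix_sat$outcome, store = TRUE)
  U <- eif_values(f)
  # direct transcription of the static-regime (always treat) influence
  # function: sum_j (T_j - Q_{j-1}) prod I(A_k = 1)/pi_k + T_0 - psi,
  # with T_j = Q_j^{A_j = 1}
  cmp <- f$components
  a <- p$A; y <- p$Y
  w1 <- (a[, 1] == 1) / cmp$pi[[1]]
  w1[is.na(w1)] <- 0
  w2 <- w1 * (a[, 2] == 1) / cmp$pi[[2]]
  w2[is.na(w2)] <- 0
  T1 <- cmp$Qstar[[2]]; T1[!is.na(y[, 2]) & y[, 2] == 0] <- 0
  T2 <- y[, 3]
  t2 <- (T2 - cmp$Q[[2]]) * w2; t2[is.na(t2)] <- 0
  t1 <- (T1 - cmp$Q[[1]]) * w1; t1[is.na(t1)] <- 0
  U_direct <- t2 + t1 + cmp$Qstar[[1]] - f$psi
  expect_equal(U, U_direct, tolerance = 1e-10)
})
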