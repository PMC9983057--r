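# Small discrete longitudinal fixtures and independent oracles used
# across the test files.  Everything here is deliberately written from
# first principles (tables, closed forms, direct transcriptions) so the
# package's estimators can be checked against independent computations.

expit <- function(x) 1 / (1 + exp(-x))

# Parameters of the J=2 discrete fixture law (single binary covariate,
# the indication lstar; no censoring).  Chosen once: interior hazards,
# strong covariate effects so misspecification bites.
fix_par <- list(
  pl0 = 0.5,
  a0 = function(l0) expit(-0.4 + 2.0 * l0),
  y1 = function(l0, a0) expit(0.3 + 1.0 * a0 - 2.0 * l0),
  l1 = function(l0, a0) expit(-0.2 + 0.8 * a0 + 1.2 * l0),
  a1 = function(l0, a0, l1) expit(-0.5 + 1.8 * l1 + 1.0 * a0),
  y2 = function(l0, a0, l1, a1) expit(0.2 + 1.2 * a1 - 1.8 * l1 + 0.4 * a0))

# Simulate a long-format data frame from the fixture law; censor_rate
# adds an optional independent-ish censoring hazard before survival.
sim_fixture_long <- function(n, seed, censor = FALSE, par = fix_par) {
  set.seed(seed)
  rb <- function(p) rbinom(length(p), 1L, p)
  l0 <- rb(rep(par$pl0, n))
  a0 <- rb(par$a0(l0))
  c1 <- if (censor) rb(expit(-2.2 + 0.8 * l0)) else rep(0L, n)
  y1 <- ifelse(c1 == 1, NA, rb(par$y1(l0, a0)))
  alive1 <- !is.na(y1) & y1 == 1
  l1 <- a1 <- c2 <- y2 <- rep(NA_real_, n)
  l1[alive1] <- rb(par$l1(l0[alive1], a0[alive1]))
  a1[alive1] <- rb(par$a1(l0[alive1], a0[alive1], l1[alive1]))
  c2[alive1] <- if (censor)
    rb(expit(-2.5 + 0.6 * l1[alive1])) else 0L
  y2[alive1] <- ifelse(c2[alive1] == 1, NA,
                       rb(par$y2(l0[alive1], a0[alive1], l1[alive1],
                                 a1[alive1])))
  rbind(
    data.frame(id = 1:n, time = 0, lstar = l0, A = a0, C = c1, Y = y1),
    data.frame(id = 1:n, time = 1, lstar = l1, A = a1, C = c2, Y = y2))
}

fixture_panel <- function(n, seed, censor = FALSE, par = fix_par) {
  df <- sim_fixture_long(n, seed, censor, par)
  panel_data(df, covariates = "lstar", lstar = "lstar")
}

# J = 1 (point treatment) version: keep only the first interval.
fixture_panel1 <- function(n, seed, par = fix_par) {
  df <- sim_fixture_long(n, seed, FALSE, par)
  panel_data(df[df$time == 0, ], covariates = "lstar", lstar = "lstar")
}

# Saturated full-history model formulas for the J=2 fixture.
fix_sat <- list(
  treatment = list(~ lstar, ~ lstar * A_prev * lstar_lag),
  outcome = list(~ A * lstar, ~ A * lstar * A_prev * lstar_lag))

# --- independent empirical plug-in enumeration (full-history cells) ----
# Computes the g-formula for the multiplicative shift at delta from the
# *empirical* conditional frequencies of a long fixture data frame,
# conditioning on complete histories.  No package code involved.
plugin_gformula <- function(df, delta) {
  w0 <- df[df$time == 0, ]
  w1 <- df[df$time == 1, ]
  n <- nrow(w0)
  qm <- function(f1, l, a)                 # multiplicative shift, transcribed
    (1 - delta) * l * a + (l * delta + 1 - l) * (a * f1 + (1 - a) * (1 - f1))
  psi <- 0
  for (l0 in 0:1) {
    i0 <- w0$lstar == l0
    p_l0 <- mean(i0)
    if (p_l0 == 0) next
    f0 <- mean(w0$A[i0] == 1)
    for (a0 in 0:1) {
      q0 <- qm(f0, l0, a0)
      if (q0 == 0) next
      i0a <- i0 & w0$A == a0
      if (!any(i0a)) next
      h1 <- mean(w0$Y[i0a] == 1, na.rm = TRUE)
      surv <- w0$id[i0a & !is.na(w0$Y) & w0$Y == 1]
      if (h1 == 0 || !length(surv)) next
      r1 <- w1[w1$id %in% surv, ]
      for (l1 in 0:1) {
        i1 <- r1$lstar == l1
        p_l1 <- mean(i1)
        if (is.na(p_l1) || p_l1 == 0) next
        f1 <- mean(r1$A[i1] == 1)
        for (a1 in 0:1) {
          q1 <- qm(f1, l1, a1)
          if (q1 == 0) next
          i1a <- i1 & r1$A == a1
          if (!any(i1a)) next
          h2 <- mean(r1$Y[i1a] == 1)
          psi <- psi + p_l0 * q0 * h1 * p_l1 * q1 * h2
        }
      }
    }
  }
  psi
}

# --- exact truth of the fixture law by direct summation ---------------
fixture_truth <- function(delta, par = fix_par) {
  qm <- function(f1, l, a)
    (1 - delta) * l * a + (l * delta + 1 - l) * (a * f1 + (1 - a) * (1 - f1))
  psi <- 0
  for (l0 in 0:1) {
    p0 <- ifelse(l0 == 1, par$pl0, 1 - par$pl0)
    f0 <- par$a0(l0)
    for (a0 in 0:1) {
      q0 <- qm(f0, l0, a0)
      h1 <- par$y1(l0, a0)
      for (l1 in 0:1) {
        pl1 <- ifelse(l1 == 1, par$l1(l0, a0), 1 - par$l1(l0, a0))
        f1 <- par$a1(l0, a0, l1)
        for (a1 in 0:1) {
          q1 <- qm(f1, l1, a1)
          psi <- psi + p0 * q0 * h1 * pl1 * q1 *
            par$y2(l0, a0, l1, a1)
        }
      }
    }
  }
  psi
}

# Package discrete_law object for the same fixture (for exact_gformula).
fixture_law <- function(par = fix_par) {
  lev <- data.frame(lstar = c(0, 1))
  discrete_law(
    J = 2,
    l_levels = lev,
    p_l = function(j, l, lbar, abar) {
      if (j == 0) ifelse(l$lstar == 1, par$pl0, 1 - par$pl0)
      else {
        p <- par$l1(lbar$lstar[1], abar[1])
        ifelse(l$lstar == 1, p, 1 - p)
      }
    },
    f = function(j, lbar, abar) {
      if (j == 0) par$a0(lbar$lstar[1])
      else par$a1(lbar$lstar[1], abar[1], lbar$lstar[2])
    },
    surv = function(j, lbar, abar) {
      if (j == 0) par$y1(lbar$lstar[1], abar[1])
      else par$y2(lbar$lstar[1], abar[1], lbar$lstar[2], abar[2])
    })
}

# --- independent Newton solver for binary logistic MLE ----------------
newton_logit <- function(x, y, tol = 1e-12) {
  th <- numeric(ncol(x))
  for (i in 1:200) {
    p <- expit(drop(x %*% th))
    g <- crossprod(x, y - p)
    h <- crossprod(x, x * (p * (1 - p)))
    st <- solve(h, g)
    th <- th + st
    if (max(abs(g)) < tol) break
  }
  drop(th)
}
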