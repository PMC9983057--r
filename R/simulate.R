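#' Built-in longitudinal data-generating processes
#'
#' Two simulators over `J = 5` treatment intervals with the ordering
#' \eqn{(L_j, A_j, C_{j+1}, Y_{j+1})}, binary treatment, informative
#' censoring and death; everything after death or censoring is missing.
#'
#' `simulate_study1()` is a fully discrete system with covariates
#' \eqn{L_j = (L^*_j, L1_j, L2_j)}: at baseline \eqn{L^*_0, L1_0 \sim
#' \mathrm{Ber}\{\mathrm{expit}(-1)\}} and \eqn{L2_0 \sim
#' \mathrm{Ber}\{\mathrm{expit}(1 + L^*_0)\}; treatment
#' \eqn{A_j \sim \mathrm{Ber}\{\mathrm{expit}(-1 - 2L^*_j - L1_j + L2_j +
#' 2A_{j-1})\}}; censoring hazard \eqn{\mathrm{expit}(-2 + L1_j - L2_j)};
#' death hazard complement \eqn{\mathrm{expit}(1 + 3A_j - 2L^*_j + L1_j -
#' L2_j)}; and covariate transitions as coded.
#'
#' `simulate_study2()` mixes continuous and binary covariates with
#' nonlinear (absolute-value and power) terms in the outcome and
#' censoring hazards, and an *absorbing* treatment: \eqn{A_j = 1}
#' whenever \eqn{A_{j-1} = 1} among survivors.  Baseline covariates
#' `L01 ~ Ber(0.5)`, `L02 ~ N(0, 1)` are carried in every interval's
#' covariate set.
#'
#' @param n number of subjects.
#' @param seed optional RNG seed.
#' @return a [panel_data] object.
#' @export
simulate_study1 <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- 5L
  Y <- matrix(NA_real_, n, J + 1L); Y[, 1L] <- 1
  C <- matrix(NA_real_, n, J + 1L); C[, 1L] <- 0
  A <- matrix(NA_real_, n, J)
  lstar <- L1 <- L2 <- matrix(NA_real_, n, J)
  rb <- function(p) stats::rbinom(length(p), 1L, p)
  lstar[, 1L] <- rb(rep(plogis(-1), n))
  L1[, 1L] <- rb(rep(plogis(-1), n))
  L2[, 1L] <- rb(plogis(1 + lstar[, 1L]))
  alive <- rep(TRUE, n)
  aprev <- rep(0, n)
  for (j in seq_len(J) - 1L) {
    jj <- j + 1L
    idx <- which(alive)
    if (!length(idx)) break
    A[idx, jj] <- rb(plogis(-1 - 2 * lstar[idx, jj] - L1[idx, jj] +
                              L2[idx, jj] + 2 * aprev[idx]))
    C[idx, jj + 1L] <- rb(plogis(-2 + L1[idx, jj] - L2[idx, jj]))
    unc <- idx[C[idx, jj + 1L] == 0]
    Y[unc, jj + 1L] <- rb(plogis(1 + 3 * A[unc, jj] - 2 * lstar[unc, jj] +
                                   L1[unc, jj] - L2[unc, jj]))
    nalive <- unc[Y[unc, jj + 1L] == 1]
    if (j < J - 1L && length(nalive)) {
      kk <- jj + 1L
      lstar[nalive, kk] <- rb(plogis(-1 - A[nalive, jj] +
                                       lstar[nalive, jj] -
                                       L1[nalive, jj] + L2[nalive, jj]))
      L1[nalive, kk] <- rb(plogis(-1 + A[nalive, jj] + L1[nalive, jj] -
                                    L2[nalive, jj]))
      L2[nalive, kk] <- rb(plogis(1 + A[nalive, jj] + lstar[nalive, kk] +
                                    L2[nalive, jj]))
    }
    aprev <- ifelse(is.na(A[, jj]), 0, A[, jj])
    alive[] <- FALSE; alive[nalive] <- TRUE
  }
  validate_panel(new_panel(n, J, A, C, Y,
                           list(lstar = lstar, L1 = L1, L2 = L2),
                           "lstar", seq_len(n)))
}

#' @rdname simulate_study1
#' @export
simulate_study2 <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- 5L
  Y <- matrix(NA_real_, n, J + 1L); Y[, 1L] <- 1
  C <- matrix(NA_real_, n, J + 1L); C[, 1L] <- 0
  A <- matrix(NA_real_, n, J)
  lstar <- L1 <- matrix(NA_real_, n, J)
  L01 <- stats::rbinom(n, 1L, 0.5)
  L02 <- stats::rnorm(n)
  rb <- function(p) stats::rbinom(length(p), 1L, p)
  L1[, 1L] <- stats::rnorm(n, 2 + L01, 1)
  lstar[, 1L] <- rb(plogis(1.5 - 0.5 * L1[, 1L] + L01 + 0.25 * L02))
  alive <- rep(TRUE, n)
  aprev <- rep(0, n)
  for (j in seq_len(J) - 1L) {
    jj <- j + 1L
    idx <- which(alive)
    if (!length(idx)) break
    newa <- idx[aprev[idx] == 0]
    A[newa, jj] <- rb(plogis(-3 + lstar[newa, jj] - 0.5 * L1[newa, jj] +
                               0.25 * lstar[newa, jj] * L1[newa, jj] +
                               0.5 * L01[newa] + 0.25 * L02[newa] +
                               0.5 * abs(L02[newa])))
    A[idx[aprev[idx] == 1], jj] <- 1            # absorbing treatment
    C[idx, jj + 1L] <- rb(plogis(
      -4 - A[idx, jj] - lstar[idx, jj] -
        0.5 * abs(L1[idx, jj] * L02[idx]) +
        1.5 * abs(L1[idx, jj]) / (1 + exp(L02[idx]))))
    unc <- idx[C[idx, jj + 1L] == 0]
    Y[unc, jj + 1L] <- rb(plogis(
      -1 + 2 * A[unc, jj] - 2 * lstar[unc, jj] +
        0.25 * lstar[unc, jj] * L1[unc, jj] + 0.5 * L01[unc] +
        0.75 * abs(L1[unc, jj] + L02[unc])^1.5))
    nalive <- unc[Y[unc, jj + 1L] == 1]
    if (j < J - 1L && length(nalive)) {
      kk <- jj + 1L
      L1[nalive, kk] <- stats::rnorm(length(nalive),
                                     2 + A[nalive, jj] -
                                       lstar[nalive, jj] +
                                       0.5 * L1[nalive, jj] + L01[nalive],
                                     1)
      lstar[nalive, kk] <- rb(plogis(1.5 - A[nalive, jj] -
                                       0.5 * L1[nalive, kk] +
                                       lstar[nalive, jj] + L01[nalive] +
                                       0.25 * L02[nalive]))
    }
    aprev <- ifelse(is.na(A[, jj]), 0, A[, jj])
    alive[] <- FALSE; alive[nalive] <- TRUE
  }
  L01m <- matrix(L01, n, J); L02m <- matrix(L02, n, J)
  L01m[is.na(L1)] <- NA; L02m[is.na(L1)] <- NA
  validate_panel(new_panel(n, J, A, C, Y,
                           list(lstar = lstar, L1 = L1,
                                L01 = L01m, L02 = L02m),
                           "lstar", seq_len(n)))
}

#' Monte-Carlo intervention-world truth
#'
#' Simulates the covariate and outcome laws of a built-in
#' data-generating process with treatment drawn from the intervention
#' distribution \eqn{q^g} built from the *true* treatment probabilities,
#' censoring eliminated, and returns the fraction surviving to `J`
#' together with its Monte-Carlo standard error.  With \eqn{\delta = 1}
#' (multiplicative shift) this is the no-censoring observational survival
#' probability of the same process.
#'
#' @param dgp `"study1"` or `"study2"`.
#' @param delta multiplicative-shift parameter (ignored when `spec` is
#'   given).
#' @param n_mc Monte-Carlo sample size.
#' @param seed optional RNG seed.
#' @param spec optional [intervention_spec][mult_shift]
#'   (multiplicative/odds shift or static) replacing the default
#'   multiplicative shift at `delta`.
#' @param chunk simulation block size (memory bound).
#' @return object of class `mc_truth`: fields `psi`, `mcse`, `n_mc`.
#' @export
monte_carlo_truth <- function(dgp = c("study1", "study2"), delta = 1,
                              n_mc = 1e6, seed = NULL, spec = NULL,
                              chunk = 1e6) {
  dgp <- match.arg(dgp)
  if (is.null(spec)) spec <- mult_shift(delta)
  if (!is.null(seed)) set.seed(seed)
  q1_of <- function(pi1, lst) {
    switch(spec$family,
           multiplicative_shift = mult_shift_q(pi1, lst, 1, spec$delta),
           odds_shift = odds_shift_q(pi1, 1, spec$delta),
           static = rep(as.numeric(spec$a_star), length(pi1)),
           stop("unsupported intervention family for the built-in DGPs",
                call. = FALSE))
  }
  total <- 0; surv <- 0
  left <- n_mc
  while (left > 0) {
    nb <- min(left, chunk); left <- left - nb
    surv <- surv + if (dgp == "study1")
      mc_block_study1(nb, q1_of) else mc_block_study2(nb, q1_of)
    total <- total + nb
  }
  psi <- surv / total
  structure(list(psi = psi, mcse = sqrt(psi * (1 - psi) / total),
                 n_mc = total, dgp = dgp, family = spec$family,
                 delta = spec$delta),
            class = "mc_truth")
}

#' @export
print.mc_truth <- function(x, ...) {
  cat("Monte-Carlo intervention-world survival (", x$dgp, ", ",
      x$family, if (!is.na(x$delta)) paste0(", delta = ", x$delta),
      ")\n  psi = ", format(round(x$psi, 5)), " (MCSE ",
      format(signif(x$mcse, 3)), ", n = ", format(x$n_mc, big.mark = ","),
      ")\n", sep = "")
  invisible(x)
}

mc_block_study1 <- function(n, q1_of) {
  rb <- function(p) stats::rbinom(length(p), 1L, p)
  lstar <- rb(rep(plogis(-1), n)); L1 <- rb(rep(plogis(-1), n))
  L2 <- rb(plogis(1 + lstar))
  alive <- rep(TRUE, n); aprev <- rep(0, n)
  for (j in 0:4) {
    idx <- which(alive)
    if (!length(idx)) break
    pi1 <- plogis(-1 - 2 * lstar[idx] - L1[idx] + L2[idx] + 2 * aprev[idx])
    a <- rb(q1_of(pi1, lstar[idx]))
    y <- rb(plogis(1 + 3 * a - 2 * lstar[idx] + L1[idx] - L2[idx]))
    nal <- idx[y == 1]
    if (j < 4 && length(nal)) {
      asub <- a[y == 1]
      ls_new <- rb(plogis(-1 - asub + lstar[nal] - L1[nal] + L2[nal]))
      L1[nal] <- rb(plogis(-1 + asub + L1[nal] - L2[nal]))
      L2[nal] <- rb(plogis(1 + asub + ls_new + L2[nal]))
      lstar[nal] <- ls_new
    }
    aprev[idx] <- a
    alive[] <- FALSE; alive[nal] <- TRUE
  }
  sum(alive)
}

mc_block_study2 <- function(n, q1_of) {
  rb <- function(p) stats::rbinom(length(p), 1L, p)
  L01 <- stats::rbinom(n, 1L, 0.5); L02 <- stats::rnorm(n)
  L1 <- stats::rnorm(n, 2 + L01, 1)
  lstar <- rb(plogis(1.5 - 0.5 * L1 + L01 + 0.25 * L02))
  alive <- rep(TRUE, n); aprev <- rep(0, n)
  for (j in 0:4) {
    idx <- which(alive)
    if (!length(idx)) break
    pi1 <- ifelse(aprev[idx] == 1, 1,
                  plogis(-3 + lstar[idx] - 0.5 * L1[idx] +
                           0.25 * lstar[idx] * L1[idx] + 0.5 * L01[idx] +
                           0.25 * L02[idx] + 0.5 * abs(L02[idx])))
    a <- rb(q1_of(pi1, lstar[idx]))
    y <- rb(plogis(-1 + 2 * a - 2 * lstar[idx] +
                     0.25 * lstar[idx] * L1[idx] + 0.5 * L01[idx] +
                     0.75 * abs(L1[idx] + L02[idx])^1.5))
    nal <- idx[y == 1]
    if (j < 4 && length(nal)) {
      asub <- a[y == 1]
      L1_new <- stats::rnorm(length(nal),
                             2 + asub - lstar[nal] + 0.5 * L1[nal] +
                               L01[nal], 1)
      lstar[nal] <- rb(plogis(1.5 - asub - 0.5 * L1_new + lstar[nal] +
                                L01[nal] + 0.25 * L02[nal]))
      L1[nal] <- L1_new
    }
    aprev[idx] <- a
    alive[] <- FALSE; alive[nal] <- TRUE
  }
  sum(alive)
}

# ---------------------------------------------------------------------------
# Exact enumeration of the generalized g-formula on finite discrete laws

#' Finite discrete longitudinal law
#'
#' Full conditional probability tables for a small discrete system, for
#' exact evaluation of the generalized g-formula by enumeration.
#'
#' @param J number of treatment intervals.
#' @param l_levels data frame whose rows are the possible covariate
#'   vectors at each interval (must contain the `lstar` column).
#' @param p_l function `(j, l, lbar, abar)` giving the probability of
#'   covariate row `l` (a 1-row data frame) at interval `j` given the
#'   covariate history `lbar` (data frame of previous rows, `j` rows) and
#'   treatment history `abar`; must sum to 1 over the rows of `l_levels`.
#' @param f function `(j, lbar, abar_prev)` giving the observed
#'   probability of treatment (`A_j = 1`) given the measured past
#'   (`lbar` has `j + 1` rows, including the current covariates).
#' @param surv function `(j, lbar, abar)` giving the conditional
#'   survival probability \eqn{\Pr(Y_{j+1} = 1 \mid Y_j = 1, \cdot)}
#'   (`abar` has `j + 1` entries).
#' @param lstar name of the indication column in `l_levels`.
#' @return object of class `discrete_law`.
#' @export
discrete_law <- function(J, l_levels, p_l, f, surv, lstar = "lstar") {
  stopifnot(is.data.frame(l_levels), lstar %in% names(l_levels))
  structure(list(J = J, l_levels = l_levels, p_l = p_l, f = f,
                 surv = surv, lstar = lstar),
            class = "discrete_law")
}

#' Exact generalized g-formula by enumeration
#'
#' Sums the g-formula
#' \deqn{\psi^g = \sum_{\bar{a}} \sum_{\bar{l}} \prod_{j} \Pr(Y_{j+1} =
#' 1 \mid \cdot)\, f(l_j \mid \cdot)\, q^g(a_j \mid \cdot)}
#' exactly over every covariate/treatment history of a
#' [discrete_law()].  Conditional covariate tables that do not sum to 1
#' (within `1e-8`) raise a validation error.
#'
#' @param law a [discrete_law()].
#' @param spec an [intervention_spec][mult_shift].
#' @return the cumulative survival probability under the intervention.
#' @export
exact_gformula <- function(law, spec) {
  stopifnot(inherits(law, "discrete_law"),
            inherits(spec, "intervention_spec"))
  lev <- law$l_levels
  frame_of <- function(lbar, a, abar) {
    cur <- lbar[nrow(lbar), , drop = FALSE]
    prev <- if (nrow(lbar) >= 2L) lbar[nrow(lbar) - 1L, , drop = FALSE]
    fr <- cur
    for (nm in names(lev))
      fr[[paste0(nm, "_lag")]] <- if (is.null(prev)) 0 else prev[[nm]]
    fr$A <- a
    fr$A_prev <- if (length(abar)) abar[length(abar)] else 0
    fr$lstar <- cur[[law$lstar]]
    fr$lstar_lag <- if (is.null(prev)) 0 else prev[[law$lstar]]
    fr
  }
  recurse <- function(j, lbar, abar) {
    if (j == law$J) return(1)
    total <- 0
    psum <- 0
    for (r in seq_len(nrow(lev))) {
      l <- lev[r, , drop = FALSE]
      pl <- law$p_l(j, l, lbar, abar)
      psum <- psum + pl
      if (pl <= 0) next
      lbar2 <- rbind(lbar, l)
      f1 <- law$f(j, lbar2, abar)
      for (a in c(0, 1)) {
        qa <- q_eval(spec, f1, frame_of(lbar2, a, abar), a)
        if (qa <= 0) next
        s <- law$surv(j, lbar2, c(abar, a))
        if (s <= 0) next
        total <- total + pl * qa * s * recurse(j + 1L, lbar2, c(abar, a))
      }
    }
    if (abs(psum - 1) > 1e-8)
      stop("covariate table at interval ", j, " sums to ",
           format(psum), ", not 1", call. = FALSE)
    total
  }
  recurse(0L, lev[0, , drop = FALSE], numeric(0))
}

# ---------------------------------------------------------------------------
# Model-specification scenarios for the discrete simulation study

#' Model formulas for the misspecification scenarios
#'
#' Working-model formulas (over the [interval_frame()] columns of the
#' discrete study-1 process) for the three estimation scenarios: all
#' models correct; only the outcome regressions correct; only the
#' treatment and censoring models correct.  The correct outcome model is
#' saturated in \eqn{(A_j, L^*_j, L1_j, L2_j)}; the misspecified outcome
#' model drops every pairwise interaction between treatment and
#' covariates; the misspecified treatment process drops \eqn{A_{j-1}}
#' from the treatment model and ignores the censoring process (no
#' censoring model, hence no censoring weights).
#'
#' @param scenario one of `"all_correct"`, `"outcome_only"`,
#'   `"treatment_only"` (naming which set of models is correctly
#'   specified; `outcome_only` misspecifies treatment/censoring and vice
#'   versa).
#' @return list with elements `treatment`, `censoring`, `outcome`
#'   (one-sided formulas, recycled over intervals).
#' @export
misspecified_formulas <- function(scenario = c("all_correct",
                                               "outcome_only",
                                               "treatment_only")) {
  scenario <- match.arg(scenario)
  correct <- list(treatment = ~ lstar + L1 + L2 + A_prev,
                  censoring = ~ L1 + L2,
                  outcome = ~ A * lstar * L1 * L2)
  mis_t <- ~ lstar + L1 + L2
  mis_q <- ~ A + lstar + L1 + L2
  switch(scenario,
         all_correct = correct,
         # misspecified weighting ignores the censoring process entirely
         # and drops the previous treatment from the treatment model
         outcome_only = list(treatment = mis_t, censoring = NULL,
                             outcome = correct$outcome),
         treatment_only = list(treatment = correct$treatment,
                               censoring = correct$censoring,
                               outcome = mis_q))
}

#' Replicated simulation grid
#'
#' Runs `reps` replications of a scenario cell: simulate a panel from a
#' built-in process, estimate with each requested estimator, and return
#' one row per replication and estimator.  Per-replication seeds are
#' `seed + 1, ..., seed + reps`.
#'
#' @param dgp `"study1"` or `"study2"`.
#' @param n sample size per replication.
#' @param delta multiplicative-shift parameter.
#' @param scenario misspecification scenario (study 1 formulas).
#' @param reps number of replications.
#' @param seed base seed.
#' @param estimators subset of `c("wice", "ice", "ipw", "tmle")`.
#' @param learners optional learner list replacing the parametric
#'   formulas for every nuisance (study 2 style).
#' @param M TMLE split count.
#' @return data frame with columns `rep`, `estimator`, `psi`, `se`.
#' @export
run_scenario <- function(dgp = c("study1", "study2"), n, delta,
                         scenario = "all_correct", reps, seed,
                         estimators = c("wice", "ice", "ipw"),
                         learners = NULL, M = 2L) {
  dgp <- match.arg(dgp)
  spec <- mult_shift(delta)
  absorbing <- dgp == "study2"
  out <- vector("list", reps * length(estimators))
  k <- 0L
  for (r in seq_len(reps)) {
    set.seed(seed + r)
    panel <- if (dgp == "study1") simulate_study1(n) else
      simulate_study2(n)
    forms <- misspecified_formulas(scenario)
    tr_mod <- if (is.null(learners)) forms$treatment else learners
    cn_mod <- if (is.null(learners)) forms$censoring else learners
    qr_mod <- if (is.null(learners)) forms$outcome else learners
    for (est in estimators) {
      fit <- suppressWarnings(switch(
        est,
        wice = wice(panel, spec, treatment = tr_mod, outcome = qr_mod,
                    censoring = cn_mod, absorbing = absorbing, se = FALSE),
        ice = ice(panel, spec, outcome = qr_mod, absorbing = absorbing),
        ipw = ipw(panel, spec, treatment = tr_mod, censoring = cn_mod,
                  absorbing = absorbing),
        tmle = tmle_crossfit(panel, spec, treatment = tr_mod,
                             outcome = qr_mod, censoring = cn_mod,
                             absorbing = absorbing, M = M),
        stop("unknown estimator ", est, call. = FALSE)))
      k <- k + 1L
      out[[k]] <- data.frame(rep = r, estimator = est, psi = fit$psi,
                             se = fit$se)
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Summarize a replication grid against a truth
#'
#' @param results data frame from [run_scenario()].
#' @param truth true survival probability (e.g. from
#'   [monte_carlo_truth()]).
#' @return data frame per estimator: `bias100`, `se100`, `rmse100`
#'   (all multiplied by 100) and the Monte-Carlo standard error of the
#'   bias, `mcse100`.
#' @export
summarize_scenario <- function(results, truth) {
  if (inherits(truth, "mc_truth")) truth <- truth$psi
  agg <- lapply(split(results, results$estimator), function(d) {
    data.frame(estimator = d$estimator[1],
               bias100 = 100 * (mean(d$psi) - truth),
               se100 = 100 * stats::sd(d$psi),
               rmse100 = 100 * sqrt(mean((d$psi - truth)^2)),
               mcse100 = 100 * stats::sd(d$psi) / sqrt(nrow(d)),
               reps = nrow(d))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
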