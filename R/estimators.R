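#' @importFrom stats plogis qlogis
NULL

# ---------------------------------------------------------------------------
# shared helpers

subset_panel <- function(panel, rows) {
  new_panel(length(rows), panel$J,
            panel$A[rows, , drop = FALSE],
            panel$C[rows, , drop = FALSE],
            panel$Y[rows, , drop = FALSE],
            lapply(panel$L, function(m) m[rows, , drop = FALSE]),
            panel$lstar, panel$id[rows])
}

# q^g at the observed treatment from per-row canonical coefficients
# (avoids rebuilding frames inside tight loops); odds shift via closed
# form.
q_obs_from_terms <- function(spec, terms, pi1, a) {
  fa <- a * pi1 + (1 - a) * (1 - pi1)
  if (identical(spec$family, "odds_shift"))
    return(odds_shift_q(pi1, a, spec$delta))
  q <- terms$w2 * fa + terms$w1 * (a == terms$a_star)
  if (!is.null(terms$w3)) q <- q + terms$w3 * terms$p_obs
  q
}

#' Cumulative intervention-to-observed weight products
#'
#' The observational weights of the weighted sequential-regression
#' estimators:
#' \deqn{W_j = \prod_{k=0}^{j} \frac{\hat q^g_k(A_k \mid \cdot)}
#' {\hat\pi_k(A_k \mid \cdot)} \times \prod_{k=1}^{j+1}
#' \frac{1}{1 - \hat\lambda^c_k(\cdot)},}
#' the censoring factors entering only when a censoring fit is supplied
#' (an intervention eliminating censoring).  The weight is zero for
#' subjects not at risk at `j` and from the interval of censoring
#' onward.  Under \eqn{\delta = 1} (multiplicative shift) the treatment
#' ratios cancel exactly and, absent censoring, all weights are 1.
#'
#' @param panel a [panel_data] object.
#' @param spec an [intervention_spec][mult_shift].
#' @param treatment_fit a [fit_treatment()] result.
#' @param censoring_fit optional [fit_censoring()] result.
#' @param j interval through which to accumulate (`0..J-1`).
#' @return nonnegative weight vector of length `n`.
#' @export
cumulative_weights <- function(panel, spec, treatment_fit,
                               censoring_fit = NULL, j) {
  stopifnot(inherits(panel, "panel_data"), j >= 0, j <= panel$J - 1L)
  w <- rep(1, panel$n)
  for (k in 0:j) {
    risk <- at_risk(panel, k)
    frame <- interval_frame(panel, k)
    pi1 <- treatment_fit$pi[[k + 1L]]
    a <- panel$A[, k + 1L]
    wk <- rep(NA_real_, panel$n)
    idx <- which(risk & !is.na(pi1) & !is.na(a))
    q <- q_eval(spec, pi1[idx], frame[idx, , drop = FALSE], a[idx])
    f <- a[idx] * pi1[idx] + (1 - a[idx]) * (1 - pi1[idx])
    wk[idx] <- q / f
    if (!is.null(censoring_fit)) {
      h <- censoring_fit$hazard[[k + 1L]]
      wk[idx] <- wk[idx] / (1 - h[idx])
      cens <- !is.na(panel$C[, k + 2L]) & panel$C[, k + 2L] == 1
      wk[cens] <- 0
    }
    w <- w * wk
  }
  w[is.na(w)] <- 0
  w
}

# ---------------------------------------------------------------------------
# The sequential-regression engine shared by ICE / IPW / WICE.
#
# Precomputes per-interval frames, canonical coefficients and design
# matrices on the full sample once; run(idx) then re-estimates everything
# on a row subset (bootstrap resample) cheaply.

make_engine <- function(panel, spec, treatment = NULL, outcome = NULL,
                        censoring = NULL, absorbing = FALSE,
                        weighted = TRUE, method = "wice",
                        eps = 1e-6, learner_folds = 5L,
                        max_weight = Inf) {
  n <- panel$n; J <- panel$J
  canonical <- isTRUE(spec$canonical)
  if (method %in% c("wice")) stop_not_canonical(spec)
  if (method == "ice" && !canonical && is.null(treatment))
    stop("ICE under a non-canonical intervention needs a treatment model ",
         "to evaluate q^g", call. = FALSE)
  need_treat <- weighted || (method == "ice" && !canonical)
  if (need_treat && is.null(treatment))
    stop("a treatment model is required", call. = FALSE)

  frames <- lapply(seq_len(J) - 1L, interval_frame, panel = panel)
  terms <- if (canonical)
    lapply(frames, canonical_terms, spec = spec) else vector("list", J)
  if (canonical && !is.null(spec$p_star))
    for (j in seq_len(J))
      terms[[j]]$p_obs <- spec$p_star(frames[[j]], panel$A[, j])

  t_models <- if (need_treat) recycle_model(treatment, J)
  c_models <- if (!is.null(censoring)) recycle_model(censoring, J)
  q_models <- if (method != "ipw") recycle_model(outcome, J)

  frames_star <- frames_a0 <- frames_a1 <- NULL
  need_levels <- method == "ice" && !canonical ||
    (canonical && !is.null(spec$p_star))
  if (method != "ipw") {
    if (canonical)
      frames_star <- lapply(seq_len(J), function(jj) {
        fr <- frames[[jj]]; fr$A <- terms[[jj]]$a_star; fr
      })
    if (need_levels) {
      frames_a0 <- lapply(frames, function(fr) { fr$A <- 0; fr })
      frames_a1 <- lapply(frames, function(fr) { fr$A <- 1; fr })
    }
  }

  mm <- function(model, frame)
    if (inherits(model, "formula")) model_frame_cols(model, frame)
  mm_t <- lapply(seq_len(J), function(jj)
    if (need_treat) mm(t_models[[jj]], frames[[jj]]))
  mm_c <- lapply(seq_len(J), function(jj)
    if (!is.null(censoring)) mm(c_models[[jj]], frames[[jj]]))
  mm_q <- mm_qs <- mm_q0 <- mm_q1 <- vector("list", J)
  if (method != "ipw")
    for (jj in seq_len(J)) {
      mm_q[[jj]] <- mm(q_models[[jj]], frames[[jj]])
      if (canonical) mm_qs[[jj]] <- mm(q_models[[jj]], frames_star[[jj]])
      if (need_levels) {
        mm_q0[[jj]] <- mm(q_models[[jj]], frames_a0[[jj]])
        mm_q1[[jj]] <- mm(q_models[[jj]], frames_a1[[jj]])
      }
    }

  # warm starts: coefficients from the full-sample fit seed the
  # bootstrap-replicate fits (identical solutions, far fewer iterations)
  warm_t <- warm_c <- warm_q <- vector("list", J)

  run <- function(idx = NULL, store = FALSE) {
    take <- function(x) if (is.null(idx) || is.null(x)) x else
      x[idx, , drop = FALSE]
    takev <- function(x) if (is.null(idx) || is.null(x)) x else x[idx]
    Y <- take(panel$Y); C <- take(panel$C); A <- take(panel$A)
    nn <- nrow(Y)
    risk <- lapply(seq_len(J), function(jj)
      !is.na(Y[, jj]) & Y[, jj] == 1 & !is.na(C[, jj]) & C[, jj] == 0)
    tm_s <- lapply(seq_len(J), function(jj) {
      tj <- terms[[jj]]
      if (is.null(tj)) NULL else
        lapply(tj, function(v) if (is.null(idx)) v else v[idx])
    })
    fr_s <- NULL
    any_learner <- any(vapply(seq_len(J), function(jj)
      (need_treat && is_learner_list(t_models[[jj]])) ||
      (!is.null(censoring) && is_learner_list(c_models[[jj]])) ||
      (method != "ipw" && is_learner_list(q_models[[jj]])), TRUE))
    if (any_learner) fr_s <- lapply(frames, take)

    clipped <- 0L
    capped <- 0L
    pi1 <- ratio <- haz <- cumw <- vector("list", J)
    if (weighted || need_treat) {
      Wprev <- rep(1, nn)
      for (j in seq_len(J) - 1L) {
        jj <- j + 1L
        a_j <- A[, jj]
        a_prev <- if (j == 0L) rep(0, nn) else A[, j]
        p <- rep(NA_real_, nn)
        fit_rows <- which(risk[[jj]] & !is.na(a_j) &
                            (!absorbing | a_prev == 0))
        if (length(fit_rows)) {
          if (is_learner_list(t_models[[jj]])) {
            vars <- setdiff(names(frames[[jj]]), "A")
            st <- cv_stack(t_models[[jj]],
                           fr_s[[jj]][fit_rows, vars, drop = FALSE],
                           a_j[fit_rows], v = learner_folds)
            p[fit_rows] <- predict_stack(st, fr_s[[jj]][fit_rows, vars,
                                                        drop = FALSE])
          } else {
            if (length(unique(a_j[fit_rows])) < 2L)
              stop("single-class treatment at interval ", j, call. = FALSE)
            X <- take(mm_t[[jj]])
            fl <- frac_logit(X[fit_rows, , drop = FALSE], a_j[fit_rows],
                             start = warm_t[[jj]])
            if (is.null(idx)) warm_t[[jj]] <<- fl$coef
            p[fit_rows] <- plogis(drop(X[fit_rows, , drop = FALSE] %*%
                                         fl$coef))
          }
          clipped <- clipped + sum(p < eps | p > 1 - eps, na.rm = TRUE)
          p[fit_rows] <- pmin(pmax(p[fit_rows], eps), 1 - eps)
        }
        if (absorbing) p[risk[[jj]] & a_prev == 1] <- 1
        pi1[[jj]] <- p
        fa <- a_j * p + (1 - a_j) * (1 - p)
        q <- q_obs_from_terms(spec, tm_s[[jj]], p, a_j)
        r <- q / fa
        ratio[[jj]] <- r
        wk <- Wprev * r
        if (!is.null(censoring)) {
          cnext <- C[, jj + 1L]
          h <- rep(NA_real_, nn)
          crows <- which(risk[[jj]] & !is.na(cnext))
          if (length(crows)) {
            if (sum(cnext[crows]) == 0) {
              h[crows] <- 0
            } else if (is_learner_list(c_models[[jj]])) {
              st <- cv_stack(c_models[[jj]],
                             fr_s[[jj]][crows, , drop = FALSE],
                             cnext[crows], v = learner_folds)
              h[crows] <- pmin(predict_stack(st, fr_s[[jj]][crows, ,
                                                            drop = FALSE]),
                               1 - eps)
            } else {
              X <- take(mm_c[[jj]])
              fl <- frac_logit(X[crows, , drop = FALSE], cnext[crows],
                               start = warm_c[[jj]])
              if (is.null(idx)) warm_c[[jj]] <<- fl$coef
              h[crows] <- pmin(plogis(drop(X[crows, , drop = FALSE] %*%
                                             fl$coef)), 1 - eps)
            }
          }
          haz[[jj]] <- h
          wk <- wk / (1 - h)
          wk[!is.na(cnext) & cnext == 1] <- 0
        }
        if (is.finite(max_weight)) {
          capped <- capped + sum(wk > max_weight, na.rm = TRUE)
          wk <- pmin(wk, max_weight)
        }
        cumw[[jj]] <- wk
        Wprev <- wk
      }
    }

    if (method == "ipw") {
      ups <- numeric(J)
      for (j in seq_len(J) - 1L) {
        jj <- j + 1L
        rows <- which(risk[[jj]] & !is.na(C[, jj + 1L]) &
                        C[, jj + 1L] == 0 & !is.na(Y[, jj + 1L]))
        w <- cumw[[jj]][rows]
        if (!length(rows) || sum(w) <= 0)
          stop("zero total weight at interval ", j, call. = FALSE)
        ups[jj] <- sum(w * Y[rows, jj + 1L]) / sum(w)
      }
      psi <- prod(ups)
      return(list(psi = psi, hazards = ups, T0 = NULL,
                  diagnostics = weight_diag(cumw, clipped, capped),
                  components = NULL))
    }

    # backward recursion
    Tlist <- vector("list", J + 1L)
    Qobs_l <- Qstar_l <- vector("list", J)
    Tlist[[J + 1L]] <- Y[, J + 1L]
    for (j in rev(seq_len(J) - 1L)) {
      jj <- j + 1L
      Tnext <- Tlist[[jj + 1L]]
      rows <- which(risk[[jj]] & !is.na(C[, jj + 1L]) &
                      C[, jj + 1L] == 0 & !is.na(Tnext))
      prows <- which(risk[[jj]])
      w <- if (weighted) cumw[[jj]][rows] else rep(1, length(rows))
      Qobs <- Qstar <- Q0 <- Q1 <- rep(NA_real_, nn)
      if (!length(rows)) {
        Qobs[prows] <- Qstar[prows] <- Q0[prows] <- Q1[prows] <- 0
      } else if (is_learner_list(q_models[[jj]])) {
        st <- cv_stack(q_models[[jj]], fr_s[[jj]][rows, , drop = FALSE],
                       Tnext[rows], v = learner_folds, weights = w)
        Qobs[prows] <- predict_stack(st, fr_s[[jj]][prows, , drop = FALSE])
        if (canonical) {
          frs <- fr_s[[jj]][prows, , drop = FALSE]
          frs$A <- tm_s[[jj]]$a_star[prows]
          Qstar[prows] <- predict_stack(st, frs)
        }
        if (need_levels) {
          fr0 <- fr_s[[jj]][prows, , drop = FALSE]; fr0$A <- 0
          fr1 <- fr_s[[jj]][prows, , drop = FALSE]; fr1$A <- 1
          Q0[prows] <- predict_stack(st, fr0)
          Q1[prows] <- predict_stack(st, fr1)
        }
      } else {
        X <- take(mm_q[[jj]])
        is_intercept <- ncol(X) == 1L && all(X[rows, 1L] == X[rows[1L], 1L])
        if (is_intercept) {
          qv <- sum(w * Tnext[rows]) / sum(w)
          Qobs[prows] <- Qstar[prows] <- Q0[prows] <- Q1[prows] <- qv
        } else {
          fl <- tryCatch(
            frac_logit(X[rows, , drop = FALSE], Tnext[rows], w,
                       start = warm_q[[jj]]),
            error = function(e)
              stop("outcome model at interval ", j, ": ",
                   conditionMessage(e), call. = FALSE))
          if (is.null(idx)) warm_q[[jj]] <<- fl$coef
          Qobs[prows] <- plogis(drop(take(mm_q[[jj]])[prows, ,
                                                      drop = FALSE] %*%
                                       fl$coef))
          if (canonical)
            Qstar[prows] <- plogis(drop(take(mm_qs[[jj]])[prows, ,
                                                          drop = FALSE] %*%
                                          fl$coef))
          if (need_levels) {
            Q0[prows] <- plogis(drop(take(mm_q0[[jj]])[prows, ,
                                                       drop = FALSE] %*%
                                      fl$coef))
            Q1[prows] <- plogis(drop(take(mm_q1[[jj]])[prows, ,
                                                       drop = FALSE] %*%
                                      fl$coef))
          }
        }
      }
      Tj <- rep(NA_real_, nn)
      if (canonical) {
        tj <- tm_s[[jj]]
        Tj[prows] <- tj$w1[prows] * Qstar[prows] +
          tj$w2[prows] * Qobs[prows]
        if (!is.null(tj$w3)) {
          p1 <- spec$p_star(frames[[jj]][if (is.null(idx)) prows else
            idx[prows], , drop = FALSE], 1)
          Tj[prows] <- Tj[prows] + tj$w3[prows] *
            (p1 * Q1[prows] + (1 - p1) * Q0[prows])
        }
      } else {
        # generic stochastic update: T_j = sum_a q^g(a | .) Q_j^a
        q1 <- odds_shift_q(pi1[[jj]][prows], 1, spec$delta)
        Tj[prows] <- q1 * Q1[prows] + (1 - q1) * Q0[prows]
      }
      dead <- !is.na(Y[, jj]) & Y[, jj] == 0
      Tj[dead] <- 0
      Tlist[[jj]] <- Tj
      Qobs_l[[jj]] <- Qobs; Qstar_l[[jj]] <- Qstar
    }
    psi <- mean(Tlist[[1L]])
    comp <- if (store)
      list(T = Tlist, Q = Qobs_l, Qstar = Qstar_l, cumw = cumw,
           pi = pi1, ratio = ratio, hazard = haz)
    list(psi = psi, T0 = Tlist[[1L]],
         diagnostics = weight_diag(if (weighted) cumw, clipped, capped),
         components = comp)
  }
  run
}

weight_diag <- function(cumw, clipped, capped = 0L) {
  if (is.null(cumw) || is.null(cumw[[1]]))
    return(list(clipped = clipped))
  w <- cumw[[length(cumw)]]
  w <- w[!is.na(w)]
  list(max_weight = if (length(w)) max(w) else NA_real_,
       weight_quantiles = if (length(w))
         stats::quantile(w, c(.5, .9, .99, 1)) else NULL,
       clipped = clipped, capped = capped)
}

new_ipsi_fit <- function(method, spec, out, se = NA_real_,
                         ci = c(NA_real_, NA_real_), level = NA_real_) {
  structure(list(psi = out$psi, se = se, ci = ci, level = level,
                 method = method, family = spec$family,
                 delta = spec$delta, T0 = out$T0,
                 hazards = out$hazards,
                 diagnostics = out$diagnostics,
                 components = out$components),
            class = "ipsi_fit")
}

#' @export
print.ipsi_fit <- function(x, digits = 4, ...) {
  cat(toupper(x$method), " estimate of survival under the ", x$family,
      " intervention", sep = "")
  if (!is.na(x$delta)) cat(" (delta = ", format(x$delta), ")", sep = "")
  cat("\n  psi_hat = ", format(round(x$psi, digits)), sep = "")
  if (!is.na(x$se)) cat("  (SE ", format(round(x$se, digits)), ")", sep = "")
  if (!any(is.na(x$ci)))
    cat("  ", format(100 * x$level), "% CI [",
        format(round(x$ci[1], digits)), ", ",
        format(round(x$ci[2], digits)), "]", sep = "")
  cat("\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# public estimators

#' Sequential-regression (ICE) estimator
#'
#' The singly robust iterated conditional expectation estimator: the
#' weighted-ICE backward recursion with all observational weights set
#' to 1.  Consistency requires every outcome regression to be correctly
#' specified.  Canonical interventions need no treatment model; for the
#' (non-canonical) odds shift a treatment model must be supplied and the
#' update marginalizes the per-level regressions over \eqn{\hat q^g}.
#'
#' @param panel a [panel_data] object.
#' @param spec an [intervention_spec][mult_shift].
#' @param outcome outcome-regression specification: a one-sided formula
#'   over the [interval_frame()] columns (recycled), a list of `J`
#'   formulas, or a learner list (see [lrn_glm()]).
#' @param treatment optional treatment model (required only for
#'   non-canonical interventions).
#' @param absorbing is treatment an absorbing initiation process?
#' @param store keep per-interval components (for [eif_values()])?
#' @param learner_folds folds for [cv_stack()] when learners are used.
#' @return an `ipsi_fit`: point estimate `psi`, per-subject `T0`,
#'   weight/clipping diagnostics.  Standard errors for the singly robust
#'   estimators come from [bootstrap_ci()].
#' @export
ice <- function(panel, spec, outcome, treatment = NULL,
                absorbing = FALSE, store = FALSE, learner_folds = 5L) {
  run <- make_engine(panel, spec, treatment = treatment, outcome = outcome,
                     censoring = NULL, absorbing = absorbing,
                     weighted = FALSE, method = "ice",
                     learner_folds = learner_folds)
  fit <- new_ipsi_fit("ice", spec, run(NULL, store = store))
  fit$engine <- run
  fit
}

#' Inverse-probability-weighted estimator
#'
#' \eqn{\hat\psi = \prod_{j=0}^{J-1} \hat\Upsilon_j}, where each
#' \eqn{\hat\Upsilon_j} solves
#' \eqn{P_n[Y_j \prod_{k \le j}(\hat q^g_k/\hat\pi_k)\{Y_{j+1} -
#' \Upsilon_j\}] = 0} — the weighted discrete hazard complement under the
#' intervention.  Equals the weighted-ICE estimator with intercept-only
#' outcome models.  Consistency requires the treatment (and censoring)
#' models to be correct.
#'
#' @inheritParams ice
#' @param treatment treatment-process model (formula, list of formulas,
#'   or learner list).
#' @param censoring optional censoring-hazard model.
#' @param max_weight optional cap on the cumulative weights (default
#'   none); the number of capped person-intervals is reported in the
#'   diagnostics.
#' @export
ipw <- function(panel, spec, treatment, censoring = NULL,
                absorbing = FALSE, learner_folds = 5L,
                max_weight = Inf) {
  run <- make_engine(panel, spec, treatment = treatment, outcome = NULL,
                     censoring = censoring, absorbing = absorbing,
                     weighted = TRUE, method = "ipw",
                     learner_folds = learner_folds,
                     max_weight = max_weight)
  fit <- new_ipsi_fit("ipw", spec, run(NULL))
  fit$engine <- run
  fit
}

#' Weighted-ICE estimator (multiply robust)
#'
#' Sequential weighted fractional logistic regression: at each interval
#' \eqn{j = J-1, \dots, 0} the response \eqn{\hat T_{j+1}} is regressed
#' on \eqn{\phi(\bar L_j, \bar A_j)} among survivors with score weights
#' \eqn{\prod_{k \le j}(\hat q^g_k / \hat\pi_k)} (times
#' inverse-probability-of-censoring factors when censoring is modeled),
#' and \eqn{\hat T_j} is formed by the canonical backward update
#' ([tj_update()]) with \eqn{\hat T_j = 0} for the dead.  The estimate
#' is \eqn{P_n(\hat T_0)}.  The estimator is \eqn{J+1} multiply robust:
#' consistent whenever the outcome regressions are correct from some
#' interval \eqn{k} onward and the treatment models are correct before
#' \eqn{k}.
#'
#' The default standard error is the empirical standard deviation of the
#' EIF values at the fit divided by \eqn{\sqrt n}; [bootstrap_ci()]
#' provides the percentile-bootstrap alternative.
#'
#' @inheritParams ipw
#' @param outcome outcome-regression models (formula(s) or learners).
#' @param se compute the EIF-based standard error?
#' @export
wice <- function(panel, spec, treatment, outcome, censoring = NULL,
                 absorbing = FALSE, store = FALSE, se = TRUE,
                 learner_folds = 5L, max_weight = Inf) {
  run <- make_engine(panel, spec, treatment = treatment, outcome = outcome,
                     censoring = censoring, absorbing = absorbing,
                     weighted = TRUE, method = "wice",
                     learner_folds = learner_folds,
                     max_weight = max_weight)
  out <- run(NULL, store = store || se)
  fit <- new_ipsi_fit("wice", spec, out)
  if (se) {
    U <- eif_from_components(out$components, out$psi)
    fit$se <- stats::sd(U) / sqrt(panel$n)
    fit$ci <- fit$psi + c(-1, 1) * stats::qnorm(0.975) * fit$se
    fit$level <- 0.95
  }
  if (!store) fit$components <- NULL
  fit$engine <- run
  fit
}

#' Percentile bootstrap confidence interval
#'
#' Subject-level nonparametric resampling: `B` bootstrap panels are
#' drawn by resampling subjects with replacement, the estimator is
#' recomputed on each, and the interval is formed from the
#' \eqn{(1-\text{level})/2} and \eqn{1-(1-\text{level})/2} percentiles
#' (2.5th and 97.5th at the default 95% level).  Replicates on which the
#' estimator fails are dropped and counted; more than 10% failures is an
#' error.
#'
#' @param est either an `ipsi_fit` returned by [ice()], [ipw()] or
#'   [wice()] (its internal engine is reused, which is fast), or a
#'   function `f(panel)` returning a scalar estimate.
#' @param panel the original [panel_data] object.
#' @param B number of bootstrap replicates (>= 2).
#' @param level confidence level.
#' @param seed optional RNG seed for reproducibility.
#' @return list with `ci`, `level`, `replicates`, `failed`.
#' @export
bootstrap_ci <- function(est, panel, B = 1000L, level = 0.95,
                         seed = NULL) {
  stopifnot(B >= 2L, inherits(panel, "panel_data"))
  if (!is.null(seed)) set.seed(seed)
  n <- panel$n
  one <- if (inherits(est, "ipsi_fit") && !is.null(est$engine)) {
    function(idx) est$engine(idx)$psi
  } else if (is.function(est)) {
    function(idx) {
      v <- est(subset_panel(panel, idx))
      if (inherits(v, "ipsi_fit")) v$psi else as.numeric(v)
    }
  } else stop("est must be an ipsi_fit or a function of the panel",
              call. = FALSE)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(suppressWarnings(one(idx)),
                        error = function(e) NA_real_)
  }
  failed <- sum(is.na(reps))
  if (failed > 0.1 * B)
    stop("bootstrap failed on ", failed, " of ", B, " replicates",
         call. = FALSE)
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  list(ci = ci, level = level, replicates = reps, failed = failed)
}
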