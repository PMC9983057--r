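# Cross-fitted targeted maximum likelihood estimation.

# Fit a conditional-mean model for a [0,1] response on an interval frame;
# returns a predict closure usable on new frames (so counterfactual
# treatment columns can be substituted).
fit_mean_model <- function(model, frame, y, weights = NULL, v = 2L) {
  if (is_learner_list(model)) {
    st <- cv_stack(model, frame, y, v = v, weights = weights)
    return(function(newframe) predict_stack(st, newframe))
  }
  mm <- model_frame_cols(model, frame)
  fl <- frac_logit(mm, y, weights)
  function(newframe)
    plogis(drop(model_frame_cols(model, newframe) %*% fl$coef))
}

# Apply a fitted treatment process to a (new) panel: per-interval
# \hat\pi_j vectors with absorbing handling and clipping.
predict_treatment <- function(tfit, panel, eps = 1e-6) {
  J <- panel$J
  out <- vector("list", J)
  for (j in seq_len(J) - 1L) {
    frame <- interval_frame(panel, j)
    risk <- at_risk(panel, j)
    p <- rep(NA_real_, panel$n)
    rows <- which(risk & (!tfit$absorbing | frame$A_prev == 0))
    f <- tfit$fits[[j + 1L]]
    if (length(rows) && !is.null(f) && !identical(f$kind, "empty"))
      p[rows] <- clip_prob(f$predict(frame[rows, , drop = FALSE]), eps,
                           warn = FALSE)
    if (tfit$absorbing) p[risk & frame$A_prev == 1] <- 1
    out[[j + 1L]] <- p
  }
  out
}

predict_censoring <- function(cfit, panel, eps = 1e-6) {
  J <- panel$J
  out <- vector("list", J)
  for (j in seq_len(J) - 1L) {
    frame <- interval_frame(panel, j)
    risk <- which(at_risk(panel, j))
    h <- rep(NA_real_, panel$n)
    f <- cfit$fits[[j + 1L]]
    if (length(risk) && !is.null(f))
      h[risk] <- pmin(f$predict(frame[risk, , drop = FALSE]), 1 - eps)
    out[[j + 1L]] <- h
  }
  out
}

# Cumulative q/pi (x IPCW) products on a panel given pi / hazard lists.
cumw_from_pi <- function(panel, spec, pi_list, haz_list = NULL) {
  J <- panel$J; n <- panel$n
  out <- vector("list", J)
  Wprev <- rep(1, n)
  for (j in seq_len(J) - 1L) {
    frame <- interval_frame(panel, j)
    a <- panel$A[, j + 1L]
    p <- pi_list[[j + 1L]]
    q <- rep(NA_real_, n)
    idx <- which(!is.na(p) & !is.na(a))
    if (length(idx))
      q[idx] <- q_eval(spec, p[idx], frame[idx, , drop = FALSE], a[idx])
    fa <- a * p + (1 - a) * (1 - p)
    wk <- Wprev * q / fa
    if (!is.null(haz_list)) {
      h <- haz_list[[j + 1L]]
      wk <- wk / (1 - h)
      cens <- !is.na(panel$C[, j + 2L]) & panel$C[, j + 2L] == 1
      wk[cens] <- 0
    }
    out[[j + 1L]] <- wk
    Wprev <- wk
  }
  out
}

solve_fluctuation <- function(tvals, offset, w, nscale,
                              bounds = c(-10, 10)) {
  if (!length(w) || sum(w) <= 0)
    return(list(gamma = 0, score = 0))
  sc <- function(g) sum(w * (tvals - plogis(offset + g))) / nscale
  lo <- sc(bounds[1L]); hi <- sc(bounds[2L])
  if (is.na(lo) || is.na(hi) || lo < 0 || hi > 0)
    stop("targeting fluctuation not bracketed in [", bounds[1L], ", ",
         bounds[2L], "]: score endpoints ", signif(lo, 4), ", ",
         signif(hi, 4), call. = FALSE)
  g <- stats::uniroot(sc, bounds, tol = 1e-10)$root
  for (i in 1:20) {                      # Newton polish on the score
    s <- sc(g)
    if (abs(s) < 1e-12) break
    p <- plogis(offset + g)
    d <- sum(w * p * (1 - p)) / nscale
    if (!is.finite(d) || d <= 0) break
    g2 <- g + s / d
    if (g2 < bounds[1L] || g2 > bounds[2L]) break
    g <- g2
  }
  list(gamma = g, score = sc(g))
}

#' TMLE with sample splitting and cross-fitting
#'
#' Targeted maximum likelihood estimation of survival under a canonical
#' intervention.  The sample is split into `M` near-equal random folds.
#' For each fold \eqn{m}: the treatment process, censoring hazard and
#' the backward outcome-regression recursion are fit on the complement
#' \eqn{S_{-m}} (by formulas or machine-learning stacks); then, on
#' \eqn{S_m}, an intercept-only logit fluctuation \eqn{\gamma_j} is
#' solved recursively for \eqn{j = J-1, \dots, 0} from
#' \deqn{P_{n_m}\Big(Y_j \prod_{k \le j}
#' \tfrac{\hat q^{g(-m)}_k}{\hat\pi^{(-m)}_k}
#' \big[\hat T_{j+1} - \mathrm{expit}\{\mathrm{logit}(\hat Q^{(-m)}_j)
#' + \gamma_j\}\big]\Big) = 0,}
#' with \eqn{\hat T_j} formed from the fluctuated
#' \eqn{\hat Q^\Delta_j} by the canonical update.  The estimate is
#' \eqn{M^{-1} \sum_m P_{n_m}(\hat T_0)}; the standard error is the
#' cross-fitted empirical standard deviation of the EIF values divided
#' by \eqn{\sqrt n}.  Out-of-fold nuisance estimation removes the
#' Donsker-class requirement, so arbitrary learners may be used.
#'
#' @inheritParams wice
#' @param M number of splits (`M = 1` disables cross-fitting, with a
#'   warning).
#' @param seed optional RNG seed (splits, fold assignment, forests).
#' @param level confidence level for the Wald interval.
#' @param min_split smallest admissible split size.
#' @param gamma_bounds bracketing interval for the fluctuation root.
#' @param eps_q bound keeping the initial outcome predictions inside
#'   `[eps_q, 1 - eps_q]` before the logit fluctuation (offsets then lie
#'   within about ±7, which guarantees the root is bracketed).
#' @return an `ipsi_fit` with `psi`, EIF-based `se` and CI, per-split
#'   diagnostics (`gammas`, post-targeting `scores`, split estimates
#'   `psi_splits`), and per-subject EIF values in `diagnostics$eif`.
#' @export
tmle_crossfit <- function(panel, spec, treatment, outcome,
                          censoring = NULL, M = 2L, absorbing = FALSE,
                          learner_folds = 5L, seed = NULL, level = 0.95,
                          min_split = 50L, gamma_bounds = c(-10, 10),
                          eps_q = 1e-3, store = FALSE) {
  stopifnot(inherits(panel, "panel_data"))
  stop_not_canonical(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- panel$n; J <- panel$J
  if (M < 1L) stop("M must be >= 1", call. = FALSE)
  if (M == 1L)
    warning("M = 1: nuisances fit and targeted on the same sample ",
            "(no cross-fitting)", call. = FALSE)
  if (M > 1L && n / M < min_split)
    stop("split size ", floor(n / M), " below the floor of ", min_split,
         call. = FALSE)
  split_id <- if (M == 1L) rep(1L, n) else sample(rep_len(seq_len(M), n))

  t_models <- recycle_model(treatment, J)
  q_models <- recycle_model(outcome, J)

  psi_m <- numeric(M)
  gammas <- scores <- matrix(NA_real_, J, M,
                             dimnames = list(paste0("j=", 0:(J - 1)),
                                             paste0("m=", 1:M)))
  U <- rep(NA_real_, n)
  T0_all <- rep(NA_real_, n)
  comp_all <- if (store)
    list(T = rep(list(rep(NA_real_, n)), J + 1L),
         Q = rep(list(rep(NA_real_, n)), J),
         Qstar = rep(list(rep(NA_real_, n)), J),
         cumw = rep(list(rep(NA_real_, n)), J))
  maxw <- 0

  for (m in seq_len(M)) {
    tr <- if (M == 1L) seq_len(n) else which(split_id != m)
    te <- if (M == 1L) seq_len(n) else which(split_id == m)
    ptr <- subset_panel(panel, tr)
    pte <- subset_panel(panel, te)
    n_te <- length(te)

    tfit <- fit_treatment(ptr, treatment, absorbing = absorbing)
    cfit <- if (!is.null(censoring)) fit_censoring(ptr, censoring)

    # --- backward recursion on the training fold: defines Q-hat_j^(-m)
    qhat <- vector("list", J)
    Ttr <- ptr$Y[, J + 1L]
    for (j in rev(seq_len(J) - 1L)) {
      jj <- j + 1L
      frame_tr <- interval_frame(ptr, j)
      risk_tr <- at_risk(ptr, j)
      rows <- which(risk_tr & !is.na(ptr$C[, jj + 1L]) &
                      ptr$C[, jj + 1L] == 0 & !is.na(Ttr))
      if (!length(rows)) {
        qhat[[jj]] <- function(newframe) rep(0, nrow(newframe))
      } else {
        qhat[[jj]] <- fit_mean_model(q_models[[jj]],
                                     frame_tr[rows, , drop = FALSE],
                                     Ttr[rows], v = learner_folds)
      }
      prows <- which(risk_tr)
      tm <- canonical_terms(spec, frame_tr)
      Qo <- Qs <- rep(NA_real_, ptr$n)
      if (length(prows)) {
        Qo[prows] <- qhat[[jj]](frame_tr[prows, , drop = FALSE])
        frs <- frame_tr[prows, , drop = FALSE]
        frs$A <- tm$a_star[prows]
        Qs[prows] <- qhat[[jj]](frs)
      }
      Tnew <- rep(NA_real_, ptr$n)
      Tnew[prows] <- tm$w1[prows] * Qs[prows] + tm$w2[prows] * Qo[prows]
      if (!is.null(tm$w3))
        Tnew[prows] <- Tnew[prows] + tm$w3[prows] *
          p_star_mix(spec, frame_tr[prows, , drop = FALSE], qhat[[jj]])
      Tnew[!is.na(ptr$Y[, jj]) & ptr$Y[, jj] == 0] <- 0
      Ttr <- Tnew
    }

    # --- targeting on the held-out fold
    pi_te <- predict_treatment(tfit, pte)
    haz_te <- if (!is.null(cfit)) predict_censoring(cfit, pte)
    cumw_te <- cumw_from_pi(pte, spec, pi_te, haz_te)
    maxw <- max(maxw, unlist(lapply(cumw_te, function(w)
      max(c(0, w), na.rm = TRUE))))

    Tte <- vector("list", J + 1L)
    Tte[[J + 1L]] <- pte$Y[, J + 1L]
    Qd_l <- Qds_l <- vector("list", J)
    for (j in rev(seq_len(J) - 1L)) {
      jj <- j + 1L
      frame_te <- interval_frame(pte, j)
      risk_te <- at_risk(pte, j)
      prows <- which(risk_te)
      tm <- canonical_terms(spec, frame_te)
      Qo <- Qs <- rep(NA_real_, n_te)
      if (length(prows)) {
        # initial predictions bounded away from 0/1 so the logit
        # fluctuation offset stays finite and the root is bracketed
        Qo[prows] <- clip_prob(qhat[[jj]](frame_te[prows, , drop = FALSE]),
                               eps = eps_q, warn = FALSE)
        frs <- frame_te[prows, , drop = FALSE]
        frs$A <- tm$a_star[prows]
        Qs[prows] <- clip_prob(qhat[[jj]](frs), eps = eps_q, warn = FALSE)
      }
      Tnext <- Tte[[jj + 1L]]
      rows <- which(risk_te & !is.na(pte$C[, jj + 1L]) &
                      pte$C[, jj + 1L] == 0 & !is.na(Tnext))
      fl <- solve_fluctuation(Tnext[rows], qlogis(Qo[rows]),
                              cumw_te[[jj]][rows], n_te, gamma_bounds)
      gammas[jj, m] <- fl$gamma
      scores[jj, m] <- fl$score
      Qd <- plogis(qlogis(Qo) + fl$gamma)
      Qds <- plogis(qlogis(Qs) + fl$gamma)
      Tnew <- rep(NA_real_, n_te)
      Tnew[prows] <- tm$w1[prows] * Qds[prows] + tm$w2[prows] * Qd[prows]
      if (!is.null(tm$w3))
        Tnew[prows] <- Tnew[prows] + tm$w3[prows] *
          p_star_mix(spec, frame_te[prows, , drop = FALSE],
                     function(fr) plogis(qlogis(clip_prob(qhat[[jj]](fr),
                                                          eps = eps_q,
                                                          warn = FALSE)) +
                                           fl$gamma))
      Tnew[!is.na(pte$Y[, jj]) & pte$Y[, jj] == 0] <- 0
      Tte[[jj]] <- Tnew
      Qd_l[[jj]] <- Qd; Qds_l[[jj]] <- Qds
    }
    psi_m[m] <- mean(Tte[[1L]])
    comp <- list(T = Tte, Q = Qd_l, cumw = cumw_te)
    U[te] <- eif_from_components(comp, 0)      # uncentered contributions
    T0_all[te] <- Tte[[1L]]
    if (store) {
      for (k in seq_len(J + 1L)) comp_all$T[[k]][te] <- Tte[[k]]
      for (k in seq_len(J)) {
        comp_all$Q[[k]][te] <- Qd_l[[k]]
        comp_all$Qstar[[k]][te] <- Qds_l[[k]]
        comp_all$cumw[[k]][te] <- cumw_te[[k]]
      }
    }
  }

  psi <- mean(psi_m)
  se <- sqrt(mean((U - psi)^2) / n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- list(psi = psi, T0 = T0_all,
              diagnostics = list(psi_splits = psi_m, gammas = gammas,
                                 scores = scores, max_weight = maxw,
                                 eif = U - psi, split_id = split_id),
              components = comp_all)
  fit <- new_ipsi_fit("tmle", spec, out, se = se,
                      ci = psi + c(-1, 1) * z * se, level = level)
  fit
}

p_star_mix <- function(spec, frame, predict_fun) {
  p1 <- spec$p_star(frame, 1)
  fr1 <- frame; fr1$A <- 1
  fr0 <- frame; fr0$A <- 0
  p1 * predict_fun(fr1) + (1 - p1) * predict_fun(fr0)
}
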