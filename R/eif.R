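#' Backward response update for canonical interventions
#'
#' One step of the backward recursion defining the responses
#' \eqn{T_j} from the outcome regressions \eqn{Q_j}:
#' \deqn{T_j = c_1 Q_j^{A_j = a^*} h_1 + c_2 Q_j h_2 + c_3 \{\textstyle
#' \sum_a p^*(a \mid \cdot) Q_j^{A_j = a}\} h_3,}
#' with \eqn{T_J = Y_J} and \eqn{T_j = 0} whenever \eqn{Y_j = 0}.  For
#' the multiplicative shift this reduces to
#' \eqn{T_j = (1 - \delta) Q_j^{A_j = 1} l^*_j + Q_j (l^*_j \delta + 1 -
#' l^*_j)}.
#'
#' @param spec a canonical [intervention_spec][mult_shift].
#' @param frame interval frame supplying the history functions.
#' @param Q_obs \eqn{Q_j} evaluated at the observed treatment.
#' @param Q_star \eqn{Q_j} evaluated at \eqn{A_j = a^*} (required when
#'   `c1 != 0`).
#' @param Q_levels named list (`"0"`, `"1"`) of \eqn{Q_j} at each level,
#'   required when the spec carries a nonzero `h3`/`p_star` term.
#' @return numeric vector of \eqn{T_j} values.
#' @export
tj_update <- function(spec, frame, Q_obs, Q_star = NULL, Q_levels = NULL) {
  tm <- canonical_terms(spec, frame)
  out <- tm$w2 * Q_obs
  if (any(tm$w1 != 0)) {
    if (is.null(Q_star))
      stop("Q at A = a* required when c1*h1 is nonzero", call. = FALSE)
    out <- out + tm$w1 * Q_star
  }
  if (!is.null(tm$w3)) {
    if (is.null(Q_levels))
      stop("per-level Q values required when c3*h3 is nonzero",
           call. = FALSE)
    mix <- numeric(nrow(frame))
    for (a in c(0, 1))
      mix <- mix + spec$p_star(frame, a) * Q_levels[[as.character(a)]]
    out <- out + tm$w3 * mix
  }
  out
}

#' Efficient influence function values
#'
#' Evaluates the per-subject EIF
#' \deqn{U = \sum_{j=1}^{J} (T_j - Q_{j-1}) \prod_{k=0}^{j-1}
#' \frac{q^g_k(A_k \mid \cdot)}{f_k(A_k \mid \cdot)} + T_0 - \psi,}
#' with \eqn{T_J = Y_J}, from the stored components of a fitted
#' sequential-regression estimator.  When censoring was modeled the
#' inverse-probability-of-censoring factors are folded into the
#' cumulative products, and a subject's terms are zero from the interval
#' at which they were censored.  The empirical mean of `U` at the TMLE
#' solution is zero up to the targeting tolerance.
#'
#' @param fit a [wice()] or [tmle_crossfit()] result obtained with
#'   `store = TRUE` (it carries `components`: lists `T` (values
#'   \eqn{T_0..T_J}), `Q` (\eqn{Q_0..Q_{J-1}} at observed treatment) and
#'   `cumw` (cumulative weight products)).
#' @param psi centering value \eqn{\psi}; defaults to the fit's point
#'   estimate.  Passing it explicitly lets the same evaluator serve
#'   one-step checks, TMLE score verification and variance estimation.
#' @return numeric vector of per-subject EIF values.
#' @export
eif_values <- function(fit, psi = fit$psi) {
  comp <- fit$components
  if (is.null(comp))
    stop("fit carries no stored components; re-run with store = TRUE",
         call. = FALSE)
  eif_from_components(comp, psi)
}

eif_from_components <- function(comp, psi) {
  J <- length(comp$Q)
  n <- length(comp$T[[1]])
  U <- comp$T[[1]] - psi                      # T_0 - psi
  for (j in seq_len(J)) {                     # terms j = 1..J
    term <- (comp$T[[j + 1L]] - comp$Q[[j]]) * comp$cumw[[j]]
    term[is.na(term)] <- 0                    # censored: contributes zero
    U <- U + term
  }
  U
}

#' Point-treatment (J = 1) efficient influence function
#'
#' For a parameter of the linear-combination form
#' \eqn{\psi = c_1 E\{h_1(O)\} + c_2 E[E\{h_2(O) \mid A = a^*, L\}]}
#' with \eqn{h_2(O) = Y \tilde h_2(A, L)}, the EIF is
#' \deqn{U = c_1 h_1(O) + c_2 \Big[\frac{I(A = a^*)}{f(A \mid L)}
#' \{h_2(O) - E(h_2 \mid A, L)\} + E(h_2 \mid A = a^*, L)\Big] - \psi.}
#' The static regime \eqn{(h_1 = 0, c_2 = 1, \tilde h_2 = 1)} recovers
#' the familiar augmented-IPW influence function
#' \eqn{I(A = a^*)/f \cdot (Y - m) + m(a^*, L) - \psi}.
#'
#' @param y outcome vector.
#' @param a observed treatment vector.
#' @param a_star intervention treatment level.
#' @param c1,c2 constants of the representation.
#' @param h1 vector \eqn{h_1(O)} per subject.
#' @param h2_factor vector \eqn{\tilde h_2(A, L)} at the observed
#'   treatment; `h2_factor_star` the same at \eqn{A = a^*}.
#' @param m_obs,m_star fitted outcome regressions \eqn{m(A, L)} and
#'   \eqn{m(a^*, L)}.
#' @param f_obs fitted \eqn{f(A \mid L)} at the observed treatment
#'   (guarded below by `eps`).
#' @param psi centering value.
#' @param eps clip for small `f_obs`.
#' @return numeric vector of per-subject EIF values.
#' @export
point_treatment_eif <- function(y, a, a_star, c1, c2, h1, h2_factor,
                                h2_factor_star, m_obs, m_star, f_obs,
                                psi, eps = 1e-6) {
  f_obs <- clip_prob(f_obs, eps)
  c1 * h1 +
    c2 * ((a == a_star) / f_obs * (y * h2_factor - m_obs * h2_factor) +
            m_star * h2_factor_star) - psi
}
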