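#' Intervention treatment distributions
#'
#' An intervention treatment distribution \eqn{q^g(a_j \mid Y_j = 1,
#' \bar{l}_j, \bar{a}_{j-1})} specifies how treatment is assigned at each
#' interval under a (possibly stochastic) strategy \eqn{g}.  The
#' distributions supported here may depend on the *observed* treatment
#' process \eqn{f(a_j \mid \cdot)}: the built-in families are the
#' multiplicative shift, which among subjects with an indication
#' (\eqn{L^*_j = 1}) multiplies the probability of *not* initiating
#' treatment by \eqn{\delta \in [0, 1]}; the odds shift, which multiplies
#' the propensity odds by \eqn{\delta > 0}; and degenerate static and
#' dynamic regimes.
#'
#' Every family except the odds shift is stored in the canonical form
#' \deqn{q^g(a_j \mid \cdot) = c_1 h_1 I(a_j = a^*) + c_2 h_2 f(a_j \mid
#' \cdot) + c_3 h_3 p^*(a_j \mid \cdot),}
#' where \eqn{c_1, c_2, c_3} are constants, \eqn{h_1, h_2, h_3} are known
#' functions of the measured past, and \eqn{p^*} is a known non-degenerate
#' distribution.  Interventions of this form admit multiply robust
#' estimators built from a backward recursion on outcome regressions; the
#' odds shift does not, so it is flagged `canonical = FALSE` and may only
#' be used with the singly robust IPW and ICE estimators.
#'
#' The history functions `h1`, `h2`, `h3` receive a per-interval data
#' frame (the "interval frame", see [interval_frame()]) containing the
#' covariates at interval `j`, their one-interval lags (`<name>_lag`), and
#' the previous treatment `A_prev`, and must return a numeric vector.
#'
#' @param delta shift parameter.  Multiplicative shift: \eqn{\delta \in
#'   [0, 1]}, the factor by which the probability of non-initiation is
#'   decreased among subjects with `lstar = 1` (\eqn{\delta = 0} always
#'   treats them, \eqn{\delta = 1} leaves the observed process
#'   unchanged).  Odds shift: \eqn{\delta \in (0, \infty)}, the
#'   multiplier on the propensity odds.
#' @return An object of class `intervention_spec`.
#' @examples
#' spec <- mult_shift(0.5)
#' mult_shift_q(f1 = 0.3, lstar = 1, a = 1, delta = 0.5)  # 0.65
#' @export
mult_shift <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta < 0 || delta > 1)
    stop("multiplicative shift requires delta in [0, 1]", call. = FALSE)
  new_intervention(
    family = "multiplicative_shift", delta = delta, a_star = 1L,
    c1 = 1 - delta, c2 = 1, c3 = 0,
    h1 = function(frame) frame$lstar,
    h2 = function(frame) frame$lstar * delta + 1 - frame$lstar,
    h3 = NULL, p_star = NULL, canonical = TRUE)
}

#' @rdname mult_shift
#' @export
odds_shift <- function(delta) {
  if (!is.numeric(delta) || length(delta) != 1L || is.na(delta) ||
      delta <= 0)
    stop("odds shift requires delta > 0", call. = FALSE)
  new_intervention(
    family = "odds_shift", delta = delta, a_star = NA_integer_,
    c1 = NA_real_, c2 = NA_real_, c3 = NA_real_,
    h1 = NULL, h2 = NULL, h3 = NULL, p_star = NULL, canonical = FALSE)
}

#' @rdname mult_shift
#' @param a treatment level assigned at every interval (static regime).
#' @export
static_regime <- function(a) {
  a <- as.integer(a)
  stopifnot(a %in% c(0L, 1L))
  new_intervention(
    family = "static", delta = NA_real_, a_star = a,
    c1 = 1, c2 = 0, c3 = 0,
    h1 = function(frame) rep(1, nrow(frame)),
    h2 = NULL, h3 = NULL, p_star = NULL, canonical = TRUE)
}

#' @rdname mult_shift
#' @param rule function of the interval frame returning the assigned
#'   treatment level (0/1 per row) for a dynamic regime.
#' @export
dynamic_regime <- function(rule) {
  stopifnot(is.function(rule))
  new_intervention(
    family = "dynamic", delta = NA_real_, a_star = rule,
    c1 = 1, c2 = 0, c3 = 0,
    h1 = function(frame) rep(1, nrow(frame)),
    h2 = NULL, h3 = NULL, p_star = NULL, canonical = TRUE)
}

#' Register a custom canonical intervention
#'
#' Builds an `intervention_spec` directly from the canonical constants and
#' history functions.  `p_star` may be omitted if and only if `h3` is
#' absent (identically zero).
#'
#' @param a_star intervention treatment level (0/1), or a rule function of
#'   the interval frame.
#' @param c1,c2,c3 real constants.
#' @param h1,h2,h3 functions of the interval frame returning numeric
#'   vectors; `NULL` means identically zero.
#' @param p_star function `(frame, a)` returning a non-degenerate
#'   probability of treatment level `a` given the measured past.
#' @param delta optional shift parameter recorded for provenance.
#' @export
custom_intervention <- function(a_star = NA_integer_, c1 = 0, c2 = 0,
                                c3 = 0, h1 = NULL, h2 = NULL, h3 = NULL,
                                p_star = NULL, delta = NA_real_) {
  if (is.null(h3) && c3 != 0)
    stop("c3 != 0 requires h3", call. = FALSE)
  if (!is.null(h3) && is.null(p_star))
    stop("h3 supplied without p_star", call. = FALSE)
  new_intervention(family = "custom", delta = delta, a_star = a_star,
                   c1 = c1, c2 = c2, c3 = c3, h1 = h1, h2 = h2, h3 = h3,
                   p_star = p_star, canonical = TRUE)
}

new_intervention <- function(family, delta, a_star, c1, c2, c3,
                             h1, h2, h3, p_star, canonical) {
  structure(
    list(family = family, delta = delta, a_star = a_star,
         c1 = c1, c2 = c2, c3 = c3, h1 = h1, h2 = h2, h3 = h3,
         p_star = p_star, canonical = canonical),
    class = "intervention_spec")
}

#' @export
print.intervention_spec <- function(x, ...) {
  cat("Intervention treatment distribution: ", x$family, sep = "")
  if (!is.na(x$delta)) cat(" (delta = ", format(x$delta), ")", sep = "")
  cat("\n  canonical form available: ", x$canonical, "\n", sep = "")
  invisible(x)
}

stop_not_canonical <- function(spec) {
  if (!isTRUE(spec$canonical))
    stop("the '", spec$family, "' intervention has no canonical ",
         "representation; only IPW and ICE support it", call. = FALSE)
  invisible(spec)
}

#' Evaluate the multiplicative-shift intervention distribution
#'
#' \eqn{q^g(a \mid \cdot) = (1 - \delta) l^* a + (l^* \delta + 1 - l^*)
#' f(a \mid \cdot)}: among subjects with the indication \eqn{l^* = 1} the
#' probability of non-initiation is multiplied by \eqn{\delta}; subjects
#' with \eqn{l^* = 0} keep the observed process.
#'
#' @param f1 observed probability of treatment (`A = 1`) given the
#'   measured past; vectorized.
#' @param lstar indication indicator (0/1); vectorized.
#' @param a treatment level at which to evaluate (0/1); vectorized.
#' @param delta shift in `[0, 1]`.
#' @return probability vector.
#' @export
mult_shift_q <- function(f1, lstar, a, delta) {
  if (!is.numeric(delta) || any(is.na(delta)) || any(delta < 0 | delta > 1))
    stop("multiplicative shift requires delta in [0, 1]", call. = FALSE)
  stopifnot(all(a %in% c(0, 1)), all(lstar %in% c(0, 1)),
            all(f1 >= 0 & f1 <= 1))
  fa <- a * f1 + (1 - a) * (1 - f1)
  (1 - delta) * lstar * a + (lstar * delta + 1 - lstar) * fa
}

#' Evaluate the odds-shift intervention distribution
#'
#' \eqn{q^g(1 \mid \cdot) = \delta f_1 / (\delta f_1 + 1 - f_1)}: the
#' propensity odds are multiplied by \eqn{\delta}.
#'
#' @inheritParams mult_shift_q
#' @param delta shift in `(0, Inf)`.
#' @export
odds_shift_q <- function(f1, a, delta) {
  if (!is.numeric(delta) || any(is.na(delta)) || any(delta <= 0))
    stop("odds shift requires delta > 0", call. = FALSE)
  stopifnot(all(a %in% c(0, 1)), all(f1 >= 0 & f1 <= 1))
  q1 <- delta * f1 / (delta * f1 + (1 - f1))
  a * q1 + (1 - a) * (1 - q1)
}

#' Evaluate an intervention distribution at treatment level `a`
#'
#' Dispatches on the intervention family; canonical families are
#' evaluated through their canonical terms, the odds shift through its
#' closed form.
#'
#' @param spec an [intervention_spec][mult_shift].
#' @param f1 observed probability of treatment given the measured past
#'   (vector over rows of `frame`).
#' @param frame interval frame (see [interval_frame()]) supplying the
#'   history arguments of `h1`, `h2`, `h3`.
#' @param a treatment level (scalar or vector).
#' @return probability vector, one entry per row of `frame`.
#' @export
q_eval <- function(spec, f1, frame, a) {
  stopifnot(inherits(spec, "intervention_spec"))
  n <- length(f1)
  a <- rep_len(a, n)
  if (identical(spec$family, "odds_shift"))
    return(odds_shift_q(f1, a, spec$delta))
  tm <- canonical_terms(spec, frame)
  fa <- a * f1 + (1 - a) * (1 - f1)
  q <- tm$w2 * fa
  if (any(tm$w1 != 0)) q <- q + tm$w1 * (a == tm$a_star)
  if (!is.null(tm$w3)) q <- q + tm$w3 * spec$p_star(frame, a)
  q
}

# Per-row canonical coefficients: w1 = c1*h1, w2 = c2*h2, w3 = c3*h3,
# and the (possibly rule-derived) a_star vector.
canonical_terms <- function(spec, frame) {
  stop_not_canonical(spec)
  n <- nrow(frame)
  w1 <- if (is.null(spec$h1) || spec$c1 == 0) numeric(n) else
    spec$c1 * spec$h1(frame)
  w2 <- if (is.null(spec$h2) || spec$c2 == 0) numeric(n) else
    spec$c2 * spec$h2(frame)
  w3 <- if (is.null(spec$h3) || spec$c3 == 0) NULL else
    spec$c3 * spec$h3(frame)
  a_star <- if (is.function(spec$a_star)) spec$a_star(frame) else
    rep_len(spec$a_star, n)
  list(w1 = w1, w2 = w2, w3 = w3, a_star = a_star)
}

#' Generalized positivity diagnostic
#'
#' The generalized positivity condition requires that any treatment level
#' possible under the intervention be possible in the observed data given
#' the same history.  This report flags at-risk person-intervals where
#' the intervention assigns strictly more probability than the observed
#' process to a treatment level whose estimated observational probability
#' falls below `epsilon` (a near or true violation).  With \eqn{\delta =
#' 1} the intervention coincides with the observed process and no flags
#' can occur.  The check is report-only: nothing is truncated.
#'
#' @param spec an [intervention_spec][mult_shift].
#' @param panel a [panel_data] object.
#' @param fit a treatment-process fit from [fit_treatment()] (or a list
#'   whose element `pi` is a list of per-interval probability vectors
#'   aligned with subjects).
#' @param epsilon positivity threshold (default `1e-3`).
#' @param weights optional list of per-interval cumulative weight vectors
#'   (as from [cumulative_weights()]) to summarize.
#' @return object of class `positivity_report`: per-interval flag counts,
#'   the minimum estimated probability over the intervention's support,
#'   and quantiles of the cumulative weight products when supplied.
#' @export
positivity_check <- function(spec, panel, fit, epsilon = 1e-3,
                             weights = NULL) {
  stopifnot(inherits(panel, "panel_data"))
  pi_list <- if (!is.null(fit$pi)) fit$pi else fit
  J <- panel$J
  flags <- integer(J)
  minf <- rep(NA_real_, J)
  for (j in seq_len(J) - 1L) {
    risk <- which(at_risk(panel, j))
    if (!length(risk)) next
    f1 <- pi_list[[j + 1L]][risk]
    ok <- !is.na(f1)
    risk <- risk[ok]; f1 <- f1[ok]
    if (!length(risk)) next
    frame <- interval_frame(panel, j)[risk, , drop = FALSE]
    fl <- 0L
    fsupp <- numeric(0)
    for (a in c(0, 1)) {
      qa <- q_eval(spec, f1, frame, a)
      fa <- a * f1 + (1 - a) * (1 - f1)
      fl <- fl + sum(qa > fa & fa < epsilon)
      fsupp <- c(fsupp, fa[qa > 0])
    }
    flags[j + 1L] <- fl
    minf[j + 1L] <- if (length(fsupp)) min(fsupp) else NA_real_
  }
  wq <- NULL
  if (!is.null(weights)) {
    wq <- t(vapply(weights, function(w)
      stats::quantile(w[w > 0], c(0, .5, .9, .99, 1), na.rm = TRUE),
      numeric(5)))
    rownames(wq) <- paste0("j=", seq_along(weights) - 1L)
  }
  structure(list(flags = flags, min_f = minf, epsilon = epsilon,
                 weight_quantiles = wq),
            class = "positivity_report")
}

#' @export
print.positivity_report <- function(x, ...) {
  cat("Generalized positivity diagnostic (epsilon = ",
      format(x$epsilon), ")\n", sep = "")
  df <- data.frame(interval = seq_along(x$flags) - 1L,
                   flagged = x$flags, min_f_support = signif(x$min_f, 3))
  print(df, row.names = FALSE)
  if (sum(x$flags) == 0)
    cat("No near-positivity flags.\n")
  if (!is.null(x$weight_quantiles)) {
    cat("Cumulative weight quantiles:\n")
    print(round(x$weight_quantiles, 3))
  }
  invisible(x)
}
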