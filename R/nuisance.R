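#' Fractional logistic regression
#'
#' Solves the weighted logistic score equation
#' \deqn{\sum_i w_i \phi_i \{T_i - \mathrm{expit}(o_i + \theta^\top
#' \phi_i)\} = 0}
#' for responses \eqn{T_i \in [0, 1]} (a quasibinomial logit fit).  This
#' is the regression at the heart of the weighted sequential-regression
#' estimators: the iterated outcome regressions have fractional
#' responses, and the observational weights enter the score directly.
#' Fitting uses iteratively reweighted least squares (Newton steps with
#' step-halving); convergence is declared when the maximum absolute score
#' component, scaled by the total weight, falls below `tol`.
#'
#' @param x design matrix (include an intercept column if wanted).
#' @param y responses in `[0, 1]`.
#' @param weights nonnegative observation weights (default 1).
#' @param offset optional linear-predictor offset.
#' @param tol target tolerance on the max-abs scaled score.
#' @param max_iter maximum IRLS iterations.
#' @param fail_tol hard tolerance: a fit whose final score exceeds this
#'   raises a convergence error (scores between `tol` and `fail_tol`,
#'   as can happen under quasi-separation, are returned with
#'   `converged = FALSE`).
#' @param start optional starting coefficients (warm start).
#' @return list with `coef`, `fitted`, `score` (max-abs scaled score),
#'   `converged`, `iter`.
#' @export
frac_logit <- function(x, y, weights = NULL, offset = NULL,
                       tol = 1e-12, max_iter = 200L, fail_tol = 1e-8,
                       start = NULL) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("negative weights", call. = FALSE)
  if (!any(weights > 0)) stop("all weights are zero", call. = FALSE)
  if (is.null(offset)) offset <- rep(0, n)
  wsum <- sum(weights)

  theta <- if (!is.null(start) && length(start) == p &&
               all(is.finite(start))) as.numeric(start) else numeric(p)
  eta <- offset + if (all(theta == 0)) 0 else drop(x %*% theta)
  score_of <- function(p_hat) crossprod(x, weights * (y - p_hat)) / wsum
  # quasibinomial log-likelihood: concave in theta, so Newton with
  # step-halving on it is globally convergent
  ll_of <- function(p_hat) {
    ph <- pmin(pmax(p_hat, 1e-300), 1 - 1e-16)
    sum(weights * (y * log(ph) + (1 - y) * log1p(-ph)))
  }
  p_hat <- stats::plogis(eta)
  sc <- score_of(p_hat)
  snorm <- max(abs(sc))
  ll <- ll_of(p_hat)
  it <- 0L
  degenerate <- FALSE
  while (snorm > tol && it < max_iter) {
    it <- it + 1L
    wv <- weights * p_hat * (1 - p_hat)
    info <- crossprod(x, x * wv) / wsum
    # always-damped solve: the 1e-10 relative ridge is invisible at the
    # solution but keeps rank-deficient designs (empty cells) solvable
    # while still moving boundary-cell directions that a pseudoinverse
    # would zero out
    lam <- 1e-10 * max(mean(diag(info)), 1e-300)
    diag(info) <- diag(info) + lam
    step <- tryCatch(solve(info, sc),
                     error = function(e) MASS::ginv(info) %*% sc)
    if (any(!is.finite(step))) break
    ok <- FALSE
    lambda <- 1
    for (h in 1:30) {
      th_new <- theta + lambda * drop(step)
      eta_new <- offset + drop(x %*% th_new)
      p_new <- stats::plogis(eta_new)
      ll_new <- ll_of(p_new)
      if (ll_new >= ll) { ok <- TRUE; break }
      lambda <- lambda / 2
    }
    if (!ok) { degenerate <- TRUE; break }
    if (ll_new == ll && lambda < 1) degenerate <- TRUE  # stalled ascent
    theta <- th_new; eta <- eta_new; p_hat <- p_new
    ll <- ll_new
    sc <- score_of(p_hat)
    snorm <- max(abs(sc))
    if (degenerate) break
  }
  conv <- snorm <= tol
  if (!conv && snorm > fail_tol)
    stop("fractional logistic fit did not converge in ", it,
         " iterations (score norm ", format(snorm), ")", call. = FALSE)
  list(coef = theta, fitted = p_hat, score = snorm,
       converged = conv, iter = it)
}

# Global probability clip. Near-degenerate fitted treatment or censoring
# probabilities are stabilized at eps so the q/pi ratios stay finite; the
# number of clipped values is surfaced via a warning and, downstream, the
# estimator diagnostics.
clip_prob <- function(p, eps = 1e-6, warn = TRUE) {
  k <- sum(p < eps | p > 1 - eps, na.rm = TRUE)
  if (k > 0 && warn)
    warning(sprintf("%d prediction(s) clipped to [%g, %g]", k, eps, 1 - eps),
            call. = FALSE)
  pmin(pmax(p, eps), 1 - eps)
}

model_frame_cols <- function(formula, frame) {
  stats::model.matrix(formula,
                      stats::model.frame(formula, frame,
                                         na.action = stats::na.pass))
}

# ---------------------------------------------------------------------------
# Per-interval binary-process fits (treatment and censoring hazards)

fit_interval_binary <- function(panel, response, model, j, rows,
                                exclude = character()) {
  frame <- interval_frame(panel, j)
  y <- response
  if (is_learner_list(model)) {
    vars <- setdiff(names(frame), exclude)
    fit <- cv_stack(model, frame[rows, vars, drop = FALSE], y[rows])
    predict_fun <- function(newframe)
      predict_stack(fit, newframe[, vars, drop = FALSE])
    return(list(kind = "learner", fit = fit, predict = predict_fun))
  }
  mm <- model_frame_cols(model, frame)
  if (length(unique(y[rows])) < 2L) {
    # degenerate (single-class) response: constant hazard
    p0 <- mean(y[rows])
    return(list(kind = "constant", value = p0,
                predict = function(newframe) rep(p0, nrow(newframe))))
  }
  fl <- frac_logit(mm[rows, , drop = FALSE], y[rows])
  predict_fun <- function(newframe) {
    nm <- model_frame_cols(model, newframe)
    stats::plogis(drop(nm %*% fl$coef))
  }
  list(kind = "parametric", fit = fl, predict = predict_fun, formula = model)
}

#' Fit the per-interval treatment process
#'
#' Fits \eqn{\pi_j = f(A_j = 1 \mid Y_j = 1, C_j = 0, \bar{A}_{j-1},
#' \bar{L}_j)} separately at every interval, by logistic regression
#' (formula over the [interval_frame()] columns) or by a cross-validated
#' learner stack.  With `absorbing = TRUE`, treatment is treated as an
#' initiation process: models are fit only among subjects with
#' `A_prev = 0`, and \eqn{\hat\pi_j = 1} deterministically once treatment
#' has been initiated.
#'
#' @param panel a [panel_data] object.
#' @param model a one-sided formula (recycled over intervals), a list of
#'   `J` formulas, or a list of learners (see [lrn_glm()]).
#' @param absorbing is treatment absorbing (once initiated, always 1)?
#' @param eps clipping constant for predicted probabilities.
#' @return object of class `treatment_fit`: per-interval model list and
#'   `pi`, a list of length-`n` vectors of \eqn{\hat\pi_j} (`NA` off the
#'   risk set), plus the count of clipped predictions.
#' @export
fit_treatment <- function(panel, model, absorbing = FALSE, eps = 1e-6) {
  stopifnot(inherits(panel, "panel_data"))
  models <- recycle_model(model, panel$J)
  fits <- vector("list", panel$J)
  pi_list <- vector("list", panel$J)
  clipped <- 0L
  for (j in seq_len(panel$J) - 1L) {
    risk <- at_risk(panel, j)
    a <- panel$A[, j + 1L]
    frame <- interval_frame(panel, j)
    fit_rows <- which(risk & (!absorbing | frame$A_prev == 0))
    p <- rep(NA_real_, panel$n)
    if (length(fit_rows) == 0L) {
      fits[[j + 1L]] <- list(kind = "empty")
    } else {
      if (length(unique(a[fit_rows])) < 2L && !absorbing)
        stop("single-class treatment at interval ", j,
             "; use absorbing = TRUE for initiation designs", call. = FALSE)
      fits[[j + 1L]] <- fit_interval_binary(panel, a, models[[j + 1L]],
                                            j, fit_rows, exclude = "A")
      pr <- which(risk & (!absorbing | frame$A_prev == 0))
      raw <- fits[[j + 1L]]$predict(frame[pr, , drop = FALSE])
      clipped <- clipped + sum(raw < eps | raw > 1 - eps, na.rm = TRUE)
      p[pr] <- clip_prob(raw, eps, warn = FALSE)
    }
    if (absorbing) p[risk & frame$A_prev == 1] <- 1
    pi_list[[j + 1L]] <- p
  }
  if (clipped > 0)
    warning(clipped, " treatment prediction(s) clipped", call. = FALSE)
  structure(list(fits = fits, pi = pi_list, absorbing = absorbing,
                 clipped = clipped),
            class = "treatment_fit")
}

#' Fit the per-interval censoring hazard
#'
#' Fits \eqn{\Pr(C_{j+1} = 1 \mid C_j = 0, Y_j = 1, \bar{A}_j,
#' \bar{L}_j)} at every interval.  The censoring formula may reference
#' the current treatment `A` (treatment precedes censoring in the
#' interval ordering).  If no censoring events occur at an interval the
#' hazard is the degenerate constant fit.
#'
#' @inheritParams fit_treatment
#' @return object of class `censoring_fit` with `hazard`, a list of
#'   length-`n` vectors of fitted hazards (`NA` off the risk set).
#' @export
fit_censoring <- function(panel, model, eps = 1e-6) {
  stopifnot(inherits(panel, "panel_data"))
  models <- recycle_model(model, panel$J)
  fits <- vector("list", panel$J)
  hz <- vector("list", panel$J)
  for (j in seq_len(panel$J) - 1L) {
    risk <- which(at_risk(panel, j))
    cnext <- panel$C[, j + 2L]
    h <- rep(NA_real_, panel$n)
    if (length(risk)) {
      fits[[j + 1L]] <- fit_interval_binary(panel, cnext, models[[j + 1L]],
                                            j, risk)
      frame <- interval_frame(panel, j)
      h[risk] <- fits[[j + 1L]]$predict(frame[risk, , drop = FALSE])
      h[risk] <- pmin(h[risk], 1 - eps)
    }
    hz[[j + 1L]] <- h
  }
  structure(list(fits = fits, hazard = hz), class = "censoring_fit")
}

recycle_model <- function(model, J) {
  if (inherits(model, "formula") || is_learner_list(model))
    return(rep(list(model), J))
  if (is.list(model) && length(model) == J) return(model)
  stop("model must be a formula, a learner list, or a list of J such",
       call. = FALSE)
}

# ---------------------------------------------------------------------------
# Learners and cross-validated stacking

is_learner_list <- function(x)
  is.list(x) && length(x) > 0 && all(vapply(x, inherits, TRUE, "ipsi_learner"))

new_learner <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "ipsi_learner")
}

#' Prediction-algorithm library
#'
#' Candidate learners for the cross-validated stack used to estimate
#' nuisance functions.  Each learner fits a conditional-mean model for a
#' response in `[0, 1]` (binary or fractional) given a data frame of
#' predictors and predicts probabilities on new frames:
#'
#' * `lrn_glm()`: main-effects quasibinomial GLM;
#' * `lrn_glm_interaction()`: quasibinomial GLM with all pairwise
#'   interactions;
#' * `lrn_spline(df)`: additive natural-cubic-spline logit model on
#'   continuous predictors (those with more than 10 distinct values),
#'   linear in the rest;
#' * `lrn_ranger(num.trees)`: random regression forest, predictions
#'   truncated to `[0, 1]`;
#' * `lrn_nnet(size, decay, maxit)`: single-hidden-layer neural network
#'   on standardized inputs with entropy loss;
#' * `lrn_mean()`: the constant (intercept-only) predictor.
#'
#' @return an object of class `ipsi_learner`.
#' @export
lrn_glm <- function() {
  new_learner("glm",
    fit = function(data, y, weights) {
      x <- stats::model.matrix(~ ., data)
      frac_logit(x, y, weights)
    },
    predict = function(object, data)
      stats::plogis(drop(stats::model.matrix(~ ., data) %*% object$coef)))
}

#' @rdname lrn_glm
#' @export
lrn_glm_interaction <- function() {
  new_learner("glm.interaction",
    fit = function(data, y, weights) {
      x <- stats::model.matrix(~ .^2, data)
      frac_logit(x, y, weights)
    },
    predict = function(object, data)
      stats::plogis(drop(stats::model.matrix(~ .^2, data) %*% object$coef)))
}

#' @rdname lrn_glm
#' @param df spline degrees of freedom per continuous predictor.
#' @export
lrn_spline <- function(df = 4L) {
  new_learner("spline",
    fit = function(data, y, weights) {
      smooth <- vapply(data, function(v)
        is.numeric(v) && length(unique(v)) > 10, TRUE)
      rhs <- c(
        if (any(smooth)) paste0("splines::ns(", names(data)[smooth],
                                ", df = ", df, ")"),
        if (any(!smooth)) names(data)[!smooth])
      if (!length(rhs)) rhs <- "1"
      f <- stats::reformulate(rhs)
      mf <- stats::model.frame(f, data)
      mt <- attr(mf, "terms")
      x <- stats::model.matrix(mt, mf)
      list(fl = frac_logit(x, y, weights), terms = mt)
    },
    # terms carry predvars, so spline knots from the fit are reused
    predict = function(object, data) {
      mf <- stats::model.frame(object$terms, data)
      x <- stats::model.matrix(object$terms, mf)
      stats::plogis(drop(x %*% object$fl$coef))
    })
}

#' @rdname lrn_glm
#' @param num.trees number of trees in the forest.
#' @export
lrn_ranger <- function(num.trees = 100L) {
  new_learner("ranger",
    fit = function(data, y, weights) {
      dd <- data; dd$.y <- y
      ranger::ranger(.y ~ ., data = dd, num.trees = num.trees,
                     case.weights = weights, num.threads = 1L,
                     seed = sample.int(.Machine$integer.max, 1L))
    },
    predict = function(object, data)
      pmin(pmax(stats::predict(object, data = data,
                               num.threads = 1L)$predictions, 0), 1))
}

#' @rdname lrn_glm
#' @param size,decay,maxit single-hidden-layer network settings.
#' @export
lrn_nnet <- function(size = 4L, decay = 0.01, maxit = 200L) {
  new_learner("nnet",
    fit = function(data, y, weights) {
      x <- stats::model.matrix(~ . - 1, data)
      xs <- scale(x)
      xs[, attr(xs, "scaled:scale") == 0] <- 0
      m <- nnet::nnet(xs, y, size = size, decay = decay, maxit = maxit,
                      weights = weights, trace = FALSE, entropy = TRUE)
      list(m = m, center = attr(xs, "scaled:center"),
           scale = attr(xs, "scaled:scale"))
    },
    predict = function(object, data) {
      x <- stats::model.matrix(~ . - 1, data)
      xs <- sweep(sweep(x, 2, object$center), 2,
                  pmax(object$scale, 1e-12), "/")
      pmin(pmax(as.numeric(stats::predict(object$m, xs)), 0), 1)
    })
}

#' @rdname lrn_glm
#' @export
lrn_mean <- function() {
  new_learner("mean",
    fit = function(data, y, weights)
      list(mu = stats::weighted.mean(y, weights)),
    predict = function(object, data) rep(object$mu, nrow(data)))
}

#' Default learner library
#'
#' GLM with and without pairwise interactions, an additive spline model,
#' a random forest, and a single-hidden-layer neural network:
#' parametric-rate candidates, a smooth candidate, a tree ensemble and
#' an adaptive nonlinear candidate.
#' @param num.trees trees for the forest candidate.
#' @export
default_learners <- function(num.trees = 100L)
  list(lrn_glm(), lrn_glm_interaction(), lrn_spline(),
       lrn_ranger(num.trees), lrn_nnet())

#' Cross-validated learner stacking
#'
#' Fits every candidate learner, computes out-of-fold predictions on `v`
#' cross-validation folds, and selects the convex combination of
#' candidates minimizing the cross-validated squared error on the
#' probability scale (nonnegative least squares, weights renormalized to
#' sum to one).  `method = "select"` instead picks the single candidate
#' with the lowest cross-validated risk.  Learners that error on a fold
#' are dropped with a warning; if all fail, an error is raised.
#'
#' Fold assignment consumes the R random number stream; seed the stream
#' for reproducibility.
#'
#' @param learners list of learners (see [lrn_glm()]).
#' @param data data frame of predictors.
#' @param y response in `[0, 1]`.
#' @param v number of folds (>= 2).
#' @param weights optional observation weights.
#' @param method `"nnls"` (convex stack) or `"select"` (discrete pick).
#' @return object of class `learner_stack` with fields `weights`,
#'   `cv_risk`, `fits` (full-data refits); predict with
#'   [predict_stack()].
#' @export
cv_stack <- function(learners, data, y, v = 5L, weights = NULL,
                     method = c("nnls", "select")) {
  method <- match.arg(method)
  stopifnot(is_learner_list(learners))
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  k <- length(learners)
  if (k == 1L) {
    fit <- learners[[1]]$fit(data, y, weights)
    return(structure(list(learners = learners, fits = list(fit),
                          weights = 1, cv_risk = NA_real_),
                     class = "learner_stack"))
  }
  if (v < 2L) stop("need at least 2 folds", call. = FALSE)
  folds <- sample(rep_len(seq_len(v), n))
  Z <- matrix(NA_real_, n, k)
  for (f in seq_len(v)) {
    tr <- folds != f; te <- !tr
    for (l in seq_len(k)) {
      Z[te, l] <- tryCatch({
        m <- learners[[l]]$fit(data[tr, , drop = FALSE], y[tr], weights[tr])
        learners[[l]]$predict(m, data[te, , drop = FALSE])
      }, error = function(e) NA_real_)
    }
  }
  alive <- colSums(is.na(Z)) == 0
  if (!any(alive)) stop("all candidate learners failed", call. = FALSE)
  if (!all(alive))
    warning("dropping failed learner(s): ",
            paste(vapply(learners[!alive], `[[`, "", "name"),
                  collapse = ", "), call. = FALSE)
  risks <- colMeans(weights * (Z - y)^2 / mean(weights))
  w <- rep(0, k)
  if (method == "select") {
    w[which.min(replace(risks, !alive, Inf))] <- 1
  } else {
    sw <- sqrt(weights / mean(weights))
    sol <- pracma::lsqnonneg(Z[, alive, drop = FALSE] * sw, y * sw)$x
    if (sum(sol) <= 0) sol[which.min(risks[alive])] <- 1
    w[alive] <- sol / sum(sol)
  }
  fits <- vector("list", k)
  for (l in which(w > 0)) {
    res <- tryCatch(learners[[l]]$fit(data, y, weights),
                    error = function(e) NULL)
    if (is.null(res)) {
      warning("full-data refit of learner '", learners[[l]]$name,
              "' failed; dropped from the stack", call. = FALSE)
      w[l] <- 0
    } else {
      fits[[l]] <- res
    }
  }
  if (sum(w) <= 0) stop("all candidate learners failed", call. = FALSE)
  w <- w / sum(w)
  structure(list(learners = learners, fits = fits, weights = w,
                 cv_risk = risks),
            class = "learner_stack")
}

#' Predict from a fitted learner stack
#' @param object a `learner_stack` from [cv_stack()].
#' @param data data frame of predictors.
#' @return probability vector (convex combination of candidate
#'   predictions, truncated to `[0, 1]`).
#' @export
predict_stack <- function(object, data) {
  stopifnot(inherits(object, "learner_stack"))
  out <- numeric(nrow(data))
  for (l in which(object$weights > 0))
    out <- out + object$weights[l] *
      object$learners[[l]]$predict(object$fits[[l]], data)
  pmin(pmax(out, 0), 1)
}
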