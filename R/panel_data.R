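#' Longitudinal survival panel
#'
#' Container for a longitudinal panel with the variable ordering
#' \eqn{O = (L_j, A_j, C_{j+1}, Y_{j+1})} over treatment intervals
#' \eqn{j = 0, \dots, J-1}.  Survival indicators are monotone
#' non-increasing with \eqn{Y_0 = 1}; censoring indicators are monotone
#' non-decreasing with \eqn{C_0 = 0}; everything after death or censoring
#' is missing and excluded from every downstream fit.  By convention
#' \eqn{A_{-1} = 0}.
#'
#' `data` is long format, one row per subject-interval `j = 0..J-1`.  The
#' outcome column on row `j` stores \eqn{Y_{j+1}} and the censoring
#' column stores \eqn{C_{j+1}} (the indicators realized at the *end* of
#' interval `j`).  Rows after death or censoring may be absent or
#' missing-coded; both are accepted.
#'
#' @param data long-format data frame.
#' @param id,time names of the subject-id and interval columns (`time`
#'   runs 0-based).
#' @param covariates character vector of time-varying covariate columns.
#' @param lstar name of the indication-indicator column \eqn{L^*_j}
#'   (must be among `covariates`).
#' @param treatment,censor,outcome names of the \eqn{A_j}, \eqn{C_{j+1}}
#'   and \eqn{Y_{j+1}} columns.
#' @return object of class `panel_data` with fields `n`, `J`, `A`
#'   (`n x J`), `C` and `Y` (`n x (J+1)`, columns are times `0..J`), `L`
#'   (named list of `n x J` covariate matrices), `lstar`, `id`.
#' @export
panel_data <- function(data, id = "id", time = "time",
                       covariates, lstar = covariates[1],
                       treatment = "A", censor = "C", outcome = "Y") {
  needed <- c(id, time, covariates, treatment, censor, outcome)
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!lstar %in% covariates)
    stop("'lstar' must be one of the covariate columns", call. = FALSE)
  ids <- unique(data[[id]])
  n <- length(ids)
  J <- max(data[[time]]) + 1L
  if (min(data[[time]]) < 0L) stop("negative interval index", call. = FALSE)
  ridx <- match(data[[id]], ids)
  cidx <- data[[time]] + 1L

  put <- function(col, ncol) {
    m <- matrix(NA_real_, n, ncol)
    m[cbind(ridx, cidx)] <- as.numeric(data[[col]])
    m
  }
  A <- put(treatment, J)
  L <- lapply(covariates, put, ncol = J)
  names(L) <- covariates
  # Y_{j+1} on row j -> time columns 1..J of the n x (J+1) matrices.
  Y <- cbind(1, put(outcome, J))
  C <- cbind(0, put(censor, J))

  x <- new_panel(n, J, A, C, Y, L, lstar, ids)
  validate_panel(x)
}

new_panel <- function(n, J, A, C, Y, L, lstar, id) {
  structure(list(n = n, J = J, A = A, C = C, Y = Y, L = L,
                 lstar = lstar, id = id),
            class = "panel_data")
}

# Enforce the monotone death/censoring structure and normalize missing
# coding: after C_k = 1 or Y_k = 0 everything later is NA.
validate_panel <- function(x) {
  n <- x$n; J <- x$J
  for (tcol in 2:(J + 1L)) {
    y_now <- x$Y[, tcol]; y_prev <- x$Y[, tcol - 1L]
    c_now <- x$C[, tcol]; c_prev <- x$C[, tcol - 1L]
    bad <- which(!is.na(y_now) & !is.na(y_prev) & y_now > y_prev)
    if (length(bad))
      stop("non-monotone survival indicator for subject ",
           x$id[bad[1]], " at time ", tcol - 1L, call. = FALSE)
    bad <- which(!is.na(c_now) & !is.na(c_prev) & c_now < c_prev)
    if (length(bad))
      stop("non-monotone censoring indicator for subject ",
           x$id[bad[1]], " at time ", tcol - 1L, call. = FALSE)
    # anyone previously censored stays censored; previously dead stays dead
    x$C[, tcol] <- ifelse(!is.na(c_prev) & c_prev == 1, 1, c_now)
    x$Y[, tcol] <- ifelse(!is.na(y_prev) & y_prev == 0, 0, y_now)
    # once censored, survival is unobserved
    x$Y[!is.na(x$C[, tcol]) & x$C[, tcol] == 1, tcol] <- NA_real_
  }
  # interval data exist only while at risk at j (Y_j = 1, C_j = 0)
  for (j in seq_len(J) - 1L) {
    off <- !at_risk_complete(x, j)
    x$A[off, j + 1L] <- NA_real_
    for (nm in names(x$L)) x$L[[nm]][off, j + 1L] <- NA_real_
  }
  x
}

at_risk_complete <- function(x, j) {
  ok <- !is.na(x$Y[, j + 1L]) & x$Y[, j + 1L] == 1 &
    !is.na(x$C[, j + 1L]) & x$C[, j + 1L] == 0
  ok
}

#' Risk set at interval `j`
#'
#' Subjects alive and uncensored at the start of interval `j`
#' (\eqn{Y_j = 1, C_j = 0}); every model fit downstream is restricted to
#' this set.
#'
#' @param panel a [panel_data] object.
#' @param j interval, `0 <= j <= J-1`.
#' @return logical vector of length `n`.
#' @export
at_risk <- function(panel, j) {
  stopifnot(inherits(panel, "panel_data"))
  if (j < 0 || j > panel$J - 1L)
    stop("interval j out of range [0, ", panel$J - 1L, "]", call. = FALSE)
  at_risk_complete(panel, j)
}

#' Interval design frame
#'
#' Per-interval covariate frame used by model formulas, history functions
#' and learners: for each covariate its value at `j` plus a lag-1 column
#' `<name>_lag` (0 at `j = 0`), the current treatment `A`, and the
#' previous treatment `A_prev` (\eqn{A_{j-1}}, 0 at `j = 0`).  Rows not
#' at risk carry `NA`.
#'
#' @inheritParams at_risk
#' @return data frame with `n` rows.
#' @export
interval_frame <- function(panel, j) {
  stopifnot(inherits(panel, "panel_data"))
  out <- lapply(panel$L, function(m) m[, j + 1L])
  names(out) <- names(panel$L)
  for (nm in names(panel$L))
    out[[paste0(nm, "_lag")]] <-
      if (j == 0L) rep(0, panel$n) else panel$L[[nm]][, j]
  out$A <- panel$A[, j + 1L]
  out$A_prev <- if (j == 0L) rep(0, panel$n) else panel$A[, j]
  out$lstar <- panel$L[[panel$lstar]][, j + 1L]
  out$lstar_lag <- if (j == 0L) rep(0, panel$n) else
    panel$L[[panel$lstar]][, j]
  as.data.frame(out)
}

#' Read / write a longitudinal panel as delimited text
#'
#' `read_panel()` reads a long-format CSV (one row per subject-interval)
#' and validates it into a [panel_data] object; `write_panel()` writes
#' one back, with missing entries blank.  Round-tripping preserves the
#' validity mask.
#'
#' @param path CSV file path.
#' @param schema named list mapping roles to column names: `id`, `time`,
#'   `treatment`, `censor`, `outcome`, `covariates` (character vector)
#'   and `lstar`.
#' @export
read_panel <- function(path, schema) {
  need <- c("id", "time", "treatment", "censor", "outcome",
            "covariates", "lstar")
  miss <- setdiff(need, names(schema))
  if (length(miss))
    stop("schema missing: ", paste(miss, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path)
  panel_data(df, id = schema$id, time = schema$time,
             covariates = schema$covariates, lstar = schema$lstar,
             treatment = schema$treatment, censor = schema$censor,
             outcome = schema$outcome)
}

#' @rdname read_panel
#' @param panel a [panel_data] object.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_data"))
  rows <- lapply(seq_len(panel$J) - 1L, function(j) {
    df <- data.frame(id = panel$id, time = j)
    for (nm in names(panel$L)) df[[nm]] <- panel$L[[nm]][, j + 1L]
    df$A <- panel$A[, j + 1L]
    df$C <- panel$C[, j + 2L]
    df$Y <- panel$Y[, j + 2L]
    df
  })
  long <- do.call(rbind, rows)
  long <- long[order(long$id, long$time), ]
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.panel_data <- function(x, ...) {
  cat("Longitudinal survival panel: n = ", x$n, ", J = ", x$J,
      " treatment intervals\n", sep = "")
  cat("  covariates: ", paste(names(x$L), collapse = ", "),
      " (indication: ", x$lstar, ")\n", sep = "")
  rs <- vapply(seq_len(x$J) - 1L, function(j) sum(at_risk(x, j)), 0L)
  cat("  risk-set sizes: ", paste(rs, collapse = ", "), "\n", sep = "")
  cat("  deaths by end of follow-up: ",
      sum(!is.na(x$Y[, x$J + 1L]) & x$Y[, x$J + 1L] == 0),
      "; censored: ", sum(x$C[, x$J + 1L] == 1, na.rm = TRUE),
      "\n", sep = "")
  invisible(x)
}
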