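#' Fit the quadratic binding isotherm to an MST binding trace
#'
#' Least squares of
#' `signal = S_free + (S_bound - S_free) * fracBound(Kd, Pt, conc)`,
#' sharing the [fracBound()] implementation with the NMR isotherm.
#' Initialization: plateau signals from the low/high-concentration ends,
#' Kd from the geometric mean of the concentration range.  Flat traces
#' (no transition) are flagged `converged = FALSE`.
#'
#' @param trace data.frame `conc_M, signal` (any order).
#' @param Pt labelled-target concentration in molar (default 50e-9).
#' @return list `Kd, signal_free, signal_bound, converged, rss`.
#' @export
fitIsotherm <- function(trace, Pt = 50e-9) {
  stopifnot(nrow(trace) >= 6)
  tr <- trace[order(trace$conc_M), ]
  x <- tr$conc_M; y <- tr$signal
  sf0 <- mean(y[1:2]); sb0 <- mean(y[(length(y) - 1):length(y)])
  kd0 <- exp(mean(log(range(x[x > 0]))))
  fail <- list(Kd = NA_real_, signal_free = NA_real_,
               signal_bound = NA_real_, converged = FALSE, rss = NA_real_)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(sf = sf0, sb = sb0, Kd = kd0),
                       lower = c(-Inf, -Inf, 1e-15),
                       fn = function(p)
                         y - (p[1] + (p[2] - p[1]) * fracBound(p[3], Pt, x)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(fail)
  est <- fit$par
  span <- abs(est["sb"] - est["sf"])
  noise <- sd(fit$fvec)
  conv <- span > 3 * max(noise, 1e-12)
  list(Kd = unname(est["Kd"]), signal_free = unname(est["sf"]),
       signal_bound = unname(est["sb"]), converged = conv,
       rss = sum(fit$fvec^2))
}

#' Fit a four-parameter Hill (logistic) model
#'
#' `y = bottom + (top - bottom) / (1 + (ec50 / x)^n)` with `y(0) = bottom`.
#' The slope sign is free (top may be below bottom).  Initialization:
#' ec50 from the geometric mean of the concentration range, n = 1
#' (bounds 0.2 to 10), plateaus from the trace ends.
#'
#' @param trace data.frame `conc_M, signal`.
#' @return list `ec50, hill_n, top, bottom, converged, rss`.
#' @export
fitHill <- function(trace) {
  stopifnot(nrow(trace) >= 6)
  tr <- trace[order(trace$conc_M), ]
  x <- tr$conc_M; y <- tr$signal
  hill <- function(x, bottom, top, ec50, n)
    ifelse(x <= 0, bottom, bottom + (top - bottom) / (1 + (ec50 / x)^n))
  b0 <- mean(y[1:2]); t0 <- mean(y[(length(y) - 1):length(y)])
  ec0 <- exp(mean(log(range(x[x > 0]))))
  fail <- list(ec50 = NA_real_, hill_n = NA_real_, top = NA_real_,
               bottom = NA_real_, converged = FALSE, rss = NA_real_)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(bottom = b0, top = t0, ec50 = ec0, n = 1),
                       lower = c(-Inf, -Inf, 1e-15, 0.2),
                       upper = c(Inf, Inf, Inf, 10),
                       fn = function(p) y - hill(x, p[1], p[2], p[3], p[4]),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-12, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(fail)
  est <- fit$par
  conv <- abs(est["top"] - est["bottom"]) > 3 * max(sd(fit$fvec), 1e-12)
  list(ec50 = unname(est["ec50"]), hill_n = unname(est["n"]),
       top = unname(est["top"]), bottom = unname(est["bottom"]),
       converged = conv, rss = sum(fit$fvec^2))
}

#' Normalized inhibition curve and IC50 from a dose-response trace
#'
#' Signals are normalized to \[0, 1\] between the no-inhibitor control
#' (-> 1) and the no-chemoattractant control (-> 0); the Hill fit of the
#' normalized curve gives the IC50.
#'
#' @param trace data.frame `conc_M, signal` (e.g. migrated-cell counts).
#' @param controlMax no-inhibitor control signal.
#' @param controlMin no-chemoattractant control signal.
#' @return list `curve` (data.frame conc_M, normalized), `ic50`, `fit`.
#' @export
ic50Report <- function(trace, controlMax, controlMin) {
  if (controlMax == controlMin)
    stop("ic50Report: controls are equal; cannot normalize")
  norm <- (trace$signal - controlMin) / (controlMax - controlMin)
  curve <- data.frame(conc_M = trace$conc_M, normalized = norm)
  fit <- fitHill(data.frame(conc_M = trace$conc_M, signal = norm))
  list(curve = curve, ic50 = fit$ec50, fit = fit)
}

#' Read a concentration/signal trace from CSV (`conc_M,signal`)
#' @param path CSV path.
#' @return data.frame `conc_M, signal`.
#' @export
readTraceCsv <- function(path) {
  df <- read.csv(path)
  if (!all(c("conc_M", "signal") %in% names(df)))
    stop("trace format error: header must be conc_M,signal")
  df
}
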