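#' Bound fraction under the single-site quadratic binding model
#'
#' Exact solution of the 1:1 equilibrium at total concentrations (no
#' free-ligand approximation):
#' fracBound = ((Kd + Lt + Pt) - sqrt((Kd + Lt + Pt)^2 - 4 Pt Lt)) / (2 Pt).
#'
#' @param Kd dissociation constant (molar, > 0).
#' @param Pt total protein concentration (molar, > 0).
#' @param Lt total ligand concentration (molar, >= 0; vectorized).
#' @return bound fraction of the protein, in \[0, 1\].
#' @export
fracBound <- function(Kd, Pt, Lt) {
  if (Kd <= 0 || Pt <= 0) stop("fracBound: Kd and Pt must be > 0")
  if (any(Lt < 0)) stop("fracBound: Lt must be >= 0")
  s <- Kd + Lt + Pt
  disc <- pmax(s^2 - 4 * Pt * Lt, 0)
  (s - sqrt(disc)) / (2 * Pt)
}

#' Observed chemical shift under fast-exchange single-site binding
#'
#' Computes the quadratic-isotherm shift
#' `delta_i = (b - sqrt(b^2 - 4 a c)) / (2 a)` with
#' `a = (Ka / delta_b) Pt`, `b = 1 + Ka (Lt + Pt)`, `c = delta_b Ka Lt`
#' and `Ka = 1 / Kd`; algebraically identical to
#' `delta_b * fracBound(Kd, Pt, Lt)` (the `form = "standard"` route).
#'
#' @param Kd dissociation constant (molar, > 0).
#' @param delta_b shift of the fully bound resonance (ppm, > 0).
#' @param Pt total protein concentration (molar, > 0).
#' @param Lt total ligand concentration (molar, >= 0; vectorized).
#' @param form `"abc"` (quadratic coefficients) or `"standard"`.
#' @return observed shift change delta_i in ppm.
#' @export
modelShift <- function(Kd, delta_b, Pt, Lt, form = c("abc", "standard")) {
  form <- match.arg(form)
  if (Kd <= 0 || delta_b <= 0 || Pt <= 0)
    stop("modelShift: Kd, delta_b and Pt must be > 0")
  if (any(Lt < 0)) stop("modelShift: Lt must be >= 0")
  if (form == "standard") return(delta_b * fracBound(Kd, Pt, Lt))
  Ka <- 1 / Kd
  a <- (Ka / delta_b) * Pt
  b <- 1 + Ka * (Lt + Pt)
  cc <- delta_b * Ka * Lt
  disc <- pmax(b^2 - 4 * a * cc, 0)
  (b - sqrt(disc)) / (2 * a)
}

#' Fit the quadratic isotherm to one residue's CSP titration curve
#'
#' Nonlinear least squares of [modelShift()] against CSP as a function of
#' total ligand concentration, with Kd and delta_b as free parameters.
#' Initialization: Kd0 = median ligand total, delta_b0 = 1.5 x the largest
#' observed CSP.  Bounds: Kd in (0, 1 M], delta_b in (0, 10 ppm].  Fits
#' that fail, do not converge, or end on a bound are flagged
#' `converged = FALSE`.
#'
#' @param series a [TitrationSeries-class].
#' @param residue residue number.
#' @return list `residue, Kd, delta_b, residuals, rss, converged`.
#' @export
fitResidue <- function(series, residue) {
  lt <- series@ligandTotals
  csp <- numeric(0); ltUse <- numeric(0)
  free <- series@peakLists[[1]]
  for (i in seq_along(lt)) {
    pl <- series@peakLists[[i]]
    row <- pl[pl$residue == residue & pl$present, , drop = FALSE]
    f <- free[free$residue == residue & free$present, , drop = FALSE]
    if (nrow(row) == 1 && nrow(f) == 1) {
      ddH <- row$dH - f$dH; ddN <- row$dN - f$dN
      csp <- c(csp, sqrt((ddH^2 + ddN^2 / 25) / 2))
      ltUse <- c(ltUse, lt[i])
    }
  }
  if (length(csp) < 4)
    stop("fitResidue: residue ", residue, " present at fewer than 4 points")
  kd0 <- max(median(lt), 1e-9)
  db0 <- max(1.5 * max(csp), 1e-6)
  fail <- list(residue = residue, Kd = NA_real_, delta_b = NA_real_,
               residuals = rep(NA_real_, length(csp)), rss = NA_real_,
               converged = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(csp ~ modelShift(Kd, db, series@pt, ltUse),
                      start = list(Kd = kd0, db = db0),
                      lower = c(1e-12, 1e-12), upper = c(1, 10),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-10, ptol = 1e-8)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  est <- coef(fit)
  onBound <- est["Kd"] >= 1 * (1 - 1e-6) || est["Kd"] <= 2e-12 ||
             est["db"] >= 10 * (1 - 1e-6) || est["db"] <= 2e-12
  list(residue = residue, Kd = unname(est["Kd"]), delta_b = unname(est["db"]),
       residuals = as.numeric(resid(fit)), rss = sum(resid(fit)^2),
       converged = !onBound)
}

#' Aggregate per-residue Kd fits into a mean +/- SD estimate
#'
#' @param fits list of results from [fitResidue()].
#' @param residues residue numbers to aggregate (must all have converged).
#' @return list `mean_Kd, sd_Kd, residues` (molar).
#' @export
aggregateKd <- function(fits, residues) {
  if (!length(residues)) stop("aggregateKd: empty residue list")
  byRes <- setNames(fits, vapply(fits, `[[`, numeric(1), "residue"))
  kds <- numeric(0)
  for (r in residues) {
    f <- byRes[[as.character(r)]]
    if (is.null(f)) stop("aggregateKd: no fit for residue ", r)
    if (!isTRUE(f$converged))
      stop("aggregateKd: residue ", r, " did not converge")
    kds <- c(kds, f$Kd)
  }
  list(mean_Kd = mean(kds),
       sd_Kd = if (length(kds) > 1) sd(kds) else 0,
       residues = residues)
}

#' Fit every residue of a titration series
#'
#' @param series a [TitrationSeries-class].
#' @param residues residue numbers (default: all residues present at >= 4
#'   points).
#' @return list of [fitResidue()] results.
#' @export
fitAllResidues <- function(series, residues = NULL) {
  if (is.null(residues)) {
    counts <- table(unlist(lapply(series@peakLists, function(pl)
      pl$residue[pl$present])))
    residues <- as.integer(names(counts)[counts >= 4])
  }
  lapply(residues, function(r) fitResidue(series, r))
}

#' Write a per-residue fit report (CSV) and aggregate estimate (JSON)
#'
#' @param fits list of [fitResidue()] results.
#' @param agg result of [aggregateKd()] or NULL.
#' @param csvPath,jsonPath output paths (NULL = skip).
#' @export
writeFitReport <- function(fits, agg = NULL, csvPath = NULL, jsonPath = NULL) {
  if (!is.null(csvPath)) {
    df <- do.call(rbind, lapply(fits, function(f)
      data.frame(residue = f$residue, Kd_M = f$Kd, delta_b_ppm = f$delta_b,
                 converged = f$converged, rss = f$rss)))
    write.csv(df, csvPath, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(jsonPath) && !is.null(agg))
    jsonlite::write_json(agg, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
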