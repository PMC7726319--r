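#' TitrationSeries: HSQC peak lists across a ligand-addition schedule
#'
#' @slot pt total protein concentration in molar.
#' @slot ligandTotals total ligand concentration (molar) per titration
#'   point; the first point is the ligand-free reference (0).
#' @slot peakLists list of peak-list data.frames (`residue, dH, dN,
#'   intensity, present`), one per titration point.
#' @slot truth list of generating parameters when the series is synthetic.
#' @export
setClass("TitrationSeries",
  representation(pt = "numeric", ligandTotals = "numeric",
                 peakLists = "list", truth = "list"),
  prototype(truth = list()))

setValidity("TitrationSeries", function(object) {
  msgs <- character()
  lt <- object@ligandTotals
  if (length(lt)) {
    if (lt[1] != 0) msgs <- c(msgs, "first titration point must be ligand-free (0)")
    if (length(lt) > 1 && any(diff(lt) <= 0))
      msgs <- c(msgs, "ligand totals must be strictly increasing")
  }
  if (length(object@peakLists) != length(lt))
    msgs <- c(msgs, "one peak list per titration point required")
  if (object@pt <= 0) msgs <- c(msgs, "protein concentration must be > 0")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TitrationSeries", function(object) {
  cat("TitrationSeries:", length(object@ligandTotals), "points, Pt =",
      format(object@pt * 1e3), "mM\n")
  cat("  ligand totals (mM):",
      paste(format(object@ligandTotals * 1e3, digits = 3), collapse = ", "), "\n")
})

#' @describeIn TitrationSeries ligand totals accessor (molar)
#' @param x a `TitrationSeries`
#' @export
ligandTotals <- function(x) x@ligandTotals

#' @describeIn TitrationSeries peak list for one titration point
#' @param i point index (1 = free reference)
#' @export
peakList <- function(x, i) x@peakLists[[i]]

#' Read an HSQC peak list from CSV
#'
#' Expected header `residue,dH,dN,intensity`; rows with blank shifts are
#' recorded as absent peaks (`present = FALSE`).
#'
#' @param path CSV path.
#' @return data.frame `residue, dH, dN, intensity, present`.
#' @export
readPeaklist <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(residue = "integer"))
  need <- c("residue", "dH", "dN", "intensity")
  if (!all(need %in% names(df)))
    stop("peak list format error: header must contain ",
         paste(need, collapse = ","))
  if (anyDuplicated(df$residue))
    stop("peak list format error: duplicate residue ",
         df$residue[duplicated(df$residue)][1], " in ", path)
  df$dH <- suppressWarnings(as.numeric(df$dH))
  df$dN <- suppressWarnings(as.numeric(df$dN))
  df$present <- !is.na(df$dH) & !is.na(df$dN)
  df
}

#' Write a peak list as CSV
#' @param pl peak-list data.frame.
#' @param path output path.
#' @export
writePeaklist <- function(pl, path) {
  out <- pl[, c("residue", "dH", "dN", "intensity")]
  out$dH[!pl$present] <- NA
  out$dN[!pl$present] <- NA
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Combined chemical-shift perturbation between two peak lists
#'
#' CSP = sqrt((d_dHN^2 + d_dN^2 / 25) / 2) per residue present in both
#' lists.  Residues present in the free list but absent from the bound
#' list are reported as disappeared (no CSP value); the mean and sample
#' standard deviation are computed over present residues only.
#'
#' @param free reference (ligand-free) peak list.
#' @param bound peak list after ligand addition.
#' @return list `csp` (named numeric, residue -> ppm), `disappeared`
#'   (residue numbers), `mean`, `sd`.
#' @export
computeCsp <- function(free, bound) {
  fr <- free[free$present, ]
  bd <- bound[bound$present, ]
  common <- intersect(fr$residue, bd$residue)
  gone <- setdiff(fr$residue, bd$residue)
  if (!length(common)) stop("computeCsp: no residues shared between lists")
  i <- match(common, fr$residue); j <- match(common, bd$residue)
  ddH <- bd$dH[j] - fr$dH[i]
  ddN <- bd$dN[j] - fr$dN[i]
  csp <- sqrt((ddH^2 + ddN^2 / 25) / 2)
  names(csp) <- common
  list(csp = csp, disappeared = sort(gone),
       mean = mean(csp), sd = if (length(csp) > 1) sd(csp) else 0)
}

#' Residues with CSP above the mean + SD threshold
#'
#' Strictly greater than mean plus one sample standard deviation (n - 1
#' denominator).
#'
#' @param profile result of [computeCsp()].
#' @return integer residue numbers.
#' @export
thresholdResidues <- function(profile) {
  if (length(profile$csp) < 3)
    stop("thresholdResidues: need at least 3 residues with CSP values")
  thr <- profile$mean + profile$sd
  sort(as.integer(names(profile$csp)[profile$csp > thr]))
}

#' CSP profile across a titration series (last point vs free)
#'
#' @param series a [TitrationSeries-class].
#' @param point index of the bound point (default last).
#' @return result of [computeCsp()].
#' @export
seriesCsp <- function(series, point = length(series@ligandTotals)) {
  computeCsp(series@peakLists[[1]], series@peakLists[[point]])
}
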