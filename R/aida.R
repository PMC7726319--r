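#' Antagonist-induced dissociation (AIDA) metrics
#'
#' Tracks, relative to the free labelled-protein reference spectrum (point
#' 1), the fraction of visible peaks and the mean intensity ratio over
#' co-present residues at each competitor-addition point.  The verdict is
#' `"recovery"` when the intensity trajectory dips at an interior point and
#' the final mean ratio exceeds that minimum by at least `margin`
#' (line broadening on complex/competitor mixing followed by signal
#' narrowing on complex dissociation); `"broadening"` when the trajectory
#' ends at least `margin` below its start without recovering; `"none"`
#' otherwise.
#'
#' @param series a [TitrationSeries-class] whose first point is the free
#'   labelled protein.
#' @param margin recovery/broadening margin on the mean intensity ratio
#'   (default 0.2).
#' @return list `trajectory` (data.frame point, ligand_total,
#'   visible_fraction, mean_intensity_ratio) and `verdict`.
#' @export
aidaMetrics <- function(series, margin = 0.2) {
  if (!length(series@peakLists)) stop("aidaMetrics: empty series")
  ref <- series@peakLists[[1]]
  refPresent <- ref$residue[ref$present]
  if (!length(refPresent)) stop("aidaMetrics: reference spectrum has no peaks")
  n <- length(series@peakLists)
  rows <- lapply(seq_len(n), function(i) {
    pl <- series@peakLists[[i]]
    pres <- pl$residue[pl$present]
    co <- intersect(refPresent, pres)
    ratio <- if (length(co)) {
      mean(pl$intensity[match(co, pl$residue)] /
           ref$intensity[match(co, ref$residue)])
    } else 0
    data.frame(point = i, ligand_total = series@ligandTotals[i],
               visible_fraction = length(intersect(refPresent, pres)) /
                 length(refPresent),
               mean_intensity_ratio = ratio)
  })
  traj <- do.call(rbind, rows)
  r <- traj$mean_intensity_ratio[-1]          # competitor-addition points
  verdict <- "none"
  if (length(r) >= 2) {
    imin <- which.min(r)
    if (imin < length(r) && r[length(r)] - r[imin] >= margin)
      verdict <- "recovery"
    else if (r[1] - r[length(r)] >= margin)
      verdict <- "broadening"
  }
  list(trajectory = traj, verdict = verdict)
}
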