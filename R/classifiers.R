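# Whole-protein binary order/disorder classification: CDF curves and
# signed distances from a calibrated boundary, charge-hydropathy (CH)
# coordinates and distances, and joint CH-CDF quadrant calls.

#' Default CDF cutpoint grid
#'
#' Twenty equal cutpoints k/20, k = 1..20.
#'
#' @return Numeric vector of cutpoints in (0, 1].
#' @export
cdfThresholds <- function() seq_len(20L) / 20

#' Cumulative distribution curve of per-residue disorder scores
#'
#' The value at cutpoint t is the fraction of residues with score <= t.
#' Structured proteins (low scores) saturate immediately; fully disordered
#' proteins stay near zero until the top cutpoint.
#'
#' @param scores Per-residue disorder scores for one protein.
#' @param thresholds Strictly increasing cutpoints in (0, 1].
#' @return A [CDFCurve-class].
#' @export
cdfCurve <- function(scores, thresholds = cdfThresholds()) {
  if (length(scores) == 0L) stop("no residues")
  vals <- vapply(thresholds, function(t) mean(scores <= t), numeric(1))
  new("CDFCurve", thresholds = thresholds, values = vals)
}

#' CDF curves for every protein in a profile set
#'
#' @param profiles A [DisorderProfileSet-class].
#' @inheritParams cdfCurve
#' @return Named list of [CDFCurve-class] objects.
#' @export
cdfCurves <- function(profiles, thresholds = cdfThresholds()) {
  lapply(profiles@scores, cdfCurve, thresholds = thresholds)
}

.curveMatrix <- function(curves) {
  vapply(curves, function(cv) cv@values, numeric(length(curves[[1L]]@thresholds)))
}

#' Calibrate the CDF order/disorder boundary
#'
#' Compares the locations of CDF curves for a group of fully ordered and a
#' group of fully disordered calibration proteins: the boundary value at
#' each cutpoint is the midpoint of the two class-mean curves, and the
#' active bins are the cutpoints where the class means differ by more than
#' `separationTol`. The training classification accuracy of the fitted
#' boundary (curves above the boundary on active bins = ordered) is stored
#' on the result.
#'
#' @param orderedCurves,disorderedCurves Non-empty lists of
#'   [CDFCurve-class] objects on a common cutpoint grid.
#' @param separationTol Minimum class-mean separation for a bin to be
#'   active (default 0.02).
#' @return A [CDFBoundary-class].
#' @export
calibrateCDFBoundary <- function(orderedCurves, disorderedCurves,
                                 separationTol = 0.02) {
  if (length(orderedCurves) == 0L || length(disorderedCurves) == 0L)
    stop("need both classes")
  thr <- orderedCurves[[1L]]@thresholds
  all_ <- c(orderedCurves, disorderedCurves)
  same <- vapply(all_, function(cv) {
    length(cv@thresholds) == length(thr) &&
      all(abs(cv@thresholds - thr) < 1e-9)
  }, logical(1))
  if (!all(same)) stop("incompatible grids")
  mo <- rowMeans(.curveMatrix(orderedCurves))
  md <- rowMeans(.curveMatrix(disorderedCurves))
  active <- abs(mo - md) > separationTol
  if (!any(active)) stop("classes inseparable")
  b <- new("CDFBoundary", thresholds = thr, values = (mo + md) / 2,
           activeBins = active, accuracy = NA_real_)
  do <- vapply(orderedCurves, cdfDistance, numeric(1), boundary = b)
  dd <- vapply(disorderedCurves, cdfDistance, numeric(1), boundary = b)
  b@accuracy <- (sum(do >= 0) + sum(dd < 0)) / (length(do) + length(dd))
  validObject(b)
  b
}

#' Signed distance of a CDF curve from the boundary
#'
#' Mean over active bins of (curve value - boundary value). Positive
#' distances are the ordered side (curves above the boundary belong to
#' structured proteins); negative distances the disordered side.
#'
#' @param curve A [CDFCurve-class].
#' @param boundary A [CDFBoundary-class] on the same cutpoint grid.
#' @return Signed numeric distance.
#' @export
cdfDistance <- function(curve, boundary) {
  if (length(curve@thresholds) != length(boundary@thresholds) ||
      any(abs(curve@thresholds - boundary@thresholds) > 1e-9))
    stop("incompatible grids")
  a <- boundary@activeBins
  mean(curve@values[a] - boundary@values[a])
}

#' Charge-hydropathy coordinates of a protein
#'
#' The mean normalized Kyte-Doolittle hydropathy `<H>` (per-residue
#' (KD + 4.5) / 9, averaged over standard residues) and the absolute mean
#' net charge `<R>` (|K + R counts minus D + E counts| / n standard
#' residues; His is treated as neutral at pH 7 and terminal charges are
#' ignored). Ambiguity codes are excluded from both coordinates.
#'
#' @param sequence Character amino acid sequence (or `AAString`).
#' @param hydropathyWindow Optional odd window: when given, `<H>` averages
#'   window-smoothed per-residue hydropathies (edge-truncated) instead of
#'   raw ones; the two differ only through edge effects.
#' @return Named numeric vector `c(mean_hydropathy, mean_net_charge)`,
#'   both in \[0, 1\].
#' @export
chPoint <- function(sequence, hydropathyWindow = NULL) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1L]]
  std <- chars[chars %in% standardResidues()]
  if (length(std) == 0L) stop("no scorable residues")
  kd <- .KYTE_DOOLITTLE[std]
  hraw <- (kd + 4.5) / 9
  h <- if (is.null(hydropathyWindow)) mean(hraw)
       else {
         if (hydropathyWindow %% 2 == 0) stop("window must be odd")
         mean(.runningMean(hraw, as.integer(hydropathyWindow)))
       }
  r <- abs(sum(std %in% c("K", "R")) - sum(std %in% c("D", "E"))) /
    length(std)
  c(mean_hydropathy = unname(h), mean_net_charge = r)
}

#' Default charge-hydropathy boundary coefficients
#'
#' The published linear boundary separating extended disordered from
#' compact proteins in CH space: `<R> = 2.785 <H> - 1.151`.
#'
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
chBoundary <- function() c(slope = 2.785, intercept = -1.151)

#' Signed vertical distance from the CH boundary line
#'
#' `<R> - (slope * <H> + intercept)`. Positive distances lie above the
#' line (predicted extended disordered); negative below (predicted
#' compact/ordered).
#'
#' @param point Output of [chPoint()] (named numeric of length 2).
#' @param slope,intercept Boundary line coefficients; defaults
#'   [chBoundary()].
#' @return Signed numeric distance.
#' @export
chDistance <- function(point, slope = 2.785, intercept = -1.151) {
  unname(point[["mean_net_charge"]] -
           (slope * point[["mean_hydropathy"]] + intercept))
}

#' Joint CH-CDF quadrant classification
#'
#' Combines the CDF distance (positive = ordered) and CH distance
#' (positive = disordered): (CDF<0, CH<0) molten-globule-like (disordered
#' by CDF, compact by CH); (CDF<0, CH>=0) extended disordered (disordered
#' by both); (CDF>=0, CH<0) ordered; (CDF>=0, CH>=0) disordered by CH but
#' ordered by CDF. Zero distances classify via the >= rule.
#'
#' @param cdfDistance,chDistance Signed distances (vectorized).
#' @return Character vector of quadrant labels.
#' @export
classifyCHCDF <- function(cdfDistance, chDistance) {
  ifelse(cdfDistance < 0 & chDistance < 0, "molten_globule_like",
    ifelse(cdfDistance < 0, "extended_disordered",
      ifelse(chDistance < 0, "ordered", "ch_disordered_cdf_ordered")))
}

#' Quadrant labels of the CH-CDF plane
#' @return Character vector of the four labels.
#' @export
chcdfQuadrants <- function() {
  c("ordered", "extended_disordered", "molten_globule_like",
    "ch_disordered_cdf_ordered")
}

#' Classify every protein in a proteome
#'
#' Computes CH coordinates from the sequences, CDF distances from the
#' profiles against a calibrated boundary, and the joint quadrant call.
#'
#' @param proteome A [Proteome-class].
#' @param profiles A matching [DisorderProfileSet-class].
#' @param boundary A [CDFBoundary-class].
#' @param slope,intercept CH boundary line; defaults [chBoundary()].
#' @param hydropathyWindow Passed to [chPoint()].
#' @return `data.frame` with columns `protein_id`, `mean_hydropathy`,
#'   `mean_net_charge`, `ch_distance`, `cdf_distance`, `quadrant`.
#' @export
classifyProteome <- function(proteome, profiles, boundary,
                             slope = 2.785, intercept = -1.151,
                             hydropathyWindow = NULL) {
  stopifnot(is(proteome, "Proteome"), is(profiles, "DisorderProfileSet"))
  ids <- names(profiles@scores)
  seqs <- as.character(proteome@sequences)
  missing <- setdiff(ids, names(seqs))
  if (length(missing) > 0L)
    stop(sprintf("profile '%s' has no sequence in the proteome",
                 missing[1L]))
  pts <- t(vapply(seqs[ids], chPoint, numeric(2),
                  hydropathyWindow = hydropathyWindow))
  chd <- pts[, "mean_net_charge"] -
    (slope * pts[, "mean_hydropathy"] + intercept)
  cdfd <- vapply(ids, function(id) {
    cdfDistance(cdfCurve(profiles@scores[[id]],
                         thresholds = boundary@thresholds), boundary)
  }, numeric(1))
  data.frame(protein_id = ids,
             mean_hydropathy = unname(pts[, "mean_hydropathy"]),
             mean_net_charge = unname(pts[, "mean_net_charge"]),
             ch_distance = unname(chd), cdf_distance = unname(cdfd),
             quadrant = classifyCHCDF(unname(cdfd), unname(chd)),
             stringsAsFactors = FALSE)
}

#' Summarize whole-protein CH-CDF calls
#'
#' Per-quadrant counts (partitioning the input) plus the mean and the
#' root-mean-square deviation about the mean of each signed distance, the
#' summary underlying averaged CH-CDF plots with RMSD error bars.
#'
#' @param calls `data.frame` from [classifyProteome()].
#' @return List with `counts` (named integer over all four quadrants),
#'   `mean_cdf`, `rmsd_cdf`, `mean_ch`, `rmsd_ch`, `n`.
#' @export
chcdfSummary <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) stop("no calls")
  counts <- table(factor(calls$quadrant, levels = chcdfQuadrants()))
  rmsd <- function(x) sqrt(mean((x - mean(x))^2))
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       mean_cdf = mean(calls$cdf_distance),
       rmsd_cdf = rmsd(calls$cdf_distance),
       mean_ch = mean(calls$ch_distance),
       rmsd_ch = rmsd(calls$ch_distance),
       n = nrow(calls))
}

#' Write whole-protein calls as TSV
#'
#' @param calls `data.frame` from [classifyProteome()].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
writeCallsTSV <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
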