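# Per-residue disorder scoring: a propensity-scale predictor with window
# smoothing, an importer for externally computed score tables, and
# threshold calibration against labeled residues.

#' The bundled TOP-IDP disorder propensity scale
#'
#' Per-residue disorder propensities; higher values are more disorder-prone
#' (W most order-promoting at -0.884, P most disorder-promoting at 0.987).
#' This scale drives the bundled propensity predictor and orders residues
#' on the x-axis of composition profiles.
#'
#' @return A [PropensityScale-class].
#' @export
topIDPScale <- function() {
  new("PropensityScale", name = "TOP-IDP", values = .TOP_IDP)
}

# Truncated running mean (no padding; windows shrink at the ends).
.runningMean <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Score a sequence with a propensity scale
#'
#' Per-residue disorder scores in \[0, 1\]: the raw propensity at each
#' position (ambiguity codes receive the scale's mean value) is smoothed by
#' a centered running mean of odd width `window`, truncated at the sequence
#' ends, then min-max rescaled using the scale's extreme values. A
#' homopolymer of the scale's maximum-propensity residue scores 1.0
#' everywhere; the minimum-propensity residue scores 0.0.
#'
#' @param sequence Character amino acid sequence (or `AAString`).
#' @param scale A [PropensityScale-class]; default [topIDPScale()].
#' @param window Odd positive smoothing window (default 21).
#' @return Numeric vector of per-residue scores in \[0, 1\].
#' @export
scoreSequence <- function(sequence, scale = topIDPScale(), window = 21L) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      window %% 2 == 0)
    stop("window must be odd")
  seq <- toupper(as.character(sequence))
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) == 0L) stop("empty sequence")
  v <- scale@values
  raw <- unname(v[chars])
  raw[is.na(raw)] <- mean(v)
  sm <- .runningMean(raw, as.integer(window))
  sc <- (sm - min(v)) / (max(v) - min(v))
  pmin(1, pmax(0, sc))
}

#' Score every protein in a proteome
#'
#' @param proteome A [Proteome-class].
#' @inheritParams scoreSequence
#' @return A [DisorderProfileSet-class] tagged with the scale and window.
#' @export
scoreProteome <- function(proteome, scale = topIDPScale(), window = 21L) {
  stopifnot(is(proteome, "Proteome"))
  seqs <- as.character(proteome@sequences)
  scores <- lapply(seqs, scoreSequence, scale = scale, window = window)
  new("DisorderProfileSet", scores = scores,
      predictor = sprintf("propensity:%s:w%d", scale@name,
                          as.integer(window)))
}

#' Import externally computed per-residue disorder scores
#'
#' Reads a TSV with columns `protein_id`, `position` (1-based), `residue`,
#' `score` (e.g. exported from an external per-residue predictor) and
#' cross-checks it against the proteome: every position of each scored
#' protein must be present exactly once, the residue column must agree with
#' the FASTA sequence, and scores must lie in \[0, 1\].
#'
#' @param path Score TSV with header `protein_id position residue score`.
#' @param proteome A [Proteome-class] the scores refer to.
#' @param predictor Predictor tag recorded on the result.
#' @return A [DisorderProfileSet-class] covering the proteins in the file.
#' @export
loadScores <- function(path, proteome, predictor = "imported") {
  stopifnot(is(proteome, "Proteome"))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "score")
  if (!all(need %in% names(tab)))
    stop("score file must have columns protein_id, position, residue, score")
  if (any(tab$score < 0 | tab$score > 1))
    stop(sprintf("score out of range for protein '%s' at position %d",
                 tab$protein_id[tab$score < 0 | tab$score > 1][1L],
                 tab$position[tab$score < 0 | tab$score > 1][1L]))
  seqs <- as.character(proteome@sequences)
  profiles <- list()
  for (id in unique(tab$protein_id)) {
    if (!id %in% names(seqs))
      stop(sprintf("unknown protein '%s' in score file", id))
    sub <- tab[tab$protein_id == id, , drop = FALSE]
    sub <- sub[order(sub$position), , drop = FALSE]
    len <- nchar(seqs[[id]])
    if (!identical(as.integer(sub$position), seq_len(len)))
      stop(sprintf("incomplete profile for protein '%s'", id))
    expect <- strsplit(seqs[[id]], "", fixed = TRUE)[[1L]]
    bad <- which(toupper(sub$residue) != expect)
    if (length(bad) > 0L)
      stop(sprintf("sequence/score mismatch for protein '%s' at position %d",
                   id, bad[1L]))
    profiles[[id]] <- sub$score
  }
  new("DisorderProfileSet", scores = profiles, predictor = predictor)
}

#' Export per-residue disorder scores
#'
#' Writes the TSV dialect accepted by [loadScores()].
#'
#' @param profiles A [DisorderProfileSet-class].
#' @param proteome The matching [Proteome-class].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
writeScores <- function(profiles, proteome, path) {
  seqs <- as.character(proteome@sequences)
  rows <- lapply(names(profiles@scores), function(id) {
    s <- profiles@scores[[id]]
    data.frame(protein_id = id, position = seq_along(s),
               residue = strsplit(seqs[[id]], "", fixed = TRUE)[[1L]],
               score = s, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Calibrate the binary decision threshold on labeled residues
#'
#' Grid search (step 0.01 over \[0, 1\]) for the threshold maximizing
#' balanced per-residue accuracy (mean of sensitivity on disordered and
#' specificity on ordered residues), where a residue is called disordered
#' iff score >= threshold. Ties are broken deterministically at the
#' midpoint of the optimal interval (tLow, tHigh], with tLow the grid point
#' just below the smallest optimal threshold, snapped back to the grid.
#' With no labeled data the conventional default 0.5 is returned.
#'
#' @param profiles A [DisorderProfileSet-class] or list of numeric score
#'   vectors; may be missing for the data-free default.
#' @param truth Matching list of logical vectors (`TRUE` = disordered).
#' @param step Grid step (default 0.01).
#' @return The threshold, with the achieved balanced accuracy in
#'   `attr(, "balanced_accuracy")`.
#' @export
calibrateThreshold <- function(profiles = NULL, truth = NULL, step = 0.01) {
  if (is.null(profiles) || is.null(truth) ||
      length(truth) == 0L)
    return(structure(0.5, balanced_accuracy = NA_real_))
  scores <- if (is(profiles, "DisorderProfileSet")) profiles@scores
            else profiles
  ids <- names(scores)
  if (!is.null(ids) && !is.null(names(truth))) truth <- truth[ids]
  s <- unlist(scores, use.names = FALSE)
  y <- unlist(truth, use.names = FALSE)
  if (length(s) != length(y))
    stop("profiles and truth labels must align residue-by-residue")
  if (all(y) || all(!y)) stop("cannot calibrate: only one class present")
  grid <- seq(0, 1, by = step)
  sd_ <- s[y]; so <- s[!y]
  ba <- vapply(grid, function(t) {
    (mean(sd_ >= t) + mean(so < t)) / 2
  }, numeric(1))
  best <- max(ba)
  opt <- grid[ba >= best - 1e-12]
  lo <- min(opt) - step
  mid <- (lo + max(opt)) / 2
  thr <- round(mid / step) * step
  structure(thr, balanced_accuracy = best)
}
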