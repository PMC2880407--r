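# Proteome-level disorder content measures: fraction of disordered
# residues (IDAA), fraction of proteins with long disordered regions
# (IDP>30aa), fraction of wholly disordered proteins (WIDP), and
# per-domain disorder statistics.

.coerceProfiles <- function(profiles) {
  if (is(profiles, "DisorderProfileSet")) return(profiles@scores)
  if (is.numeric(profiles)) return(list(profiles))
  if (is.list(profiles)) return(profiles)
  stop("profiles must be a DisorderProfileSet or list of score vectors")
}

#' Binarize per-residue disorder scores
#'
#' A residue is called disordered iff its score is greater than or equal to
#' the threshold (the tie at the threshold goes to disordered, so
#' thresholds behave as infima of the disordered score range).
#'
#' @param scores Numeric vector of per-residue scores.
#' @param threshold Decision threshold in \[0, 1\] (default 0.5).
#' @return Logical vector, `TRUE` = disordered.
#' @export
binarize <- function(scores, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1)
    stop("threshold must lie in [0, 1]")
  scores >= threshold
}

#' Extract maximal disordered segments from per-residue labels
#'
#' Returns every maximal run of disordered labels as one segment in
#' 1-based inclusive coordinates, unfiltered by length.
#'
#' @param labels Logical vector (`TRUE` = disordered) or character vector
#'   of "D"/"O" labels.
#' @param proteinId Protein id recorded on the segments.
#' @return `data.frame` with columns `protein_id`, `start`, `end`,
#'   `length`; zero rows when no residue is disordered.
#' @export
extractSegments <- function(labels, proteinId = "protein") {
  if (is.character(labels)) labels <- toupper(labels) == "D"
  if (!is.logical(labels) || length(labels) == 0L)
    stop("labels must be a non-empty logical (or D/O character) vector")
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(protein_id = rep(proteinId, sum(keep)),
             start = starts[keep], end = ends[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

#' Fraction of disordered residues (IDAA)
#'
#' Residue-pooled over the whole collection: total disordered residues
#' divided by total residues. An alternative protein-averaged variant
#' (mean of per-protein fractions) is available via `perProtein = TRUE`.
#'
#' @param profiles A [DisorderProfileSet-class] or list of score vectors.
#' @param threshold Decision threshold (default 0.5).
#' @param perProtein If `TRUE`, average per-protein disordered fractions
#'   instead of pooling residues.
#' @return Fraction in \[0, 1\].
#' @export
idaa <- function(profiles, threshold = 0.5, perProtein = FALSE) {
  scores <- .coerceProfiles(profiles)
  if (length(scores) == 0L) stop("no profiles")
  if (perProtein)
    return(mean(vapply(scores, function(s) mean(binarize(s, threshold)),
                       numeric(1))))
  pooled <- unlist(scores, use.names = FALSE)
  mean(binarize(pooled, threshold))
}

#' Fraction of proteins with a long disordered region
#'
#' A protein qualifies when it has at least one maximal disordered run of
#' length strictly greater than `minRun` consecutive residues (>30 at the
#' default, i.e. runs of 31 or more).
#'
#' @inheritParams idaa
#' @param minRun Run-length cutoff; "long" means strictly longer than this.
#' @return Fraction in \[0, 1\].
#' @export
fractionLongIDR <- function(profiles, threshold = 0.5, minRun = 30L) {
  if (!is.numeric(minRun) || minRun < 1) stop("minRun must be >= 1")
  scores <- .coerceProfiles(profiles)
  if (length(scores) == 0L) stop("no profiles")
  has <- vapply(scores, function(s) {
    r <- rle(binarize(s, threshold))
    any(r$values & r$lengths > minRun)
  }, logical(1))
  mean(has)
}

#' Fraction of wholly disordered proteins (WIDP)
#'
#' The fraction of proteins on the disordered side of the whole-protein
#' CDF classifier, i.e. with signed CDF-distance strictly below zero
#' (positive distances are the ordered side; a distance of exactly zero
#' counts as ordered).
#'
#' @param cdfDistances Numeric vector of signed CDF distances, one per
#'   protein (see [cdfDistance()]).
#' @return Fraction in \[0, 1\].
#' @export
fractionWhollyDisordered <- function(cdfDistances) {
  if (length(cdfDistances) == 0L) stop("no classifications")
  mean(cdfDistances < 0)
}

#' Disorder statistics for a protein domain
#'
#' Percent of disordered residues (one decimal) and the maximal disordered
#' regions (of any length) within one domain-covering profile.
#'
#' @param scores Per-residue scores covering the full domain.
#' @param threshold Decision threshold (default 0.5).
#' @param domainId Identifier recorded on the result.
#' @return List with `domain_id`, `percent_disordered`, `n_regions`,
#'   `region_lengths`.
#' @export
domainDisorderStats <- function(scores, threshold = 0.5,
                                domainId = "domain") {
  labels <- binarize(scores, threshold)
  segs <- extractSegments(labels, proteinId = domainId)
  list(domain_id = domainId,
       percent_disordered = round(100 * mean(labels), 1),
       n_regions = nrow(segs),
       region_lengths = segs$length)
}

#' Proteome disorder measures for one species
#'
#' Bundles the three proteome-level disorder content measures: IDAA
#' (residue-pooled fraction of disordered residues), IDP>30aa (fraction of
#' proteins with a long disordered region), and WIDP (fraction of wholly
#' disordered proteins by CDF distance).
#'
#' @param speciesId Species identifier.
#' @param profiles A [DisorderProfileSet-class].
#' @param cdfDistances Signed CDF distances, one per protein.
#' @param threshold Decision threshold (default 0.5).
#' @param minRun Long-region cutoff (default 30).
#' @return One-row `data.frame` with columns `species_id`, `idaa`,
#'   `idp30`, `widp`.
#' @export
speciesDisorderMeasures <- function(speciesId, profiles, cdfDistances,
                                    threshold = 0.5, minRun = 30L) {
  data.frame(species_id = speciesId,
             idaa = idaa(profiles, threshold),
             idp30 = fractionLongIDR(profiles, threshold, minRun),
             widp = fractionWhollyDisordered(cdfDistances),
             stringsAsFactors = FALSE)
}

#' Export disordered segments as BED
#'
#' 0-based half-open intervals; `name` is the protein id and `score` the
#' mean per-residue disorder score over the segment when profiles are
#' supplied (0 otherwise).
#'
#' @param segments `data.frame` from [extractSegments()] (1-based
#'   inclusive), possibly row-bound over proteins.
#' @param path Output BED file.
#' @param profiles Optional [DisorderProfileSet-class] for segment scores.
#' @return Invisibly, `path`.
#' @export
writeSegmentsBED <- function(segments, path, profiles = NULL) {
  score <- rep(0, nrow(segments))
  if (!is.null(profiles)) {
    sc <- .coerceProfiles(profiles)
    score <- vapply(seq_len(nrow(segments)), function(i) {
      s <- sc[[segments$protein_id[i]]]
      mean(s[segments$start[i]:segments$end[i]])
    }, numeric(1))
  }
  bed <- data.frame(chrom = segments$protein_id,
                    start = segments$start - 1L, end = segments$end,
                    name = segments$protein_id,
                    score = round(score, 4))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
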