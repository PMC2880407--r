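#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' PropensityScale: a per-residue disorder propensity scale
#'
#' Maps each of the 20 standard amino acids to a real-valued disorder
#' propensity (higher values = more disorder-prone). The bundled default is
#' the TOP-IDP scale, see [topIDPScale()].
#'
#' @slot name Scale name.
#' @slot values Named numeric vector over the 20 standard residues.
#' @export
setClass("PropensityScale",
  representation(name = "character", values = "numeric"))

setValidity("PropensityScale", function(object) {
  v <- object@values
  missing <- setdiff(standardResidues(), names(v))
  if (length(missing) > 0)
    return(paste("missing residues:", paste(missing, collapse = ", ")))
  if (anyNA(v)) return("propensities must not be NA")
  if (max(v) <= min(v)) return("scale must have max value > min value")
  TRUE
})

#' Proteome: an identified collection of protein sequences
#'
#' Wraps a [Biostrings::AAStringSet] (names = protein ids, with per-record
#' metadata columns `description` and `n_ambiguous` in `mcols()`) together
#' with a species identifier and optional taxonomy labels.
#'
#' @slot speciesId Species identifier.
#' @slot sequences `AAStringSet` of upper-case amino acid sequences.
#' @slot taxonomy Named character vector of taxonomy labels
#'   (e.g. `c(phylum = ..., class = ...)`), possibly empty.
#' @export
setClass("Proteome",
  representation(speciesId = "character", sequences = "AAStringSet",
                 taxonomy = "character"))

setValidity("Proteome", function(object) {
  if (length(object@speciesId) != 1L || is.na(object@speciesId))
    return("speciesId must be a single string")
  if (length(object@sequences) == 0L) return("proteome must be non-empty")
  ids <- names(object@sequences)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids)))
    return("all records must be named")
  if (anyDuplicated(ids))
    return(sprintf("duplicate identifier '%s'", ids[duplicated(ids)][1L]))
  if (any(Biostrings::width(object@sequences) < 1L))
    return("all sequences must have length >= 1")
  TRUE
})

#' DisorderProfileSet: per-residue disorder scores for a set of proteins
#'
#' One numeric score vector in \[0, 1\] per protein, aligned to the protein
#' sequence (element i scores residue i), plus a tag naming the predictor
#' that produced the scores.
#'
#' @slot scores Named list of numeric vectors, each in \[0, 1\].
#' @slot predictor Predictor tag (e.g. `"propensity:TOP-IDP:w21"` or
#'   `"imported"`).
#' @export
setClass("DisorderProfileSet",
  representation(scores = "list", predictor = "character"))

setValidity("DisorderProfileSet", function(object) {
  s <- object@scores
  if (length(s) == 0L) return("no profiles")
  if (is.null(names(s)) || anyDuplicated(names(s)))
    return("profiles must be uniquely named by protein id")
  ok <- vapply(s, function(x) {
    is.numeric(x) && length(x) >= 1L && !anyNA(x) &&
      all(x >= 0) && all(x <= 1)
  }, logical(1))
  if (!all(ok))
    return(sprintf("profile '%s' has scores outside [0, 1]",
                   names(s)[!ok][1L]))
  if (length(object@predictor) != 1L)
    return("predictor must be a single string")
  TRUE
})

#' CDFCurve: cumulative distribution of per-residue disorder scores
#'
#' The value at cutpoint t is the fraction of the protein's residues with
#' disorder score <= t. Structured proteins saturate early (curve high at
#' low cutpoints); disordered proteins stay low until high cutpoints.
#'
#' @slot thresholds Strictly increasing cutpoints in (0, 1].
#' @slot values Cumulative fractions, non-decreasing, ending at 1.
#' @export
setClass("CDFCurve",
  representation(thresholds = "numeric", values = "numeric"))

setValidity("CDFCurve", function(object) {
  t <- object@thresholds; v <- object@values
  if (length(t) != length(v)) return("thresholds/values length mismatch")
  if (length(t) < 1L) return("empty curve")
  if (any(diff(t) <= 0)) return("thresholds must be strictly increasing")
  if (t[1L] <= 0 || t[length(t)] > 1)
    return("thresholds must lie in (0, 1]")
  if (any(v < -1e-12) || any(v > 1 + 1e-12)) return("values must lie in [0, 1]")
  if (any(diff(v) < -1e-12)) return("values must be non-decreasing")
  TRUE
})

#' CDFBoundary: calibrated order/disorder boundary in CDF space
#'
#' Midpoint boundary between the class-mean CDF curves of fully ordered and
#' fully disordered calibration proteins, with the subset of cutpoints
#' (active bins) where the classes actually separate and the training
#' classification accuracy of the fitted boundary.
#'
#' @slot thresholds Cutpoint grid shared with the curves.
#' @slot values Boundary values per cutpoint, in \[0, 1\].
#' @slot activeBins Logical; cutpoints used by [cdfDistance()].
#' @slot accuracy Training accuracy of the fitted boundary.
#' @export
setClass("CDFBoundary",
  representation(thresholds = "numeric", values = "numeric",
                 activeBins = "logical", accuracy = "numeric"))

setValidity("CDFBoundary", function(object) {
  n <- length(object@thresholds)
  if (length(object@values) != n || length(object@activeBins) != n)
    return("thresholds, values and activeBins must have equal length")
  if (any(object@values < 0) || any(object@values > 1))
    return("boundary values must lie in [0, 1]")
  if (!any(object@activeBins)) return("at least one active bin required")
  TRUE
})

#' CompositionVector: amino acid composition over the 20 standard residues
#'
#' Residue counts pooled over a sequence set, with frequencies normalized
#' to sum 1. Ambiguity codes are excluded from both numerator and
#' denominator, so frequencies live on the 20-residue simplex.
#'
#' @slot counts Named non-negative numeric vector over the 20 residues.
#' @slot frequencies Counts normalized to sum 1.
#' @export
setClass("CompositionVector",
  representation(counts = "numeric", frequencies = "numeric"))

setValidity("CompositionVector", function(object) {
  res <- standardResidues()
  if (!identical(names(object@counts), res) ||
      !identical(names(object@frequencies), res))
    return("counts and frequencies must be named by the 20 standard residues")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (sum(object@counts) > 0 &&
      abs(sum(object@frequencies) - 1) > 1e-12)
    return("frequencies must sum to 1")
  TRUE
})

#' GroundTruth: generator-emitted true disorder architecture
#'
#' Per-protein true per-residue state labels (`TRUE` = disordered) and the
#' corresponding true maximal disordered segments, as emitted by the
#' synthetic proteome generator.
#'
#' @slot speciesId Species identifier.
#' @slot labels Named list of logical vectors, one per protein.
#' @slot segments `data.frame` with columns `protein_id`, `start`, `end`,
#'   `length` (1-based inclusive coordinates).
#' @export
setClass("GroundTruth",
  representation(speciesId = "character", labels = "list",
                 segments = "data.frame"))

setValidity("GroundTruth", function(object) {
  if (length(object@labels) == 0L) return("no labels")
  if (is.null(names(object@labels)) || anyDuplicated(names(object@labels)))
    return("labels must be uniquely named by protein id")
  if (!all(vapply(object@labels, is.logical, logical(1))))
    return("labels must be logical vectors")
  need <- c("protein_id", "start", "end", "length")
  if (!all(need %in% names(object@segments)))
    return("segments must have protein_id/start/end/length columns")
  TRUE
})
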