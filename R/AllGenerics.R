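# Accessor generics and show methods.

#' @rdname Proteome-class
#' @param object,x A `Proteome`.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname Proteome-class
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' @rdname Proteome-class
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname Proteome-class
#' @export
setGeneric("proteinLengths", function(x) standardGeneric("proteinLengths"))

#' @rdname Proteome-class
#' @export
setGeneric("sequenceSet", function(x) standardGeneric("sequenceSet"))

#' @rdname DisorderProfileSet-class
#' @param x A `DisorderProfileSet`.
#' @export
setGeneric("profileScores", function(x) standardGeneric("profileScores"))

#' @rdname DisorderProfileSet-class
#' @export
setGeneric("predictorTag", function(x) standardGeneric("predictorTag"))

#' @rdname PropensityScale-class
#' @param x A `PropensityScale`.
#' @export
setGeneric("scaleName", function(x) standardGeneric("scaleName"))

#' @rdname PropensityScale-class
#' @export
setGeneric("scaleValues", function(x) standardGeneric("scaleValues"))

#' @rdname CompositionVector-class
#' @param x A `CompositionVector`.
#' @export
setGeneric("aaCounts", function(x) standardGeneric("aaCounts"))

#' @rdname CompositionVector-class
#' @export
setGeneric("aaFrequencies", function(x) standardGeneric("aaFrequencies"))

#' @rdname GroundTruth-class
#' @param x A `GroundTruth`.
#' @export
setGeneric("trueLabels", function(x) standardGeneric("trueLabels"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueSegments", function(x) standardGeneric("trueSegments"))

#' @rdname GroundTruth-class
#' @export
setGeneric("trueDisorderFraction",
  function(x) standardGeneric("trueDisorderFraction"))

## ---- Proteome ----

#' @rdname Proteome-class
#' @export
setMethod("speciesId", "Proteome", function(x) x@speciesId)

#' @rdname Proteome-class
#' @export
setMethod("proteinIds", "Proteome", function(x) names(x@sequences))

#' @rdname Proteome-class
#' @export
setMethod("nProteins", "Proteome", function(x) length(x@sequences))

#' @rdname Proteome-class
#' @export
setMethod("proteinLengths", "Proteome", function(x) {
  stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

#' @rdname Proteome-class
#' @export
setMethod("sequenceSet", "Proteome", function(x) x@sequences)

setMethod("show", "Proteome", function(object) {
  w <- Biostrings::width(object@sequences)
  cat(sprintf("Proteome '%s': %d proteins, lengths %d-%d (mean %.1f)\n",
              object@speciesId, length(object@sequences),
              min(w), max(w), mean(w)))
  if (length(object@taxonomy) > 0)
    cat("  taxonomy:", paste(names(object@taxonomy), object@taxonomy,
                             sep = "=", collapse = "; "), "\n")
})

## ---- DisorderProfileSet ----

#' @rdname DisorderProfileSet-class
#' @export
setMethod("profileScores", "DisorderProfileSet", function(x) x@scores)

#' @rdname DisorderProfileSet-class
#' @export
setMethod("predictorTag", "DisorderProfileSet", function(x) x@predictor)

setMethod("show", "DisorderProfileSet", function(object) {
  n <- sum(lengths(object@scores))
  cat(sprintf("DisorderProfileSet: %d proteins, %d residues, predictor '%s'\n",
              length(object@scores), n, object@predictor))
})

## ---- PropensityScale ----

#' @rdname PropensityScale-class
#' @export
setMethod("scaleName", "PropensityScale", function(x) x@name)

#' @rdname PropensityScale-class
#' @export
setMethod("scaleValues", "PropensityScale", function(x) x@values)

setMethod("show", "PropensityScale", function(object) {
  cat(sprintf("PropensityScale '%s' (range %.3f to %.3f)\n",
              object@name, min(object@values), max(object@values)))
})

## ---- CompositionVector ----

#' @rdname CompositionVector-class
#' @export
setMethod("aaCounts", "CompositionVector", function(x) x@counts)

#' @rdname CompositionVector-class
#' @export
setMethod("aaFrequencies", "CompositionVector", function(x) x@frequencies)

setMethod("show", "CompositionVector", function(object) {
  cat(sprintf("CompositionVector: %.0f residues\n", sum(object@counts)))
  print(round(object@frequencies, 4))
})

## ---- CDF classes ----

setMethod("show", "CDFCurve", function(object) {
  cat(sprintf("CDFCurve over %d cutpoints in [%.2f, %.2f]\n",
              length(object@thresholds), object@thresholds[1L],
              object@thresholds[length(object@thresholds)]))
})

setMethod("show", "CDFBoundary", function(object) {
  cat(sprintf(
    "CDFBoundary: %d cutpoints, %d active bins, training accuracy %.3f\n",
    length(object@thresholds), sum(object@activeBins), object@accuracy))
})

## ---- GroundTruth ----

#' @rdname GroundTruth-class
#' @export
setMethod("trueLabels", "GroundTruth", function(x) x@labels)

#' @rdname GroundTruth-class
#' @export
setMethod("trueSegments", "GroundTruth", function(x) x@segments)

#' @rdname GroundTruth-class
#' @export
setMethod("trueDisorderFraction", "GroundTruth", function(x) {
  lab <- unlist(x@labels, use.names = FALSE)
  sum(lab) / length(lab)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth '%s': %d proteins, true disordered fraction %.3f\n",
    object@speciesId, length(object@labels),
    trueDisorderFraction(object)))
})
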