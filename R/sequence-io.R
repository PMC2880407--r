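# Proteome FASTA input/output and descriptive statistics.

.validResidues <- function(tolerateAmbiguity = TRUE) {
  if (tolerateAmbiguity) c(standardResidues(), ambiguityCodes())
  else standardResidues()
}

# Locate the first character of `seq` outside `allowed`; 0 if none.
.firstInvalidPosition <- function(seq, allowed) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% allowed))
  if (length(bad) == 0L) 0L else bad[1L]
}

#' Construct a Proteome from character sequences
#'
#' Programmatic constructor used by the FASTA reader and the synthetic
#' proteome generator. Sequences are upper-cased and validated against the
#' 20 standard residues plus (optionally) the tolerated ambiguity codes.
#'
#' @param sequences Named character vector of amino acid sequences.
#' @param speciesId Species identifier.
#' @param descriptions Optional character vector of record descriptions.
#' @param taxonomy Optional named character vector of taxonomy labels.
#' @param tolerateAmbiguity Accept ambiguity codes X, B, Z, U, O?
#' @return A [Proteome-class] object.
#' @examples
#' p <- Proteome(c(A = "MKV", B = "EEE"), speciesId = "toy")
#' nProteins(p)
#' @export
Proteome <- function(sequences, speciesId = "proteome",
                     descriptions = NULL, taxonomy = character(),
                     tolerateAmbiguity = TRUE) {
  if (length(sequences) == 0L) stop("no records")
  ids <- names(sequences)
  if (is.null(ids) || any(!nzchar(ids))) stop("all records must be named")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop(sprintf("duplicate identifier '%s'", dup[1L]))
  seqs <- toupper(gsub("[ \t\r\n]", "", sequences))
  allowed <- .validResidues(tolerateAmbiguity)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) < 1L)
      stop(sprintf("record '%s' has an empty sequence", ids[i]))
    pos <- .firstInvalidPosition(seqs[i], allowed)
    if (pos > 0L)
      stop(sprintf("invalid residue '%s' in record '%s' at position %d",
                   substr(seqs[i], pos, pos), ids[i], pos))
  }
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- ids
  nAmb <- vapply(seqs, function(s) {
    sum(strsplit(s, "", fixed = TRUE)[[1L]] %in% ambiguityCodes())
  }, integer(1), USE.NAMES = FALSE)
  if (is.null(descriptions)) descriptions <- rep("", length(seqs))
  S4Vectors::mcols(aa) <- S4Vectors::DataFrame(
    description = descriptions, n_ambiguous = nAmb)
  new("Proteome", speciesId = speciesId, sequences = aa,
      taxonomy = taxonomy)
}

#' Read a proteome from a FASTA file
#'
#' Records are upper-cased, line wrapping and whitespace are removed, and
#' the record id is the first whitespace-delimited header token (the
#' remainder of the header is kept as the record description). Each record
#' is validated against the standard amino acid alphabet; positions with
#' ambiguity codes are counted per record in `mcols(sequenceSet(x))`.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param speciesId Species identifier; defaults to the file base name.
#' @param tolerateAmbiguity Accept ambiguity codes X, B, Z, U, O? If
#'   `FALSE`, any non-standard residue is an error naming the record and
#'   position.
#' @param taxonomy Optional named character vector of taxonomy labels.
#' @return A [Proteome-class] object.
#' @export
readProteome <- function(path, speciesId = NULL, tolerateAmbiguity = TRUE,
                         taxonomy = character()) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  aa <- withCallingHandlers(
    tryCatch(Biostrings::readAAStringSet(path),
             error = function(e) stop("no records", call. = FALSE)),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("invalid residue: non-amino-acid characters in FASTA input",
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (length(aa) == 0L) stop("no records")
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (is.null(speciesId))
    speciesId <- sub("\\.[^.]*$", "", basename(path))
  Proteome(stats::setNames(as.character(aa), ids), speciesId = speciesId,
           descriptions = desc, taxonomy = taxonomy,
           tolerateAmbiguity = tolerateAmbiguity)
}

#' Write a proteome to a FASTA file
#'
#' Headers are `id description` (description omitted when empty), so that
#' a read/write round trip reproduces ids and sequences byte-identically
#' modulo line wrapping.
#'
#' @param x A [Proteome-class].
#' @param path Output file.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
writeProteome <- function(x, path, width = 60L) {
  stopifnot(is(x, "Proteome"))
  aa <- x@sequences
  desc <- S4Vectors::mcols(aa)$description
  out <- aa
  names(out) <- ifelse(nzchar(desc), paste(names(aa), desc), names(aa))
  Biostrings::writeXStringSet(out, filepath = path, width = width)
  invisible(path)
}

#' Summarize a proteome
#'
#' Protein count and length statistics for a proteome, the per-species
#' descriptive numbers of a proteome-size survey.
#'
#' @param x A [Proteome-class].
#' @param digits Decimal places for the mean length.
#' @return One-row `data.frame` with columns `species_id`, `n_proteins`,
#'   `min_length`, `mean_length`, `max_length`.
#' @export
proteomeSummary <- function(x, digits = 2L) {
  stopifnot(is(x, "Proteome"))
  w <- Biostrings::width(x@sequences)
  data.frame(species_id = x@speciesId, n_proteins = length(w),
             min_length = min(w), mean_length = round(mean(w), digits),
             max_length = max(w), stringsAsFactors = FALSE)
}

#' Default protein length histogram bins
#'
#' 50-residue bins from 0 to 1500 plus an overflow bin.
#'
#' @return Numeric vector of bin edges.
#' @export
defaultLengthBins <- function() c(seq(0, 1500, by = 50), Inf)

#' Protein length distribution
#'
#' Fraction of proteins per half-open length bin \[low, high). A length
#' exactly at an edge belongs to the bin starting at that edge.
#'
#' @param x A [Proteome-class] or numeric vector of lengths.
#' @param binEdges Strictly increasing bin edges (>= 2 values). Default:
#'   50-residue bins up to 1500 with an overflow bin.
#' @return `data.frame` with columns `bin_start`, `bin_end`, `fraction`;
#'   fractions sum to 1.
#' @export
lengthDistribution <- function(x, binEdges = defaultLengthBins()) {
  lens <- if (is(x, "Proteome")) Biostrings::width(x@sequences)
          else as.numeric(x)
  if (length(lens) == 0L) stop("no records")
  if (!is.numeric(binEdges) || length(binEdges) < 2L ||
      any(diff(binEdges) <= 0))
    stop("invalid bins: edges must be >= 2 strictly increasing values")
  m <- length(binEdges)
  if (any(lens < binEdges[1L]) || any(lens >= binEdges[m]))
    stop("invalid bins: lengths fall outside the binned range")
  bin <- findInterval(lens, binEdges)
  frac <- tabulate(bin, nbins = m - 1L) / length(lens)
  data.frame(bin_start = binEdges[-m], bin_end = binEdges[-1L],
             fraction = frac)
}

#' Write a proteome summary table
#'
#' @param summaries `data.frame` as returned by [proteomeSummary()]
#'   (possibly row-bound over species).
#' @param path Output TSV file.
#' @return Invisibly, `path`.
#' @export
writeSummaryTSV <- function(summaries, path) {
  utils::write.table(summaries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
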