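# Shared fixtures: all test data is built in code.

makeProfiles <- function(scores, predictor = "test") {
  new("DisorderProfileSet", scores = scores, predictor = predictor)
}

writeTempFasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

randomSimplex <- function(n = 20L) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Character-by-character scanner: independent oracle for segment
# extraction.
bruteSegments <- function(labels, id = "p") {
  rows <- list()
  start <- NA_integer_
  for (i in seq_along(labels)) {
    if (labels[i] && is.na(start)) start <- i
    if (!labels[i] && !is.na(start)) {
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = id, start = start, end = i - 1L,
        length = i - start, stringsAsFactors = FALSE)
      start <- NA_integer_
    }
  }
  if (!is.na(start)) {
    n <- length(labels)
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = id, start = start, end = n, length = n - start + 1L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

randomAASequence <- function(n, residues = standardResidues()) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# Min-max rescaling of raw propensities, the reference transform for
# window-1 scoring checks.
rescaleToScale <- function(x, scale = topIDPScale()) {
  v <- scaleValues(scale)
  (x - min(v)) / (max(v) - min(v))
}
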