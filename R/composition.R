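# Amino acid composition analysis: composition vectors, fractional
# difference profiles against a fully-disordered reference, symmetrized
# Kullback-Leibler divergence with similarity bands, and pairwise KL
# matrices.

#' Construct a CompositionVector from residue counts
#'
#' @param counts Named non-negative numeric vector; missing residues are
#'   filled with zero counts.
#' @return A [CompositionVector-class].
#' @export
compositionVector <- function(counts) {
  res <- standardResidues()
  full <- stats::setNames(numeric(20L), res)
  counts <- counts[names(counts) %in% res]
  full[names(counts)] <- counts
  tot <- sum(full)
  freq <- if (tot > 0) full / tot else full
  new("CompositionVector", counts = full, frequencies = freq)
}

#' Amino acid composition of a sequence collection
#'
#' Counts pooled over all sequences, restricted to the 20 standard
#' residues; ambiguity codes are excluded from numerator and denominator.
#'
#' @param x A [Proteome-class], `AAStringSet`, or character vector of
#'   sequences.
#' @return A [CompositionVector-class].
#' @export
composition <- function(x) {
  seqs <- if (is(x, "Proteome")) x@sequences
          else if (is(x, "AAStringSet")) x
          else Biostrings::AAStringSet(toupper(as.character(x)))
  af <- Biostrings::alphabetFrequency(seqs)
  counts <- colSums(af[, standardResidues(), drop = FALSE])
  if (sum(counts) == 0) stop("empty composition")
  compositionVector(counts)
}

#' Bundled reference composition for fully disordered proteins
#'
#' An approximate composition of fully disordered proteins (enriched in
#' E, K, P, S, G; depleted in W, C, Y, F, I), shipped as the default
#' reference for [fractionalDifference()]. It approximates the composition
#' of curated fully-disordered sequence sets and is configurable: pass any
#' [CompositionVector-class] as `reference` where a specific dataset is
#' required.
#'
#' @return A [CompositionVector-class].
#' @export
fddComposition <- function() {
  f <- .FDD_REFERENCE[standardResidues()]
  compositionVector(round(f / sum(f) * 1e6))
}

#' Fractional composition difference against a reference
#'
#' For each residue X, `(C_X - C_ref) / C_ref`, where `C_X` is the
#' residue's frequency in the query set and `C_ref` in the reference
#' (a fully-disordered reference by default), so negative values mean
#' depletion relative to disordered proteins. Residues with zero reference
#' frequency are flagged undefined rather than silently zeroed. Residues
#' are ordered by increasing disorder propensity.
#'
#' @param cx Query [CompositionVector-class].
#' @param cref Reference [CompositionVector-class]; default
#'   [fddComposition()].
#' @param scale [PropensityScale-class] defining the residue order;
#'   default [topIDPScale()].
#' @return `data.frame` with columns `residue`, `delta`, `undefined`,
#'   rows in increasing propensity order.
#' @export
fractionalDifference <- function(cx, cref = fddComposition(),
                                 scale = topIDPScale()) {
  stopifnot(is(cx, "CompositionVector"), is(cref, "CompositionVector"))
  if (sum(cref@counts) == 0) stop("empty reference composition")
  ord <- names(sort(scale@values))
  fx <- cx@frequencies[ord]
  fr <- cref@frequencies[ord]
  undef <- fr == 0
  delta <- ifelse(undef, NA_real_, (fx - fr) / fr)
  data.frame(residue = ord, delta = unname(delta),
             undefined = unname(undef), stringsAsFactors = FALSE)
}

.klFrequencies <- function(x, pseudocount) {
  if (is(x, "CompositionVector")) {
    cts <- x@counts
    if (any(cts == 0)) cts <- cts + pseudocount
    return(cts / sum(cts))
  }
  if (!is.numeric(x) || length(x) < 2L)
    stop("compositions must be CompositionVectors or numeric vectors")
  if (any(x <= 0)) stop("unsupported composition: zero frequencies")
  x / sum(x)
}

#' Symmetrized Kullback-Leibler divergence between compositions
#'
#' `0.5 * (KL(p || q) + KL(q || p))` with natural logarithms. When either
#' of two [CompositionVector-class] inputs contains a zero count, the
#' pseudocount is added to every count of both vectors before normalizing
#' (KL is undefined on zeros, and symmetric regularization keeps the
#' divergence insensitive to the pseudocount choice). Bare numeric
#' frequency vectors must be strictly positive.
#'
#' @param p,q [CompositionVector-class] objects or positive numeric
#'   frequency vectors of equal length.
#' @param pseudocount Count added to each residue when zeros are present
#'   (default 0.5).
#' @return Non-negative divergence (0 iff the compositions coincide).
#' @export
klDivergence <- function(p, q, pseudocount = 0.5) {
  if (is(p, "CompositionVector") && is(q, "CompositionVector")) {
    cp <- p@counts
    cq <- q@counts
    if (any(cp == 0) || any(cq == 0)) {
      cp <- cp + pseudocount
      cq <- cq + pseudocount
    }
    fp <- cp / sum(cp)
    fq <- cq / sum(cq)
  } else {
    fp <- .klFrequencies(p, pseudocount)
    fq <- .klFrequencies(q, pseudocount)
  }
  if (length(fp) != length(fq))
    stop("compositions must have equal support")
  0.5 * (sum(fp * log(fp / fq)) + sum(fq * log(fq / fp)))
}

#' Similarity band of a KL divergence
#'
#' Bands: below 0.01 the datasets are highly similar; 0.01 to 0.05 is a
#' gray zone; above 0.05 the datasets are unlikely to be similar; above
#' 0.1 they are non-similar. Endpoints partition deterministically as
#' \[0, 0.01), \[0.01, 0.05\], (0.05, 0.1\], (0.1, Inf).
#'
#' @param d Non-negative divergence value(s); vectorized.
#' @return Character vector of `"similar"`, `"gray"`,
#'   `"unlikely_similar"`, `"non_similar"`.
#' @export
similarityClass <- function(d) {
  if (any(d < 0)) stop("invalid divergence")
  ifelse(d < 0.01, "similar",
    ifelse(d <= 0.05, "gray",
      ifelse(d <= 0.1, "unlikely_similar", "non_similar")))
}

#' Pairwise KL divergence matrix
#'
#' Symmetric matrix of symmetrized KL divergences between labeled
#' compositions, with zero diagonal (self-divergence) and per-cell
#' similarity bands attached as `attr(, "bands")`.
#'
#' @param compositions Named list of [CompositionVector-class] objects
#'   (>= 2).
#' @param pseudocount Passed to [klDivergence()].
#' @return Numeric matrix with `bands` attribute.
#' @export
klMatrix <- function(compositions, pseudocount = 0.5) {
  n <- length(compositions)
  if (n < 2L) stop("need at least two datasets")
  labs <- names(compositions)
  if (is.null(labs)) labs <- paste0("set", seq_len(n))
  m <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- klDivergence(compositions[[i]], compositions[[j]],
                        pseudocount = pseudocount)
      m[i, j] <- d
      m[j, i] <- d
    }
  }
  bands <- matrix(similarityClass(as.vector(m)), n, n,
                  dimnames = dimnames(m))
  attr(m, "bands") <- bands
  m
}

#' Write a composition profile or KL matrix as TSV
#'
#' @param x `data.frame` from [fractionalDifference()] or matrix from
#'   [klMatrix()].
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
writeCompositionTSV <- function(x, path) {
  if (is.matrix(x)) {
    df <- data.frame(label = rownames(x), as.data.frame(x),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
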