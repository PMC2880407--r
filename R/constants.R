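# Bundled amino-acid constants: residue alphabets, the TOP-IDP disorder
# propensity scale, Kyte-Doolittle hydropathies, order/disorder-promoting
# residue sets, and a reference composition for fully disordered proteins.

#' The twenty standard amino acid one-letter codes
#'
#' @return Character vector of the 20 standard residues, alphabetical.
#' @export
standardResidues <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Tolerated ambiguity codes
#'
#' Non-standard one-letter codes accepted in input sequences when ambiguity
#' tolerance is on: X (unknown), B (Asx), Z (Glx), U (selenocysteine),
#' O (pyrrolysine). Ambiguous positions are retained in sequences but
#' excluded from composition and charge/hydropathy denominators.
#'
#' @return Character vector of tolerated ambiguity codes.
#' @export
ambiguityCodes <- function() c("X", "B", "Z", "U", "O")

#' Order-promoting and disorder-promoting residue sets
#'
#' Residues depleted in (order-promoting) or enriched in (disorder-promoting)
#' intrinsically disordered proteins.
#'
#' @return Character vector of residues.
#' @export
orderPromotingResidues <- function() c("I", "L", "V", "W", "F", "Y", "C", "N")

#' @rdname orderPromotingResidues
#' @export
disorderPromotingResidues <- function() {
  c("E", "K", "R", "G", "Q", "S", "P", "A")
}

# TOP-IDP disorder propensities (Campen et al. 2008). Higher = more
# disorder-prone; W is the strongest order promoter, P the strongest
# disorder promoter.
.TOP_IDP <- c(
  A =  0.060, R =  0.180, N =  0.007, D =  0.192, C =  0.020,
  Q =  0.318, E =  0.736, G =  0.166, H =  0.303, I = -0.486,
  L = -0.326, K =  0.586, M = -0.397, F = -0.697, P =  0.987,
  S =  0.341, T =  0.059, W = -0.884, Y = -0.510, V = -0.121
)

# Kyte & Doolittle (1982) hydropathy index.
.KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

# Bundled reference composition for fully disordered proteins. The exact
# membership of published fully-disordered sequence sets is not
# redistributable here, so this is an approximate composition assembled
# from published disordered-protein composition surveys: enriched in
# E, K, P, S, G, depleted in W, C, Y, F, I. It is a configurable default;
# analyses sensitive to the reference should supply their own.
.FDD_REFERENCE <- c(
  A = 0.078, R = 0.049, N = 0.037, D = 0.056, C = 0.009,
  Q = 0.047, E = 0.096, G = 0.072, H = 0.021, I = 0.033,
  L = 0.059, K = 0.079, M = 0.019, F = 0.023, P = 0.093,
  S = 0.088, T = 0.054, V = 0.044, W = 0.006, Y = 0.017
)

#' Kyte-Doolittle hydropathy index
#'
#' @return Named numeric vector of per-residue hydropathies over the 20
#'   standard residues (range -4.5 for Arg to 4.5 for Ile).
#' @export
kyteDoolittleHydropathy <- function() .KYTE_DOOLITTLE
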