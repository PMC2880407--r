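# Synthetic proteome generator: two-state (ordered/disordered) hidden
# architecture with geometric block lengths, state-specific amino acid
# compositions, log-normal protein lengths, habitat archetypes, and full
# ground-truth bookkeeping.

#' Uniform and biased amino acid compositions
#'
#' `biasedComposition()` re-weights the uniform composition by `factor` on
#' a residue set and renormalizes; the defaults double the weight of the
#' order-promoting set (ordered state) or the disorder-promoting set
#' (disordered state).
#'
#' @param set Residues to up-weight.
#' @param factor Multiplicative weight (default 2).
#' @return Named numeric frequency vector over the 20 standard residues.
#' @export
biasedComposition <- function(set, factor = 2) {
  f <- stats::setNames(rep(1, 20L), standardResidues())
  f[set] <- factor
  f / sum(f)
}

#' @rdname biasedComposition
#' @export
defaultOrderedComposition <- function() {
  biasedComposition(orderPromotingResidues())
}

#' @rdname biasedComposition
#' @export
defaultDisorderedComposition <- function() {
  biasedComposition(disorderPromotingResidues())
}

#' Default protein length model
#'
#' Log-normal lengths (median 210 residues, log-scale shape 0.64) with a
#' hard floor of 20 residues. These defaults place the modal 50-residue
#' bin in the 100-200 range, keep the fraction of proteins shorter than
#' 50 residues below 2%, and put roughly 9% of proteins above 500
#' residues.
#'
#' @return List with `median`, `shape`, `floor`.
#' @export
defaultLengthParams <- function() list(median = 210, shape = 0.64,
                                       floor = 20L)

#' Configure a synthetic species archetype
#'
#' An archetype fixes the target stationary disordered fraction pi_d, the
#' mean lengths of disordered and ordered blocks (geometric sojourns of a
#' two-state Markov chain, so pi_d = mean_d / (mean_d + mean_o)), the two
#' state emission compositions, and a habitat template. When
#' `meanOrderedBlock` is omitted it is derived from pi_d and
#' `meanDisorderedBlock`; when both are given they must be consistent with
#' pi_d to within 1e-6.
#'
#' @param name Archetype name.
#' @param targetDisorderFraction pi_d in \[0, 1\].
#' @param meanDisorderedBlock Mean disordered block length (default 40, so
#'   long >30-residue regions occur at realistic rates).
#' @param meanOrderedBlock Mean ordered block length, or `NULL` to derive.
#' @param orderedComposition,disorderedComposition Emission frequency
#'   vectors over the 20 standard residues.
#' @param habitat Habitat template: a list with optional entries
#'   `optimal_temperature_c`, `optimal_ph` (value or `c(lo, hi)` range to
#'   sample), `salinity`, `flags`.
#' @return List of class `"ArchetypeConfig"`.
#' @export
archetypeConfig <- function(name, targetDisorderFraction,
                            meanDisorderedBlock = 40,
                            meanOrderedBlock = NULL,
                            orderedComposition = defaultOrderedComposition(),
                            disorderedComposition =
                              defaultDisorderedComposition(),
                            habitat = list()) {
  pi_d <- targetDisorderFraction
  if (!is.numeric(pi_d) || pi_d < 0 || pi_d > 1)
    stop("targetDisorderFraction must lie in [0, 1]")
  if (meanDisorderedBlock < 1) stop("block means must be >= 1")
  if (pi_d > 0 && pi_d < 1) {
    if (is.null(meanOrderedBlock))
      meanOrderedBlock <- meanDisorderedBlock * (1 - pi_d) / pi_d
    if (meanOrderedBlock < 1) stop("block means must be >= 1")
    implied <- meanDisorderedBlock / (meanDisorderedBlock + meanOrderedBlock)
    if (abs(implied - pi_d) > 1e-6)
      stop("inconsistent archetype: block means do not match pi_d")
  } else if (is.null(meanOrderedBlock)) {
    meanOrderedBlock <- meanDisorderedBlock
  }
  stopifnot(abs(sum(orderedComposition) - 1) < 1e-9,
            abs(sum(disorderedComposition) - 1) < 1e-9)
  structure(list(name = name, targetDisorderFraction = pi_d,
                 meanDisorderedBlock = meanDisorderedBlock,
                 meanOrderedBlock = meanOrderedBlock,
                 orderedComposition = orderedComposition,
                 disorderedComposition = disorderedComposition,
                 habitat = habitat),
            class = "ArchetypeConfig")
}

#' Default habitat archetype panel
#'
#' Three archetypes spanning the disorder range observed across
#' extremophile proteomes: thermophile-like (pi_d = 0.14, optimal growth
#' 85-100 degrees C), mesophile-like (pi_d = 0.20, 25-37 degrees C), and
#' halophile-like (pi_d = 0.34, high salinity). The 0.14 and 0.34
#' endpoints mirror the contrast between the least and most disordered
#' archaeal lineages.
#'
#' @return List of three `"ArchetypeConfig"` objects.
#' @export
defaultArchetypes <- function() {
  list(
    archetypeConfig("thermophile_like", 0.14,
      habitat = list(optimal_temperature_c = c(85, 100),
                     optimal_ph = c(5.5, 7.5), salinity = "normal",
                     flags = "")),
    archetypeConfig("mesophile_like", 0.20,
      habitat = list(optimal_temperature_c = c(25, 37),
                     optimal_ph = c(6, 8), salinity = "normal",
                     flags = "")),
    archetypeConfig("halophile_like", 0.34,
      habitat = list(optimal_temperature_c = c(30, 45),
                     optimal_ph = c(6.5, 7.5), salinity = "high",
                     flags = "")))
}

# Sample the hidden state path for one protein: alternating geometric
# blocks with the archetype's means, initial state from the stationary
# distribution. Returns logical labels (TRUE = disordered) plus the block
# segment table truncated to the protein length.
.sampleStatePath <- function(archetype, length) {
  pi_d <- archetype$targetDisorderFraction
  if (pi_d == 0) {
    return(list(labels = rep(FALSE, length),
                segments = data.frame(protein_id = character(0),
                                      start = integer(0), end = integer(0),
                                      length = integer(0))))
  }
  if (pi_d == 1) {
    return(list(labels = rep(TRUE, length),
                segments = data.frame(protein_id = NA_character_,
                                      start = 1L, end = as.integer(length),
                                      length = as.integer(length))))
  }
  md <- archetype$meanDisorderedBlock
  mo <- archetype$meanOrderedBlock
  state <- stats::runif(1) < pi_d
  total <- 0L
  states <- logical(0)
  lens <- integer(0)
  while (total < length) {
    m <- if (state) md else mo
    bl <- stats::rgeom(1L, prob = 1 / m) + 1L
    states <- c(states, state)
    lens <- c(lens, bl)
    total <- total + bl
    state <- !state
  }
  lens[length(lens)] <- lens[length(lens)] - (total - length)
  labels <- rep(states, lens)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  keep <- states & lens > 0L
  list(labels = labels,
       segments = data.frame(protein_id = rep(NA_character_, sum(keep)),
                             start = as.integer(starts[keep]),
                             end = as.integer(ends[keep]),
                             length = as.integer(lens[keep])))
}

#' Generate one synthetic protein with known disorder architecture
#'
#' The hidden ordered/disordered state follows a two-state Markov chain
#' with geometric block lengths (means from the archetype; stationary
#' disordered fraction pi_d). Residues are emitted from the state's
#' composition. The true labels and true maximal disordered segments are
#' returned alongside the sequence.
#'
#' @param archetype An `"ArchetypeConfig"`.
#' @param length Protein length (>= 1).
#' @param seed Optional integer seed; when `NULL` the current RNG stream
#'   is used (the same seed always reproduces the same protein).
#' @return List with `sequence` (character), `labels` (logical,
#'   `TRUE` = disordered), `segments` (`data.frame`).
#' @export
generateProtein <- function(archetype, length, seed = NULL) {
  stopifnot(inherits(archetype, "ArchetypeConfig"))
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  path <- .sampleStatePath(archetype, as.integer(length))
  labels <- path$labels
  chars <- character(length)
  nD <- sum(labels)
  if (nD > 0L)
    chars[labels] <- sample(standardResidues(), nD, replace = TRUE,
                            prob = archetype$disorderedComposition)
  if (nD < length)
    chars[!labels] <- sample(standardResidues(), length - nD,
                             replace = TRUE,
                             prob = archetype$orderedComposition)
  list(sequence = paste(chars, collapse = ""), labels = labels,
       segments = path$segments)
}

.sampleHabitatValue <- function(x) {
  if (is.numeric(x) && length(x) == 2L) round(stats::runif(1, x[1L], x[2L]), 1)
  else x
}

#' Generate a synthetic proteome with ground truth
#'
#' Protein lengths are drawn from the log-normal length model (see
#' [defaultLengthParams()]); each protein's disorder architecture and
#' residues come from [generateProtein()]. The habitat record is filled
#' from the archetype's template (ranges are sampled uniformly).
#'
#' @param archetype An `"ArchetypeConfig"`.
#' @param nProteins Number of proteins (>= 1).
#' @param lengthParams List with `median`, `shape`, `floor`.
#' @param speciesId Species identifier; defaults to the archetype name.
#' @param seed Optional integer seed.
#' @return List with `proteome` ([Proteome-class]), `truth`
#'   ([GroundTruth-class]), `habitat` (one-row `data.frame`), and
#'   `archetype`.
#' @export
generateProteome <- function(archetype, nProteins = 500L,
                             lengthParams = defaultLengthParams(),
                             speciesId = NULL, seed = NULL) {
  stopifnot(inherits(archetype, "ArchetypeConfig"))
  if (nProteins < 1) stop("nProteins must be >= 1")
  lp <- lengthParams
  if (!is.list(lp) || is.null(lp$median) || is.null(lp$shape) ||
      is.null(lp$floor) || lp$median <= 0 || lp$shape <= 0 || lp$floor < 1)
    stop("invalid length model")
  if (is.null(speciesId)) speciesId <- archetype$name
  if (!is.null(seed)) set.seed(seed)
  lens <- pmax(as.integer(lp$floor),
               as.integer(round(stats::rlnorm(nProteins, log(lp$median),
                                              lp$shape))))
  ids <- sprintf("%s_P%04d", speciesId, seq_len(nProteins))
  seqs <- character(nProteins)
  labels <- vector("list", nProteins)
  segs <- vector("list", nProteins)
  for (i in seq_len(nProteins)) {
    p <- generateProtein(archetype, lens[i])
    seqs[i] <- p$sequence
    labels[[i]] <- p$labels
    if (nrow(p$segments) > 0L) p$segments$protein_id <- ids[i]
    segs[[i]] <- p$segments
  }
  names(seqs) <- ids
  names(labels) <- ids
  hab <- archetype$habitat
  habitat <- data.frame(
    species_id = speciesId,
    optimal_ph = if (is.null(hab$optimal_ph)) NA_real_
                 else .sampleHabitatValue(hab$optimal_ph),
    optimal_temperature_c = if (is.null(hab$optimal_temperature_c)) NA_real_
                            else .sampleHabitatValue(hab$optimal_temperature_c),
    salinity = if (is.null(hab$salinity)) NA_character_ else hab$salinity,
    flags = if (is.null(hab$flags)) "" else hab$flags,
    stringsAsFactors = FALSE)
  truth <- new("GroundTruth", speciesId = speciesId, labels = labels,
               segments = do.call(rbind, segs))
  list(proteome = Proteome(seqs, speciesId = speciesId),
       truth = truth, habitat = habitat, archetype = archetype)
}

.deriveSeeds <- function(masterSeed, n) {
  set.seed(masterSeed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a multi-species synthetic panel
#'
#' One species per archetype replicate, with small per-species jitter on
#' the target disordered fraction and per-species seeds derived
#' deterministically from the master seed, so two panels built from the
#' same master seed are identical.
#'
#' @param archetypes List of `"ArchetypeConfig"` objects (default
#'   [defaultArchetypes()]).
#' @param nSpeciesPerArchetype Species replicates per archetype.
#' @param nProteins Proteins per species.
#' @param piJitter Half-width of the uniform per-species jitter on pi_d.
#' @param lengthParams Length model (see [defaultLengthParams()]).
#' @param seed Master seed.
#' @return List of class `"SpeciesPanel"`: one element per species, each
#'   as returned by [generateProteome()] plus `pi_d` (the jittered
#'   per-species target).
#' @export
generateSpeciesPanel <- function(archetypes = defaultArchetypes(),
                                 nSpeciesPerArchetype = 3L,
                                 nProteins = 500L, piJitter = 0.02,
                                 lengthParams = defaultLengthParams(),
                                 seed = NULL) {
  if (length(archetypes) == 0L) stop("no archetypes")
  total <- length(archetypes) * nSpeciesPerArchetype
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, total)
           else .deriveSeeds(seed, total)
  panel <- vector("list", total)
  k <- 0L
  for (arch in archetypes) {
    for (j in seq_len(nSpeciesPerArchetype)) {
      k <- k + 1L
      set.seed(seeds[k])
      pi_j <- arch$targetDisorderFraction
      if (pi_j > 0 && pi_j < 1)
        pi_j <- min(1, max(0, pi_j + stats::runif(1, -piJitter, piJitter)))
      archJ <- archetypeConfig(arch$name, pi_j,
                               meanDisorderedBlock = arch$meanDisorderedBlock,
                               orderedComposition = arch$orderedComposition,
                               disorderedComposition =
                                 arch$disorderedComposition,
                               habitat = arch$habitat)
      sp <- generateProteome(archJ, nProteins = nProteins,
                             lengthParams = lengthParams,
                             speciesId = sprintf("%s_%d", arch$name, j))
      sp$pi_d <- pi_j
      panel[[k]] <- sp
    }
  }
  names(panel) <- vapply(panel, function(s) s$proteome@speciesId, "")
  structure(panel, class = c("SpeciesPanel", "list"))
}

#' Habitat table of a species panel
#'
#' @param panel A `"SpeciesPanel"`.
#' @return `data.frame` with one habitat row per species.
#' @export
panelHabitats <- function(panel) {
  do.call(rbind, lapply(panel, function(s) s$habitat))
}

#' Generate a panel with a built-in temperature gradient in disorder
#'
#' Regular species are placed on an even grid of optimal growth
#' temperatures with the target disordered fraction decreasing linearly in
#' temperature; in addition, high-disorder halophile outliers are injected
#' at the hot end of the gradient (high salinity, pi_d =
#' `outlierDisorder`), deliberately violating the gradient so that outlier
#' detection can be exercised against generator ground truth.
#'
#' @param nSpecies Number of on-gradient species.
#' @param nProteins Proteins per species.
#' @param temperatureRange `c(lo, hi)` temperature grid limits.
#' @param disorderAtCold,disorderAtHot pi_d at the two ends of the grid.
#' @param nOutliers Number of injected halophile outliers.
#' @param outlierDisorder pi_d of the outlier species.
#' @param lengthParams Length model.
#' @param seed Master seed.
#' @return List with `panel` (a `"SpeciesPanel"`) and `outlier_ids`
#'   (species ids of the injected outliers).
#' @export
generateEnvironmentPanel <- function(nSpecies = 12L, nProteins = 300L,
                                     temperatureRange = c(15, 95),
                                     disorderAtCold = 0.34,
                                     disorderAtHot = 0.12,
                                     nOutliers = 2L,
                                     outlierDisorder = 0.35,
                                     lengthParams = defaultLengthParams(),
                                     seed = NULL) {
  temps <- seq(temperatureRange[1L], temperatureRange[2L],
               length.out = nSpecies)
  pis <- seq(disorderAtCold, disorderAtHot, length.out = nSpecies)
  outTemps <- seq(temperatureRange[2L] - 10, temperatureRange[2L],
                  length.out = max(nOutliers, 1L))[seq_len(nOutliers)]
  total <- nSpecies + nOutliers
  seeds <- if (is.null(seed)) sample.int(.Machine$integer.max - 1L, total)
           else .deriveSeeds(seed, total)
  panel <- vector("list", total)
  for (i in seq_len(nSpecies)) {
    set.seed(seeds[i])
    arch <- archetypeConfig(sprintf("gradient_%02d", i), pis[i],
      habitat = list(optimal_temperature_c = temps[i], salinity = "normal",
                     flags = ""))
    panel[[i]] <- generateProteome(arch, nProteins = nProteins,
                                   lengthParams = lengthParams)
    panel[[i]]$pi_d <- pis[i]
  }
  outlierIds <- character(nOutliers)
  for (j in seq_len(nOutliers)) {
    set.seed(seeds[nSpecies + j])
    id <- sprintf("halophile_outlier_%d", j)
    arch <- archetypeConfig(id, outlierDisorder,
      habitat = list(optimal_temperature_c = outTemps[j],
                     salinity = "high", flags = ""))
    panel[[nSpecies + j]] <- generateProteome(arch, nProteins = nProteins,
                                              lengthParams = lengthParams)
    panel[[nSpecies + j]]$pi_d <- outlierDisorder
    outlierIds[j] <- id
  }
  names(panel) <- vapply(panel, function(s) s$proteome@speciesId, "")
  list(panel = structure(panel, class = c("SpeciesPanel", "list")),
       outlier_ids = outlierIds)
}

#' Write a species panel to disk
#'
#' One FASTA per species, true disordered segments as BED (0-based
#' half-open), the habitat table as TSV, and a key-value manifest of
#' parameters.
#'
#' @param panel A `"SpeciesPanel"`.
#' @param dir Output directory (created if needed).
#' @param seed Master seed to record in the manifest.
#' @return Invisibly, `dir`.
#' @export
writeSpeciesPanel <- function(panel, dir, seed = NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in panel) {
    id <- sp$proteome@speciesId
    writeProteome(sp$proteome, file.path(dir, paste0(id, ".fasta")))
    segs <- sp$truth@segments
    if (nrow(segs) > 0L)
      writeSegmentsBED(segs, file.path(dir, paste0(id, ".truth.bed")))
  }
  utils::write.table(panelHabitats(panel), file.path(dir, "habitats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(
    sprintf("seed\t%s", seed),
    sprintf("n_species\t%d", length(panel)),
    vapply(panel, function(sp) {
      sprintf("species\t%s\tpi_d\t%.4f\tn_proteins\t%d",
              sp$proteome@speciesId, sp$pi_d, nProteins(sp$proteome))
    }, ""))
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
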