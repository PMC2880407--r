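# Ecology and evolution reporting: correlation of disorder measures with
# habitat factors, inter-measure correlation, and phylogenetic tree
# annotation by disorder content.

.salinityRank <- function(x) {
  if (is.numeric(x)) return(x)
  ranks <- c(low = 1, normal = 2, high = 3)
  out <- ranks[tolower(as.character(x))]
  if (anyNA(out[!is.na(x)]))
    stop("salinity must be numeric or one of low/normal/high")
  unname(out)
}

.pairCorrelation <- function(x, y, ids) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]; ids <- ids[ok]
  if (length(x) < 3L) stop("insufficient species")
  if (stats::sd(x) == 0) stop("zero variance")
  fit <- stats::lm(y ~ x)
  rs <- stats::rstudent(fit)
  list(n = length(x),
       pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       outlier_ids = ids[!is.na(rs) & abs(rs) > 2])
}

#' Correlate a disorder measure with a habitat factor
#'
#' Pearson and Spearman correlation of one proteome disorder measure
#' (`idaa`, `idp30` or `widp`) against one habitat factor across species,
#' with a least-squares fit and outlier flagging. Categorical salinity is
#' rank-coded low < normal < high; species with a missing factor or
#' measure are dropped pairwise. Outliers are species with absolute
#' externally studentized residual > 2 from the least-squares fit.
#'
#' @param measures `data.frame` with `species_id` and the measure columns
#'   (see [speciesDisorderMeasures()]).
#' @param habitats `data.frame` with `species_id` and factor columns
#'   (`optimal_ph`, `optimal_temperature_c`, `salinity`, ...).
#' @param factor Habitat factor column name.
#' @param measure Disorder measure column name (default `"idaa"`).
#' @return List with `factor`, `measure`, `n`, `pearson_r`,
#'   `spearman_rho`, `slope`, `intercept`, `outlier_ids`.
#' @export
disorderVsEnvironment <- function(measures, habitats,
                                  factor = "optimal_temperature_c",
                                  measure = "idaa") {
  if (!measure %in% names(measures))
    stop(sprintf("unknown measure '%s'", measure))
  if (!factor %in% names(habitats))
    stop(sprintf("unknown factor '%s'", factor))
  tab <- merge(measures[, c("species_id", measure)],
               habitats[, c("species_id", factor)], by = "species_id")
  x <- if (factor == "salinity") .salinityRank(tab[[factor]])
       else as.numeric(tab[[factor]])
  res <- .pairCorrelation(x, tab[[measure]], tab$species_id)
  c(list(factor = factor, measure = measure), res)
}

#' Pairwise correlation among the three disorder measures
#'
#' Least-squares fits and correlations for the pairs IDAA vs IDP>30aa,
#' IDAA vs WIDP, and IDP>30aa vs WIDP across species (y regressed on x in
#' the order named).
#'
#' @param measures `data.frame` with columns `species_id`, `idaa`,
#'   `idp30`, `widp`.
#' @return `data.frame` with one row per pair and columns `x`, `y`, `n`,
#'   `pearson_r`, `spearman_rho`, `slope`, `intercept`.
#' @export
measureCorrelation <- function(measures) {
  pairs <- list(c("idaa", "idp30"), c("idaa", "widp"),
                c("idp30", "widp"))
  rows <- lapply(pairs, function(p) {
    r <- .pairCorrelation(measures[[p[1L]]], measures[[p[2L]]],
                          measures$species_id)
    data.frame(x = p[1L], y = p[2L], n = r$n, pearson_r = r$pearson_r,
               spearman_rho = r$spearman_rho, slope = r$slope,
               intercept = r$intercept, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Color bin for a disorder percentage
#'
#' Bins on the percent scale, left-open per the strict thresholds:
#' >30 red, >21 orange, >17 yellow, >14 light blue, <=14 dark blue
#' (so exactly 21 is yellow, exactly 30 is orange, exactly 14 dark blue).
#'
#' @param percent Disordered-residue percentage(s) in \[0, 100\];
#'   vectorized.
#' @return Character vector of `"red"`, `"orange"`, `"yellow"`,
#'   `"light_blue"`, `"dark_blue"`.
#' @export
disorderColorBin <- function(percent) {
  if (any(percent < 0 | percent > 100))
    stop("percent must lie in [0, 100]")
  ifelse(percent > 30, "red",
    ifelse(percent > 21, "orange",
      ifelse(percent > 17, "yellow",
        ifelse(percent > 14, "light_blue", "dark_blue"))))
}

#' Annotate a phylogenetic tree with disorder content
#'
#' Attaches the disordered-residue percentage and its color bin to every
#' tree leaf found in the supplied map. Topology is untouched. Leaves
#' absent from the map are left uncolored, unless `strict` is on, in which
#' case the first missing leaf raises an error.
#'
#' @param tree An `ape::phylo` object, a Newick string, or a path to a
#'   Newick file.
#' @param idaaBySpecies Named numeric vector of disordered-residue
#'   percentages (names = leaf labels).
#' @param strict Error on leaves missing from the map?
#' @return List of class `"AnnotatedTree"` with elements `tree` (the
#'   `phylo`) and `annotation` (`data.frame` with `leaf`, `idaa_percent`,
#'   `color`).
#' @export
annotateTree <- function(tree, idaaBySpecies, strict = FALSE) {
  if (is.character(tree)) {
    txt <- if (length(tree) == 1L && !grepl("(", tree, fixed = TRUE) &&
               file.exists(tree)) paste(readLines(tree), collapse = "")
           else tree
    tree <- tryCatch(
      ape::read.tree(text = txt),
      error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("parse error: not a valid Newick tree")
  leaves <- tree$tip.label
  missing <- setdiff(leaves, names(idaaBySpecies))
  if (strict && length(missing) > 0L)
    stop(sprintf("unannotated leaf '%s'", missing[1L]))
  val <- unname(idaaBySpecies[leaves])
  color <- rep(NA_character_, length(val))
  color[!is.na(val)] <- disorderColorBin(val[!is.na(val)])
  ann <- data.frame(leaf = leaves, idaa_percent = val, color = color,
                    stringsAsFactors = FALSE)
  structure(list(tree = tree, annotation = ann), class = "AnnotatedTree")
}

#' @export
print.AnnotatedTree <- function(x, ...) {
  n <- sum(!is.na(x$annotation$color))
  cat(sprintf("AnnotatedTree: %d leaves, %d colored\n",
              nrow(x$annotation), n))
  invisible(x)
}

#' Write an annotated tree as Newick plus a sidecar table
#'
#' The Newick output carries the color of each annotated leaf as a
#' comment (`label[&color=red]`); the sidecar TSV lists leaf, percentage
#' and color.
#'
#' @param x An `"AnnotatedTree"` from [annotateTree()].
#' @param path Output Newick file.
#' @param sidecar Output TSV (default `path` + `.tsv`).
#' @return Invisibly, `path`.
#' @export
writeAnnotatedTree <- function(x, path, sidecar = paste0(path, ".tsv")) {
  nwk <- ape::write.tree(x$tree)
  ann <- x$annotation
  for (i in seq_len(nrow(ann))) {
    if (!is.na(ann$color[i])) {
      nwk <- sub(paste0("(^|[(,])", ann$leaf[i], "([:,)])"),
                 sprintf("\\1%s[&color=%s]\\2", ann$leaf[i], ann$color[i]),
                 nwk)
    }
  }
  writeLines(nwk, path)
  utils::write.table(ann, sidecar, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a habitat metadata table
#'
#' TSV with header `species_id`, `optimal_ph`,
#' `optimal_temperature_c`, `salinity`, `flags` (missing values empty or
#' NA). pH values are checked against \[0, 14\].
#'
#' @param path Input TSV.
#' @return `data.frame` of habitat records.
#' @export
readHabitats <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"species_id" %in% names(tab))
    stop("habitat table must have a species_id column")
  if ("optimal_ph" %in% names(tab)) {
    ph <- tab$optimal_ph
    if (any(!is.na(ph) & (ph < 0 | ph > 14)))
      stop("optimal_ph must lie in [0, 14]")
  }
  tab
}
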