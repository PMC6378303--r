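#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<- rowData<-
NULL

#' OTUExperiment: an OTU count table with sample metadata
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding one
#' \code{"counts"} assay of non-negative integer OTU counts (rows = taxa,
#' columns = samples), per-sample metadata in \code{colData} (elevation,
#' planar coordinates, gradient group, soil variables) and optional
#' per-taxon annotation (taxonomy, simulation ground truth) in
#' \code{rowData}.
#'
#' @slot .Data inherited SummarizedExperiment structure.
#' @seealso [OTUExperiment()] the constructor; [otuCounts()],
#'   [sampleData()] accessors.
#' @export
setClass("OTUExperiment", contains = "SummarizedExperiment")

.validOTUExperiment <- function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (any(!is.finite(m)))
      msg <- c(msg, "counts contain non-finite values")
    else {
      if (any(m < 0))
        msg <- c(msg, "counts contain negative values")
      if (max(abs(m - round(m))) > 1e-8)
        msg <- c(msg, "counts must be integers")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "taxon ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample ids must be present and unique")
  }
  if (length(msg)) msg else TRUE
}
setValidity("OTUExperiment", .validOTUExperiment)

#' Construct an OTUExperiment
#'
#' @param counts non-negative integer matrix, taxa in rows, samples in
#'   columns; dimnames are taken as taxon/sample ids.
#' @param sampleData optional `data.frame`/`DataFrame` of per-sample
#'   metadata, rows matching `colnames(counts)`.
#' @param taxonData optional per-taxon annotation, rows matching
#'   `rownames(counts)`.
#' @return an [OTUExperiment-class] object.
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 2L), 2, 2,
#'             dimnames = list(c("OTU1", "OTU2"), c("S1", "S2")))
#' OTUExperiment(m)
#' @export
OTUExperiment <- function(counts, sampleData = NULL, taxonData = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  args <- list(assays = SimpleList(counts = counts))
  if (!is.null(sampleData)) {
    sampleData <- DataFrame(sampleData)
    if (!is.null(rownames(sampleData))) {
      if (!setequal(rownames(sampleData), colnames(counts)))
        stop("sampleData rows do not match sample ids: ",
             paste(setdiff(colnames(counts), rownames(sampleData)),
                   collapse = ", "))
      sampleData <- sampleData[colnames(counts), , drop = FALSE]
    } else if (nrow(sampleData) != ncol(counts)) {
      stop("sampleData must have one row per sample")
    }
    args$colData <- sampleData
  }
  if (!is.null(taxonData))
    args$rowData <- DataFrame(taxonData)
  se <- do.call(SummarizedExperiment, args)
  out <- new("OTUExperiment", se)
  validObject(out)
  out
}

#' NichePartition: niche-breadth classification of taxa
#'
#' Per-taxon Levins' niche breadth B, the generalist/specialist/other
#' category implied by a pair of thresholds, and (optionally) indicator
#' value scores with permutation p-values used to confirm strict
#' specialists.
#'
#' @slot taxa character vector of classified taxon ids.
#' @slot breadth numeric, Levins' B per taxon (1 = one habitat, n = even
#'   across all n habitats).
#' @slot category factor with levels generalist/specialist/other.
#' @slot thresholds numeric length-2, `c(low, high)`; B < low is a
#'   specialist, B > high a generalist, boundaries fall to "other".
#' @slot indval `DataFrame` with columns `indval` and `p` (may have 0 rows
#'   when INDVAL was not run).
#' @slot strict character, ids of breadth specialists confirmed by INDVAL.
#' @export
setClass("NichePartition",
  representation(taxa = "character", breadth = "numeric",
                 category = "factor", thresholds = "numeric",
                 indval = "DataFrame", strict = "character"))

setValidity("NichePartition", function(object) {
  msg <- character()
  n <- length(object@taxa)
  if (length(object@breadth) != n || length(object@category) != n)
    msg <- c(msg, "taxa, breadth and category lengths differ")
  if (length(object@thresholds) != 2 ||
      object@thresholds[1] >= object@thresholds[2])
    msg <- c(msg, "thresholds must be c(low, high) with low < high")
  if (!all(levels(object@category) %in%
           c("generalist", "specialist", "other")))
    msg <- c(msg, "unknown category level")
  if (!all(object@strict %in%
           object@taxa[object@category == "specialist"]))
    msg <- c(msg, "strict specialists must be breadth specialists")
  if (length(msg)) msg else TRUE
})

#' ConstrainedOrdination: RDA/CCA summary
#'
#' @slot method "rda" or "cca".
#' @slot constrainedEig,unconstrainedEig eigenvalues of the constrained and
#'   residual components.
#' @slot totalInertia total variance (RDA) or chi-square inertia (CCA).
#' @slot r2 constrained proportion of inertia.
#' @slot siteScores,variableScores score matrices on the constrained axes.
#' @slot pvalue overall permutation p (NA when not tested).
#' @export
setClass("ConstrainedOrdination",
  representation(method = "character", constrainedEig = "numeric",
                 unconstrainedEig = "numeric", totalInertia = "numeric",
                 r2 = "numeric", siteScores = "matrix",
                 variableScores = "matrix", pvalue = "numeric"))

#' VariancePartition: adjusted-R2 decomposition of community variance
#'
#' Fractions follow the standard two-set partition: `pure_env` (E|S),
#' `pure_spatial` (S|E), `shared`, `unexplained`; they sum to 1 by
#' construction and individual fractions may be negative (adjusted R2).
#'
#' @slot fractions named numeric of the four fractions.
#' @slot pvalues named numeric: permutation p for the testable fractions
#'   (pure_env, pure_spatial, full model); the shared fraction is not
#'   testable and never receives a p-value.
#' @slot r2adj named numeric: adjusted R2 of the env, spatial and joint
#'   models.
#' @export
setClass("VariancePartition",
  representation(fractions = "numeric", pvalues = "numeric",
                 r2adj = "numeric"))

setValidity("VariancePartition", function(object) {
  f <- object@fractions
  need <- c("pure_env", "pure_spatial", "shared", "unexplained")
  if (!all(need %in% names(f)))
    return("fractions must be named pure_env/pure_spatial/shared/unexplained")
  if (abs(sum(f)) > 0 && abs(sum(f) - 1) > 1e-8)
    return("fractions must sum to 1")
  if ("shared" %in% names(object@pvalues))
    return("shared fraction is not testable")
  TRUE
})

#' BetaNullDeviation: observed vs null-model beta diversity
#'
#' @slot pairs data.frame with one row per sample pair: `sample_i`,
#'   `sample_j`, `beta_obs`, `beta_null_mean`, `beta_null_sd`, `deviation`
#'   where deviation = (beta_obs - beta_null_mean) / beta_obs.
#' @slot nNull number of null assemblies used.
#' @slot metric beta-diversity metric name.
#' @slot group optional label (e.g. subcommunity) for this run.
#' @export
setClass("BetaNullDeviation",
  representation(pairs = "data.frame", nNull = "numeric",
                 metric = "character", group = "character"))
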