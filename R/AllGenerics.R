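#' Accessors for NicheAssembly classes
#'
#' `otuCounts` returns the count matrix (taxa x samples), `sampleData` the
#' per-sample metadata as a data.frame, `taxonBreadth` the per-taxon
#' Levins' B, `taxonCategory` the generalist/specialist/other factor,
#' `nicheThresholds` the `(low, high)` B thresholds, `indvalScores` the
#' INDVAL table, `strictSpecialistIds` the confirmed strict specialists,
#' and `deviationPairs` the per-pair beta null deviation table.
#'
#' @param x an object of the documented class.
#' @return see the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname accessors
#' @export
setGeneric("taxonBreadth", function(x) standardGeneric("taxonBreadth"))

#' @rdname accessors
#' @export
setGeneric("taxonCategory", function(x) standardGeneric("taxonCategory"))

#' @rdname accessors
#' @export
setGeneric("nicheThresholds", function(x) standardGeneric("nicheThresholds"))

#' @rdname accessors
#' @export
setGeneric("indvalScores", function(x) standardGeneric("indvalScores"))

#' @rdname accessors
#' @export
setGeneric("strictSpecialistIds",
           function(x) standardGeneric("strictSpecialistIds"))

#' @rdname accessors
#' @export
setGeneric("deviationPairs", function(x) standardGeneric("deviationPairs"))

#' @rdname accessors
#' @export
setMethod("otuCounts", "OTUExperiment", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setMethod("sampleData", "OTUExperiment",
          function(x) as.data.frame(colData(x)))

#' @rdname accessors
#' @export
setMethod("taxonBreadth", "NichePartition", function(x) {
  out <- x@breadth
  names(out) <- x@taxa
  out
})

#' @rdname accessors
#' @export
setMethod("taxonCategory", "NichePartition", function(x) {
  out <- x@category
  names(out) <- x@taxa
  out
})

#' @rdname accessors
#' @export
setMethod("nicheThresholds", "NichePartition", function(x) {
  out <- x@thresholds
  names(out) <- c("low", "high")
  out
})

#' @rdname accessors
#' @export
setMethod("indvalScores", "NichePartition",
          function(x) as.data.frame(x@indval))

#' @rdname accessors
#' @export
setMethod("strictSpecialistIds", "NichePartition", function(x) x@strict)

#' @rdname accessors
#' @export
setMethod("deviationPairs", "BetaNullDeviation", function(x) x@pairs)

setMethod("show", "OTUExperiment", function(object) {
  cat("OTUExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cat("  total reads:", sum(assay(object, "counts")), "\n")
  if (ncol(colData(object)))
    cat("  sample variables:",
        paste(colnames(colData(object)), collapse = ", "), "\n")
  if (ncol(rowData(object)))
    cat("  taxon annotation:",
        paste(colnames(rowData(object)), collapse = ", "), "\n")
})

setMethod("show", "NichePartition", function(object) {
  tab <- table(object@category)
  cat("NichePartition:", length(object@taxa), "taxa classified\n")
  cat(sprintf("  thresholds: specialist B < %.3g, generalist B > %.3g\n",
              object@thresholds[1], object@thresholds[2]))
  cat(sprintf("  generalists %d, specialists %d (strict %d), other %d\n",
              tab[["generalist"]], tab[["specialist"]],
              length(object@strict), tab[["other"]]))
})

setMethod("show", "ConstrainedOrdination", function(object) {
  cat(toupper(object@method), "constrained ordination\n")
  cat(sprintf("  total inertia %.4g, constrained proportion R2 = %.4f\n",
              object@totalInertia, object@r2))
  if (!is.na(object@pvalue))
    cat(sprintf("  permutation p = %.4g\n", object@pvalue))
})

setMethod("show", "VariancePartition", function(object) {
  f <- object@fractions * 100
  cat("Variation partitioning (adjusted R2, % of community variance)\n")
  cat(sprintf("  pure environment %.1f%%, pure spatial %.1f%%, shared %.1f%%, unexplained %.1f%%\n",
              f["pure_env"], f["pure_spatial"], f["shared"],
              f["unexplained"]))
  if (length(object@pvalues))
    cat("  permutation p:",
        paste(names(object@pvalues),
              signif(object@pvalues, 3), sep = "=", collapse = ", "), "\n")
})

setMethod("show", "BetaNullDeviation", function(object) {
  cat("BetaNullDeviation (", object@metric, ", ", object@nNull,
      " null assemblies)\n", sep = "")
  if (nzchar(object@group)) cat("  group:", object@group, "\n")
  dev <- object@pairs$deviation
  cat(sprintf("  %d sample pairs, mean deviation %.3f (range %.3f..%.3f)\n",
              nrow(object@pairs), mean(dev, na.rm = TRUE),
              min(dev, na.rm = TRUE), max(dev, na.rm = TRUE)))
})
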