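#' Read an OTU table
#'
#' Reads a taxa-x-samples count table. The TSV dialect is tab-separated
#' UTF-8 with first column `#OTU_ID` (taxon ids), remaining headers taken
#' as sample ids, and an optional final `taxonomy` column. BIOM 2.x files
#' are read through the biomformat package when `format = "biom"`.
#'
#' All-zero taxa are retained on read; filtering is an explicit,
#' separate step ([filterRare()]).
#'
#' @param path file path.
#' @param format "tsv" (default) or "biom".
#' @return an [OTUExperiment-class].
#' @export
readOtuTable <- function(path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE))
      stop("the biomformat package is required to read BIOM files")
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")
    return(OTUExperiment(m))
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!ncol(df) >= 2) stop("OTU table needs an id column and >=1 sample")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate taxon ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  taxonomy <- NULL
  if (tolower(colnames(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- df[[ncol(df)]]
    df <- df[, -ncol(df), drop = FALSE]
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  m <- matrix(NA_real_, nrow(df), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("non-numeric count in sample '", samples[j], "', taxon '",
           ids[bad[1]], "'")
    neg <- which(v < 0)
    if (length(neg))
      stop("negative count in sample '", samples[j], "', taxon '",
           ids[neg[1]], "'")
    m[, j] <- v
  }
  taxonData <- if (!is.null(taxonomy))
    data.frame(taxonomy = taxonomy, row.names = ids)
  OTUExperiment(m, taxonData = taxonData)
}

#' Write an OTU table as TSV
#'
#' Inverse of [readOtuTable()]; integer tables round-trip bit-identically.
#'
#' @param x an [OTUExperiment-class].
#' @param path output path.
#' @export
writeOtuTable <- function(x, path) {
  m <- otuCounts(x)
  df <- data.frame("#OTU_ID" = rownames(m), m, check.names = FALSE)
  if ("taxonomy" %in% colnames(rowData(x)))
    df$taxonomy <- rowData(x)$taxonomy
  utils::write.table(format(df, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with required columns `sample_id`, `elevation_m`, `x_m`, `y_m`,
#' `gradient`; any remaining numeric columns are treated as environmental
#' variables.
#'
#' @param path file path.
#' @return data.frame with `sample_id` as row names.
#' @export
readSampleMetadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "elevation_m", "x_m", "y_m", "gradient")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("metadata is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in metadata")
  if (any(!is.finite(df$x_m)) || any(!is.finite(df$y_m)))
    stop("non-finite coordinates in metadata")
  rownames(df) <- df$sample_id
  df
}

#' Attach sample metadata to an OTUExperiment
#'
#' @param x an [OTUExperiment-class].
#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @return `x` with `colData` populated; errors if a table sample is
#'   missing from the metadata.
#' @export
attachMetadata <- function(x, metadata) {
  miss <- setdiff(colnames(x), rownames(metadata))
  if (length(miss))
    stop("metadata missing for samples: ", paste(miss, collapse = ", "))
  colData(x) <- DataFrame(metadata[colnames(x), , drop = FALSE])
  validObject(x)
  x
}

#' Per-sample relative abundances
#'
#' Column-normalizes the count matrix so every sample sums to 1. These are
#' the P_ij inputs to Levins' niche breadth.
#'
#' @param x an [OTUExperiment-class] or a counts matrix (taxa x samples).
#' @return numeric matrix of the same shape with unit column sums.
#' @export
relativeAbundances <- function(x) {
  m <- if (is(x, "OTUExperiment")) otuCounts(x) else as.matrix(x)
  tot <- colSums(m)
  zero <- colnames(m)[tot == 0]
  if (length(zero))
    stop("samples with zero total count: ", paste(zero, collapse = ", "))
  sweep(m, 2, tot, "/")
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (per-taxon counts are
#' hypergeometric) to exactly `depth` reads, removing sequencing-depth
#' bias. Samples whose total is below `depth` are dropped with a warning
#' (or raise an error when `dropBelowDepth = FALSE`); a sample whose total
#' equals `depth` is returned unchanged.
#'
#' @param x an [OTUExperiment-class].
#' @param depth target reads per sample (default 22310).
#' @param seed optional integer seed for reproducibility.
#' @param dropBelowDepth drop shallow samples (default) instead of erroring.
#' @return rarefied [OTUExperiment-class]; every retained column sums to
#'   `depth`.
#' @export
rarefyCounts <- function(x, depth = 22310, seed = NULL,
                         dropBelowDepth = TRUE) {
  stopifnot(depth >= 1)
  m <- otuCounts(x)
  tot <- colSums(m)
  shallow <- colnames(m)[tot < depth]
  if (length(shallow) == ncol(m))
    stop("all samples are below the rarefaction depth ", depth)
  if (length(shallow)) {
    if (!dropBelowDepth)
      stop("samples below depth ", depth, ": ",
           paste(shallow, collapse = ", "))
    warning("dropping ", length(shallow), " sample(s) below depth ",
            depth, ": ", paste(shallow, collapse = ", "))
    x <- x[, setdiff(colnames(m), shallow)]
    m <- otuCounts(x)
  }
  if (!is.null(seed)) set.seed(seed)
  r <- t(vegan::rrarefy(t(m), depth))
  out <- x
  assays(out)$counts <- r
  validObject(out)
  out
}

#' Remove rare taxa by mean relative abundance
#'
#' Drops taxa whose mean relative abundance across samples is strictly
#' below `threshold` (default 2e-5); such taxa can erroneously look like
#' habitat specialists. A taxon exactly at the threshold is retained. The
#' removed ids are recorded in `metadata(result)$removed_taxa`.
#'
#' @param x an [OTUExperiment-class].
#' @param threshold strictly-positive removal threshold on mean relative
#'   abundance.
#' @return filtered [OTUExperiment-class].
#' @export
filterRare <- function(x, threshold = 2e-5) {
  stopifnot(threshold > 0)
  p <- relativeAbundances(x)
  keep <- rowMeans(p) >= threshold
  if (!any(keep))
    warning("all taxa fall below the rare-taxon threshold")
  out <- x[keep, ]
  metadata(out)$removed_taxa <- rownames(x)[!keep]
  out
}

#' @importFrom SummarizedExperiment assays assays<-
NULL
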