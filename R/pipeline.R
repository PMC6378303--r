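#' Derive a per-stage seed from the master seed
#'
#' Fixed documented derivation (`(master * 131 + 17 * stage index) mod
#' (2^31 - 2) + 1`, stages in the fixed pipeline order) so every
#' stochastic stage is independently seeded yet the whole run is
#' reproducible from one master seed.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed.
#' @export
stageSeed <- function(master, stage) {
  stages <- c("simulate", "rarefy", "partition", "diversity", "spatial",
              "vpa", "mantel", "nulldev")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(master) * 131 + 17 * i) %% (2^31 - 2) + 1)
}

.writeTsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 10,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.stageLog <- function(stage, t0, ...) {
  message(sprintf("[%s] %s (%.2fs)", stage,
                  paste(..., collapse = " "),
                  as.numeric(proc.time()[3] - t0)))
}

#' Default pipeline configuration
#'
#' Defaults mirror the emulated study: rarefaction depth 22310, rare-taxon
#' threshold 2e-5, breadth thresholds 1.5/8.7, 999 permutations and 999
#' null assemblies.
#'
#' @param ... overrides of the default fields (`simulate` logical or a
#'   list of [simulationConfig()] arguments, `otu_table`/`metadata` input
#'   paths, `depth`, `filter_threshold`, `low`, `high`,
#'   `auto_thresholds`, `n_perm`, `n_null`, `seed`).
#' @return configuration list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(simulate = TRUE, otu_table = NULL, metadata = NULL,
              depth = 22310, filter_threshold = 2e-5,
              low = 1.5, high = 8.7, auto_thresholds = FALSE,
              n_perm = 999, n_null = 999, seed = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of key-value pairs matching [pipelineConfig()]
#'   fields; a `simulate:` mapping is forwarded to [simulationConfig()].
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

#' Run the full niche-breadth community-assembly pipeline
#'
#' Simulates (or ingests) an OTU table with sample metadata, rarefies and
#' rare-filters it, partitions taxa by Levins' niche breadth (with INDVAL
#' confirmation of strict specialists), and then, for the full community
#' and each subcommunity: alpha diversity compared across gradient groups,
#' Bray-Curtis PCoA, overall and pairwise ANOSIM, PCNM spatial
#' eigenvectors, forward selection of environmental and spatial
#' variables, variation partitioning, Mantel/partial Mantel tests, and
#' beta null deviation. All outputs are written as TSV under `outdir`
#' together with a reproducibility manifest.
#'
#' @param config list from [pipelineConfig()] / [readPipelineConfig()].
#' @param outdir output directory (created if missing).
#' @param seed master seed overriding `config$seed`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, seed = NULL) {
  t0 <- proc.time()[3]
  if (!is.null(seed)) config$seed <- seed
  master <- config$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  # --- ingest or simulate -------------------------------------------------
  if (isTRUE(config$simulate) || is.list(config$simulate)) {
    simargs <- if (is.list(config$simulate)) config$simulate else list()
    simargs$depth <- config$depth
    sc <- do.call(simulationConfig, simargs)
    x <- simulateMetacommunity(sc, seed = stageSeed(master, "simulate"))
  } else {
    if (is.null(config$otu_table) || is.null(config$metadata))
      stop("stage ingest: need otu_table and metadata paths when not simulating")
    x <- readOtuTable(config$otu_table)
    x <- attachMetadata(x, readSampleMetadata(config$metadata))
  }
  .stageLog("ingest", t0, nrow(x), "taxa x", ncol(x), "samples")

  # --- rarefy + filter ----------------------------------------------------
  x <- rarefyCounts(x, depth = config$depth,
                    seed = stageSeed(master, "rarefy"))
  x <- filterRare(x, threshold = config$filter_threshold)
  .stageLog("rarefy+filter", t0, nrow(x), "taxa retained")

  # --- niche partition ----------------------------------------------------
  part <- nichePartition(x, groups = sampleData(x)$gradient,
                         low = config$low, high = config$high,
                         autoThresholds = isTRUE(config$auto_thresholds),
                         nPerm = config$n_perm,
                         seed = stageSeed(master, "partition"))
  pt <- data.frame(taxon = part@taxa, B = part@breadth,
                   category = as.character(part@category),
                   strict = part@taxa %in% part@strict)
  iv <- indvalScores(part)
  if (nrow(iv)) pt <- merge(pt, iv[, c("taxon", "indval", "p")],
                            by = "taxon", sort = TRUE)
  .writeTsv(pt[order(pt$taxon), ], file.path(outdir, "partition.tsv"))
  subs <- subcommunities(x, part)
  .stageLog("partition", t0, "generalists",
            sum(pt$category == "generalist"), "specialists",
            sum(pt$category == "specialist"))

  md <- sampleData(x)
  envVars <- setdiff(colnames(md)[vapply(md, is.numeric, logical(1))],
                     c("x_m", "y_m"))
  env <- md[, envVars, drop = FALSE]
  grad <- md$gradient

  # samples with no reads in a subcommunity carry no information about it
  dropEmpty <- function(tab) tab[, colSums(otuCounts(tab)) > 0]

  # --- diversity ----------------------------------------------------------
  set.seed(stageSeed(master, "diversity"))
  alpha <- do.call(rbind, lapply(names(subs), function(nm) {
    tab <- dropEmpty(subs[[nm]])
    a <- alphaDiversity(tab)
    cbind(group = nm, a, gradient = grad[match(colnames(tab), colnames(x))])
  }))
  .writeTsv(alpha, file.path(outdir, "alpha.tsv"))
  bc <- brayCurtis(x)
  bm <- as.matrix(bc)
  .writeTsv(data.frame(sample = rownames(bm), bm, check.names = FALSE),
            file.path(outdir, "bray_curtis.tsv"))
  pco <- pcoaOrdination(bc)
  .writeTsv(data.frame(sample = rownames(pco$points),
                       pco$points[, 1:min(4, ncol(pco$points))],
                       check.names = FALSE),
            file.path(outdir, "pcoa_coords.tsv"))
  anosim_rows <- do.call(rbind, lapply(names(subs), function(nm) {
    tab <- dropEmpty(subs[[nm]])
    a <- anosimTest(brayCurtis(tab),
                    grad[match(colnames(tab), colnames(x))],
                    nPerm = config$n_perm, pairwise = TRUE)
    rbind(data.frame(group = nm, comparison = "overall", R = a$R, p = a$p),
          data.frame(group = nm,
                     comparison = paste(a$pairwise$group1,
                                        a$pairwise$group2, sep = "-"),
                     R = a$pairwise$R, p = a$pairwise$p))
  }))
  .writeTsv(anosim_rows, file.path(outdir, "anosim.tsv"))
  .stageLog("diversity", t0, nrow(alpha), "alpha rows")

  # --- spatial ------------------------------------------------------------
  set.seed(stageSeed(master, "spatial"))
  geo <- geoDistance(x)
  pcnm <- pcnmVectors(geo)
  .writeTsv(data.frame(sample = rownames(pcnm$vectors), pcnm$vectors,
                       check.names = FALSE),
            file.path(outdir, "pcnm_scores.tsv"))
  sel <- list()
  for (nm in names(subs)) {
    tab <- dropEmpty(subs[[nm]])
    keep <- colnames(tab)
    Y <- hellinger(tab)
    se_ <- forwardSelect(Y, env[keep, , drop = FALSE], alpha = 0.05,
                         nPerm = config$n_perm)
    ss <- forwardSelect(Y, as.data.frame(pcnm$vectors)[keep, , drop = FALSE],
                        alpha = 0.05, nPerm = config$n_perm)
    sel[[nm]] <- list(env = se_, spatial = ss)
  }
  selrows <- do.call(rbind, lapply(names(sel), function(nm) {
    rbind(if (nrow(sel[[nm]]$env))
            cbind(group = nm, set = "env", sel[[nm]]$env),
          if (nrow(sel[[nm]]$spatial))
            cbind(group = nm, set = "spatial", sel[[nm]]$spatial))
  }))
  if (is.null(selrows))
    selrows <- data.frame(group = character(), set = character(),
                          variable = character(), r2_added = numeric(),
                          r2_cum = numeric(), p = numeric())
  .writeTsv(selrows, file.path(outdir, "selected_vars.tsv"))
  .stageLog("spatial", t0, ncol(pcnm$vectors), "PCNM axes,",
            nrow(selrows), "selected vars")

  # --- variation partitioning --------------------------------------------
  set.seed(stageSeed(master, "vpa"))
  vpa_rows <- do.call(rbind, lapply(names(subs), function(nm) {
    tab <- dropEmpty(subs[[nm]])
    keep <- colnames(tab)
    Y <- hellinger(tab)
    env <- env[keep, , drop = FALSE]
    pcnm <- list(vectors = pcnm$vectors[keep, , drop = FALSE])
    # forward-selected sets; fall back to the full candidate set when
    # selection is empty so the fraction is still reported
    ev <- sel[[nm]]$env$variable
    sv <- sel[[nm]]$spatial$variable
    Xe <- if (length(ev)) env[, ev, drop = FALSE] else env
    Xs <- if (length(sv)) as.data.frame(pcnm$vectors)[, sv, drop = FALSE]
          else as.data.frame(pcnm$vectors)
    # keep the joint model estimable (n - p - 1 >= 1): truncate unselected
    # fallback sets to their leading columns (PCNM axes are already
    # ordered broad to fine)
    cap <- max(1, floor((nrow(Y) - 2) / 2) - 1)
    if (!length(ev)) Xe <- Xe[, seq_len(min(cap, ncol(Xe))), drop = FALSE]
    if (!length(sv)) Xs <- Xs[, seq_len(min(cap, ncol(Xs))), drop = FALSE]
    while (ncol(Xe) + ncol(Xs) > nrow(Y) - 2) {
      if (ncol(Xs) >= ncol(Xe) && ncol(Xs) > 1)
        Xs <- Xs[, -ncol(Xs), drop = FALSE]
      else Xe <- Xe[, -ncol(Xe), drop = FALSE]
    }
    vp <- variationPartition(Y, Xe, Xs, nPerm = config$n_perm)
    f <- vp@fractions * 100
    data.frame(group = nm, pure_env_pct = f[["pure_env"]],
               pure_spatial_pct = f[["pure_spatial"]],
               shared_pct = f[["shared"]],
               unexplained_pct = f[["unexplained"]],
               p_pure_env = vp@pvalues[["pure_env"]],
               p_pure_spatial = vp@pvalues[["pure_spatial"]])
  }))
  .writeTsv(vpa_rows, file.path(outdir, "vpa.tsv"))
  .stageLog("vpa", t0, nrow(vpa_rows), "groups partitioned")

  # --- Mantel tests -------------------------------------------------------
  set.seed(stageSeed(master, "mantel"))
  de <- envDistance(env)
  mantel_rows <- do.call(rbind, lapply(names(subs), function(nm) {
    tab <- dropEmpty(subs[[nm]])
    keep <- colnames(tab)
    db <- brayCurtis(tab)
    dek <- stats::as.dist(as.matrix(de)[keep, keep])
    geok <- stats::as.dist(as.matrix(geo)[keep, keep])
    m1 <- mantelTest(db, dek, nPerm = config$n_perm)
    m2 <- mantelTest(db, geok, nPerm = config$n_perm)
    p1 <- partialMantelTest(db, dek, geok, nPerm = config$n_perm)
    p2 <- partialMantelTest(db, geok, dek, nPerm = config$n_perm)
    data.frame(group = nm,
               comparison = c("community-env", "community-space",
                              "community-env|space",
                              "community-space|env"),
               r = c(m1$r, m2$r, p1$r, p2$r),
               p = c(m1$p, m2$p, p1$p, p2$p),
               n_perm = config$n_perm)
  }))
  .writeTsv(mantel_rows, file.path(outdir, "mantel.tsv"))
  .stageLog("mantel", t0, nrow(mantel_rows), "tests")

  # --- null deviation -----------------------------------------------------
  nd <- subcommunityNullDeviation(x, part, nNull = config$n_null,
                                  seed = stageSeed(master, "nulldev"))
  nd_rows <- do.call(rbind, lapply(names(nd), function(nm)
    cbind(group = nm, deviationPairs(nd[[nm]]))))
  .writeTsv(nd_rows, file.path(outdir, "nulldev.tsv"))
  .stageLog("nulldev", t0, nrow(nd_rows), "pairs")

  manifest <- list(
    package_version = as.character(utils::packageVersion("NicheAssembly")),
    master_seed = master,
    stage_seeds = stats::setNames(
      lapply(c("simulate", "rarefy", "partition", "diversity", "spatial",
               "vpa", "mantel", "nulldev"),
             function(s) stageSeed(master, s)),
      c("simulate", "rarefy", "partition", "diversity", "spatial",
        "vpa", "mantel", "nulldev")),
    parameters = config[c("depth", "filter_threshold", "low", "high",
                          "auto_thresholds", "n_perm", "n_null")],
    dims = list(taxa = nrow(x), samples = ncol(x)),
    elapsed_s = round(as.numeric(proc.time()[3] - t0), 2))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))

  invisible(list(table = x, partition = part, alpha = alpha,
                 anosim = anosim_rows, selected = sel, vpa = vpa_rows,
                 mantel = mantel_rows, nulldev = nd))
}
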