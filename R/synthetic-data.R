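#' Gaussian niche response
#'
#' Expected abundance of a taxon with a Gaussian response to an
#' environmental gradient: `height * exp(-(env - optimum)^2 / (2 sigma^2))`.
#' Narrow `sigma` encodes a habitat specialist's strict environmental
#' requirements; `sigma` much larger than the gradient span gives the flat
#' response of a habitat generalist.
#'
#' @param env gradient value(s).
#' @param optimum niche optimum on the same scale.
#' @param sigma niche breadth (> 0), same units as `env`.
#' @param height maximal expected abundance (>= 0).
#' @return numeric of the same length as `env`.
#' @export
gaussianNicheResponse <- function(env, optimum, sigma, height = 1) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (height < 0) stop("height must be >= 0")
  height * exp(-(env - optimum)^2 / (2 * sigma^2))
}

#' The 13-site elevational sampling design
#'
#' Thirteen sites between 2085 and 3051 m on a mountain transect, grouped
#' into low (LEG, 4 sites), medium (MEG, 4 sites) and high (HEG, 5 sites)
#' elevational gradients. Planar coordinates place the sites along the
#' slope (assumed 20% grade) with a small fixed cross-slope offset so the
#' configuration is not exactly collinear.
#'
#' @return data.frame with columns `sample_id`, `elevation_m`, `x_m`,
#'   `y_m`, `gradient`.
#' @export
gradientSiteDesign <- function() {
  elev <- c(2085, 2172, 2221, 2295, 2581, 2657, 2707, 2728,
            2900, 2950, 3019, 3031, 3051)
  grad <- c(rep("LEG", 4), rep("MEG", 4), rep("HEG", 5))
  ids <- paste0(grad, c(1:4, 1:4, 1:5))
  data.frame(
    sample_id = ids,
    elevation_m = elev,
    x_m = (elev - min(elev)) / 0.20,
    y_m = rep(c(-25, 25), length.out = length(elev)),
    gradient = grad,
    stringsAsFactors = FALSE)
}

# Group means and standard errors of the soil variables along the three
# gradients (per-site SD = SE * sqrt(group size); groups HEG/MEG/LEG have
# 5/4/4 sites).
.envParameters <- function() {
  p <- rbind(
    pH      = c(5.85, 0.04, 5.86, 0.07, 6.32, 0.14),
    ST      = c(12.39, 0.23, 15.02, 0.23, 18.12, 0.46),
    SWC     = c(37.53, 1.86, 42.61, 2.07, 25.57, 3.52),
    EC      = c(130.27, 10.22, 97.50, 5.76, 96.92, 10.33),
    TN      = c(0.52, 0.02, 0.63, 0.05, 0.45, 0.03),
    TC      = c(5.65, 0.22, 8.07, 0.41, 6.01, 0.27),
    CN      = c(10.86, 0.17, 13.41, 0.98, 13.62, 0.50),
    SOC     = c(41.68, 0.98, 38.95, 1.31, 38.51, 1.50),
    NH4_N   = c(48.1, 2.72, 70.99, 2.40, 49.8, 3.04),
    NO3_N   = c(4.40, 0.16, 5.27, 0.42, 6.56, 0.40),
    NO2_N   = c(1.48, 0.04, 1.47, 0.07, 1.48, 0.10))
  colnames(p) <- c("HEG_mean", "HEG_se", "MEG_mean", "MEG_se",
                   "LEG_mean", "LEG_se")
  p
}

#' Simulate soil environmental variables for a site design
#'
#' Draws the eleven soil variables (pH, ST, SWC, EC, TN, TC, C:N, SOC,
#' NH4-N, NO3-N, NO2-N) per site as Normal(group mean, SE * sqrt(n_g)),
#' so gradient-group means match the emulated field values in expectation
#' and the elevational trends keep their signs (pH, ST and NO3-N decrease
#' with elevation).
#'
#' @param sites data.frame as from [gradientSiteDesign()].
#' @param seed optional integer seed.
#' @return `sites` with the environmental columns appended.
#' @export
simulateEnv <- function(sites = gradientSiteDesign(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pars <- .envParameters()
  ngrp <- table(sites$gradient)
  bad <- setdiff(unique(sites$gradient), c("HEG", "MEG", "LEG"))
  if (length(bad))
    stop("unknown gradient group label: ", paste(bad, collapse = ", "))
  for (v in rownames(pars)) {
    mu <- pars[v, paste0(sites$gradient, "_mean")]
    se <- pars[v, paste0(sites$gradient, "_se")]
    sd_site <- se * sqrt(as.numeric(ngrp[sites$gradient]))
    sites[[v]] <- stats::rnorm(nrow(sites), mu, sd_site)
  }
  sites
}

#' Configuration for the synthetic gradient metacommunity
#'
#' Defaults emulate the study design: 13 sites in three elevational
#' gradients, per-sample read depth 22310, and 300/300/2400 taxa in the
#' specialist/generalist/neutral classes. Niche sigmas are in standardized
#' elevation units (the latent gradient is z-scored elevation); the
#' specialist sigma of 0.02 (~7 m of elevation) produces taxa effectively
#' confined to one site, while the generalist sigma of 50 spans the whole
#' gradient many times over. Neutral taxa draw regional lognormal
#' abundances dispersal-limited around a home site with exponential decay
#' per metre of transect distance.
#'
#' @param nSpecialist,nGeneralist,nNeutral taxa per class.
#' @param depth reads per sample.
#' @param sigmaSpecialist,sigmaGeneralist Gaussian niche breadths
#'   (standardized elevation units); must satisfy
#'   `sigmaSpecialist < sigmaGeneralist`.
#' @param dispersalDecay exponential dispersal decay rate for neutral taxa
#'   (per metre); 0 gives a single shared regional pool.
#' @param massFractions named numeric: share of total reads contributed by
#'   each class (specialist/generalist/neutral), summing to 1.
#' @param sdlog named numeric: lognormal sd of per-taxon abundance within
#'   each class.
#' @param layout "transect" keeps the slope coordinates; "random" scatters
#'   sites uniformly in the bounding box (spatial arrangement then carries
#'   no gradient information).
#' @param sites site design data.frame.
#' @return validated configuration list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nSpecialist = 300, nGeneralist = 300,
                             nNeutral = 2400, depth = 22310,
                             sigmaSpecialist = 0.02, sigmaGeneralist = 50,
                             dispersalDecay = 1 / 1000,
                             massFractions = c(specialist = 0.04,
                                               generalist = 0.45,
                                               neutral = 0.51),
                             sdlog = c(specialist = 0.8, generalist = 0.8,
                                       neutral = 1.5),
                             layout = c("transect", "random"),
                             sites = gradientSiteDesign()) {
  layout <- match.arg(layout)
  stopifnot(depth >= 1, sigmaSpecialist > 0,
            sigmaSpecialist < sigmaGeneralist,
            dispersalDecay >= 0,
            all(c("specialist", "generalist", "neutral") %in%
                names(massFractions)),
            abs(sum(massFractions) - 1) < 1e-8)
  if (nSpecialist + nGeneralist + nNeutral == 0)
    stop("at least one taxon class must be non-empty")
  structure(list(nSpecialist = nSpecialist, nGeneralist = nGeneralist,
                 nNeutral = nNeutral, depth = depth,
                 sigmaSpecialist = sigmaSpecialist,
                 sigmaGeneralist = sigmaGeneralist,
                 dispersalDecay = dispersalDecay,
                 massFractions = massFractions, sdlog = sdlog,
                 layout = layout, sites = sites),
            class = "SimulationConfig")
}

#' Simulate a gradient metacommunity with known assembly structure
#'
#' Builds expected per-site compositions from three taxon classes --
#' specialists with narrow Gaussian responses to the standardized
#' elevation gradient (optima centred on the sites themselves),
#' generalists with near-flat responses, and neutrally assembled taxa
#' whose site weights come from a regional lognormal pool thinned by
#' exponential dispersal decay with transect distance -- then draws reads
#' per sample from a multinomial at the configured depth, so column sums
#' equal the depth exactly (rarefied-table semantics).
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed; the draw is fully reproducible.
#' @return an [OTUExperiment-class] with simulated soil variables in
#'   `colData`, the truth channel (`class`, `optimum`, `sigma`) in
#'   `rowData`, and the expected composition matrix in
#'   `metadata(x)$expected`.
#' @export
simulateMetacommunity <- function(config = simulationConfig(), seed = 1) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(seed)
  sites <- simulateEnv(config$sites)
  n_site <- nrow(sites)
  if (config$layout == "random") {
    sites$x_m <- stats::runif(n_site, 0, max(config$sites$x_m))
    sites$y_m <- stats::runif(n_site, 0, max(config$sites$x_m) / 10)
  }
  z <- as.numeric(scale(sites$elevation_m))
  geo <- as.matrix(stats::dist(cbind(sites$x_m, sites$y_m)))

  blocks <- list(); truth <- list()
  if (config$nSpecialist > 0) {
    ns <- config$nSpecialist
    home <- sample.int(n_site, ns, replace = TRUE)
    opt <- z[home] + stats::rnorm(ns, 0, config$sigmaSpecialist / 2)
    h <- stats::rlnorm(ns, 0, config$sdlog[["specialist"]])
    w <- h * exp(-outer(opt, z, "-")^2 / (2 * config$sigmaSpecialist^2))
    blocks$specialist <- w
    truth$specialist <- data.frame(class = "specialist", optimum = opt,
                                   sigma = config$sigmaSpecialist)
  }
  if (config$nGeneralist > 0) {
    ng <- config$nGeneralist
    opt <- stats::runif(ng, min(z), max(z))
    h <- stats::rlnorm(ng, 0, config$sdlog[["generalist"]])
    w <- h * exp(-outer(opt, z, "-")^2 / (2 * config$sigmaGeneralist^2))
    blocks$generalist <- w
    truth$generalist <- data.frame(class = "generalist", optimum = opt,
                                   sigma = config$sigmaGeneralist)
  }
  if (config$nNeutral > 0) {
    nn <- config$nNeutral
    origin <- sample.int(n_site, nn, replace = TRUE)
    a <- stats::rlnorm(nn, 0, config$sdlog[["neutral"]])
    w <- a * exp(-config$dispersalDecay * geo[origin, , drop = FALSE])
    blocks$neutral <- w
    truth$neutral <- data.frame(class = rep("neutral", nn),
                                optimum = NA_real_, sigma = NA_real_)
  }

  # rescale each class block to its configured share of total mass
  for (cl in names(blocks)) {
    s <- sum(blocks[[cl]])
    if (s > 0)
      blocks[[cl]] <- blocks[[cl]] * config$massFractions[[cl]] / s
  }
  W <- do.call(rbind, blocks)
  truth <- do.call(rbind, truth)
  ids <- sprintf("OTU%05d", seq_len(nrow(W)))
  dimnames(W) <- list(ids, sites$sample_id)
  rownames(truth) <- ids

  expected <- sweep(W, 2, colSums(W), "/")
  counts <- vapply(seq_len(n_site), function(i)
    stats::rmultinom(1, config$depth, expected[, i])[, 1],
    numeric(nrow(W)))
  dimnames(counts) <- dimnames(expected)

  out <- OTUExperiment(counts,
                       sampleData = data.frame(sites,
                                               row.names = sites$sample_id),
                       taxonData = truth)
  metadata(out)$expected <- expected
  metadata(out)$seed <- seed
  out
}

#' Ground-truth class labels of a simulated metacommunity
#'
#' @param x an [OTUExperiment-class] from [simulateMetacommunity()].
#' @return named character vector of true classes
#'   (specialist/generalist/neutral).
#' @export
groundTruthClasses <- function(x) {
  rd <- rowData(x)
  if (!"class" %in% colnames(rd))
    stop("no ground-truth channel: not a simulated metacommunity")
  stats::setNames(as.character(rd$class), rownames(x))
}
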