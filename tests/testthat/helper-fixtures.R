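# shared fixture builders (all generated in code; no data files)

makeTable <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- paste0("OTU", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  OTUExperiment(m, ...)
}

# scaled-down simulation settings used where a test needs many replicates
smallConfig <- function(nSpecialist = 40, nGeneralist = 40, nNeutral = 120,
                        depth = 2000, ...) {
  simulationConfig(nSpecialist = nSpecialist, nGeneralist = nGeneralist,
                   nNeutral = nNeutral, depth = depth, ...)
}

# random count table with all samples non-empty
randomTable <- function(ntaxa, nsamp, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(ntaxa * nsamp, lambda), ntaxa, nsamp)
  m[1, ] <- m[1, ] + 1
  makeTable(m)
}
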