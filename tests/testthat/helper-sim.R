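# Small, fast simulated studies shared across test files.

tinyParams <- function(...) {
  args <- list(...)
  defaults <- list(genomeLength = 5e4, organelleLength = 8000, nGenes = 6,
                   nSpikes = 5, nReplicates = 3, seed = 11)
  do.call(simulationParams, utils::modifyList(defaults, args))
}

# memoised medium simulation used by several files (built once per run)
.simCache <- new.env()
mediumSim <- function() {
  if (!is.null(.simCache$sim)) return(.simCache$sim)
  p <- simulationParams(genomeLength = 3e5, organelleLength = 20000,
                        nGenes = 40, nSpikes = 30, seed = 7)
  g <- simulateGenome(p)
  pair <- simulateMethylomePair(g$genome, g$genes, p)
  .simCache$sim <- list(params = p, genome = g$genome, genes = g$genes,
                        pair = pair)
  .simCache$sim
}

# the full-scale study: 1 Mb nuclear genome, 25x negative-binomial coverage,
# non-conversion 0.005, 100 spiked 100-bp regions at |delta| = 0.4
bigSim <- function() {
  if (!is.null(.simCache$big)) return(.simCache$big)
  p <- simulationParams(seed = 42)
  g <- simulateGenome(p)
  pair <- simulateMethylomePair(g$genome, g$genes, p)
  .simCache$big <- list(params = p, genome = g$genome, genes = g$genes,
                        pair = pair)
  .simCache$big
}
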