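test_that("gene models respect bounds and packing constraints", {
  p <- tinyParams(genomeLength = 1e5, nGenes = 20, seed = 7)
  g <- simulateGenome(p)
  gr <- geneRanges(g$genes)
  expect_equal(length(gr), 20L)
  lens <- GenomeInfoDb::seqlengths(gr)
  chr <- as.character(GenomicRanges::seqnames(gr))
  expect_true(all(GenomicRanges::start(gr) >= 1))
  expect_true(all(GenomicRanges::end(gr) <= lens[chr]))
  # non-overlapping genes
  o <- order(GenomicRanges::start(gr))
  expect_true(all(GenomicRanges::start(gr)[o][-1] >
                    GenomicRanges::end(gr)[o][-length(gr)]))
  # organelle surrogate carries no genes
  expect_false("chrC" %in% chr)
  # impossible packing errors out
  expect_error(simulateGenome(tinyParams(genomeLength = 2e4, nGenes = 50)),
               "pack")
})

test_that("identical seeds give byte-identical simulated studies", {
  run <- function(dir) {
    p <- tinyParams(genomeLength = 3e4, organelleLength = 4000, nGenes = 4,
                    nSpikes = 4, seed = 13)
    g <- simulateGenome(p)
    pair <- simulateMethylomePair(g$genome, g$genes, p)
    expr <- simulateExpression(g$genes, pair$truth, p)
    writeSimulation(list(genome = g$genome, genes = g$genes, pair = pair,
                         expr = expr), dir)
    dir
  }
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run(d1); run(d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("degenerate GC composition produces a G/C-only genome", {
  p <- tinyParams(genomeLength = 12000, organelleLength = 2000, nGenes = 1,
                  gcFraction = 1.0, seed = 2)
  g <- simulateGenome(p)
  freq <- Biostrings::alphabetFrequency(g$genome[["chr1"]])
  expect_equal(sum(freq[c("A", "T")]), 0)
  expect_equal(sum(freq[c("G", "C")]),
               length(g$genome[["chr1"]]))
})

test_that("organelle methylome reflects pure non-conversion noise", {
  sim <- mediumSim()
  s <- methSites(sim$pair$control)
  onC <- as.character(GenomicRanges::seqnames(s)) == "chrC"
  mc <- S4Vectors::mcols(s)
  nReads <- sum(mc$total[onC])
  frac <- sum(mc$meth[onC]) / nReads
  se <- sqrt(0.005 * 0.995 / nReads)
  expect_lt(abs(frac - 0.005), 3 * se)
  # and the ground truth says level zero everywhere there
  tl <- sim$pair$truth$siteLevels
  expect_true(all(tl[tl$chrom == "chrC", ]$levelControl == 0))
})

test_that("spiked regions shift the observed level by their delta", {
  sim <- mediumSim()
  reg <- sim$pair$truth$regions[sim$pair$truth$regions$type == "spike", ]
  bins <- filterBins(tileAndPool(sim$pair$treatment, sim$pair$control))
  got <- merge(bins, reg[, c("chrom", "start", "delta")],
               by = c("chrom", "start"))
  expect_gt(nrow(got), 50)  # spikes x contexts present in pooled bins
  diffs <- got$levelT - got$levelC
  # each bin's observed difference tracks its spike's sign and size
  expect_gt(cor(diffs, got$delta), 0.95)
  # per-bin deviations are pooled-binomial noise; bulk stays close to delta
  expect_lt(unname(quantile(abs(diffs - got$delta), 0.9)), 0.15)
  expect_lt(abs(mean(diffs - got$delta)), 0.02)
})

test_that("coverage and baseline levels follow the requested model", {
  sim <- mediumSim()
  s <- methSites(sim$pair$control)
  mc <- S4Vectors::mcols(s)
  # zero-depth sites are dropped, so correct the observed mean for the
  # truncation of the negative binomial at zero
  p0 <- dnbinom(0, mu = sim$params$coverageMean,
                size = sim$params$coverageDispersion)
  expect_lt(abs(mean(mc$total) - sim$params$coverageMean / (1 - p0)) /
              sim$params$coverageMean, 0.05)
  # unspiked bins: treatment - control level differences centred at zero
  bins <- tileAndPool(sim$pair$treatment, sim$pair$control)
  reg <- sim$pair$truth$regions
  spiked <- paste(reg$chrom, reg$start)
  nul <- bins[!paste(bins$chrom, bins$start) %in% spiked]
  expect_lt(abs(mean(nul$levelT - nul$levelC)), 0.01)
})

test_that("observed levels are unbiased for the error-model expectation", {
  sim <- mediumSim()
  s <- methSites(sim$pair$control)
  mc <- S4Vectors::mcols(s)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(s)),
    pos = GenomicRanges::start(s),
    strand = as.character(GenomicRanges::strand(s)),
    obs = mc$meth / mc$total, total = mc$total)
  tl <- sim$pair$truth$siteLevels
  j <- merge(dt, tl, by = c("chrom", "pos", "strand"))
  expect_gt(nrow(j), 1e4)
  expected <- j$levelControl + (1 - j$levelControl) * 0.005
  fit <- lm(j$obs ~ expected, weights = j$total)
  ci <- confint(fit, "expected", level = 0.999)
  expect_gt(1, ci[1]); expect_lt(1, ci[2])
})

test_that("simulated CpG methylation is strand-symmetric at baseline", {
  sim <- mediumSim()
  tl <- sim$pair$truth$siteLevels
  cg <- tl[tl$context == "CG" & tl$chrom == "chr1", ]
  w <- cg[cg$strand == "+", ]
  c <- cg[cg$strand == "-", ]
  c$pos <- c$pos - 1L
  j <- merge(w, c, by = c("chrom", "pos"))
  reg <- sim$pair$truth$regions
  inSpike <- rep(FALSE, nrow(j))
  for (i in seq_len(nrow(reg)))
    inSpike <- inSpike | (j$pos >= reg$start[i] - 1 & j$pos <= reg$end[i])
  j <- j[!inSpike, ]
  expect_gt(nrow(j), 1000)
  expect_equal(j$levelControl.x, j$levelControl.y)
})

test_that("expression linkage follows the promoter-methylation model", {
  p <- tinyParams(seed = 5)
  g <- simulateGenome(p)
  pair <- simulateMethylomePair(g$genome, g$genes, p)
  expr <- simulateExpression(g$genes, pair$truth, p)
  expect_equal(dim(expr$fpkm), c(6L, 6L))
  # deterministic under the seed
  expr2 <- simulateExpression(g$genes, pair$truth, p)
  expect_identical(expr$fpkm, expr2$fpkm)
  # expected log2 fold change: -slope * promoterDelta = -2 * -0.5 = +1 for
  # linked genes, 0 for unlinked (checked in expectation over replicates)
  lfc <- rowMeans(log2(expr$fpkm[, 4:6])) - rowMeans(log2(expr$fpkm[, 1:3]))
  linked <- rownames(expr$fpkm) %in% pair$truth$linkedGenes$gene_id
  expect_true(all(abs(lfc[linked] - 1) < 0.8))
  expect_true(all(abs(lfc[!linked]) < 0.8))
  # fewer than two replicates is an error
  expect_error(simulateExpression(g$genes, pair$truth,
                                  tinyParams(nReplicates = 1)),
               "nReplicates")
})

test_that("every spiked region covers cytosines of its stated context", {
  sim <- mediumSim()
  reg <- sim$pair$truth$regions
  tl <- sim$pair$truth$siteLevels
  for (i in seq_len(nrow(reg))) {
    sub <- tl[tl$chrom == reg$chrom[i] & tl$pos >= reg$start[i] &
                tl$pos <= reg$end[i], ]
    if (reg$context[i] != "all")
      sub <- sub[sub$context == reg$context[i], ]
    expect_gt(nrow(sub), 0)
  }
})
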