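mkPair <- function(df) {
  # df: chrom, pos, strand, context, methT, totalT, methC, totalC
  mk <- function(meth, total, cond, id) {
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$pos, width = 1L), strand = df$strand,
      context = df$context, meth = as.integer(meth),
      total = as.integer(total))
    Methylome(gr, sampleId = id, condition = cond)
  }
  list(treatment = mk(df$methT, df$totalT, "stress", "T"),
       control = mk(df$methC, df$totalC, "control", "C"))
}

test_that("tiling uses fixed 100-bp bins with the floor rule", {
  df <- data.frame(chrom = "chr1", pos = c(100, 101, 199, 200, 201),
                   strand = "+", context = "CHH",
                   methT = 5L, totalT = 10L, methC = 5L, totalC = 10L)
  pr <- mkPair(df)
  bins <- tileAndPool(pr$treatment, pr$control)
  # 0-based bin of pos0 = pos-1: 99 -> [0,100); 100,198,199 -> [100,200);
  # 200 -> [200,300). In 1-based terms: [1,100], [101,200], [201,300].
  expect_equal(bins$start, c(1, 101, 201))
  expect_equal(bins$nCytosines, c(1L, 3L, 1L))
  expect_equal(bins$end - bins$start + 1L, rep(100L, 3))
})

test_that("only sites assayed in both samples are pooled", {
  t <- mkPair(data.frame(chrom = "chr1", pos = c(10, 20), strand = "+",
                         context = "CG", methT = 1L, totalT = 10L,
                         methC = 1L, totalC = 10L))$treatment
  c <- mkPair(data.frame(chrom = "chr1", pos = c(20, 30), strand = "+",
                         context = "CG", methT = 2L, totalT = 10L,
                         methC = 2L, totalC = 10L))$control
  bins <- tileAndPool(t, c)
  expect_equal(nrow(bins), 1L)         # only pos 20 shared
  expect_equal(bins$nCytosines, 1L)
  # mismatched chromosome sets warn and use the intersection
  c2 <- mkPair(data.frame(chrom = "chr9", pos = 20, strand = "+",
                          context = "CG", methT = 1L, totalT = 10L,
                          methC = 1L, totalC = 10L))$control
  expect_warning(b2 <- tileAndPool(t, c2), "intersection")
  expect_equal(nrow(b2), 0L)
})

test_that("bin filters enforce depth in both samples and cytosine count", {
  bins <- data.table::data.table(
    chrom = "chr1", start = c(1, 101, 201), end = c(100, 200, 300),
    context = "CHH", nCytosines = c(2L, 3L, 3L),
    methT = 10L, unmethT = 10L, methC = 10L, unmethC = 10L,
    levelT = 0.5, levelC = 0.5,
    meanDepthT = c(25, 25, 25), meanDepthC = c(25, 4.9, 25))
  kept <- filterBins(bins)
  expect_equal(kept$start, 201)        # row 1: too few C; row 2: depth
  expect_equal(nrow(filterBins(bins, minDepth = 4, minCytosines = 2)), 3L)
})

test_that("bin Fisher test and BH control behave as exact statistics", {
  bins <- data.table::data.table(
    chrom = "chr1", start = c(1, 101, 201), end = c(100, 200, 300),
    context = "CHH", nCytosines = 3L,
    methT = c(8L, 5L, 10L), unmethT = c(2L, 5L, 0L),
    methC = c(2L, 5L, 0L), unmethC = c(8L, 5L, 10L),
    meanDepthT = 25, meanDepthC = 25)
  bins[, `:=`(levelT = methT / (methT + unmethT),
              levelC = methC / (methC + unmethC))]
  fb <- fisherBinTest(bins)
  expect_equal(fb$pValue, c(0.023014137565, 1, 2 / choose(20, 10)),
               tolerance = 1e-9)
  out <- callDMRs(fb, dmcs = NULL, allBins = TRUE)
  expect_true(all(out$qValue >= out$pValue))
  expect_equal(out$qValue[out$pValue == 1], 1)
  # single test: q equals p
  one <- callDMRs(fisherBinTest(bins[3]), dmcs = NULL, allBins = TRUE)
  expect_equal(one$qValue, one$pValue)
})

test_that("DMR thresholds: difference, fold, q and DmC support", {
  base <- data.table::data.table(
    chrom = "chr1", start = 1, end = 100, context = "CHH", nCytosines = 5L,
    meanDepthT = 25, meanDepthC = 25)
  mk <- function(mT, uT, mC, uC) {
    b <- data.table::copy(base)
    b[, `:=`(methT = mT, unmethT = uT, methC = mC, unmethC = uC,
             levelT = mT / (mT + uT), levelC = mC / (mC + uC))]
    fisherBinTest(b)
  }
  # passes everything: 0.80 vs 0.20 -> diff 0.6, fold 4
  strong <- mk(80L, 20L, 20L, 80L)
  d <- callDMRs(strong, dmcs = NULL)
  expect_equal(nrow(d), 1L)
  expect_equal(d$direction, "hyper")
  expect_equal(d$levelDiff, 0.6)
  expect_equal(d$fold, 4)
  # diff 0.15 < 0.20: rejected despite tiny p
  expect_equal(nrow(callDMRs(mk(450L, 550L, 300L, 700L), dmcs = NULL)), 0L)
  # fold 0.50/0.28 = 1.79 < 2: rejected
  expect_equal(nrow(callDMRs(mk(500L, 500L, 280L, 720L), dmcs = NULL)), 0L)
  # with a DmC table attached, the >= 3 DmC rule is a post-filter
  noDmc <- data.table::data.table(chrom = "chr1", pos = 50L,
                                  context = "CHH", isDmC = TRUE)
  expect_equal(nrow(callDMRs(strong, dmcs = noDmc, minDmcs = 3)), 0L)
  threeDmc <- data.table::data.table(chrom = "chr1", pos = c(10L, 50L, 90L),
                                     context = "CHH", isDmC = TRUE)
  expect_equal(callDMRs(strong, dmcs = threeDmc, minDmcs = 3)$nDmcs, 3L)
})

test_that("per-site DmC calls apply depth, q and difference rules", {
  df <- data.frame(chrom = "chr1", pos = c(10, 20, 30), strand = "+",
                   context = "CHH",
                   methT = c(5L, 20L, 2L), totalT = c(10L, 20L, 20L),
                   methC = c(5L, 0L, 2L), totalC = c(10L, 20L, 3L))
  pr <- mkPair(df)
  dm <- callDmCs(pr$treatment, pr$control, minDepth = 5)
  # pos 30 skipped: control depth 3 < 5
  expect_equal(dm$pos, c(10L, 20L))
  # identical counts: not a DmC
  expect_false(dm$isDmC[dm$pos == 10])
  # 20/20 vs 0/20: extreme table, p = 2 / C(40,20)
  expect_equal(dm$pValue[dm$pos == 20], 2 / choose(40, 20), tolerance = 1e-12)
  expect_true(dm$isDmC[dm$pos == 20])
  expect_equal(dm$direction[dm$pos == 20], "hyper")
})

test_that("swapping treatment and control inverts every DMR direction with
           identical statistics", {
  sim <- mediumSim()
  bins1 <- fisherBinTest(filterBins(tileAndPool(sim$pair$treatment,
                                                sim$pair$control)))
  bins2 <- fisherBinTest(filterBins(tileAndPool(sim$pair$control,
                                                sim$pair$treatment)))
  d1 <- callDMRs(bins1, dmcs = NULL)
  d2 <- callDMRs(bins2, dmcs = NULL)
  expect_gt(nrow(d1), 20)
  expect_equal(nrow(d1), nrow(d2))
  key <- function(d) paste(d$chrom, d$start, d$context)
  expect_identical(key(d1), key(d2))
  o <- match(key(d1), key(d2))
  expect_identical(d1$pValue, d2$pValue[o])
  expect_identical(d1$qValue, d2$qValue[o])
  expect_identical(d1$direction,
                   ifelse(d2$direction[o] == "hyper", "hypo", "hyper"))
  expect_equal(d1$levelDiff, -d2$levelDiff[o])
})

test_that("hyper and hypo DMRs partition the called set by context", {
  sim <- mediumSim()
  bins <- fisherBinTest(filterBins(tileAndPool(sim$pair$treatment,
                                               sim$pair$control)))
  dmcs <- callDmCs(sim$pair$treatment, sim$pair$control)
  d <- callDMRs(bins, dmcs)
  expect_gt(nrow(d), 0)
  expect_equal(sum(d$direction == "hyper") + sum(d$direction == "hypo"),
               nrow(d))
  expect_false(any(duplicated(paste(d$chrom, d$start, d$context))))
})

test_that("four-way membership partition is exact set algebra", {
  mkSet <- function(starts) data.table::data.table(
    chrom = "chr1", start = starts, end = starts + 99,
    context = "CHH", direction = "hyper")
  A <- mkSet(c(1, 101)); B <- mkSet(c(101, 201))
  C <- mkSet(numeric(0)); D <- mkSet(numeric(0))
  pt <- fourwayPartition(list(A = A, B = B, C = C, D = D))
  expect_equal(attr(pt, "unionSize"), 3L)
  expect_equal(pt$count[pt$members == "A"], 1L)
  expect_equal(pt$count[pt$members == "B"], 1L)
  expect_equal(pt$count[pt$members == "A+B"], 1L)
  # identical sets: all mass in the four-way intersection
  pt2 <- fourwayPartition(list(A = A, B = A, C = A, D = A))
  expect_equal(pt2$members, "A+B+C+D")
  expect_equal(pt2$count, 2L)
  # disjoint sets: exclusive counts, union = sum of sizes
  sets <- list(A = mkSet(seq(1, 101, 100)),
               B = mkSet(seq(1001, 1201, 100)),
               C = mkSet(seq(2001, 2301, 100)),
               D = mkSet(seq(3001, 3401, 100)))
  pt3 <- fourwayPartition(sets)
  expect_equal(attr(pt3, "unionSize"), 14L)
  expect_equal(sum(pt3$count), 14L)
  expect_equal(pt3$count[order(pt3$members)], c(2L, 3L, 4L, 5L))
})

test_that("spiked DMRs are recovered with controlled false discovery", {
  sim <- mediumSim()
  bins <- fisherBinTest(filterBins(tileAndPool(sim$pair$treatment,
                                               sim$pair$control)))
  dmcs <- callDmCs(sim$pair$treatment, sim$pair$control)
  d <- callDMRs(bins, dmcs)
  reg <- sim$pair$truth$regions
  overlapsTruth <- function(chrom, start, end) {
    hit <- rep(FALSE, length(start))
    for (i in seq_len(nrow(reg)))
      hit <- hit | (chrom == reg$chrom[i] & start <= reg$end[i] &
                      end >= reg$start[i])
    hit
  }
  # recall over bin-aligned spiked bins that survive the filters
  spk <- reg[reg$type == "spike", ]
  spikedKey <- paste(spk$chrom, spk$start)
  binKey <- paste(bins$chrom, bins$start)
  dmrKey <- paste(d$chrom, d$start)
  eligible <- spikedKey[spikedKey %in% binKey]
  expect_gt(length(eligible), 20)
  recall <- mean(eligible %in% dmrKey)
  expect_gte(recall, 0.8)
  # empirical false discovery among bins touching no true region at all
  falsePos <- sum(!overlapsTruth(d$chrom, d$start, d$end))
  expect_lte(falsePos / max(nrow(d), 1), 0.10)
})
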