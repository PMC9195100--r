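#' Parameters for the synthetic WGBS study
#'
#' Bundles every knob of the synthetic data generator. Defaults emulate the
#' study conditions the pipeline is designed for: ~25x mean coverage with
#' negative-binomial site-to-site variation, a non-conversion rate of 0.005
#' (i.e. >99.5% bisulfite conversion, measured on an unmethylated organelle
#' surrogate chromosome), per-context baseline methylation mixtures giving
#' CG > CHG > CHH mean levels and a genome-wide methylated-cytosine
#' fraction in the low-to-mid teens of percent, and 100 spiked 100-bp
#' regions whose treatment-vs-control level shift is +/-0.4.
#'
#' @param genomeLength total nuclear genome length in bases (default 1e6).
#' @param gcFraction G+C fraction of the simulated sequence (default 0.44).
#' @param nChroms number of chromosomes including the organelle surrogate
#'   (default 2: one nuclear + `chrC`).
#' @param organelleLength length of the unmethylated organelle chromosome
#'   (default 30000).
#' @param nGenes number of gene models on the nuclear chromosomes
#'   (default 120).
#' @param geneSpan min/max gene span in bases (default c(1000, 5000)).
#' @param minGeneGap minimum intergenic gap in bases (default 2000).
#' @param coverageMean mean per-site read depth (default 25).
#' @param coverageDispersion negative-binomial size parameter (default 5).
#' @param contextLevels per-context two-component beta mixtures for the
#'   baseline true methylation level: a list with elements `CG`, `CHG`,
#'   `CHH`, each `list(w =, shape1 =, shape2 =)` of length-2 vectors.
#' @param nonconversionRate fraction of unmethylated cytosines escaping
#'   conversion (default 0.005).
#' @param nSpikes number of spiked differentially methylated regions
#'   (default 100).
#' @param spikeDelta absolute true level shift of each spike (default 0.4;
#'   signs alternate between spikes).
#' @param spikeContext `"all"` (default) or a single context; a spike only
#'   shifts cytosines of its stated context.
#' @param spikes optional explicit spike table (`chrom`, `start`, `end`,
#'   `context`, `delta`, 1-based inclusive) overriding automatic placement.
#' @param linkedGeneFraction fraction of genes whose expression responds to
#'   promoter methylation (default 0.3).
#' @param promoterDelta true level shift applied to linked genes' proximal
#'   promoters (default -0.5, i.e. hypomethylation under treatment).
#' @param expressionEffectSlope log2 expression change per unit promoter
#'   methylation decrease (default 2; promoter hypomethylation raises
#'   expression).
#' @param expressionNoiseSd replicate noise sd on the log2 scale
#'   (default 0.25).
#' @param nReplicates expression replicates per condition (default 3).
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @return a validated list of class `SimulationParams`.
#' @export
simulationParams <- function(genomeLength = 1e6,
                             gcFraction = 0.44,
                             nChroms = 2,
                             organelleLength = 30000,
                             nGenes = 120,
                             geneSpan = c(1000, 5000),
                             minGeneGap = 1000,
                             coverageMean = 25,
                             coverageDispersion = 5,
                             contextLevels = NULL,
                             nonconversionRate = 0.005,
                             nSpikes = 100,
                             spikeDelta = 0.4,
                             spikeContext = "all",
                             spikes = NULL,
                             linkedGeneFraction = 0.3,
                             promoterDelta = -0.5,
                             expressionEffectSlope = 2,
                             expressionNoiseSd = 0.25,
                             nReplicates = 3,
                             seed = 1) {
  if (is.null(contextLevels)) {
    contextLevels <- list(
      CG  = list(w = c(0.76, 0.24), shape1 = c(0.6, 18), shape2 = c(25, 2)),
      CHG = list(w = c(0.85, 0.15), shape1 = c(0.6, 6),  shape2 = c(25, 4)),
      CHH = list(w = c(0.94, 0.06), shape1 = c(0.5, 3),  shape2 = c(40, 12))
    )
  }
  p <- list(genomeLength = genomeLength, gcFraction = gcFraction,
            nChroms = as.integer(nChroms), organelleLength = organelleLength,
            nGenes = as.integer(nGenes), geneSpan = geneSpan,
            minGeneGap = minGeneGap, coverageMean = coverageMean,
            coverageDispersion = coverageDispersion,
            contextLevels = contextLevels,
            nonconversionRate = nonconversionRate,
            nSpikes = as.integer(nSpikes), spikeDelta = spikeDelta,
            spikeContext = spikeContext, spikes = spikes,
            linkedGeneFraction = linkedGeneFraction,
            promoterDelta = promoterDelta,
            expressionEffectSlope = expressionEffectSlope,
            expressionNoiseSd = expressionNoiseSd,
            nReplicates = as.integer(nReplicates), seed = as.integer(seed))
  stopifnot(
    genomeLength >= 10000,
    gcFraction > 0, gcFraction <= 1,
    nChroms >= 2,
    nonconversionRate >= 0, nonconversionRate <= 1,
    linkedGeneFraction >= 0, linkedGeneFraction <= 1,
    coverageMean > 0, coverageDispersion > 0,
    abs(spikeDelta) <= 1, abs(promoterDelta) <= 1,
    length(geneSpan) == 2, geneSpan[1] <= geneSpan[2]
  )
  class(p) <- "SimulationParams"
  p
}

# deterministic sub-seeds (< 2^31) derived from the master seed
.subSeed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

#' Simulate a reference genome and gene models
#'
#' Draws i.i.d. bases at the requested GC fraction for `nChroms - 1`
#' nuclear chromosomes (`chr1`, `chr2`, ...) plus an unmethylated organelle
#' surrogate (`chrC`, which carries no genes), and places non-overlapping
#' gene models with 1-5 exons, strand assigned at random, and short
#' terminal UTRs on sufficiently long first/last exons.
#'
#' @param params a [simulationParams()] object.
#' @return list with elements `genome` ([Biostrings::DNAStringSet]) and
#'   `genes` ([GeneModelSet-class]).
#' @export
simulateGenome <- function(params) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(.subSeed(params$seed, 1L))
  gc <- params$gcFraction
  baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  nNuc <- params$nChroms - 1L
  nucLen <- rep(floor(params$genomeLength / nNuc), nNuc)
  nucLen[1] <- nucLen[1] + params$genomeLength - sum(nucLen)
  lens <- c(nucLen, params$organelleLength)
  chroms <- c(paste0("chr", seq_len(nNuc)), "chrC")
  seqs <- vapply(lens, function(L)
    paste(sample(names(baseProb), L, replace = TRUE, prob = baseProb),
          collapse = ""), character(1))
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))

  # distribute genes over nuclear chromosomes proportional to length
  ng <- params$nGenes
  alloc <- diff(round(cumsum(c(0, nucLen / sum(nucLen))) * ng))
  gap <- params$minGeneGap
  rows <- list()
  for (i in seq_len(nNuc)) {
    k <- alloc[i]
    if (k == 0) next
    spans <- sample(seq(params$geneSpan[1], params$geneSpan[2]), k,
                    replace = TRUE)
    slack <- nucLen[i] - sum(spans) - (k + 1) * gap
    if (slack < 0)
      stop("cannot pack ", k, " genes of the requested span into ",
           chroms[i], " (", nucLen[i], " bp); reduce nGenes or geneSpan")
    cuts <- sort(runif(k))
    extra <- floor(c(cuts, 1) * slack) - floor(c(0, cuts) * slack)
    starts <- gap + cumsum(extra[seq_len(k)] + c(0, spans[-k] + gap)) + 1
    rows[[i]] <- data.table::data.table(
      chrom = chroms[i], start = starts, end = starts + spans - 1,
      strand = sample(c("+", "-"), k, replace = TRUE))
  }
  gdt <- data.table::rbindlist(rows)
  gdt[, gene_id := sprintf("gene%03d", seq_len(.N))]

  genes <- GenomicRanges::GRanges(
    gdt$chrom, IRanges::IRanges(gdt$start, gdt$end), strand = gdt$strand,
    seqinfo = GenomeInfoDb::Seqinfo(chroms, seqlengths = lens))
  names(genes) <- gdt$gene_id

  exL <- vector("list", nrow(gdt)); u5L <- exL; u3L <- exL
  for (j in seq_len(nrow(gdt))) {
    span <- gdt$end[j] - gdt$start[j] + 1
    maxEx <- max(1L, min(5L, span %/% 300L))
    nex <- sample.int(maxEx, 1L)
    nseg <- 2L * nex - 1L
    w <- runif(nseg, 0.5, 1.5)
    segs <- pmax(50L, floor(w / sum(w) * span))
    segs[1] <- segs[1] + span - sum(segs)  # absorb rounding in first exon
    bounds <- gdt$start[j] + cumsum(c(0L, segs))
    segStart <- bounds[seq_len(nseg)]
    segEnd <- bounds[-1L] - 1L
    exIdx <- seq(1L, nseg, by = 2L)
    ex <- GenomicRanges::GRanges(gdt$chrom[j],
                                 IRanges::IRanges(segStart[exIdx], segEnd[exIdx]),
                                 strand = gdt$strand[j])
    exL[[j]] <- ex
    firstEx <- if (gdt$strand[j] == "+") ex[1] else ex[length(ex)]
    lastEx <- if (gdt$strand[j] == "+") ex[length(ex)] else ex[1]
    mk <- function(e, atStart) {
      if (GenomicRanges::width(e) < 150) return(GenomicRanges::GRanges())
      if (atStart)
        GenomicRanges::GRanges(gdt$chrom[j],
          IRanges::IRanges(GenomicRanges::start(e),
                           GenomicRanges::start(e) + 49L),
          strand = gdt$strand[j])
      else
        GenomicRanges::GRanges(gdt$chrom[j],
          IRanges::IRanges(GenomicRanges::end(e) - 49L,
                           GenomicRanges::end(e)),
          strand = gdt$strand[j])
    }
    if (gdt$strand[j] == "+") {
      u5L[[j]] <- mk(firstEx, TRUE); u3L[[j]] <- mk(lastEx, FALSE)
    } else {
      u5L[[j]] <- mk(firstEx, FALSE); u3L[[j]] <- mk(lastEx, TRUE)
    }
  }
  nm <- gdt$gene_id
  asGL <- function(lst) {
    gl <- GenomicRanges::GRangesList(lst)
    names(gl) <- nm
    gl
  }
  gms <- GeneModelSet(genes, exons = asGL(exL), utr5 = asGL(u5L),
                      utr3 = asGL(u3L))
  list(genome = genome, genes = gms)
}

.drawMixtureLevels <- function(n, mix) {
  comp <- sample.int(length(mix$w), n, replace = TRUE, prob = mix$w)
  stats::rbeta(n, mix$shape1[comp], mix$shape2[comp])
}

# Spike placement: nSpikes distinct bin-aligned 100-bp regions on nuclear
# chromosomes, avoiding the linked genes' promoter spikes; alternating sign.
.autoSpikes <- function(params, genome, promoterSpikes) {
  nucChroms <- setdiff(names(genome), "chrC")
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  cand <- data.table::rbindlist(lapply(nucChroms, function(ch) {
    nb <- lens[[ch]] %/% 100L
    data.table::data.table(chrom = ch, start = (seq_len(nb) - 1L) * 100L + 1L)
  }))
  cand[, end := start + 99L]
  if (nrow(promoterSpikes)) {
    data.table::setkey(promoterSpikes, chrom, start, end)
    ov <- data.table::foverlaps(cand, promoterSpikes,
                                by.x = c("chrom", "start", "end"),
                                which = TRUE, nomatch = NULL)
    if (nrow(ov)) cand <- cand[-unique(ov$xid)]
  }
  pick <- cand[sample.int(nrow(cand), params$nSpikes)]
  pick[, context := params$spikeContext]
  pick[, delta := params$spikeDelta * rep_len(c(1, -1), .N)]
  pick[, type := "spike"]
  pick[, gene_id := NA_character_]
  data.table::setorder(pick, chrom, start)
  pick[]
}

#' Simulate a paired treatment/control methylome with known spiked DMRs
#'
#' Every resolvable cytosine of the genome (both strands) receives a true
#' baseline methylation level drawn from its context's beta mixture (CG
#' sites strand-symmetric: both cytosines of a CpG share one level;
#' CHG/CHH independent per strand); the organelle surrogate `chrC` is
#' truly unmethylated everywhere. Inside each spiked region the control
#' baseline is redrawn uniformly so that `base + delta` stays within
#' [0.05, 0.95], and the treatment level is exactly `base + delta`;
#' a fraction of genes additionally get a promoter spike
#' ([TSS-200, TSS)) whose shift later drives their expression. Observed
#' counts are then drawn per sample: depth ~ NegBinom(mean, dispersion)
#' and methylated reads ~ Binomial(depth, level + (1-level) *
#' nonconversion) - methylated cytosines are treated as fully protected
#' from conversion, so only non-conversion of unmethylated cytosines
#' inflates the signal.
#'
#' @param genome,genes output of [simulateGenome()] (`genes` may be the
#'   [GeneModelSet-class] itself).
#' @param params a [simulationParams()] object.
#' @return list: `control` and `treatment` ([Methylome-class], sites with
#'   zero coverage dropped), and `truth` - a list with `siteLevels`
#'   (data.table of every site's true level per condition), `regions`
#'   (spiked regions with `delta`, `direction`, `type`, `gene_id`) and
#'   `linkedGenes` (gene id, promoter delta, expression effect sign).
#' @export
simulateMethylomePair <- function(genome, genes, params) {
  stopifnot(inherits(params, "SimulationParams"))
  gms <- if (is(genes, "GeneModelSet")) genes else genes$genes
  set.seed(.subSeed(params$seed, 2L))

  sites <- cytosineContexts(genome)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(sites)),
    pos = GenomicRanges::start(sites),
    strand = as.character(GenomicRanges::strand(sites)),
    context = S4Vectors::mcols(sites)$context,
    dinucleotide = S4Vectors::mcols(sites)$dinucleotide)

  # baseline true levels
  dt[, level := 0]
  for (ctx in c("CG", "CHG", "CHH")) {
    idx <- which(dt$context == ctx & dt$chrom != "chrC")
    dt$level[idx] <- .drawMixtureLevels(length(idx),
                                        params$contextLevels[[ctx]])
  }
  # strand-symmetric CpG: copy the Watson CG level onto the paired Crick C
  w <- dt[context == "CG" & strand == "+" & chrom != "chrC",
          .(chrom, pos, level)]
  w[, pos := pos + 1L]
  dt[w, on = c("chrom", "pos"),
     level := ifelse(context == "CG" & strand == "-", i.level, level)]

  # linked genes and their promoter spikes
  nLinked <- round(params$linkedGeneFraction * length(geneIds(gms)))
  linked <- sort(sample(geneIds(gms), nLinked))
  g <- geneRanges(gms)[linked]
  strnd <- as.character(GenomicRanges::strand(g))
  tssP <- ifelse(strnd == "+", GenomicRanges::start(g),
                 GenomicRanges::end(g))
  promStart <- ifelse(strnd == "+", tssP - 200L, tssP + 1L)
  promoterSpikes <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = pmax(1L, as.integer(promStart)),
    end = as.integer(promStart) + 199L,
    context = "all", delta = params$promoterDelta,
    type = "promoter", gene_id = linked)

  spikes <- if (!is.null(params$spikes)) {
    s <- data.table::as.data.table(params$spikes)
    s[, type := "spike"]
    if (!"gene_id" %in% names(s)) s[, gene_id := NA_character_]
    s
  } else if (params$nSpikes > 0) {
    .autoSpikes(params, genome, promoterSpikes)
  } else {
    data.table::data.table()
  }
  regions <- data.table::rbindlist(list(spikes, promoterSpikes),
                                   use.names = TRUE)
  if (nrow(regions)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    if (any(!regions$chrom %in% names(genome)) ||
        any(regions$end > lens[regions$chrom]) || any(regions$start < 1))
      stop("spiked region outside the genome")
    if (any(regions$chrom == "chrC"))
      stop("spiked region on the unmethylated organelle chromosome")
    regions[, direction := ifelse(delta > 0, "hyper", "hypo")]
  }

  dt[, levelT := level]
  if (nrow(regions)) {
    data.table::setkey(regions, chrom, start, end)
    qdt <- dt[, .(chrom, start = pos, end = pos)]
    ov <- data.table::foverlaps(qdt, regions,
                                by.x = c("chrom", "start", "end"),
                                which = TRUE, nomatch = NULL)
    if (nrow(ov)) {
      hitCtx <- regions$context[ov$yid]
      keep <- hitCtx == "all" | hitCtx == dt$context[ov$xid]
      ov <- ov[keep]
      ov <- ov[!duplicated(ov$xid)]  # first region wins on overlap
      idx <- ov$xid
      dlt <- regions$delta[ov$yid]
      lo <- pmax(0.05, 0.05 - dlt)
      hi <- pmin(0.95, 0.95 - dlt)
      base <- runif(length(idx), lo, hi)
      dt$level[idx] <- base
      dt$levelT[idx] <- base + dlt
      # verify every spiked region covers >= 1 cytosine of its context
      nPer <- tabulate(ov$yid, nbins = nrow(regions))
      if (any(nPer == 0))
        warning(sum(nPer == 0),
                " spiked region(s) contain no cytosine of their context")
    }
  }

  r <- params$nonconversionRate
  n <- nrow(dt)
  drawSample <- function(trueLevel, seedOff) {
    set.seed(.subSeed(params$seed, seedOff))
    depth <- stats::rnbinom(n, mu = params$coverageMean,
                            size = params$coverageDispersion)
    pObs <- trueLevel + (1 - trueLevel) * r
    meth <- stats::rbinom(n, depth, pObs)
    list(depth = depth, meth = meth)
  }
  ctl <- drawSample(dt$level, 3L)
  trt <- drawSample(dt$levelT, 4L)

  mkMeth <- function(draw, id, cond) {
    keep <- draw$depth > 0
    gr <- GenomicRanges::GRanges(
      dt$chrom[keep], IRanges::IRanges(dt$pos[keep], width = 1L),
      strand = dt$strand[keep],
      context = dt$context[keep], dinucleotide = dt$dinucleotide[keep],
      meth = as.integer(draw$meth[keep]),
      total = as.integer(draw$depth[keep]),
      seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                      seqlengths = Biostrings::width(genome)))
    Methylome(gr, sampleId = id, condition = cond,
              nonconversionRate = NA_real_)
  }
  truth <- list(
    siteLevels = dt[, .(chrom, pos, strand, context,
                        levelControl = level, levelTreatment = levelT)],
    regions = if (nrow(regions)) regions[] else regions,
    linkedGenes = data.table::data.table(
      gene_id = linked, promoterDelta = params$promoterDelta,
      effectSign = sign(-params$expressionEffectSlope *
                          params$promoterDelta))
  )
  list(control = mkMeth(ctl, "sim_control", "control"),
       treatment = mkMeth(trt, "sim_treatment", "stress"),
       truth = truth)
}

#' Simulate a replicate-level expression matrix linked to promoter
#' methylation
#'
#' Baseline log2 abundances are drawn per gene; replicates add log-normal
#' noise. Genes listed as linked in the ground truth have their treatment
#' mean shifted by `-expressionEffectSlope * promoterDelta` on the log2
#' scale, so promoter hypomethylation (negative delta) raises expression;
#' unlinked genes have zero expected shift.
#'
#' @param genes a [GeneModelSet-class] (or `simulateGenome()` output).
#' @param truth ground truth from [simulateMethylomePair()].
#' @param params a [simulationParams()] object (`nReplicates >= 2`).
#' @return list: `fpkm` (matrix, genes x samples, FPKM scale), `design`
#'   (data.frame sample/condition/replicate).
#' @export
simulateExpression <- function(genes, truth, params) {
  stopifnot(inherits(params, "SimulationParams"))
  if (params$nReplicates < 2)
    stop("nReplicates must be >= 2 for differential expression testing")
  gms <- if (is(genes, "GeneModelSet")) genes else genes$genes
  ids <- geneIds(gms)
  set.seed(.subSeed(params$seed, 5L))
  nGene <- length(ids)
  nRep <- params$nReplicates
  base <- stats::rnorm(nGene, mean = 5, sd = 2)
  shift <- rep(0, nGene)
  li <- match(truth$linkedGenes$gene_id, ids)
  shift[li] <- -params$expressionEffectSlope * truth$linkedGenes$promoterDelta
  noise <- matrix(stats::rnorm(nGene * 2 * nRep, 0, params$expressionNoiseSd),
                  nrow = nGene)
  logMat <- cbind(matrix(base, nGene, nRep),
                  matrix(base + shift, nGene, nRep)) + noise
  fpkm <- 2^logMat
  samples <- c(paste0("control_", seq_len(nRep)),
               paste0("treatment_", seq_len(nRep)))
  dimnames(fpkm) <- list(ids, samples)
  design <- data.frame(
    sample = samples,
    condition = rep(c("control", "stress"), each = nRep),
    replicate = rep(seq_len(nRep), 2),
    stringsAsFactors = FALSE)
  list(fpkm = fpkm, design = design)
}
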