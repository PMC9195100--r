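#' Classify differentially expressed genes
#'
#' A gene is `up` when log2 of the (pseudocounted) treatment/control FPKM
#' mean ratio is at least `log2(minFold)` and the Welch two-sample t-test
#' on log2(FPKM + 1) across replicates gives p < `alpha`; `down`
#' symmetrically; otherwise `ns`. Genes with all-zero FPKM, or with
#' replicate vectors too degenerate to test, are `ns`.
#'
#' The test is a surrogate for a full RNA-seq differential pipeline (which
#' sits upstream of this package); with few replicates it is deliberately
#' simple and is applied on the log scale where FPKM noise is roughly
#' homoscedastic.
#'
#' @param fpkm matrix (genes x samples) of FPKM values.
#' @param design data.frame with `sample` and `condition`
#'   (control/stress) matching the matrix columns.
#' @param minFold fold-change threshold (default 2).
#' @param alpha p-value threshold (default 0.05).
#' @return data.table: `gene_id`, `meanControl`, `meanTreatment`,
#'   `log2fc`, `pValue`, `degClass`.
#' @export
classifyDEG <- function(fpkm, design, minFold = 2, alpha = 0.05) {
  stopifnot(ncol(fpkm) == nrow(design))
  ctl <- design$condition == "control"
  trt <- !ctl
  if (sum(ctl) < 2 || sum(trt) < 2)
    stop("need >= 2 replicates per condition")
  mC <- rowMeans(fpkm[, ctl, drop = FALSE])
  mT <- rowMeans(fpkm[, trt, drop = FALSE])
  lfc <- log2((mT + 1) / (mC + 1))
  lt <- log2(fpkm[, trt, drop = FALSE] + 1)
  lc <- log2(fpkm[, ctl, drop = FALSE] + 1)
  pv <- vapply(seq_len(nrow(fpkm)), function(i) {
    x <- lt[i, ]; y <- lc[i, ]
    if (all(x == 0) && all(y == 0)) return(1)
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) 1)
  }, numeric(1))
  thr <- log2(minFold)
  cls <- ifelse(lfc >= thr & pv < alpha, "up",
                ifelse(lfc <= -thr & pv < alpha, "down", "ns"))
  data.table::data.table(
    gene_id = rownames(fpkm), meanControl = mC, meanTreatment = mT,
    log2fc = lfc, pValue = pv, degClass = cls)
}

#' Metagene methylation profiles stratified by expression level
#'
#' Genes are partitioned into `nStrata` quantile strata of expression;
#' for each stratum and context the pooled (read-weighted) methylation
#' level is profiled along a normalized gene axis: `flankBins` fixed-width
#' windows across the `flank` bases upstream of the TSS, `bodyBins`
#' positionally scaled windows across the gene body, and `flankBins`
#' windows downstream of the gene end, strand-flipped so the profile always
#' reads 5' to 3'.
#'
#' @param methylome a [Methylome-class].
#' @param gms a [GeneModelSet-class].
#' @param expression named numeric vector of expression values (e.g. mean
#'   FPKM), or a matrix whose row means are used; names are gene ids.
#' @param nStrata number of quantile strata (default 4).
#' @param bodyBins windows across the gene body (default 40).
#' @param flank flank length in bases (default 2000).
#' @param flankBins windows per flank (default 20).
#' @return data.table: `stratum` (1 = lowest expression), `context`,
#'   `bin` (1..flankBins+bodyBins+flankBins), `region`
#'   (upstream/body/downstream), `nSites`, `level`.
#' @export
methylationByExpressionStrata <- function(methylome, gms, expression,
                                          nStrata = 4, bodyBins = 40,
                                          flank = 2000, flankBins = 20) {
  if (is.matrix(expression)) expression <- rowMeans(expression)
  ids <- geneIds(gms)
  expression <- expression[ids]
  stopifnot(!any(is.na(expression)))
  rk <- rank(expression, ties.method = "first")
  stratum <- as.integer(cut(rk, breaks = nStrata, labels = FALSE))

  g <- geneRanges(gms)
  strnd <- as.character(GenomicRanges::strand(g))
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)

  s <- methSites(methylome)
  mc <- S4Vectors::mcols(s)
  sdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(s)),
    pos = GenomicRanges::start(s),
    context = as.character(mc$context), meth = mc$meth, total = mc$total)
  gdt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = pmax(1L, gs - as.integer(flank)),
    end = ge + as.integer(flank),
    gi = seq_along(g))
  data.table::setkey(gdt, chrom, start, end)
  ov <- data.table::foverlaps(sdt[, .(chrom, start = pos, end = pos,
                                      sid = .I)],
                              gdt, by.x = c("chrom", "start", "end"),
                              nomatch = NULL)
  if (!nrow(ov)) stop("no methylome sites near any gene")
  gi <- ov$gi; sid <- ov$sid
  pos <- sdt$pos[sid]
  up <- gs[gi] - pos        # >0 when left of gene start
  dn <- pos - ge[gi]        # >0 when right of gene end
  wid <- ge[gi] - gs[gi] + 1
  nb <- as.integer(flankBins); bb <- as.integer(bodyBins)
  totBins <- 2L * nb + bb
  # bin index on the Watson axis, then flip for minus-strand genes
  binW <- integer(length(gi))
  left <- up > 0
  right <- dn > 0
  body <- !left & !right
  binW[left] <- nb - pmin(nb - 1L, as.integer((up[left] - 1) %/%
                                                (flank / nb)))
  binW[body] <- nb + 1L +
    pmin(bb - 1L, as.integer((pos[body] - gs[gi][body]) / wid[body] * bb))
  binW[right] <- nb + bb +
    pmin(nb, 1L + as.integer((dn[right] - 1) %/% (flank / nb)))
  minus <- strnd[gi] == "-"
  binFinal <- ifelse(minus, totBins + 1L - binW, binW)

  prof <- data.table::data.table(
    stratum = stratum[gi], context = sdt$context[sid], bin = binFinal,
    meth = sdt$meth[sid], total = sdt$total[sid])
  res <- prof[, .(nSites = .N, level = sum(meth) / sum(total)),
              by = .(stratum, context, bin)]
  res[, region := ifelse(bin <= nb, "upstream",
                         ifelse(bin <= nb + bb, "body", "downstream"))]
  data.table::setorder(res, stratum, context, bin)
  res[]
}

#' Correlate DMR direction with differential expression
#'
#' Joins territory-annotated DMRs with DEG classes into one record per
#' (gene, context) pair carrying at least one DMR. When a gene has several
#' DMRs in a context, the one whose territory ranks first under the
#' promoter-first precedence ([promoterFirstLabels()]) decides the
#' methylation direction - promoter methylation is treated as the primary
#' regulatory signal. Categories: `hypo_up`, `hypo_down`, `hyper_up`,
#' `hyper_down`, and `uncorrelated` for genes whose expression change is
#' not significant.
#'
#' @param dmrTerritories data.table of DMRs with territory columns: needs
#'   `gene_id`, `label`, `context`, `direction` (rows with `gene_id` NA,
#'   i.e. distal intergenic DMRs, are ignored).
#' @param degs data.table from [classifyDEG()].
#' @param nGenesTotal denominator for the reported percentages; defaults
#'   to the number of genes in `degs`.
#' @return list: `records` (one row per gene x context: `gene_id`,
#'   `context`, `label`, `methDirection`, `degClass`, `category`) and
#'   `summary` (category counts and percentages).
#' @export
correlateDmrDeg <- function(dmrTerritories, degs,
                            nGenesTotal = nrow(degs)) {
  dt <- data.table::as.data.table(dmrTerritories)
  dt <- dt[!is.na(gene_id)]
  cats <- c("hypo_up", "hypo_down", "hyper_up", "hyper_down", "uncorrelated")
  if (nrow(dt) == 0) {
    records <- data.table::data.table(
      gene_id = character(), context = character(), label = character(),
      methDirection = character(), degClass = character(),
      category = character())
  } else {
    dt[, rank_ := match(label, promoterFirstLabels())]
    data.table::setorder(dt, gene_id, context, rank_)
    best <- dt[!duplicated(paste(gene_id, context))]
    records <- merge(best[, .(gene_id, context, label,
                              methDirection = direction)],
                     degs[, .(gene_id, degClass)],
                     by = "gene_id", all.x = TRUE)
    records[is.na(degClass), degClass := "ns"]
    records[, category := ifelse(degClass == "ns", "uncorrelated",
                                 paste0(methDirection,
                                        ifelse(degClass == "up", "_up",
                                               "_down")))]
    data.table::setorder(records, gene_id, context)
  }
  tab <- table(factor(records$category, levels = cats))
  summary <- data.frame(category = cats, count = as.integer(tab),
                        percent = 100 * as.integer(tab) /
                          max(nGenesTotal, 1L),
                        stringsAsFactors = FALSE)
  list(records = records[], summary = summary)
}

#' Relative expression by the 2^-ddCt method
#'
#' qPCR relative quantification: per condition, delta-Ct is the mean target
#' Ct minus the mean reference-gene Ct; delta-delta-Ct is the treated
#' delta-Ct minus the control delta-Ct; the returned fold change is
#' 2^(-ddCt). Adding any constant to all four Ct means leaves the result
#' unchanged.
#'
#' @param ctTargetTreated,ctReferenceTreated numeric replicate vectors of
#'   cycle-threshold values in the treated condition.
#' @param ctTargetControl,ctReferenceControl same for the control.
#' @return the relative expression fold change (1 when ddCt = 0).
#' @export
relativeExpressionDdct <- function(ctTargetTreated, ctReferenceTreated,
                                   ctTargetControl, ctReferenceControl) {
  vals <- c(ctTargetTreated, ctReferenceTreated, ctTargetControl,
            ctReferenceControl)
  if (!length(ctTargetTreated) || !length(ctReferenceTreated) ||
      !length(ctTargetControl) || !length(ctReferenceControl))
    stop("all four Ct replicate vectors must be non-empty")
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("Ct values must be positive and finite")
  dctT <- mean(ctTargetTreated) - mean(ctReferenceTreated)
  dctC <- mean(ctTargetControl) - mean(ctReferenceControl)
  2^(-(dctT - dctC))
}
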