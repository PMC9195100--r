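# Inner-join two methylomes on (chrom, pos, strand); only sites assayed in
# both samples are comparable.
.joinSites <- function(treatment, control) {
  asDT <- function(m, suf) {
    s <- methSites(m)
    mc <- S4Vectors::mcols(s)
    data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(s)),
      pos = GenomicRanges::start(s),
      strand = as.character(GenomicRanges::strand(s)),
      context = as.character(mc$context),
      meth = mc$meth, total = mc$total
    )
  }
  t <- asDT(treatment); c <- asDT(control)
  chrT <- unique(t$chrom); chrC <- unique(c$chrom)
  if (!setequal(chrT, chrC))
    warning("chromosome sets differ between samples; using their intersection")
  data.table::setnames(t, c("meth", "total"), c("methT", "totalT"))
  data.table::setnames(c, c("meth", "total"), c("methC", "totalC"))
  j <- merge(t, c, by = c("chrom", "pos", "strand", "context"))
  data.table::setorder(j, chrom, pos, strand)
  j
}

#' Tile the genome into fixed bins and pool methylation counts
#'
#' Cytosines assayed in both samples are assigned to fixed, non-overlapping
#' bins of `binSize` bases (bin start = floor((pos-1)/binSize)*binSize in
#' 0-based terms) and their read counts pooled per bin and context.
#'
#' @param treatment,control [Methylome-class] objects on the same reference.
#' @param contexts contexts to tile (default all three).
#' @param binSize bin width in bases (default 100).
#' @return data.table with one row per non-empty (bin, context):
#'   `chrom`, `start`/`end` (1-based inclusive), `context`, `nCytosines`,
#'   `methT`, `unmethT`, `methC`, `unmethC`, `levelT`, `levelC`,
#'   `meanDepthT`, `meanDepthC`.
#' @export
tileAndPool <- function(treatment, control,
                        contexts = c("CG", "CHG", "CHH"), binSize = 100) {
  j <- .joinSites(treatment, control)
  j <- j[context %in% contexts]
  j[, bin := (pos - 1L) %/% as.integer(binSize)]
  pooled <- j[, .(
    nCytosines = .N,
    methT = sum(methT), unmethT = sum(totalT - methT),
    methC = sum(methC), unmethC = sum(totalC - methC),
    meanDepthT = sum(totalT) / .N, meanDepthC = sum(totalC) / .N
  ), by = .(chrom, bin, context)]
  pooled[, `:=`(
    start = bin * as.integer(binSize) + 1L,
    end = (bin + 1L) * as.integer(binSize),
    levelT = methT / (methT + unmethT),
    levelC = methC / (methC + unmethC)
  )]
  pooled[, bin := NULL]
  data.table::setcolorder(pooled, c("chrom", "start", "end", "context"))
  data.table::setorder(pooled, chrom, start, context)
  pooled[]
}

#' Filter pooled bins on coverage and cytosine count
#'
#' Bins enter differential testing only when covered by at least
#' `minDepth` reads per cytosine in both samples and containing at least
#' `minCytosines` comparable cytosines.
#'
#' @param bins data.table from [tileAndPool()].
#' @param minDepth minimum mean per-cytosine depth in each sample
#'   (default 5).
#' @param minCytosines minimum cytosines per bin (default 3).
#' @return the retained subset, same columns.
#' @export
filterBins <- function(bins, minDepth = 5, minCytosines = 3) {
  bins[meanDepthT >= minDepth & meanDepthC >= minDepth &
         nCytosines >= minCytosines]
}

#' Fisher's exact test on pooled bin counts
#'
#' Adds the two-sided exact p-value for the 2x2 table
#' `[[methT, unmethT], [methC, unmethC]]` of each bin.
#'
#' @param bins data.table from [filterBins()].
#' @return the same table with a `pValue` column appended.
#' @export
fisherBinTest <- function(bins) {
  bins <- data.table::copy(bins)
  bins[, pValue := fisherTest2x2(methT, unmethT, methC, unmethC)]
  bins[]
}

#' Call differentially methylated cytosines (DmCs)
#'
#' Per-site two-sided Fisher's exact test on the methylated/unmethylated
#' read counts of the two samples, restricted to sites with at least
#' `minDepth` reads in both; Benjamini-Hochberg q-values computed within
#' each context. A site is a DmC when q < `alphaQ` and the absolute
#' level difference is at least `minDiff`.
#'
#' @param treatment,control [Methylome-class] objects.
#' @param minDepth minimum depth per sample for a site to be tested
#'   (default 5).
#' @param alphaQ FDR threshold (default 0.05).
#' @param minDiff minimum absolute methylation-level difference
#'   (default 0.20).
#' @return data.table of all tested sites: `chrom`, `pos`, `strand`,
#'   `context`, counts, `levelT`, `levelC`, `pValue`, `qValue`,
#'   `direction` (hyper when treatment level exceeds control) and `isDmC`.
#' @export
callDmCs <- function(treatment, control, minDepth = 5, alphaQ = 0.05,
                     minDiff = 0.20) {
  j <- .joinSites(treatment, control)
  j <- j[totalT >= minDepth & totalC >= minDepth]
  j[, `:=`(levelT = methT / totalT, levelC = methC / totalC)]
  j[, pValue := fisherTest2x2(methT, totalT - methT, methC, totalC - methC)]
  j[, qValue := stats::p.adjust(pValue, method = "BH"), by = context]
  j[, direction := ifelse(levelT > levelC, "hyper", "hypo")]
  j[, isDmC := qValue < alphaQ & abs(levelT - levelC) >= minDiff]
  data.table::setorder(j, chrom, pos, strand)
  j[]
}

#' Call differentially methylated regions (DMRs)
#'
#' Benjamini-Hochberg q-values are computed within each context across the
#' filtered, tested bins; a bin is a DMR when q < `alphaQ`, the absolute
#' level difference is at least `minDiff` (default 20 percentage points),
#' the level ratio max/min (with an epsilon floor on the denominator) is at
#' least `minFold` (default 2), and the bin contains at least `minDmcs`
#' DmCs (default 3). Direction is hyper when the treatment level exceeds
#' the control level.
#'
#' @param bins data.table from [fisherBinTest()] (filtered bins with
#'   `pValue`).
#' @param dmcs data.table from [callDmCs()] on the same sample pair; used
#'   to count supporting DmCs per bin. Pass `NULL` to skip the DmC-count
#'   filter (sets `minDmcs` to 0).
#' @param alphaQ FDR threshold (default 0.05).
#' @param minDiff minimum absolute level difference (default 0.20).
#' @param minFold minimum level fold ratio (default 2).
#' @param minDmcs minimum DmCs inside a DMR (default 3).
#' @param eps floor for the fold denominator (default 0.01).
#' @param allBins return every tested bin with an `isDMR` flag instead of
#'   only the DMRs (default FALSE).
#' @return data.table of DMRs sorted by genomic position: bin columns plus
#'   `pValue`, `qValue`, `levelDiff`, `fold`, `nDmcs`, `direction`.
#' @export
callDMRs <- function(bins, dmcs = NULL, alphaQ = 0.05, minDiff = 0.20,
                     minFold = 2.0, minDmcs = 3, eps = 0.01,
                     allBins = FALSE) {
  if (nrow(bins) == 0) return(bins)
  stopifnot("pValue" %in% colnames(bins))
  out <- data.table::copy(bins)
  data.table::setorder(out, chrom, start, context)
  out[, qValue := stats::p.adjust(pValue, method = "BH"), by = context]
  out[, levelDiff := levelT - levelC]
  out[, fold := pmax(levelT, levelC) / pmax(pmin(levelT, levelC), eps)]
  out[, direction := ifelse(levelDiff > 0, "hyper", "hypo")]
  if (is.null(dmcs)) {
    minDmcs <- 0
    out[, nDmcs := NA_integer_]
  } else {
    dm <- dmcs[isDmC == TRUE,
               .(chrom, pos, context)]
    if (nrow(dm)) {
      dm[, `:=`(start_ = pos, end_ = pos)]
      data.table::setkey(dm, chrom, context, start_, end_)
      qy <- out[, .(chrom, context, start_ = start, end_ = end)]
      ov <- data.table::foverlaps(qy, dm,
                                  by.x = c("chrom", "context", "start_", "end_"),
                                  which = TRUE, nomatch = NULL)
      cnt <- tabulate(ov$xid, nbins = nrow(out))
      out[, nDmcs := cnt]
    } else {
      out[, nDmcs := 0L]
    }
  }
  out[, isDMR := qValue < alphaQ & abs(levelDiff) >= minDiff &
        fold >= minFold]
  if (minDmcs > 0)
    out[, isDMR := isDMR & nDmcs >= minDmcs]
  if (allBins) return(out[])
  res <- out[isDMR == TRUE]
  res[, isDMR := NULL]
  res[]
}

#' Four-way membership partition of DMR sets
#'
#' Partitions the union of up to four labelled DMR sets (keyed by
#' chrom:start-end:context) into all non-empty membership classes:
#' exclusive to one set, each pairwise/triple overlap, and the all-way
#' intersection.
#'
#' @param dmrSets named list of DMR data.tables (columns `chrom`, `start`,
#'   `end`, `context`; optionally `direction`).
#' @param direction optional filter: keep only DMRs of this direction
#'   before partitioning.
#' @return data.frame with one row per non-empty membership class:
#'   `members` (set labels joined with `+`), `count`; attribute
#'   `"unionSize"` carries the union cardinality.
#' @export
fourwayPartition <- function(dmrSets, direction = NULL) {
  stopifnot(is.list(dmrSets), length(dmrSets) >= 2, !is.null(names(dmrSets)))
  keysOf <- function(d) {
    if (!is.null(direction) && "direction" %in% colnames(d))
      d <- d[d$direction == direction, ]
    if (nrow(d) == 0) return(character())
    unique(paste0(d$chrom, ":", d$start, "-", d$end, ":", d$context))
  }
  keys <- lapply(dmrSets, keysOf)
  uni <- unique(unlist(keys))
  member <- vapply(keys, function(k) uni %in% k, logical(length(uni)))
  if (length(uni) == 1L) member <- matrix(member, nrow = 1,
                                          dimnames = list(NULL, names(keys)))
  cls <- apply(member, 1L, function(r)
    paste(names(dmrSets)[r], collapse = "+"))
  tab <- table(cls)
  out <- data.frame(members = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  attr(out, "unionSize") <- length(uni)
  out
}
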