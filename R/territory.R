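#' Genic territory labels
#'
#' The eleven gene-relative territories used to localise methylation
#' changes: three tiered promoter windows upstream of the TSS (<1 kb,
#' 1-2 kb, 2-3 kb in transcription direction), 5' UTR, first exon, other
#' exons, first intron, other introns, 3' UTR, 1 kb downstream of the gene
#' end, and distal intergenic (everything else).
#'
#' `territoryLabels()` returns them in the precedence order used when a
#' position is covered by several candidates (genic features beat
#' promoters beat downstream); `promoterFirstLabels()` returns the
#' alternative ranking used when choosing the regulatory DMR of a gene
#' (promoter tiers first).
#'
#' @return character vector of labels.
#' @export
territoryLabels <- function() {
  c("utr5", "utr3", "exon_first", "exon_other", "intron_first",
    "intron_other", "promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb",
    "downstream", "distal_intergenic")
}

#' @rdname territoryLabels
#' @export
promoterFirstLabels <- function() {
  c("promoter_0_1kb", "promoter_1_2kb", "promoter_2_3kb", "utr5",
    "exon_first", "exon_other", "intron_first", "intron_other", "utr3",
    "downstream", "distal_intergenic")
}

# All candidate (gene, label) territory intervals as one GRanges.
# Promoters/downstream are measured in transcription direction and clipped
# at position 1 (and at the chromosome end when seqlengths are known).
.territoryRanges <- function(gms) {
  g <- geneRanges(gms)
  ids <- geneIds(gms)
  strnd <- as.character(GenomicRanges::strand(g))
  gs <- GenomicRanges::start(g); ge <- GenomicRanges::end(g)
  chr <- as.character(GenomicRanges::seqnames(g))
  sl <- GenomeInfoDb::seqlengths(g)
  chrEnd <- if (all(is.na(sl))) rep(Inf, length(g)) else
    ifelse(is.na(sl[chr]), Inf, sl[chr])

  rows <- list()
  add <- function(chrom, start, end, gene, label) {
    keep <- start <= end & end >= 1
    if (!any(keep)) return()
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      chrom = chrom[keep], start = pmax(1, start[keep]), end = end[keep],
      gene_id = gene[keep], label = label)
  }

  plus <- strnd == "+"
  for (tier in 1:3) {
    lo <- (tier - 1) * 1000 + 1; hi <- tier * 1000
    lab <- sprintf("promoter_%d_%dkb", tier - 1, tier)
    add(chr[plus], gs[plus] - hi, gs[plus] - lo, ids[plus], lab)
    add(chr[!plus], ge[!plus] + lo, pmin(ge[!plus] + hi, chrEnd[!plus]),
        ids[!plus], lab)
  }
  add(chr[plus], ge[plus] + 1, pmin(ge[plus] + 1000, chrEnd[plus]),
      ids[plus], "downstream")
  add(chr[!plus], gs[!plus] - 1000, gs[!plus] - 1, ids[!plus], "downstream")

  ex <- exonRanges(gms)
  nex <- S4Vectors::elementNROWS(ex)
  ue <- unlist(ex, use.names = FALSE)
  gi <- rep(seq_along(g), nex)
  # transcription-order index: genomic order for +, reversed for -
  ordIdx <- unlist(lapply(seq_along(g), function(i) {
    k <- nex[i]
    if (strnd[i] == "+") seq_len(k) else rev(seq_len(k))
  }))
  rows[[length(rows) + 1L]] <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(ue)),
    start = GenomicRanges::start(ue), end = GenomicRanges::end(ue),
    gene_id = ids[gi],
    label = ifelse(ordIdx == 1L, "exon_first", "exon_other"))

  # introns: gaps between consecutive exons (genomic order) within the gene
  intr <- lapply(seq_along(g), function(i) {
    e <- ex[[i]]
    if (length(e) < 2L) return(NULL)
    s <- GenomicRanges::end(e)[-length(e)] + 1L
    t <- GenomicRanges::start(e)[-1L] - 1L
    k <- length(s)
    ord <- if (strnd[i] == "+") seq_len(k) else rev(seq_len(k))
    data.table::data.table(
      chrom = chr[i], start = s, end = t, gene_id = ids[i],
      label = ifelse(ord == 1L, "intron_first", "intron_other"))
  })
  intr <- data.table::rbindlist(intr)
  if (nrow(intr)) rows[[length(rows) + 1L]] <- intr

  for (u in c("utr5", "utr3")) {
    gl <- if (u == "utr5") utr5Ranges(gms) else utr3Ranges(gms)
    nu <- S4Vectors::elementNROWS(gl)
    if (sum(nu)) {
      uu <- unlist(gl, use.names = FALSE)
      add(as.character(GenomicRanges::seqnames(uu)),
          GenomicRanges::start(uu), GenomicRanges::end(uu),
          ids[rep(seq_along(g), nu)], u)
    }
  }

  dt <- data.table::rbindlist(rows)
  dt[start <= end]
}

#' Assign features to genic territories
#'
#' Each query position (intervals are represented by their midpoint) is
#' tested against every candidate (gene, territory) interval; the winning
#' assignment is chosen by label precedence (see [territoryLabels()]),
#' with ties broken by distance to the candidate gene's TSS and then by
#' gene id for determinism. Positions hitting no candidate are
#' `distal_intergenic`.
#'
#' @param x GRanges of features (DmCs or DMRs), or a data.frame/data.table
#'   with `chrom`, `start`, `end` (1-based inclusive; `end` may be absent
#'   for point features).
#' @param gms a [GeneModelSet-class].
#' @param precedence `"genic"` (default, [territoryLabels()] order) or
#'   `"promoter"` ([promoterFirstLabels()] order).
#' @return data.table parallel to `x`: `chrom`, `pos` (midpoint used),
#'   `gene_id` (NA for distal intergenic), `label`, `distanceToTss`
#'   (signed, positive downstream of the TSS in transcription direction;
#'   NA for distal intergenic).
#' @export
assignTerritory <- function(x, gms, precedence = c("genic", "promoter")) {
  precedence <- match.arg(precedence)
  ranks <- if (precedence == "genic") territoryLabels() else
    promoterFirstLabels()
  if (is(x, "GRanges")) {
    q <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x), end = GenomicRanges::end(x))
  } else {
    q <- data.table::as.data.table(x)[, .(chrom, start,
                                          end = if ("end" %in% names(x)) end else start)]
  }
  q[, pos := (start + end) %/% 2L]
  q[, qid := .I]

  terr <- .territoryRanges(gms)
  tssAll <- stats::setNames(tss(gms), geneIds(gms))

  out <- data.table::data.table(
    chrom = q$chrom, pos = q$pos, gene_id = NA_character_,
    label = "distal_intergenic", distanceToTss = NA_real_)

  if (nrow(terr)) {
    data.table::setkey(terr, chrom, start, end)
    hits <- data.table::foverlaps(
      q[, .(chrom, start = pos, end = pos, qid)], terr,
      by.x = c("chrom", "start", "end"), nomatch = NULL)
    if (nrow(hits)) {
      strandOf <- stats::setNames(
        as.character(GenomicRanges::strand(geneRanges(gms))), geneIds(gms))
      hits[, rank_ := match(label, ranks)]
      hits[, tssPos := tssAll[gene_id]]
      hits[, distanceToTss := ifelse(strandOf[gene_id] == "+",
                                     i.start - tssPos, tssPos - i.start)]
      hits[, absD := abs(distanceToTss)]
      data.table::setorder(hits, qid, rank_, absD, gene_id)
      best <- hits[!duplicated(qid)]
      out[best$qid, `:=`(gene_id = best$gene_id, label = best$label,
                         distanceToTss = best$distanceToTss)]
    }
  }
  out[]
}

#' Fractions of features per genic territory
#'
#' @param assignments data.table from [assignTerritory()].
#' @return data.frame over all eleven labels plus a merged `promoter` row
#'   (the three tiers combined; not part of the sum-to-1 partition):
#'   `label`, `count`, `fraction`.
#' @export
territoryDistribution <- function(assignments) {
  if (nrow(assignments) == 0) stop("no assignments to summarise")
  labs <- territoryLabels()
  tab <- table(factor(assignments$label, levels = labs))
  n <- sum(tab)
  out <- data.frame(label = labs, count = as.integer(tab),
                    fraction = as.numeric(tab) / n, stringsAsFactors = FALSE)
  prom <- grepl("^promoter_", out$label)
  rbind(out,
        data.frame(label = "promoter", count = sum(out$count[prom]),
                   fraction = sum(out$fraction[prom])))
}

#' Mean methylation level per genic territory and context
#'
#' Assigns every assayed cytosine of a methylome to a territory and
#' reports the pooled (read-weighted) methylation level
#' sum(meth)/sum(total) per territory x context. Combinations with no
#' sites are absent from the result, not reported as zero.
#'
#' @param methylome a [Methylome-class].
#' @param gms a [GeneModelSet-class].
#' @return data.table: `label`, `context`, `nSites`, `level`.
#' @export
territoryMethylationProfile <- function(methylome, gms) {
  s <- methSites(methylome)
  asg <- assignTerritory(s, gms)
  mc <- S4Vectors::mcols(s)
  dt <- data.table::data.table(
    label = asg$label, context = as.character(mc$context),
    meth = mc$meth, total = mc$total)
  res <- dt[, .(nSites = .N, level = sum(meth) / sum(total)),
            by = .(label, context)]
  data.table::setorder(res, label, context)
  res[]
}
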