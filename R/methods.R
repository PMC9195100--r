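.sortSites <- function(gr) {
  o <- order(as.integer(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr),
             as.integer(GenomicRanges::strand(gr)))
  gr[o]
}

#' Construct a Methylome
#'
#' @param sites GRanges of width-1 cytosine positions with metadata columns
#'   `context`, `meth`, `total` (and optionally `dinucleotide`). Sites with
#'   `total == 0` are not representable; drop them before construction.
#' @param sampleId sample identifier.
#' @param condition one of `"control"`, `"stress"`, `"other"`.
#' @param genotype,tissue free-text labels.
#' @param nonconversionRate known or estimated non-conversion rate, or NA.
#' @return a [Methylome-class] object with sites sorted by
#'   (chrom, pos, strand).
#' @export
Methylome <- function(sites, sampleId = NA_character_, condition = "other",
                      genotype = "other", tissue = "other",
                      nonconversionRate = NA_real_) {
  if (!"dinucleotide" %in% colnames(S4Vectors::mcols(sites)))
    S4Vectors::mcols(sites)$dinucleotide <- NA_character_
  new("Methylome", sites = .sortSites(sites), sampleId = sampleId,
      condition = condition, genotype = genotype, tissue = tissue,
      nonconversionRate = nonconversionRate)
}

#' @rdname Methylome-class
#' @export
setMethod("methSites", "Methylome", function(x) x@sites)

#' @rdname Methylome-class
#' @export
setMethod("sampleId", "Methylome", function(x) x@sampleId)

#' @rdname Methylome-class
#' @export
setMethod("condition", "Methylome", function(x) x@condition)

#' @rdname Methylome-class
#' @export
setMethod("nonconversionRate", "Methylome", function(x) x@nonconversionRate)

#' @rdname Methylome-class
#' @export
setReplaceMethod("nonconversionRate", "Methylome", function(x, value) {
  x@nonconversionRate <- value
  validObject(x)
  x
})

#' @rdname Methylome-class
#' @export
setMethod("methLevels", "Methylome", function(x) {
  mc <- S4Vectors::mcols(x@sites)
  mc$meth / mc$total
})

#' @rdname Methylome-class
#' @param object a `Methylome`
#' @export
setMethod("show", "Methylome", function(object) {
  s <- object@sites
  ctx <- table(factor(as.character(S4Vectors::mcols(s)$context),
                      levels = c("CG", "CHG", "CHH")))
  cat(sprintf("Methylome '%s' (%s, %s, %s)\n", object@sampleId,
              object@genotype, object@tissue, object@condition))
  cat(sprintf("  %d cytosine sites on %d sequence(s): CG %d, CHG %d, CHH %d\n",
              length(s), length(unique(as.character(GenomicRanges::seqnames(s)))),
              ctx[["CG"]], ctx[["CHG"]], ctx[["CHH"]]))
  if (length(s))
    cat(sprintf("  mean depth %.1f, pooled methylation level %.4f\n",
                mean(S4Vectors::mcols(s)$total),
                sum(S4Vectors::mcols(s)$meth) / sum(S4Vectors::mcols(s)$total)))
  cat(sprintf("  non-conversion rate: %s\n",
              ifelse(is.na(object@nonconversionRate), "not estimated",
                     format(object@nonconversionRate, digits = 4))))
  invisible(NULL)
})

#' Construct a GeneModelSet
#'
#' @param genes named GRanges of gene spans (strand required).
#' @param exons GRangesList parallel to `genes`; defaults to one exon
#'   spanning each gene.
#' @param utr5,utr3 GRangesList parallel to `genes`; default empty.
#' @return a [GeneModelSet-class]
#' @export
GeneModelSet <- function(genes, exons = NULL, utr5 = NULL, utr3 = NULL) {
  ids <- names(genes)
  if (is.null(exons)) {
    exons <- S4Vectors::split(genes, factor(ids, levels = ids))
  }
  emptyList <- function() {
    gl <- GenomicRanges::GRangesList(rep(list(GenomicRanges::GRanges()),
                                         length(genes)))
    names(gl) <- ids
    gl
  }
  if (is.null(utr5)) utr5 <- emptyList()
  if (is.null(utr3)) utr3 <- emptyList()
  exons <- exons[ids]
  new("GeneModelSet", genes = genes, exons = exons,
      utr5 = utr5[ids], utr3 = utr3[ids])
}

#' @rdname GeneModelSet-class
#' @param x,object a `GeneModelSet`
#' @export
setMethod("geneRanges", "GeneModelSet", function(x) x@genes)

#' @rdname GeneModelSet-class
#' @export
setMethod("exonRanges", "GeneModelSet", function(x) x@exons)

#' @rdname GeneModelSet-class
#' @export
setMethod("utr5Ranges", "GeneModelSet", function(x) x@utr5)

#' @rdname GeneModelSet-class
#' @export
setMethod("utr3Ranges", "GeneModelSet", function(x) x@utr3)

#' @rdname GeneModelSet-class
#' @export
setMethod("geneIds", "GeneModelSet", function(x) names(x@genes))

#' @rdname GeneModelSet-class
#' @export
setMethod("tss", "GeneModelSet", function(x) {
  g <- x@genes
  ifelse(as.character(GenomicRanges::strand(g)) == "+",
         GenomicRanges::start(g), GenomicRanges::end(g))
})

#' @rdname GeneModelSet-class
#' @export
setMethod("tes", "GeneModelSet", function(x) {
  g <- x@genes
  ifelse(as.character(GenomicRanges::strand(g)) == "+",
         GenomicRanges::end(g), GenomicRanges::start(g))
})

#' @rdname GeneModelSet-class
#' @export
setMethod("show", "GeneModelSet", function(object) {
  g <- object@genes
  cat(sprintf("GeneModelSet: %d gene model(s) on %d sequence(s)\n",
              length(g), length(unique(as.character(GenomicRanges::seqnames(g))))))
  if (length(g)) {
    nex <- S4Vectors::elementNROWS(object@exons)
    cat(sprintf("  exons per gene: median %d (range %d-%d); %d gene(s) with UTRs\n",
                as.integer(stats::median(nex)), min(nex), max(nex),
                sum(S4Vectors::elementNROWS(object@utr5) > 0 |
                      S4Vectors::elementNROWS(object@utr3) > 0)))
  }
  invisible(NULL)
})
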