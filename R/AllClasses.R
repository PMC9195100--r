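#' Methylome: per-cytosine methylation counts for one sample
#'
#' Container for a single sample's whole-genome bisulfite methylome at
#' single-cytosine resolution. Sites live in a [GenomicRanges::GRanges]
#' (width-1 ranges at the Watson-strand coordinate of each cytosine; the
#' strand slot records which strand the cytosine is on) with metadata
#' columns `context` (`CG`, `CHG` or `CHH`, where H is A, C or T),
#' `dinucleotide` (the cytosine plus its next base read 5'->3' on its own
#' strand), `meth` (reads supporting methylation) and `total` (all reads).
#'
#' @slot sites GRanges of assayed cytosines, sorted by (chrom, pos, strand),
#'   no duplicates, `meth <= total`, `total >= 1`.
#' @slot sampleId single character sample identifier.
#' @slot condition `"control"`, `"stress"` or `"other"`.
#' @slot genotype free-text genotype label (e.g. tolerant/sensitive line).
#' @slot tissue free-text tissue label.
#' @slot nonconversionRate estimated fraction of unmethylated cytosines that
#'   escaped bisulfite conversion, or `NA_real_` when not yet estimated.
#'
#' @seealso [readCGmap()], [writeCGmap()], [estimateNonconversion()],
#'   [callMC()]
#' @export
setClass("Methylome",
  representation(
    sites = "GRanges",
    sampleId = "character",
    condition = "character",
    genotype = "character",
    tissue = "character",
    nonconversionRate = "numeric"
  ),
  prototype(
    sampleId = NA_character_,
    condition = "other",
    genotype = "other",
    tissue = "other",
    nonconversionRate = NA_real_
  )
)

setValidity("Methylome", function(object) {
  msg <- character()
  s <- object@sites
  mc <- S4Vectors::mcols(s)
  need <- c("context", "meth", "total")
  if (!all(need %in% colnames(mc))) {
    return(paste("sites must carry metadata columns:",
                 paste(need, collapse = ", ")))
  }
  if (length(s)) {
    if (!all(as.character(mc$context) %in% c("CG", "CHG", "CHH")))
      msg <- c(msg, "context must be one of CG, CHG, CHH")
    if (any(mc$meth > mc$total))
      msg <- c(msg, "meth exceeds total for some sites")
    if (any(mc$meth < 0) || any(mc$total < 1))
      msg <- c(msg, "counts must satisfy 0 <= meth <= total, total >= 1")
    if (any(GenomicRanges::width(s) != 1L))
      msg <- c(msg, "sites must be width-1 positions")
    key <- paste(GenomicRanges::seqnames(s), GenomicRanges::start(s),
                 GenomicRanges::strand(s))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, pos, strand) sites")
    # (chrom, pos, strand) ordering is enforced by the constructor
  }
  if (length(object@sampleId) != 1L)
    msg <- c(msg, "sampleId must be length 1")
  r <- object@nonconversionRate
  if (length(r) != 1L || (!is.na(r) && (r < 0 || r > 1)))
    msg <- c(msg, "nonconversionRate must be length-1 in [0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' GeneModelSet: gene structures used for territory annotation
#'
#' One model per gene: the gene span, its exons (and implied introns), and
#' optional UTRs, all 1-based inclusive as in [GenomicRanges::GRanges].
#' Exons are stored in genomic order; transcription order is derived from
#' the strand.
#'
#' @slot genes GRanges, one range per gene, names = gene ids, strand set.
#' @slot exons GRangesList parallel to `genes` (same names), >= 1 exon per
#'   gene, non-overlapping within a gene, all inside the gene span.
#' @slot utr5,utr3 GRangesList parallel to `genes`; elements may be empty.
#'
#' @seealso [readGFF3Genes()], [assignTerritory()]
#' @export
setClass("GeneModelSet",
  representation(
    genes = "GRanges",
    exons = "GRangesList",
    utr5 = "GRangesList",
    utr3 = "GRangesList"
  )
)

setValidity("GeneModelSet", function(object) {
  msg <- character()
  g <- object@genes
  ids <- names(g)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "genes must have unique names (gene ids)")
  if (any(as.character(GenomicRanges::strand(g)) == "*"))
    msg <- c(msg, "every gene needs an explicit strand")
  for (slotnm in c("exons", "utr5", "utr3")) {
    gl <- slot(object, slotnm)
    if (length(gl) != length(g) || !identical(names(gl), ids))
      msg <- c(msg, sprintf("%s must be parallel to genes (same names)", slotnm))
  }
  if (!length(msg) && length(g)) {
    ex <- object@exons
    n_ex <- S4Vectors::elementNROWS(ex)
    if (any(n_ex < 1L))
      msg <- c(msg, "every gene needs >= 1 exon")
    ue <- unlist(ex, use.names = FALSE)
    gi <- rep(seq_along(g), n_ex)
    if (any(GenomicRanges::start(ue) < GenomicRanges::start(g)[gi]) ||
        any(GenomicRanges::end(ue) > GenomicRanges::end(g)[gi]))
      msg <- c(msg, "exon outside its gene span")
    ov <- vapply(seq_along(ex), function(i) {
      e <- ex[[i]]
      length(e) > 1L &&
        any(GenomicRanges::start(e)[-1L] <=
              GenomicRanges::end(e)[-length(e)])
    }, logical(1))
    if (any(ov))
      msg <- c(msg, "overlapping or unsorted exons within a gene")
  }
  if (length(msg)) msg else TRUE
})
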