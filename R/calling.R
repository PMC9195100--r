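#' Estimate the bisulfite non-conversion rate from an unmethylated genome
#'
#' The chloroplast genome is essentially devoid of cytosine methylation, so
#' any methylation signal observed there measures incomplete bisulfite
#' conversion. The estimate is the pooled read fraction
#' sum(meth) / sum(total) over every cytosine of the organelle sequence;
#' the conversion rate is 1 minus this value.
#'
#' @param methylome a [Methylome-class].
#' @param organelle name of the chromosome assumed unmethylated; default
#'   uses all sites of `methylome` (pass a methylome already restricted to
#'   the organelle, or name it here).
#' @return the non-conversion rate, a proportion in `[0, 1]`.
#' @export
estimateNonconversion <- function(methylome, organelle = NULL) {
  s <- methSites(methylome)
  if (!is.null(organelle)) {
    s <- s[as.character(GenomicRanges::seqnames(s)) == organelle]
    if (!length(s)) stop("no sites on chromosome ", organelle)
  }
  mc <- S4Vectors::mcols(s)
  tot <- sum(as.numeric(mc$total))
  if (tot == 0) stop("zero total reads; cannot estimate non-conversion")
  sum(as.numeric(mc$meth)) / tot
}

#' Call 5-methylcytosines by exact binomial test
#'
#' Each cytosine with at least `minDepth` reads is tested against the
#' null that all its methylated-read signal arises from non-conversion:
#' p = P(X >= meth | n = total, rate = nonconversion), one-sided upper
#' tail (under this error model an excess of unconverted reads can only
#' indicate methylation). Sites below `minDepth` are marked unassayed,
#' not unmethylated. No multiple-testing correction is applied at this
#' stage; a raw p cutoff (default 0.001) defines the call, with FDR
#' control deferred to the DmC/DMR stages.
#'
#' @param methylome a [Methylome-class].
#' @param nonconversion non-conversion rate in (0, 1); defaults to the
#'   methylome's stored rate.
#' @param alpha raw p-value cutoff for a methylated call (default 0.001).
#' @param minDepth minimum reads for a site to be assayed (default 5).
#' @return GRanges of all sites with added metadata columns `pValue`,
#'   `assayed` and `isMethylated`.
#' @export
callMC <- function(methylome, nonconversion = nonconversionRate(methylome),
                   alpha = 0.001, minDepth = 5) {
  if (is.na(nonconversion) || nonconversion <= 0 || nonconversion >= 1)
    stop("nonconversion must lie strictly in (0, 1)")
  s <- methSites(methylome)
  mc <- S4Vectors::mcols(s)
  p <- binomUpperTail(mc$meth, mc$total, nonconversion)
  assayed <- mc$total >= minDepth
  S4Vectors::mcols(s)$pValue <- p
  S4Vectors::mcols(s)$assayed <- assayed
  S4Vectors::mcols(s)$isMethylated <- assayed & p < alpha
  s
}

#' Global and per-context 5-mC content
#'
#' Summarises methylated-cytosine calls into the familiar genome-wide
#' percentages: per context (CG, CHG, CHH) and overall, the number of
#' assayed sites, the number called methylated, and 100 * methylated /
#' assayed. Unassayed sites are excluded from denominators.
#'
#' @param calls GRanges from [callMC()].
#' @return data.frame with rows CG, CHG, CHH, overall and columns
#'   `context`, `assayed`, `methylated`, `percent`.
#' @export
globalMcContent <- function(calls) {
  mc <- S4Vectors::mcols(calls)
  keep <- mc$assayed
  if (!any(keep)) stop("no assayed sites; cannot summarise 5-mC content")
  ctx <- factor(as.character(mc$context)[keep], levels = c("CG", "CHG", "CHH"))
  met <- mc$isMethylated[keep]
  ass <- as.integer(table(ctx))
  nmet <- as.integer(tapply(met, ctx, sum, default = 0L))
  out <- data.frame(
    context = c("CG", "CHG", "CHH", "overall"),
    assayed = c(ass, sum(ass)),
    methylated = c(nmet, sum(nmet)),
    stringsAsFactors = FALSE
  )
  out$percent <- ifelse(out$assayed > 0, 100 * out$methylated / out$assayed, NA)
  out
}
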