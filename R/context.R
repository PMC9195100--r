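.COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Scan one chromosome's base vector for cytosines on both strands.
# Returns a data.table: pos (Watson, 1-based), strand, context
# (CG/CHG/CHH, NA when a contig end leaves the class unresolved) and
# dinucleotide (cytosine + next base, read 5'->3' on the site's strand).
.contextScan <- function(chars) {
  n <- length(chars)
  scan1 <- function(p, n1, n2) {
    ctx <- rep(NA_character_, length(p))
    ok1 <- !is.na(n1)
    ctx[ok1 & n1 == "G"] <- "CG"
    ok2 <- ok1 & n1 != "G" & !is.na(n2)
    ctx[ok2 & n2 == "G"] <- "CHG"
    ctx[ok2 & n2 != "G"] <- "CHH"
    list(context = ctx,
         dinucleotide = paste0("C", ifelse(ok1, n1, "N")))
  }
  pw <- which(chars == "C")
  w1 <- ifelse(pw + 1L <= n, chars[pmin(pw + 1L, n)], NA)
  w2 <- ifelse(pw + 2L <= n, chars[pmin(pw + 2L, n)], NA)
  watson <- scan1(pw, w1, w2)
  pc <- which(chars == "G")
  c1 <- ifelse(pc - 1L >= 1L, unname(.COMP[chars[pmax(pc - 1L, 1L)]]), NA)
  c2 <- ifelse(pc - 2L >= 1L, unname(.COMP[chars[pmax(pc - 2L, 1L)]]), NA)
  crick <- scan1(pc, c1, c2)
  data.table::data.table(
    pos = c(pw, pc),
    strand = rep(c("+", "-"), c(length(pw), length(pc))),
    context = c(watson$context, crick$context),
    dinucleotide = c(watson$dinucleotide, crick$dinucleotide)
  )
}

#' Classify the sequence context of cytosines
#'
#' Plant methylomes distinguish three cytosine contexts: `CG`, `CHG` and
#' `CHH`, where H is A, C or T, read 5'->3' on the strand carrying the
#' cytosine. On the Watson (+) strand the two following bases are
#' inspected; on the Crick (-) strand the reverse-complement triplet is
#' used, i.e. for a Watson-strand G at `pos` the Crick cytosine's context
#' is read from positions `pos-1` and `pos-2` after complementing.
#'
#' @param genome a [Biostrings::DNAStringSet] (or single character string)
#'   of reference sequences.
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 1-based Watson-strand position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @return character vector: `"CG"`, `"CHG"` or `"CHH"`; `"notC"` when the
#'   addressed base is not a cytosine on the requested strand; `NA` when a
#'   contig end truncates the triplet before the class is resolved (a
#'   terminal `C` followed directly by `G` is still `CG`).
#' @examples
#' classifyContext(Biostrings::DNAStringSet(c(chr1 = "ACGT")), "chr1", 2, "+")
#' @export
classifyContext <- function(genome, chrom, pos, strand) {
  if (is.character(genome))
    genome <- Biostrings::DNAStringSet(genome)
  if (is.null(names(genome)))
    names(genome) <- paste0("seq", seq_along(genome))
  n <- max(length(chrom), length(pos), length(strand))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  strand <- rep_len(strand, n)
  out <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) stop("unknown chromosome: ", ch)
    chars <- strsplit(as.character(genome[[ch]]), "", fixed = TRUE)[[1]]
    len <- length(chars)
    sel <- which(chrom == ch)
    for (i in sel) {
      p <- pos[i]
      if (p < 1 || p > len) stop("position out of range on ", ch)
      if (strand[i] == "+") {
        if (chars[p] != "C") { out[i] <- "notC"; next }
        b1 <- if (p + 1 <= len) chars[p + 1] else NA
        b2 <- if (p + 2 <= len) chars[p + 2] else NA
      } else {
        if (chars[p] != "G") { out[i] <- "notC"; next }
        b1 <- if (p - 1 >= 1) unname(.COMP[chars[p - 1]]) else NA
        b2 <- if (p - 2 >= 1) unname(.COMP[chars[p - 2]]) else NA
      }
      out[i] <-
        if (!is.na(b1) && b1 == "G") "CG"
        else if (!is.na(b1) && !is.na(b2) && b2 == "G") "CHG"
        else if (!is.na(b1) && !is.na(b2)) "CHH"
        else NA_character_
    }
  }
  out
}

#' Enumerate every cytosine of a genome with its context
#'
#' Scans both strands of each sequence and returns all cytosines whose
#' context is resolvable (positions truncated by a contig end are dropped).
#'
#' @param genome a [Biostrings::DNAStringSet].
#' @return GRanges of width-1 sites with `context` and `dinucleotide`
#'   metadata columns, sorted by (chrom, pos, strand).
#' @export
cytosineContexts <- function(genome) {
  stopifnot(!is.null(names(genome)))
  per <- lapply(names(genome), function(ch) {
    dt <- .contextScan(strsplit(as.character(genome[[ch]]), "",
                                fixed = TRUE)[[1]])
    dt <- dt[!is.na(context)]
    dt[, chrom := ch]
    dt
  })
  dt <- data.table::rbindlist(per)
  gr <- GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$pos, width = 1L),
    strand = dt$strand,
    context = dt$context,
    dinucleotide = dt$dinucleotide,
    seqinfo = GenomeInfoDb::Seqinfo(names(genome),
                                    seqlengths = Biostrings::width(genome))
  )
  .sortSites(gr)
}
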