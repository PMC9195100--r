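# Independent oracles, deliberately written with different machinery than
# the implementation (explicit loops, lchoose arithmetic, substring scans).

# P(X >= m | n, r) by explicit term-by-term summation
oracleBinomTail <- function(m, n, r) {
  if (m <= 0) return(1)
  sum(vapply(m:n, function(k) choose(n, k) * r^k * (1 - r)^(n - k),
             numeric(1)))
}

# two-sided Fisher's exact p by enumeration of all tables with the observed
# margins, log-factorial arithmetic, tie tolerance on the observed density
oracleFisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  logp <- function(x) lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)
  xs <- max(0, c1 - r2):min(c1, r1)
  ps <- exp(vapply(xs, logp, numeric(1)))
  pobs <- exp(logp(a))
  min(1, sum(ps[ps <= pobs * (1 + 1e-7)]))
}

# context of every cytosine by direct per-position triplet inspection
# (plain character loop, preallocated result vectors)
oracleContextScan <- function(seqString) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars <- strsplit(seqString, "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- integer(2 * n); strand <- character(2 * n); ctx <- character(2 * n)
  k <- 0L
  triplet <- function(b1, b2) {
    if (!is.na(b1) && b1 == "G") "CG"
    else if (!is.na(b1) && !is.na(b2) && b2 == "G") "CHG"
    else if (!is.na(b1) && !is.na(b2)) "CHH" else NA_character_
  }
  for (i in seq_len(n)) {
    b <- chars[i]
    if (b == "C") {
      cc <- triplet(if (i + 1 <= n) chars[i + 1] else NA,
                    if (i + 2 <= n) chars[i + 2] else NA)
      if (!is.na(cc)) {
        k <- k + 1L; pos[k] <- i; strand[k] <- "+"; ctx[k] <- cc
      }
    } else if (b == "G") {
      cc <- triplet(if (i - 1 >= 1) comp[[chars[i - 1]]] else NA,
                    if (i - 2 >= 1) comp[[chars[i - 2]]] else NA)
      if (!is.na(cc)) {
        k <- k + 1L; pos[k] <- i; strand[k] <- "-"; ctx[k] <- cc
      }
    }
  }
  data.frame(pos = pos[seq_len(k)], strand = strand[seq_len(k)],
             context = ctx[seq_len(k)])
}

# exhaustive per-base territory oracle: for one position, enumerate every
# (gene, label) candidate by plain interval arithmetic (minus-strand genes
# handled by mirroring coordinates and reusing the plus-strand rule), then
# apply the precedence and nearest-TSS tie-break
oracleTerritory <- function(pos, chrom, genesDf, precedence) {
  cand <- list()
  for (i in seq_len(nrow(genesDf))) {
    gn <- genesDf[i, ]
    if (gn$chrom != chrom) next
    # mirror so the gene reads left-to-right in transcription direction
    if (gn$strand == "+") {
      x <- pos; s <- gn$start; e <- gn$end
      exs <- gn$exons[[1]]
    } else {
      M <- gn$start + gn$end           # mirror: x' = M - x
      x <- M - pos; s <- M - gn$end; e <- M - gn$start
      exs <- gn$exons[[1]]
      exs <- data.frame(start = M - rev(exs$end), end = M - rev(exs$start))
    }
    tssX <- s
    lab <- NULL
    if (x >= s - 1000 && x <= s - 1) lab <- c(lab, "promoter_0_1kb")
    if (x >= s - 2000 && x <= s - 1001) lab <- c(lab, "promoter_1_2kb")
    if (x >= s - 3000 && x <= s - 2001) lab <- c(lab, "promoter_2_3kb")
    if (x >= e + 1 && x <= e + 1000) lab <- c(lab, "downstream")
    if (x >= s && x <= e) {
      inEx <- which(exs$start <= x & x <= exs$end)
      if (length(inEx)) {
        lab <- c(lab, if (min(inEx) == 1) "exon_first" else "exon_other")
      } else {
        k <- sum(exs$end < x)  # intron after k-th exon in transcription order
        lab <- c(lab, if (k == 1) "intron_first" else "intron_other")
      }
      u5 <- gn$utr5[[1]]
      if (!is.null(u5) && nrow(u5) &&
          any(u5$start <= pos & pos <= u5$end)) lab <- c(lab, "utr5")
      u3 <- gn$utr3[[1]]
      if (!is.null(u3) && nrow(u3) &&
          any(u3$start <= pos & pos <= u3$end)) lab <- c(lab, "utr3")
    }
    for (l in lab)
      cand[[length(cand) + 1]] <- data.frame(
        gene_id = gn$gene_id, label = l, dist = abs(x - tssX))
  }
  if (!length(cand))
    return(data.frame(gene_id = NA_character_, label = "distal_intergenic"))
  cand <- do.call(rbind, cand)
  cand$rank <- match(cand$label, precedence)
  cand <- cand[order(cand$rank, cand$dist, cand$gene_id), ]
  cand[1, c("gene_id", "label")]
}

# GeneModelSet -> plain data.frame consumed by oracleTerritory
gmsToDf <- function(gms) {
  g <- geneRanges(gms)
  data.frame(
    gene_id = geneIds(gms),
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(GenomicRanges::strand(g)),
    exons = I(lapply(seq_along(g), function(i) {
      e <- exonRanges(gms)[[i]]
      data.frame(start = GenomicRanges::start(e),
                 end = GenomicRanges::end(e))
    })),
    utr5 = I(lapply(seq_along(g), function(i) {
      e <- utr5Ranges(gms)[[i]]
      data.frame(start = GenomicRanges::start(e),
                 end = GenomicRanges::end(e))
    })),
    utr3 = I(lapply(seq_along(g), function(i) {
      e <- utr3Ranges(gms)[[i]]
      data.frame(start = GenomicRanges::start(e),
                 end = GenomicRanges::end(e))
    }))
  )
}
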