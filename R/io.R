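#' Read a CGmap-style per-cytosine methylation table
#'
#' Ingests the 8-column tab-separated per-cytosine format (chrom,
#' Watson-strand nucleotide, 1-based position, context class, dinucleotide,
#' methylation level, methylated reads, total reads). Strand is inferred
#' from the Watson-strand nucleotide (`C` -> `+`, `G` -> `-`). Sites with
#' zero total reads are dropped with a message. Malformed lines (unknown
#' nucleotide or context token, `meth > total`) abort with their line
#' numbers.
#'
#' @param path file path.
#' @param sampleId,condition,genotype,tissue sample metadata passed to
#'   [Methylome()].
#' @return a [Methylome-class].
#' @export
readCGmap <- function(path, sampleId = basename(path), condition = "other",
                      genotype = "other", tissue = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = c(1, 2, 4, 5)))
  if (ncol(dt) != 8)
    stop("expected 8 tab-separated columns, found ", ncol(dt))
  data.table::setnames(dt, c("chrom", "nuc", "pos", "context",
                             "dinucleotide", "level", "meth", "total"))
  bad <- which(!dt$nuc %in% c("C", "G"))
  if (length(bad))
    stop("nucleotide column must be C or G; offending line(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(!dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad))
    stop("unknown context token; offending line(s): ",
         paste(head(bad, 5), collapse = ", "))
  bad <- which(dt$meth > dt$total)
  if (length(bad))
    stop("meth_reads > total_reads; offending line(s): ",
         paste(head(bad, 5), collapse = ", "))
  nzero <- sum(dt$total == 0)
  if (nzero) {
    message(nzero, " site(s) with zero coverage dropped at ingest")
    dt <- dt[total > 0]
  }
  gr <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$pos, width = 1L),
    strand = ifelse(dt$nuc == "C", "+", "-"),
    context = dt$context, dinucleotide = dt$dinucleotide,
    meth = as.integer(dt$meth), total = as.integer(dt$total))
  Methylome(gr, sampleId = sampleId, condition = condition,
            genotype = genotype, tissue = tissue)
}

#' Write a Methylome as a CGmap-style table
#'
#' Inverse of [readCGmap()]: 8 tab-separated columns, positions 1-based,
#' level written as methylated/total with 6 decimals.
#'
#' @param methylome a [Methylome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCGmap <- function(methylome, path) {
  s <- methSites(methylome)
  mc <- S4Vectors::mcols(s)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(s)),
    nuc = ifelse(as.character(GenomicRanges::strand(s)) == "+", "C", "G"),
    pos = GenomicRanges::start(s),
    context = as.character(mc$context),
    dinucleotide = as.character(mc$dinucleotide),
    level = sprintf("%.6f", mc$meth / mc$total),
    meth = mc$meth, total = mc$total)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon (and optional five_prime_UTR/three_prime_UTR)
#' features; when a gene has several transcripts the longest is retained.
#' Exons outside their gene span are a format error.
#'
#' @param path GFF3 file (1-based inclusive coordinates).
#' @return a [GeneModelSet-class].
#' @export
readGFF3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  if (!length(genes)) stop("no gene features in ", path)
  gid <- as.character(genes$ID)
  mrna <- gr[typ == "mRNA"]
  firstParent <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, character(1))
  if (length(mrna)) {
    mParent <- firstParent(mrna$Parent)
    mid <- as.character(mrna$ID)
    # longest transcript per gene
    o <- order(mParent, -GenomicRanges::width(mrna))
    pickTx <- mid[o][!duplicated(mParent[o])]
    names(pickTx) <- mParent[o][!duplicated(mParent[o])]
  } else {
    pickTx <- stats::setNames(gid, gid)  # exons parented to genes directly
  }
  sub <- gr[typ %in% c("exon", "five_prime_UTR", "three_prime_UTR")]
  sParent <- firstParent(sub$Parent)
  keep <- sParent %in% pickTx
  sub <- sub[keep]; sParent <- sParent[keep]
  geneOf <- stats::setNames(names(pickTx), pickTx)
  sGene <- unname(geneOf[sParent])

  out <- genes
  names(out) <- gid
  S4Vectors::mcols(out) <- NULL
  mkList <- function(what) {
    sel <- as.character(sub$type) == what
    grs <- sub[sel]
    S4Vectors::mcols(grs) <- NULL
    f <- factor(sGene[sel], levels = gid)
    gl <- S4Vectors::split(grs, f)
    gl <- gl[gid]
    names(gl) <- gid
    GenomicRanges::GRangesList(lapply(gl, function(e) sort(e, ignore.strand = TRUE)))
  }
  ex <- mkList("exon")
  noEx <- S4Vectors::elementNROWS(ex) == 0
  if (any(noEx)) {
    for (i in which(noEx)) {
      g1 <- out[i]
      S4Vectors::mcols(g1) <- NULL
      ex[[i]] <- g1
    }
  }
  ue <- unlist(ex, use.names = FALSE)
  gi <- rep(seq_along(out), S4Vectors::elementNROWS(ex))
  if (any(GenomicRanges::start(ue) < GenomicRanges::start(out)[gi]) ||
      any(GenomicRanges::end(ue) > GenomicRanges::end(out)[gi]))
    stop("exon outside its gene span in ", path)
  GeneModelSet(out, exons = ex, utr5 = mkList("five_prime_UTR"),
               utr3 = mkList("three_prime_UTR"))
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA (one per gene), exon and UTR features, 1-based
#' inclusive, suitable for round-tripping through [readGFF3Genes()].
#'
#' @param gms a [GeneModelSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGFF3Genes <- function(gms, path) {
  g <- geneRanges(gms)
  ids <- geneIds(gms)
  lines <- c("##gff-version 3")
  fmt <- function(chrom, start, end, type, strand, attrs)
    sprintf("%s\tmethTiler\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, type, start, end, strand, attrs)
  for (i in seq_along(g)) {
    ch <- as.character(GenomicRanges::seqnames(g))[i]
    st <- as.character(GenomicRanges::strand(g))[i]
    gid <- ids[i]; tid <- paste0(gid, ".1")
    lines <- c(lines,
      fmt(ch, GenomicRanges::start(g)[i], GenomicRanges::end(g)[i], "gene",
          st, paste0("ID=", gid)),
      fmt(ch, GenomicRanges::start(g)[i], GenomicRanges::end(g)[i], "mRNA",
          st, paste0("ID=", tid, ";Parent=", gid)))
    emit <- function(grs, type) {
      if (!length(grs)) return(character())
      fmt(ch, GenomicRanges::start(grs), GenomicRanges::end(grs), type, st,
          paste0("Parent=", tid))
    }
    lines <- c(lines,
               emit(exonRanges(gms)[[i]], "exon"),
               emit(utr5Ranges(gms)[[i]], "five_prime_UTR"),
               emit(utr3Ranges(gms)[[i]], "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write DMRs as BED6
#'
#' 0-based half-open intervals; `name` is `context:direction`; `score` is
#' `min(1000, round(-10 * log10(q)))` (q of 1 gives 0; q of 0 saturates at
#' 1000). An empty DMR set yields a file holding only the header comment.
#'
#' @param dmrs data.table from [callDMRs()] (columns `chrom`, `start`,
#'   `end` 1-based inclusive, `context`, `direction`, `qValue`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDMRBed <- function(dmrs, path) {
  header <- "# methTiler DMRs: chrom start end context:direction score strand"
  if (is.null(dmrs) || nrow(dmrs) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  score <- pmin(1000, round(-10 * log10(pmax(dmrs$qValue, 1e-100))))
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.", dmrs$chrom,
                   as.integer(dmrs$start) - 1L, as.integer(dmrs$end),
                   paste0(dmrs$context, ":", dmrs$direction),
                   as.integer(score))
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Write a DMR table with full test statistics
#'
#' @param dmrs data.table from [callDMRs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDMRTable <- function(dmrs, path) {
  data.table::fwrite(dmrs, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write an expression matrix (gene_id + one FPKM column per sample)
#'
#' @param path TSV path.
#' @return `readExpressionMatrix`: numeric matrix, rownames = gene ids.
#' @export
readExpressionMatrix <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  m
}

#' @rdname readExpressionMatrix
#' @param fpkm matrix, genes x samples.
#' @export
writeExpressionMatrix <- function(fpkm, path) {
  dt <- data.table::data.table(gene_id = rownames(fpkm))
  dt <- cbind(dt, data.table::as.data.table(fpkm))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Write a full simulated study to disk
#'
#' Emits the genome FASTA, gene models GFF3, both sample CGmap tables, the
#' ground-truth spiked regions as 0-based half-open BED plus a TSV with
#' deltas, the linked-gene table, and the expression matrix with its
#' design. Output is deterministic: identical simulations produce
#' byte-identical files.
#'
#' @param sim list with `genome`, `genes`, `pair` (from
#'   [simulateMethylomePair()]) and optionally `expr` (from
#'   [simulateExpression()]).
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(sim$genome, p("genome.fa"))
  writeGFF3Genes(sim$genes, p("genes.gff3"))
  writeCGmap(sim$pair$control, p("control.cgmap.tsv"))
  writeCGmap(sim$pair$treatment, p("treatment.cgmap.tsv"))
  reg <- sim$pair$truth$regions
  if (!is.null(reg) && nrow(reg)) {
    bed <- sprintf("%s\t%d\t%d\t%s\t0\t.", reg$chrom,
                   as.integer(reg$start) - 1L, as.integer(reg$end),
                   paste0(reg$context, ":", reg$direction))
    writeLines(c("# true spiked regions (0-based half-open)", bed),
               p("truth_regions.bed"))
    data.table::fwrite(reg, p("truth_regions.tsv"), sep = "\t", quote = FALSE)
  } else {
    writeLines("# true spiked regions (0-based half-open)",
               p("truth_regions.bed"))
  }
  data.table::fwrite(sim$pair$truth$linkedGenes, p("truth_linked_genes.tsv"),
                     sep = "\t", quote = FALSE)
  out <- c(genome = p("genome.fa"), genes = p("genes.gff3"),
           control = p("control.cgmap.tsv"),
           treatment = p("treatment.cgmap.tsv"),
           truthBed = p("truth_regions.bed"))
  if (!is.null(sim$expr)) {
    writeExpressionMatrix(sim$expr$fpkm, p("fpkm.tsv"))
    data.table::fwrite(sim$expr$design, p("design.tsv"), sep = "\t",
                       quote = FALSE)
    out <- c(out, fpkm = p("fpkm.tsv"), design = p("design.tsv"))
  }
  invisible(out)
}
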