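## GFF3 import/export of annotations (1-based inclusive coordinates, the
## GFF3 convention; BED export is 0-based half-open via grToBed).

.GFF_TYPE <- c(V = "V_gene_segment", D = "D_gene_segment",
               J = "J_gene_segment", C = "C_gene_segment")

#' Write an annotation to GFF3
#'
#' Gene features are typed \code{V_gene_segment} / \code{D_gene_segment} /
#' \code{J_gene_segment} / \code{C_gene_segment} with \code{exon} children;
#' functionality, reasons, subgroup, locus, name, flags and RS coordinates
#' are carried as attributes.
#'
#' @param ann A \code{\linkS4class{TRBAnnotation}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeAnnotationGFF3 <- function(ann, path) {
  g <- ann@genes
  if (!length(g)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  mc <- S4Vectors::mcols(g)
  n <- length(g)
  if (is.null(mc$name)) mc$name <- rep(NA_character_, n)
  if (is.null(mc$functionality)) mc$functionality <- rep(NA_character_, n)
  if (is.null(mc$subgroup)) mc$subgroup <- rep(NA_character_, n)
  if (is.null(mc$locus)) mc$locus <- rep(NA_character_, n)
  if (is.null(mc$reasons)) mc$reasons <- IRanges::CharacterList(
    rep(list(character(0)), n))
  if (is.null(mc$flags)) mc$flags <- IRanges::CharacterList(
    rep(list(character(0)), n))
  rsAttr <- vapply(g$gene_id, function(id) {
    r <- if (id %in% names(ann@rs)) ann@rs[[id]] else NULL
    if (is.null(r) || !length(r)) return(NA_character_)
    paste(sprintf("%d..%d/%d..%d:%d", r$heptamer_start, r$heptamer_end,
                  r$nonamer_start, r$nonamer_end, r$spacer_class),
          collapse = ",")
  }, character(1L))
  geneGr <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(g), IRanges::IRanges(GenomicRanges::start(g),
                                                 GenomicRanges::end(g)),
    strand = BiocGenerics::strand(g),
    type = unname(.GFF_TYPE[mc$type]),
    ID = mc$gene_id,
    Name = ifelse(is.na(mc$name), mc$gene_id, mc$name),
    gene_type = mc$type,
    functionality = mc$functionality,
    reasons = vapply(mc$reasons, function(x)
      if (length(x)) paste(x, collapse = ",") else NA_character_,
      character(1L)),
    subgroup = mc$subgroup,
    locus = mc$locus,
    flags = vapply(mc$flags, function(x)
      if (length(x)) paste(x, collapse = ",") else NA_character_,
      character(1L)),
    rs_coordinates = rsAttr)
  exons <- ann@exons[mc$gene_id[mc$gene_id %in% names(ann@exons)]]
  exGr <- unlist(exons, use.names = FALSE)
  if (length(exGr)) {
    parent <- rep(names(exons), lengths(exons))
    S4Vectors::mcols(exGr) <- S4Vectors::DataFrame(
      type = "exon", ID = paste0(parent, ".exon",
                                 unlist(lapply(lengths(exons), seq_len))),
      Parent = parent)
    ## align mcols for concatenation
    for (col in setdiff(colnames(S4Vectors::mcols(geneGr)),
                        colnames(S4Vectors::mcols(exGr)))) {
      S4Vectors::mcols(exGr)[[col]] <- NA_character_
    }
    S4Vectors::mcols(geneGr)$Parent <- NA_character_
    exGr <- exGr[, colnames(S4Vectors::mcols(geneGr))]
    out <- c(geneGr, exGr)
  } else {
    out <- geneGr
  }
  out <- sort(out, ignore.strand = TRUE)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read an annotation back from GFF3
#'
#' Reconstructs a \code{\linkS4class{TRBAnnotation}} from a GFF3 file
#' written by \code{\link{writeAnnotationGFF3}}; write-then-read is
#' semantically identical (records, coordinates, strands, attributes).
#'
#' @param path GFF3 path.
#' @param genome The genome \code{DNAStringSet} the annotation refers to.
#' @return A \code{TRBAnnotation}.
#' @export
readAnnotationGFF3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  isGene <- as.character(gr$type) %in% .GFF_TYPE
  genes <- gr[isGene]
  exons <- gr[as.character(gr$type) == "exon"]
  splitChr <- function(x) {
    if (is.null(x) || is.na(x)) character(0) else
      strsplit(x, ",", fixed = TRUE)[[1L]]
  }
  rsl <- lapply(seq_along(genes), function(i) {
    rsSpec <- genes$rs_coordinates[i]
    if (is.null(rsSpec) || is.na(rsSpec)) return(.emptyRSGRanges())
    parts <- strsplit(rsSpec, ",", fixed = TRUE)[[1L]]
    mm <- regmatches(parts,
                     regexec("^(\\d+)\\.\\.(\\d+)/(\\d+)\\.\\.(\\d+):(\\d+)$",
                             parts))
    vals <- do.call(rbind, lapply(mm, function(m) as.integer(m[-1L])))
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(genes))[i],
      IRanges::IRanges(pmin(vals[, 1L], vals[, 3L]),
                       pmax(vals[, 2L], vals[, 4L])),
      strand = "*",
      heptamer_start = vals[, 1L], heptamer_end = vals[, 2L],
      nonamer_start = vals[, 3L], nonamer_end = vals[, 4L],
      spacer_class = vals[, 5L])
  })
  names(rsl) <- genes$ID
  exl <- lapply(genes$ID, function(id) {
    sel <- exons[vapply(exons$Parent, function(p) id %in% p, logical(1L))]
    sel <- sel[order(GenomicRanges::start(sel))]
    GenomicRanges::granges(sel)
  })
  names(exl) <- genes$ID
  outGenes <- GenomicRanges::granges(genes)
  colOr <- function(x) if (is.null(x)) rep(NA_character_, length(genes)) else x
  listCol <- function(x) {
    if (is.null(x)) x <- rep(NA_character_, length(genes))
    IRanges::CharacterList(lapply(x, splitChr))
  }
  S4Vectors::mcols(outGenes) <- S4Vectors::DataFrame(
    gene_id = genes$ID,
    type = genes$gene_type,
    name = ifelse(genes$Name == genes$ID, NA_character_, genes$Name),
    functionality = colOr(genes$functionality),
    reasons = listCol(genes$reasons),
    subgroup = colOr(genes$subgroup),
    locus = colOr(genes$locus),
    flags = listCol(genes$flags),
    protein = rep(NA_character_, length(genes)))
  methods::new("TRBAnnotation", genome = genome, genes = outGenes,
               exons = GenomicRanges::GRangesList(exl),
               rs = GenomicRanges::GRangesList(rsl))
}

#' Export gene-level functionality report as TSV
#'
#' @param ann A \code{TRBAnnotation}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFunctionalityTSV <- function(ann, path) {
  g <- ann@genes
  df <- data.frame(
    gene_id = g$gene_id, name = g$name, type = g$type,
    contig = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    strand = as.character(BiocGenerics::strand(g)),
    locus = g$locus, subgroup = g$subgroup,
    functionality = g$functionality,
    reasons = vapply(g$reasons, paste, character(1L), collapse = ","),
    flags = vapply(g$flags, paste, character(1L), collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
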