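#' Read a genome or reference FASTA file
#'
#' Loads a (multi-)FASTA file into a \code{DNAStringSet}. Residues are
#' uppercased (soft-masking is discarded), \code{N} is allowed, record ids are
#' taken as the first whitespace-delimited token of each header and must be
#' unique. Empty files and zero-length records are rejected.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("FASTA file contains no records: ", path)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x))) {
    dup <- unique(names(x)[duplicated(names(x))])
    stop("duplicate sequence id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  if (any(width(x) == 0L)) {
    stop("empty record(s) in ", path, ": ",
         paste(names(x)[width(x) == 0L], collapse = ", "))
  }
  Biostrings::DNAStringSet(toupper(x))
}

#' Write sequences to FASTA
#'
#' @param x A named \code{DNAStringSet} (or object coercible to one).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
writeGenomeFasta <- function(x, path, width = 70L) {
  x <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Extract strand-aware subsequences
#'
#' Extracts the subsequence covered by each range in \code{gr} from the
#' matching sequence in \code{genome}; minus-strand ranges return the reverse
#' complement, so the result always reads 5' to 3' on the gene strand.
#'
#' @param genome A named \code{DNAStringSet}.
#' @param gr A \code{GRanges} with seqnames matching names of \code{genome}.
#' @return A \code{DNAStringSet}, one entry per range.
#' @export
extractSeq <- function(genome, gr) {
  sn <- as.character(GenomicRanges::seqnames(gr))
  bad <- !(sn %in% names(genome))
  if (any(bad)) stop("unknown contig(s): ", paste(unique(sn[bad]), collapse = ", "))
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  len <- width(genome)[match(sn, names(genome))]
  oob <- st < 1L | en > len | st > en
  if (any(oob)) {
    i <- which(oob)[1L]
    stop("interval out of bounds: ", sn[i], ":", st[i], "-", en[i],
         " (contig length ", len[i], ")")
  }
  out <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i) {
    as.character(Biostrings::subseq(genome[[sn[i]]], st[i], en[i]))
  }, character(1L)))
  minus <- as.character(BiocGenerics::strand(gr)) == "-"
  if (any(minus)) out[minus] <- Biostrings::reverseComplement(out[minus])
  names(out) <- if (!is.null(names(gr))) names(gr) else NULL
  out
}

#' Translate DNA in a given frame
#'
#' Standard genetic code; stops are rendered as \code{*}, codons containing
#' residues outside A/C/G/T as \code{X}; a trailing partial codon is dropped.
#'
#' @param dna A DNA string (character, \code{DNAString} or length-1
#'   \code{DNAStringSet}).
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return A character scalar of amino acids.
#' @export
translateDNA <- function(dna, frame = 0L) {
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  s <- toupper(as.character(dna))
  if (length(s) != 1L) stop("translateDNA expects a single sequence")
  s <- substr(s, frame + 1L, nchar(s))
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  s <- substr(s, 1L, n)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .CODON_TABLE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

.CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aa <- vapply(codons, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1L))
  stats::setNames(aa, codons)
})

#' Reverse complement of a character DNA string
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert GRanges to BED-style 0-based half-open coordinates
#'
#' @param gr A \code{GRanges}.
#' @return A \code{data.frame} with columns chrom, chromStart (0-based),
#'   chromEnd (exclusive), name, score, strand.
#' @export
grToBed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    chromStart = GenomicRanges::start(gr) - 1L,
    chromEnd = GenomicRanges::end(gr),
    name = if (!is.null(names(gr))) names(gr) else ".",
    score = 0L,
    strand = as.character(BiocGenerics::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Convert a BED-style data.frame back to GRanges
#' @param bed A data.frame as produced by \code{grToBed}.
#' @return A \code{GRanges} (1-based inclusive).
#' @export
bedToGr <- function(bed) {
  gr <- GenomicRanges::GRanges(
    seqnames = bed$chrom,
    ranges = IRanges::IRanges(start = bed$chromStart + 1L, end = bed$chromEnd),
    strand = bed$strand
  )
  if (!is.null(bed$name) && !all(bed$name == ".")) names(gr) <- bed$name
  gr
}

#' Read reads from a FASTQ file
#'
#' Qualities are not used by the expression module and are discarded.
#'
#' @param path Path to a FASTQ file (optionally gzipped).
#' @return A \code{DNAStringSet} of reads.
#' @export
readReadsFastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write reads to FASTQ with constant quality
#' @param reads A named \code{DNAStringSet}.
#' @param path Output path.
#' @param qual Single Sanger quality character used for every base.
#' @return Invisibly, \code{path}.
#' @export
writeReadsFastq <- function(reads, path, qual = "I") {
  quals <- Biostrings::BStringSet(vapply(width(reads), function(w) {
    paste(rep(qual, w), collapse = "")
  }, character(1L)))
  Biostrings::writeXStringSet(reads, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}
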