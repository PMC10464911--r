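#' @import methods
#' @importFrom stats setNames
NULL

#' TRBAnnotation: an annotated set of TRB gene segments
#'
#' Container for the result of annotating one or more contigs: the genome,
#' one range per called gene with its evidence and classification, exon
#' structures, and attached recombination-signal (RS) hits.
#'
#' Metadata columns of \code{geneCalls()}: \code{gene_id}, \code{type}
#' (V/D/J/C), \code{name}, \code{functionality} (F/ORF/P), \code{reasons}
#' (CharacterList of machine-readable codes), \code{subgroup}, \code{locus},
#' \code{flags} (CharacterList), \code{protein}.
#'
#' @slot genome A \code{DNAStringSet} of the annotated contigs.
#' @slot genes A \code{GRanges}, one range per gene (coding span).
#' @slot exons A \code{GRangesList} keyed by \code{gene_id}.
#' @slot rs A \code{GRangesList} of RS hits keyed by \code{gene_id}.
#' @aliases TRBAnnotation
#' @exportClass TRBAnnotation
setClass("TRBAnnotation", representation(
  genome = "DNAStringSet",
  genes = "GRanges",
  exons = "GRangesList",
  rs = "GRangesList"
))

setValidity("TRBAnnotation", function(object) {
  msg <- NULL
  g <- object@genes
  need <- c("gene_id", "type")
  if (length(g) && !all(need %in% colnames(S4Vectors::mcols(g))))
    msg <- c(msg, "genes must carry gene_id and type metadata columns")
  if (length(g) && anyDuplicated(g$gene_id))
    msg <- c(msg, "gene_id values must be unique")
  if (length(g) && !all(g$type %in% c("V", "D", "J", "C")))
    msg <- c(msg, "gene type must be one of V, D, J, C")
  if (length(object@exons) &&
      !all(names(object@exons) %in% g$gene_id))
    msg <- c(msg, "exon list names must match gene ids")
  if (is.null(msg)) TRUE else msg
})

#' TRBLocusStructure: loci and the locus-level duplication pattern
#'
#' @slot loci A \code{GRanges}, one per locus, with metadata columns
#'   \code{locus_id}, \code{orientation}, \code{n_v}, \code{n_d}, \code{n_j},
#'   \code{n_c}, \code{complete}.
#' @slot orphans A \code{GRanges} of genes assignable to no locus.
#' @slot pattern One of \code{head_to_head_pair}, \code{single},
#'   \code{remnant}, \code{tandem_DJC_duplication}, \code{none}.
#' @slot notes Character notes.
#' @exportClass TRBLocusStructure
setClass("TRBLocusStructure", representation(
  loci = "GRanges",
  orphans = "GRanges",
  pattern = "character",
  notes = "character"
))

setValidity("TRBLocusStructure", function(object) {
  ok <- object@pattern %in% c("head_to_head_pair", "single", "remnant",
                              "tandem_DJC_duplication", "none")
  if (all(ok)) TRUE else "unknown pattern label"
})

#' TRBTruthSet: a ground-truthed synthetic genome
#'
#' Output of \code{\link{generateLocusGenome}}: the simulated genome, the
#' planted gene features with exact coordinates and planted functionality
#' labels, the C-gene transcripts, and the reference library (subgroup
#' ancestor sequences) the genome was generated from.
#'
#' @slot genome \code{DNAStringSet}.
#' @slot features \code{GRanges} with \code{gene_id}, \code{type},
#'   \code{label} (planted F/ORF/P), \code{subgroup}, \code{locus},
#'   \code{op} (mutation operator applied).
#' @slot exons,rs \code{GRangesList} keyed by \code{gene_id}.
#' @slot transcripts \code{DNAStringSet} of C transcripts (TRBC1, TRBC2).
#' @slot refs Reference library: ancestor V-EXON, leader and C sequences,
#'   numbering profiles.
#' @slot config The generating configuration.
#' @exportClass TRBTruthSet
setClass("TRBTruthSet", representation(
  genome = "DNAStringSet",
  features = "GRanges",
  exons = "GRangesList",
  rs = "GRangesList",
  transcripts = "DNAStringSet",
  refs = "list",
  config = "list"
))

#' TRBExpression: TRBC read-assignment and RPKM result
#'
#' @slot counts Named integer vector of assigned reads per reference.
#' @slot refLength Named integer vector of reference lengths (bases).
#' @slot totalReads Total input reads (library depth used for RPKM).
#' @slot rpkm Named numeric vector of RPKM values.
#' @slot discarded Named integer vector: \code{too_many_mismatches},
#'   \code{ambiguous_tie}, \code{unmapped}.
#' @slot ratio Raw TRBC1/TRBC2 RPKM ratio (NA if undefined).
#' @slot ratioReported Ratio rounded half away from zero to 1 decimal.
#' @exportClass TRBExpression
setClass("TRBExpression", representation(
  counts = "integer",
  refLength = "integer",
  totalReads = "numeric",
  rpkm = "numeric",
  discarded = "integer",
  ratio = "numeric",
  ratioReported = "numeric"
))

setValidity("TRBExpression", function(object) {
  msg <- NULL
  if (!identical(names(object@counts), names(object@rpkm)))
    msg <- c(msg, "counts and rpkm must be parallel named vectors")
  if (is.null(msg)) TRUE else msg
})

## ------------------------------------------------------------------ accessors

#' @describeIn TRBAnnotation-accessors The gene-level \code{GRanges}.
#' @export
geneCalls <- function(x) x@genes

#' @describeIn TRBAnnotation-accessors Exon structures per gene.
#' @export
geneExons <- function(x) x@exons

#' @describeIn TRBAnnotation-accessors RS hits per gene.
#' @export
geneRS <- function(x) x@rs

#' @name TRBAnnotation-accessors
#' @title Accessors for annotation and truth-set objects
#' @param x A \code{TRBAnnotation} or \code{TRBTruthSet}.
#' @describeIn TRBAnnotation-accessors The underlying genome sequences.
#' @export
genomeSeq <- function(x) x@genome

#' @describeIn TRBAnnotation-accessors Planted truth features of a
#'   \code{TRBTruthSet}.
#' @export
truthFeatures <- function(x) x@features

#' @describeIn TRBAnnotation-accessors Reference library of a
#'   \code{TRBTruthSet} (ancestor sequences and numbering profiles).
#' @export
refLibrary <- function(x) x@refs

#' @describeIn TRBAnnotation-accessors C-gene transcripts of a
#'   \code{TRBTruthSet}.
#' @export
truthTranscripts <- function(x) x@transcripts

setMethod("show", "TRBAnnotation", function(object) {
  g <- object@genes
  cat("TRBAnnotation with", length(g), "gene calls on",
      length(object@genome), "contig(s)\n")
  if (length(g)) {
    tab <- table(factor(g$type, c("V", "D", "J", "C")))
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = "  "), "\n")
    if ("functionality" %in% colnames(S4Vectors::mcols(g))) {
      f <- table(factor(g$functionality, c("F", "ORF", "P")))
      cat("  functionality ",
          paste(names(f), f, sep = ": ", collapse = "  "), "\n")
    }
  }
})

setMethod("show", "TRBLocusStructure", function(object) {
  cat("TRBLocusStructure:", length(object@loci), "locus/loci, pattern:",
      object@pattern, "\n")
  if (length(object@orphans))
    cat("  orphan genes:", length(object@orphans), "\n")
})

setMethod("show", "TRBTruthSet", function(object) {
  cat("TRBTruthSet:", sum(width(object@genome)), "bp over",
      length(object@genome), "contig(s);",
      length(object@features), "planted genes\n")
})

setMethod("show", "TRBExpression", function(object) {
  cat("TRBExpression over", object@totalReads, "input reads\n")
  df <- data.frame(count = object@counts,
                   length = object@refLength,
                   rpkm = round(object@rpkm, 2))
  print(df)
  cat("discarded:", paste(names(object@discarded), object@discarded,
                          sep = "=", collapse = " "), "\n")
  cat("TRBC1/TRBC2 RPKM ratio:", object@ratioReported,
      sprintf("(raw %.4f)\n", object@ratio))
})
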