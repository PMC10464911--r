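## Comparative summaries: subgroup-by-locus count matrix, C-subgroup
## classification, and locus-architecture reports.

#' Subgroup-by-locus count matrix of V genes
#'
#' Tallies named, classified V genes per (subgroup, locus,
#' functionality class), with row/column margins. The margins always
#' reconcile with the annotation set.
#'
#' @param ann A \code{\linkS4class{TRBAnnotation}} with functionality and
#'   subgroup columns filled, or a \code{GRanges}/\code{data.frame} with
#'   columns \code{type}, \code{subgroup}, \code{locus},
#'   \code{functionality} (and \code{name}).
#' @return A list: \code{counts} (matrix, rows = subgroups, columns =
#'   locus.class), \code{rowTotals}, \code{colTotals}, \code{total}.
#' @export
subgroupCountTable <- function(ann) {
  df <- if (methods::is(ann, "TRBAnnotation")) {
    as.data.frame(S4Vectors::mcols(ann@genes))
  } else if (methods::is(ann, "GRanges")) {
    as.data.frame(S4Vectors::mcols(ann))
  } else {
    as.data.frame(ann)
  }
  df <- df[df$type == "V", , drop = FALSE]
  if (!nrow(df)) {
    return(list(counts = matrix(0L, 0L, 0L), rowTotals = integer(0),
                colTotals = integer(0), total = 0L))
  }
  if ("name" %in% colnames(df) && any(is.na(df$name)))
    stop("unnamed V gene(s): ",
         paste(utils::head(df$gene_id[is.na(df$name)], 5L), collapse = ", "))
  if (any(is.na(df$subgroup)))
    stop("V gene(s) without subgroup: ",
         paste(utils::head(df$gene_id[is.na(df$subgroup)], 5L), collapse = ", "))
  loc <- ifelse(is.na(df$locus), "remnant", as.character(df$locus))
  fun <- factor(df$functionality, c("F", "ORF", "P"))
  col <- paste(loc, fun, sep = ".")
  tab <- table(subgroup = df$subgroup, col)
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = dimnames(tab))
  list(counts = counts,
       rowTotals = rowSums(counts),
       colTotals = colSums(counts),
       total = sum(counts))
}

#' Classify C genes into C1/C2 subgroups
#'
#' Computes the pairwise amino-acid identity matrix of the C-gene
#' products, single-linkage clusters at the C-subgroup threshold (default
#' 85\% amino-acid identity, chosen to separate near-identical
#' same-chromosome copies from the roughly 70\%-identical other subgroup),
#' labels clusters by their best-identity exemplar, and, when at least 4
#' genes are present and pre-aligned (equal lengths), attaches the NJ
#' bootstrap support of the bipartition separating the two subgroups.
#'
#' @param cProteins Named \code{AAStringSet} of translated C genes.
#' @param exemplars Named \code{AAStringSet} with entries \code{C1} and
#'   \code{C2}.
#' @param threshold Percent amino-acid identity for clustering (strict).
#' @param nReplicates,seed Bootstrap settings (used when supports are
#'   computable).
#' @return A list: \code{identity} (matrix), \code{assignment} (named
#'   character C1/C2 per gene), \code{support} (percent, or NA),
#'   \code{clusters}.
#' @export
classifyCSubgroups <- function(cProteins, exemplars, threshold = 85,
                               nReplicates = 100L, seed = 1L) {
  if (length(cProteins) < 2L) stop("need at least 2 C genes")
  untranslatable <- grepl("\\*.", as.character(cProteins))
  if (any(untranslatable)) {
    warning("excluding C gene(s) with internal stops: ",
            paste(names(cProteins)[untranslatable], collapse = ", "))
    cProteins <- cProteins[!untranslatable]
  }
  idm <- pairwiseIdentity(cProteins)
  cl <- clusterSubgroups(idm, threshold = threshold)
  assignment <- rep(NA_character_, length(cProteins))
  names(assignment) <- names(cProteins)
  for (k in unique(cl$membership)) {
    members <- names(cl$membership)[cl$membership == k]
    best <- -Inf; bestLab <- NA_character_
    for (g in members) {
      pids <- .pidAgainst(exemplars, cProteins[[g]], TRUE)
      i <- which.max(pids)
      if (pids[i] > best) { best <- pids[i]; bestLab <- names(exemplars)[i] }
    }
    assignment[members] <- bestLab
  }
  support <- NA_real_
  if (length(cProteins) >= 4L &&
      length(unique(width(cProteins))) == 1L &&
      length(unique(assignment)) == 2L) {
    tr <- bootstrapSupports(cProteins, nReplicates = nReplicates,
                            seed = seed, model = "poisson")
    bp <- .bipartitions(tr)
    target <- sort(names(assignment)[assignment == sort(unique(assignment))[1L]])
    if (sort(tr$tip.label)[1L] %in% target)
      target <- sort(setdiff(tr$tip.label, target))
    key <- paste(target, collapse = "|")
    hit <- match(key, bp$bips)
    if (!is.na(hit)) support <- attr(tr, "supports")[hit]
  }
  list(identity = idm, assignment = assignment, support = support,
       clusters = cl$membership)
}

#' Locus architecture report
#'
#' Renders each contig's loci as an ordered gene-class string with
#' orientations (for example \code{"C<-J(10)<-D<-V(21) | V(20)->D->J(10)->C"})
#' together with the detected duplication pattern and per-locus V counts.
#'
#' @param structures A \code{TRBLocusStructure} or list of them (one per
#'   contig).
#' @param annotations Optional list of gene records used for gene ordering;
#'   when omitted the locus summary counts are used.
#' @return A \code{data.frame}: contig, pattern, n_loci, n_orphans,
#'   architecture, v_counts.
#' @export
locusArchitectureReport <- function(structures, annotations = NULL) {
  if (methods::is(structures, "TRBLocusStructure"))
    structures <- list(structures)
  rows <- lapply(structures, function(s) {
    loci <- s@loci
    if (!length(loci)) {
      return(data.frame(contig = NA_character_, pattern = s@pattern,
                        n_loci = 0L, n_orphans = length(s@orphans),
                        architecture = "", v_counts = ""))
    }
    o <- order(GenomicRanges::start(loci))
    parts <- vapply(o, function(i) {
      fwd <- as.character(BiocGenerics::strand(loci))[i] == "+"
      seg <- c(if (loci$n_v[i] > 0L) sprintf("V(%d)", loci$n_v[i]),
               if (loci$n_d[i] > 0L) "D",
               if (loci$n_j[i] > 0L) sprintf("J(%d)", loci$n_j[i]),
               if (loci$n_c[i] > 0L) "C")
      if (fwd) paste(seg, collapse = "->") else
        paste(rev(seg), collapse = "<-")
    }, character(1L))
    data.frame(
      contig = as.character(GenomicRanges::seqnames(loci))[1L],
      pattern = s@pattern,
      n_loci = length(loci),
      n_orphans = length(s@orphans),
      architecture = paste(parts, collapse = " | "),
      v_counts = paste(loci$n_v[o], collapse = ","))
  })
  do.call(rbind, rows)
}
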