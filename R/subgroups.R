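## V gene subgroup clustering at the >75% nucleotide identity threshold,
## mapping onto a reference subgroup set, and positional gene naming.

#' Pairwise percent identity matrix
#'
#' Global (Needleman-Wunsch, affine gap) alignment of every pair; identity
#' is matches over alignment columns, times 100. Nucleotide scoring is
#' match +1 / mismatch -1, gap open -4, gap extend -1 per base; amino-acid
#' sequences are aligned with BLOSUM62.
#'
#' @param seqs A named \code{DNAStringSet} or \code{AAStringSet}
#'   (at least 2 sequences).
#' @return A symmetric numeric matrix with 100 on the diagonal.
#' @export
pairwiseIdentity <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (any(width(seqs) == 0L))
    stop("empty sequence: ",
         paste(names(seqs)[width(seqs) == 0L], collapse = ", "))
  isAA <- methods::is(seqs, "AAStringSet")
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (j in 2:n) {
    pids <- .pidAgainst(seqs[seq_len(j - 1L)], seqs[[j]], isAA)
    m[seq_len(j - 1L), j] <- pids
    m[j, seq_len(j - 1L)] <- pids
  }
  m
}

## percent identity of each sequence in `set` against `subject`
## (global alignment; identity = matches / alignment columns)
.pidAgainst <- function(set, subject, isAA = methods::is(set, "AAStringSet")) {
  aln <- if (isAA) {
    Biostrings::pairwiseAlignment(set, subject, type = "global",
                                  substitutionMatrix = "BLOSUM62",
                                  gapOpening = 10, gapExtension = 0.5)
  } else {
    Biostrings::pairwiseAlignment(
      set, subject, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
  }
  nIns <- sum(width(Biostrings::insertion(aln)))
  nDel <- sum(width(Biostrings::deletion(aln)))
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) + nIns + nDel
  100 * Biostrings::nmatch(aln) / cols
}

#' Cluster genes into subgroups by identity threshold
#'
#' Single-linkage connected components over edges with identity strictly
#' greater than the threshold (genes at exactly the threshold are NOT
#' linked). Component labels are canonical: ordered by component size, then
#' by the first member's input position, so clustering is invariant to
#' input order.
#'
#' @param mat Identity matrix from \code{\link{pairwiseIdentity}}.
#' @param threshold Percent identity threshold (default 75; strict
#'   inequality).
#' @param linkage \code{"single"} (default) or \code{"complete"}.
#' @return A list: \code{membership} (named integer vector of subgroup
#'   indices) and \code{sizes}.
#' @export
clusterSubgroups <- function(mat, threshold = 75, linkage = c("single",
                                                              "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(mat)
  if (n == 0L) return(list(membership = integer(0), sizes = integer(0)))
  if (linkage == "single") {
    comp <- seq_len(n)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (mat[i, j] > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
    root <- vapply(seq_len(n), find, integer(1L))
  } else {
    hc <- stats::hclust(stats::as.dist(100 - mat), method = "complete")
    root <- stats::cutree(hc, h = 100 - threshold - 1e-9)
  }
  ## canonical labels: by size desc, then first member position
  tab <- table(root)
  first <- vapply(names(tab), function(r) min(which(root == as.integer(r))),
                  integer(1L))
  o <- order(-as.integer(tab), first)
  relabel <- stats::setNames(seq_along(o), names(tab)[o])
  membership <- relabel[as.character(root)]
  names(membership) <- rownames(mat)
  list(membership = membership,
       sizes = as.integer(table(membership)))
}

#' Map clusters onto reference subgroup labels
#'
#' Each cluster takes the label of the reference exemplar with the best
#' identity to any member, provided that identity exceeds the threshold;
#' otherwise the cluster is flagged novel and receives the next free
#' subgroup number.
#'
#' @param membership Named integer vector from \code{\link{clusterSubgroups}}.
#' @param seqs The clustered sequences (\code{DNAStringSet}, names matching
#'   \code{membership}).
#' @param refLib Named \code{DNAStringSet} of subgroup exemplars; names of
#'   the form \code{TRBV13} carry the subgroup number.
#' @param threshold Identity required to inherit a reference label
#'   (default 75, strict).
#' @return A \code{data.frame}: \code{gene}, \code{cluster},
#'   \code{subgroup} (label), \code{subgroup_number}, \code{novel}.
#' @export
mapToReferenceSubgroups <- function(membership, seqs, refLib,
                                    threshold = 75) {
  stopifnot(length(membership) == length(seqs))
  refNums <- suppressWarnings(as.integer(sub("^\\D*", "", names(refLib))))
  clusters <- sort(unique(membership))
  labels <- character(length(clusters)); nums <- integer(length(clusters))
  novel <- logical(length(clusters))
  usedNums <- refNums[!is.na(refNums)]
  nextNum <- if (length(usedNums)) max(usedNums) + 1L else 1L
  isAA <- methods::is(seqs, "AAStringSet")
  for (k in seq_along(clusters)) {
    members <- names(membership)[membership == clusters[k]]
    best <- -Inf; bestRef <- NA_character_
    for (g in members) {
      pids <- .pidAgainst(refLib, seqs[[g]], isAA)
      i <- which.max(pids)
      if (pids[i] > best) { best <- pids[i]; bestRef <- names(refLib)[i] }
    }
    if (best > threshold) {
      labels[k] <- bestRef
      nums[k] <- refNums[match(bestRef, names(refLib))]
    } else {
      labels[k] <- paste0("novel", nextNum)
      nums[k] <- nextNum
      novel[k] <- TRUE
      nextNum <- nextNum + 1L
    }
  }
  data.frame(gene = names(membership),
             cluster = unname(membership),
             subgroup = labels[match(membership, clusters)],
             subgroup_number = nums[match(membership, clusters)],
             novel = novel[match(membership, clusters)],
             stringsAsFactors = FALSE)
}

#' Assign positional gene names
#'
#' Names follow the salmonid TRB convention: \code{TRB} + locus number
#' (defined by the associated D-J-C cluster) + gene-type letter; V and C
#' genes carry their subgroup number and a dash-rank counted 5' to 3' along
#' the locus transcriptional orientation within (locus, subgroup) -- e.g.
#' \code{TRB2V13-4} is the 4th subgroup-13 V gene of locus TRB2. J genes
#' are numbered positionally (\code{TRB1J1}..), D genes are \code{TRB1D}.
#' C ranks run across loci within a C subgroup, ordered by locus number
#' (\code{TRB1C1-1}, \code{TRB2C1-2}). Ranks follow the transcriptional,
#' not the assembly, orientation, so names are invariant under
#' reverse-complementing a contig.
#'
#' @param recs Gene records with \code{locus} assignments (from
#'   \code{\link{assembleLoci}}) and, for V/C genes, a
#'   \code{subgroup_number} field.
#' @param contigOrder Character vector fixing the contig order used for
#'   locus numbering (default: order of first appearance).
#' @param remnantLocusNumber Locus number given to orphan (remnant) V
#'   genes; default: one past the last assembled locus.
#' @return The records with \code{name} fields set.
#' @export
assignNames <- function(recs, contigOrder = NULL, remnantLocusNumber = NULL) {
  if (!length(recs)) return(recs)
  ct <- vapply(recs, `[[`, character(1L), "contig")
  if (is.null(contigOrder)) contigOrder <- unique(ct)
  locus <- vapply(recs, function(r)
    if (is.null(r$locus) || is.na(r$locus)) NA_integer_ else r$locus,
    integer(1L))
  st <- vapply(recs, function(r) as.numeric(r$range[1L]), numeric(1L))
  strand <- vapply(recs, `[[`, character(1L), "strand")
  type <- vapply(recs, `[[`, character(1L), "type")

  ## locus numbering: by contig order, then C-gene position within contig
  lids <- unique(locus[!is.na(locus)])
  cPos <- vapply(lids, function(l) {
    i <- which(locus == l & type == "C")
    if (length(i)) min(st[i]) else min(st[locus == l])
  }, numeric(1L))
  lCt <- vapply(lids, function(l) ct[which(locus == l)[1L]], character(1L))
  o <- order(match(lCt, contigOrder), cPos)
  locusNumber <- stats::setNames(seq_along(lids), lids[o])
  ln <- function(i) locusNumber[[as.character(locus[i])]]

  if (is.null(remnantLocusNumber))
    remnantLocusNumber <- length(lids) + 1L

  ## transcriptional-order rank within groups
  rankWithin <- function(idx) {
    key <- ifelse(strand[idx] == "+", st[idx], -st[idx])
    rank(key, ties.method = "first")
  }
  for (i in seq_along(recs)) {
    recs[[i]]$name <- NA_character_
    recs[[i]]$locusNumber <- if (!is.na(locus[i])) ln(i)
      else if (type[i] == "V") remnantLocusNumber else NA_integer_
  }

  ## V genes
  vIdx <- which(type == "V")
  if (length(vIdx)) {
    sg <- vapply(vIdx, function(i) {
      s <- recs[[i]]$subgroup_number
      if (is.null(s) || is.na(s)) stop("V gene without subgroup assignment: ",
                                       if (!is.null(recs[[i]]$gene_id))
                                         recs[[i]]$gene_id else i)
      as.integer(s)
    }, integer(1L))
    lnum <- vapply(vIdx, function(i) {
      if (is.na(locus[i])) remnantLocusNumber else ln(i)
    }, integer(1L))
    for (key in unique(paste(lnum, sg))) {
      sel <- vIdx[paste(lnum, sg) == key]
      rk <- rankWithin(sel)
      for (z in seq_along(sel)) {
        i <- sel[z]
        recs[[i]]$name <- sprintf("TRB%dV%d-%d",
                                  lnum[match(i, vIdx)], sg[match(i, vIdx)],
                                  rk[z])
      }
    }
  }
  ## D genes
  for (i in which(type == "D" & !is.na(locus)))
    recs[[i]]$name <- sprintf("TRB%dD", ln(i))
  ## J genes
  jIdx <- which(type == "J" & !is.na(locus))
  for (l in unique(locus[jIdx])) {
    sel <- jIdx[locus[jIdx] == l]
    rk <- rankWithin(sel)
    for (z in seq_along(sel))
      recs[[sel[z]]]$name <- sprintf("TRB%dJ%d", ln(sel[z]), rk[z])
  }
  ## C genes: rank across loci within C subgroup, by locus number
  cIdx <- which(type == "C" & !is.na(locus))
  if (length(cIdx)) {
    csub <- vapply(cIdx, function(i) {
      s <- recs[[i]]$subgroup_number
      if (is.null(s) || is.na(s)) 1L else as.integer(s)
    }, integer(1L))
    for (s in unique(csub)) {
      sel <- cIdx[csub == s]
      lnums <- vapply(sel, ln, integer(1L))
      rk <- rank(lnums, ties.method = "first")
      for (z in seq_along(sel))
        recs[[sel[z]]]$name <- sprintf("TRB%dC%d-%d", lnums[z], s, rk[z])
    }
  }
  recs
}
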