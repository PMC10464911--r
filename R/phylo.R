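## Distance matrices, neighbor-joining trees and bootstrap supports.
##
## The tree-building protocol mirrors the study design at desk scale:
## neighbor joining on pairwise-deletion distances with bootstrap supports
## mapped onto the full-data tree. For nucleotide alignments the default
## model is the p-distance; for proteins the Poisson correction
## -ln(1 - p). (A rate-matrix model is deliberately not offered: with
## nucleotide inputs a JTT-style amino-acid matrix is not applicable, so
## topology-level agreement is the comparison standard; see the vignette.)

.alnToMatrix <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    ws <- unique(width(alignment))
    if (length(ws) != 1L) stop("aligned sequences must have equal length")
    m <- do.call(rbind, strsplit(as.character(alignment), ""))
    rownames(m) <- names(alignment)
    attr(m, "seqtype") <- if (methods::is(alignment, "AAStringSet")) "AA" else "DNA"
    return(m)
  }
  if (is.matrix(alignment)) {
    m <- alignment
  } else {
    m <- do.call(rbind, strsplit(toupper(as.character(alignment)), ""))
    rownames(m) <- names(alignment)
  }
  if (is.null(attr(m, "seqtype"))) {
    attr(m, "seqtype") <- if (all(m %in% c("A", "C", "G", "T", "U", "N",
                                           "-", ".", "?"))) "DNA" else "AA"
  }
  m
}

#' Compute a pairwise distance matrix from an alignment
#'
#' Supported models: \code{p} (proportion of differing sites),
#' \code{poisson} (-ln(1 - p), the protein correction) and \code{k2p}
#' (Kimura 2-parameter from transition/transversion counts). Under
#' pairwise deletion, sites with a gap (or ambiguity) in either sequence of
#' a pair are skipped for that pair only; under complete deletion such
#' sites are dropped for all pairs. Saturated entries (p >= 1 for poisson,
#' non-positive log argument for k2p) are set to \code{ceiling} and
#' recorded in the \code{"saturated"} attribute.
#'
#' @param alignment Aligned sequences (\code{DNAStringSet},
#'   \code{AAStringSet}, character vector or character matrix; equal
#'   lengths).
#' @param model \code{"p"}, \code{"poisson"} or \code{"k2p"}.
#' @param deletion \code{"pairwise"} (default) or \code{"complete"}.
#' @param ceiling Value assigned to saturated entries.
#' @return A symmetric numeric matrix with zero diagonal and attributes
#'   \code{deletion} and \code{saturated} (logical matrix).
#' @export
computeDistances <- function(alignment, model = c("p", "poisson", "k2p"),
                             deletion = c("pairwise", "complete"),
                             ceiling = 10) {
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- .alnToMatrix(alignment)
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  n <- nrow(m)
  gapChars <- if (identical(attr(m, "seqtype"), "AA"))
    c("-", ".", "X", "?", "*") else c("-", ".", "N", "?")
  valid <- !(m %in% gapChars)
  dim(valid) <- dim(m)
  if (deletion == "complete") {
    keep <- apply(valid, 2L, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- matrix(FALSE, n, n, dimnames = dimnames(d))
  if (n < 2L) return(structure(d, deletion = deletion, saturated = sat))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      nc <- sum(ok)
      if (nc == 0L) { d[i, j] <- d[j, i] <- ceiling; sat[i, j] <- sat[j, i] <- TRUE; next }
      xi <- m[i, ok]; xj <- m[j, ok]
      diff <- xi != xj
      p <- sum(diff) / nc
      val <- switch(model,
        p = p,
        poisson = if (p >= 1) NA_real_ else -log(1 - p),
        k2p = {
          ts <- sum(diff & ((xi == "A" & xj == "G") | (xi == "G" & xj == "A") |
                              (xi == "C" & xj == "T") | (xi == "T" & xj == "C")))
          P <- ts / nc; Q <- (sum(diff) - ts) / nc
          a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
          if (a1 <= 0 || a2 <= 0) NA_real_
          else -0.5 * log(a1) - 0.25 * log(a2)
        })
      if (is.na(val)) {
        d[i, j] <- d[j, i] <- ceiling
        sat[i, j] <- sat[j, i] <- TRUE
      } else {
        d[i, j] <- d[j, i] <- val
      }
    }
  }
  structure(d, deletion = deletion, saturated = sat)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q criterion and a
#' deterministic tie-break: among equal-Q pairs, the lexicographically
#' lowest pair of original taxon indices joins first. Negative branch
#' length estimates are clamped to zero; the unclamped values are kept in
#' the \code{"unclamped.length"} attribute of the returned tree. NJ
#' exactly recovers the generating tree from any additive distance matrix.
#'
#' @param d Symmetric distance matrix with at least 3 taxa.
#' @return An \code{ape} \code{phylo} object (unrooted).
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nTips <- n
  ## node bookkeeping: tips 1..n, internal nodes numbered from n+1
  active <- seq_len(n)                 # node ids of current clusters
  origMin <- seq_len(n)                # lowest original index per cluster
  D <- d
  edges <- matrix(0L, 0L, 2L); elens <- numeric(0)
  nextNode <- n + 2L                   # n+1 reserved for the root join
  nodeCount <- n
  while (length(active) > 3L) {
    r <- length(active)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- cbind(pmin(origMin[cand[, 1L]], origMin[cand[, 2L]]),
                 pmax(origMin[cand[, 1L]], origMin[cand[, 2L]]))
    o <- order(key[, 1L], key[, 2L])[1L]
    i <- cand[o, 1L]; j <- cand[o, 2L]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    newNode <- nextNode; nextNode <- nextNode + 1L
    edges <- rbind(edges, c(newNode, active[i]), c(newNode, active[j]))
    elens <- c(elens, li, lj)
    dn <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
                c(dn[keep], 0))
    active <- c(active[keep], newNode)
    origMin <- c(origMin[keep], min(origMin[c(i, j)]))
    D <- D2
  }
  ## final join of 3 clusters at one internal node (the NJ "root")
  root <- n + 1L
  if (length(active) == 3L) {
    a <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
    b <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
    cc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
    edges <- rbind(edges, c(root, active[1L]), c(root, active[2L]),
                   c(root, active[3L]))
    elens <- c(elens, a, b, cc)
  } else stop("degenerate input")
  ## renumber internal nodes to ape convention (root = n+1 first)
  nInternal <- nTips + (nextNode - nTips - 2L) + 1L
  tr <- list()
  tr$edge <- edges
  tr$edge.length <- pmax(elens, 0)
  tr$tip.label <- labels
  tr$Nnode <- nInternal - nTips
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr <- .renumberPhylo(tr, nTips)
  attr(tr, "unclamped.length") <- elens[attr(tr, "edge.perm")]
  attr(tr, "edge.perm") <- NULL
  tr
}

## Reorder edges/nodes so that internal node ids follow ape's convention
## (root first at nTips+1, edges in preorder).
.renumberPhylo <- function(tr, nTips) {
  edges <- tr$edge
  root <- nTips + 1L
  children <- split(seq_len(nrow(edges)), edges[, 1L])
  newId <- integer(max(edges))
  newId[seq_len(nTips)] <- seq_len(nTips)
  counter <- nTips
  orderEdges <- integer(0)
  visit <- function(node) {
    counter <<- counter + 1L
    newId[node] <<- counter
    for (e in children[[as.character(node)]]) {
      orderEdges <<- c(orderEdges, e)
      child <- edges[e, 2L]
      if (child > nTips) visit(child)
    }
  }
  visit(root)
  tr$edge <- cbind(newId[edges[orderEdges, 1L]], newId[edges[orderEdges, 2L]])
  tr$edge.length <- tr$edge.length[orderEdges]
  attr(tr, "edge.perm") <- orderEdges
  tr
}

## Bipartitions (as canonical tip-label strings) induced by internal edges.
.bipartitions <- function(tr) {
  nTips <- length(tr$tip.label)
  desc <- function(node) {
    kids <- tr$edge[tr$edge[, 1L] == node, 2L]
    out <- integer(0)
    for (k in kids) {
      out <- c(out, if (k <= nTips) k else desc(k))
    }
    out
  }
  internalEdges <- which(tr$edge[, 2L] > nTips)
  bips <- character(0)
  for (e in internalEdges) {
    tips <- sort(tr$tip.label[desc(tr$edge[e, 2L])])
    if (length(tips) <= 1L || length(tips) >= nTips - 1L) {
      bips <- c(bips, NA_character_); next
    }
    ## canonical side: the one not containing the first label
    if (sort(tr$tip.label)[1L] %in% tips)
      tips <- sort(setdiff(tr$tip.label, tips))
    bips <- c(bips, paste(tips, collapse = "|"))
  }
  list(edges = internalEdges, bips = bips)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the full-data tree the
#' percentage of replicates containing the same bipartition. Supports are
#' mapped onto the full-data tree (not a majority-rule consensus) and
#' written as internal node labels. Deterministic for a fixed seed.
#'
#' @param alignment Aligned sequences (see \code{\link{computeDistances}}).
#' @param nReplicates Number of bootstrap replicates (the study protocol
#'   uses 1000).
#' @param seed Integer seed.
#' @param model,deletion Passed to \code{\link{computeDistances}}.
#' @return A \code{phylo} tree with \code{node.label} percent supports and
#'   a \code{"supports"} attribute (per internal edge).
#' @export
bootstrapSupports <- function(alignment, nReplicates = 100L, seed = 1L,
                              model = c("p", "poisson", "k2p"),
                              deletion = c("pairwise", "complete")) {
  model <- match.arg(model); deletion <- match.arg(deletion)
  if (nReplicates < 1L) stop("nReplicates must be at least 1")
  m <- .alnToMatrix(alignment)
  full <- njTree(computeDistances(m, model, deletion))
  bp <- .bipartitions(full)
  counts <- stats::setNames(numeric(length(bp$bips)), bp$bips)
  set.seed(seed)
  nc <- ncol(m)
  for (r in seq_len(nReplicates)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    tb <- tryCatch(njTree(computeDistances(m[, cols, drop = FALSE],
                                           model, deletion)),
                   error = function(e) NULL)
    if (is.null(tb)) next
    rb <- .bipartitions(tb)$bips
    hit <- bp$bips %in% rb[!is.na(rb)]
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / nReplicates
  nTips <- length(full$tip.label)
  nodeLab <- rep("", full$Nnode)
  for (k in seq_along(bp$edges)) {
    node <- full$edge[bp$edges[k], 2L]
    if (!is.na(bp$bips[k]))
      nodeLab[node - nTips] <- sprintf("%.0f", supports[k])
  }
  full$node.label <- nodeLab
  attr(full, "supports") <- supports
  full
}

#' Write a tree to a newick file
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeNewick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read an aligned FASTA file (DNA or protein)
#' @param path Path to aligned FASTA.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return An \code{XStringSet} of equal-width sequences.
#' @export
readAlignedFasta <- function(path, type = c("DNA", "AA")) {
  type <- match.arg(type)
  x <- if (type == "DNA") Biostrings::readDNAStringSet(path) else
    Biostrings::readAAStringSet(path)
  if (length(unique(width(x))) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  x
}
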