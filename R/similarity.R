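#' Seeded similarity search of reference sequences against a genome
#'
#' A k-mer seeded, locally extended similarity search: exact k-mer matches
#' between query and genome are chained, nearby seed clusters are merged
#' into candidate windows, and each window is scored by local alignment of
#' the query against it. Hits from the same query within \code{mergeGap}
#' bases on the same strand are merged into one cluster hit (so that a
#' query interrupted by introns still reports its combined coverage).
#'
#' @param queryRefs Named \code{DNAStringSet} of reference sequences.
#' @param genome Named \code{DNAStringSet}.
#' @param minIdentity Minimum percent identity over the aligned region
#'   (default 70, below the 75 percent subgroup threshold so that
#'   cross-subgroup references still seed hits).
#' @param minCov Minimum percent query coverage (cluster-level, default 50).
#' @param k Seed k-mer length.
#' @param mergeGap Maximum genomic gap when merging same-query hits.
#' @return A \code{data.frame} sorted by contig, start, strand, query:
#'   \code{query}, \code{contig}, \code{start}, \code{end}, \code{strand},
#'   \code{identity}, \code{coverage}.
#' @export
similaritySearch <- function(queryRefs, genome, minIdentity = 70,
                             minCov = 50, k = 12L, mergeGap = 600L) {
  if (length(queryRefs) == 0L) stop("empty reference set")
  if (is.null(names(queryRefs)) || anyDuplicated(names(queryRefs)))
    stop("queryRefs must have unique names")
  rows <- list()
  for (ct in names(genome)) {
    gseq <- genome[[ct]]
    for (qn in names(queryRefs)) {
      q <- as.character(queryRefs[[qn]])
      for (strand in c("+", "-")) {
        qs <- if (strand == "+") q else revcomp(q)
        nq <- nchar(qs)
        if (nq < k) next
        starts <- seq_len(nq - k + 1L)
        kmers <- Biostrings::DNAStringSet(substring(qs, starts, starts + k - 1L))
        ok <- !grepl("N", as.character(kmers), fixed = TRUE)
        if (!any(ok)) next
        pd <- Biostrings::PDict(kmers[ok])
        m <- Biostrings::matchPDict(pd, gseq)
        qpos <- starts[ok]
        hits <- list()
        st <- BiocGenerics::start(m)
        for (i in seq_along(st)) {
          if (length(st[[i]])) {
            hits[[length(hits) + 1L]] <-
              cbind(g = st[[i]], q = rep.int(qpos[i], length(st[[i]])))
          }
        }
        if (!length(hits)) next
        hm <- do.call(rbind, hits)
        ## chain seeds into clusters by genomic proximity, then split each
        ## cluster by alignment diagonal so that exons separated by introns
        ## (diagonal shifts) are aligned and reported separately and later
        ## merged with combined coverage
        o <- order(hm[, "g"])
        hm <- hm[o, , drop = FALSE]
        brk <- c(0L, which(diff(hm[, "g"]) > mergeGap), nrow(hm))
        pieces <- list()
        for (b in seq_len(length(brk) - 1L)) {
          cl0 <- hm[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
          dg <- cl0[, "g"] - cl0[, "q"]
          od <- order(dg, cl0[, "g"])
          cl0 <- cl0[od, , drop = FALSE]
          dg <- dg[od]
          sub <- c(0L, which(diff(dg) > 25L), nrow(cl0))
          for (s in seq_len(length(sub) - 1L)) {
            pieces[[length(pieces) + 1L]] <-
              cl0[(sub[s] + 1L):sub[s + 1L], , drop = FALSE]
          }
        }
        for (cl in pieces) {
          ## align only the query segment this piece covers, in a window
          ## tight around the piece, so that one strong exon cannot swallow
          ## the alignments of its neighbours
          qLo <- max(1L, min(cl[, "q"]) - 25L)
          qHi <- min(nq, max(cl[, "q"]) + k - 1L + 25L)
          gs <- max(1L, min(cl[, "g"]) - (min(cl[, "q"]) - qLo) - 30L)
          ge <- min(length(gseq),
                    max(cl[, "g"]) + k - 1L + (qHi - max(cl[, "q"]) - k + 1L) +
                      30L)
          win <- Biostrings::subseq(gseq, gs, ge)
          qseg <- Biostrings::DNAString(substr(qs, qLo, qHi))
          aln <- Biostrings::pairwiseAlignment(
            qseg, win, type = "local",
            substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
              match = 2, mismatch = -3, baseOnly = FALSE),
            gapOpening = 5, gapExtension = 2)
          alen <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
            sum(width(Biostrings::insertion(aln))) +
            sum(width(Biostrings::deletion(aln)))
          if (alen == 0L) next
          ident <- 100 * Biostrings::nmatch(aln) / alen
          qcov <- 100 * (BiocGenerics::end(aln@pattern@range) -
                           BiocGenerics::start(aln@pattern@range) + 1L) / nq
          sstart <- gs - 1L + BiocGenerics::start(aln@subject@range)
          send <- gs - 1L + BiocGenerics::end(aln@subject@range)
          rows[[length(rows) + 1L]] <- data.frame(
            query = qn, contig = ct, start = sstart, end = send,
            strand = strand, identity = ident, coverage = qcov)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(query = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0),
                      coverage = numeric(0)))
  }
  df <- do.call(rbind, rows)
  df <- .mergeSimilarityHits(df, mergeGap)
  df <- df[df$identity >= minIdentity & df$coverage >= minCov, , drop = FALSE]
  df <- df[order(df$contig, df$start, df$strand, df$query), , drop = FALSE]
  rownames(df) <- NULL
  df
}

## Merge same-query, same-strand hits within mergeGap into cluster hits;
## identity is length-weighted, coverage summed (capped at 100).
.mergeSimilarityHits <- function(df, mergeGap) {
  key <- paste(df$query, df$contig, df$strand)
  out <- list()
  for (kk in unique(key)) {
    sub <- df[key == kk, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(sub$start[-1L] >
                                     sub$end[-nrow(sub)] + mergeGap)))
    for (g in unique(grp)) {
      ss <- sub[grp == g, , drop = FALSE]
      w <- ss$end - ss$start + 1
      out[[length(out) + 1L]] <- data.frame(
        query = ss$query[1L], contig = ss$contig[1L],
        start = min(ss$start), end = max(ss$end), strand = ss$strand[1L],
        identity = sum(ss$identity * w) / sum(w),
        coverage = min(100, sum(ss$coverage)))
    }
  }
  do.call(rbind, out)
}

#' Import a 12-column tab-separated local-alignment hit table
#'
#' Accepts the common 12-column tabular hit format (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query start,
#' query end, subject start, subject end, e-value, bit score) as an
#' alternative to the internal search. Subject coordinates with start >
#' end denote minus-strand hits and are normalised.
#'
#' @param path Path to the tab-separated file (no header).
#' @param queryLengths Optional named vector of query lengths, used to
#'   compute coverage; otherwise coverage is reported as NA.
#' @return A \code{data.frame} in the same shape as
#'   \code{\link{similaritySearch}}.
#' @export
readHitTable <- function(path, queryLengths = NULL) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 12L) stop("expected 12 tab-separated columns")
  names(tb)[1:12] <- c("query", "contig", "identity", "length", "mismatches",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  strand <- ifelse(tb$sstart <= tb$send, "+", "-")
  start <- pmin(tb$sstart, tb$send)
  end <- pmax(tb$sstart, tb$send)
  cov <- if (!is.null(queryLengths)) {
    100 * (abs(tb$qend - tb$qstart) + 1) / queryLengths[tb$query]
  } else NA_real_
  data.frame(query = tb$query, contig = tb$contig, start = start, end = end,
             strand = strand, identity = tb$identity, coverage = cov)
}
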