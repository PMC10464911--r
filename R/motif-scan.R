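#' @name rs-consensus
#' @title Recombination signal consensus motifs
#' @description Canonical V(D)J recombination signal consensus: heptamer
#'   \code{CACAGTG} and nonamer \code{ACAAAAACC}. The first three heptamer
#'   bases (\code{CAC}) are the recombinationally critical core and are
#'   required exact by default when scanning.
#' @export
RS_HEPTAMER <- "CACAGTG"

#' @rdname rs-consensus
#' @export
RS_NONAMER <- "ACAAAAACC"

## Mismatch counts of a fixed motif at every start position of a character
## vector, fully vectorised (one comparison per motif base).
.motifMismatches <- function(chars, motif, npos) {
  m <- strsplit(motif, "")[[1L]]
  k <- length(m)
  mm <- integer(npos)
  for (j in seq_len(k)) mm <- mm + (chars[seq_len(npos) + j - 1L] != m[j])
  mm
}

.scanRSPlus <- function(chars, spacerClass, maxHeptMM, maxNonaMM,
                        spacerSlack, requireCacCore) {
  L <- length(chars)
  out <- vector("list", 2L * spacerSlack + 1L)
  idx <- 1L
  for (sl in (spacerClass - spacerSlack):(spacerClass + spacerSlack)) {
    span <- 7L + sl + 9L
    npos <- L - span + 1L
    if (npos < 1L) { idx <- idx + 1L; next }
    hm <- .motifMismatches(chars, RS_HEPTAMER, npos)
    nstart <- seq_len(npos) + 7L + sl
    nm <- integer(npos)
    nmotif <- strsplit(RS_NONAMER, "")[[1L]]
    for (j in 1:9) nm <- nm + (chars[nstart + j - 1L] != nmotif[j])
    ok <- hm <= maxHeptMM & nm <= maxNonaMM
    if (requireCacCore) {
      ok <- ok & chars[seq_len(npos)] == "C" &
        chars[seq_len(npos) + 1L] == "A" & chars[seq_len(npos) + 2L] == "C"
    }
    w <- which(ok)
    out[[idx]] <- data.frame(h = w, spacer_length = rep.int(sl, length(w)),
                             hept_mm = hm[w], nona_mm = nm[w])
    idx <- idx + 1L
  }
  do.call(rbind, out)
}

#' Scan a sequence for recombination signal sequences
#'
#' Finds heptamer--spacer--nonamer motifs on both strands: every window whose
#' heptamer matches \code{CACAGTG} within \code{maxHeptamerMM} mismatches and
#' whose nonamer matches \code{ACAAAAACC} within \code{maxNonamerMM}, at a
#' spacer of \code{spacerClass} plus/minus \code{spacerSlack} bases, is
#' returned. By default the heptamer core \code{CAC} must be exact. The score
#' of a hit is the total mismatch count.
#'
#' A hit on strand \code{+} licenses a coding end immediately left of the
#' heptamer (genomic \code{heptamer_start - 1}); a hit on strand \code{-}
#' licenses a coding end immediately right of it (\code{heptamer_end + 1}).
#'
#' @param seq A DNA sequence (character or \code{DNAString}).
#' @param spacerClass 12 or 23.
#' @param maxHeptamerMM Maximum heptamer mismatches (default 2).
#' @param maxNonamerMM Maximum nonamer mismatches (default 3).
#' @param spacerSlack Spacer length tolerance in bases (default 1).
#' @param requireCacCore Require the CAC heptamer core exact (default TRUE).
#' @param contig Sequence name used for the returned ranges.
#' @return A \code{GRanges} spanning heptamer through nonamer, strand = scan
#'   strand, with metadata columns \code{heptamer_start}, \code{heptamer_end},
#'   \code{nonamer_start}, \code{nonamer_end}, \code{spacer_class},
#'   \code{spacer_length}, \code{hept_mm}, \code{nona_mm}, \code{score}.
#'   Hits are sorted by position, then score, then strand (+ before -).
#' @export
scanRS <- function(seq, spacerClass, maxHeptamerMM = 2L, maxNonamerMM = 3L,
                   spacerSlack = 1L, requireCacCore = TRUE, contig = "seq") {
  if (!spacerClass %in% c(12L, 23L)) stop("spacerClass must be 12 or 23")
  s <- toupper(as.character(seq))
  L <- nchar(s)
  minLen <- 7L + spacerClass - spacerSlack + 9L
  if (L < minLen) stop("sequence shorter than the minimal RS span (", minLen, ")")
  fwd <- strsplit(s, "")[[1L]]
  rev <- strsplit(revcomp(s), "")[[1L]]

  hp <- .scanRSPlus(fwd, spacerClass, maxHeptamerMM, maxNonamerMM,
                    spacerSlack, requireCacCore)
  hm <- .scanRSPlus(rev, spacerClass, maxHeptamerMM, maxNonamerMM,
                    spacerSlack, requireCacCore)

  rows <- list()
  if (!is.null(hp) && nrow(hp)) {
    rows[[1L]] <- data.frame(
      heptamer_start = hp$h, heptamer_end = hp$h + 6L,
      nonamer_start = hp$h + 7L + hp$spacer_length,
      nonamer_end = hp$h + 15L + hp$spacer_length,
      strand = "+", spacer_length = hp$spacer_length,
      hept_mm = hp$hept_mm, nona_mm = hp$nona_mm
    )
  }
  if (!is.null(hm) && nrow(hm)) {
    ## map reverse-complement local coordinates back to the forward strand
    rows[[2L]] <- data.frame(
      heptamer_start = L - (hm$h + 6L) + 1L, heptamer_end = L - hm$h + 1L,
      nonamer_start = L - (hm$h + 15L + hm$spacer_length) + 1L,
      nonamer_end = L - (hm$h + 7L + hm$spacer_length) + 1L,
      strand = "-", spacer_length = hm$spacer_length,
      hept_mm = hm$hept_mm, nona_mm = hm$nona_mm
    )
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      heptamer_start = integer(0), heptamer_end = integer(0),
      nonamer_start = integer(0), nonamer_end = integer(0),
      spacer_class = integer(0), spacer_length = integer(0),
      hept_mm = integer(0), nona_mm = integer(0), score = integer(0))
    return(gr)
  }
  df$score <- df$hept_mm + df$nona_mm
  lo <- pmin(df$heptamer_start, df$nonamer_start)
  hi <- pmax(df$heptamer_end, df$nonamer_end)
  o <- order(lo, df$score, df$heptamer_start, factor(df$strand, c("+", "-")))
  df <- df[o, , drop = FALSE]
  lo <- lo[o]; hi <- hi[o]
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = lo, end = hi),
    strand = df$strand,
    heptamer_start = df$heptamer_start, heptamer_end = df$heptamer_end,
    nonamer_start = df$nonamer_start, nonamer_end = df$nonamer_end,
    spacer_class = spacerClass, spacer_length = df$spacer_length,
    hept_mm = df$hept_mm, nona_mm = df$nona_mm, score = df$score
  )
  gr
}

## Gene strand implied by a scan hit playing a given role in a D unit:
## the 12-spacer RS sits 5' of the D (gene strand opposite to the scan
## strand), the 23-spacer RS sits 3' of it (gene strand equals scan strand).
.impliedGeneStrand <- function(scanStrand, spacerClass) {
  if (spacerClass == 23L) scanStrand else ifelse(scanStrand == "+", "-", "+")
}

#' Pair 12- and 23-spacer RS hits into candidate D-gene units
#'
#' Returns (12-class, 23-class) hit pairs flanking a candidate D region of
#' \code{minGap} to \code{maxGap} bases, in the head-to-tail configuration of
#' a D gene unit. Pairing requires that both hits license a gene on the same
#' strand; each hit is used at most once, and competing pairs are resolved
#' greedily by lowest combined mismatch score, then smallest gap, then
#' position.
#'
#' @param hits12 \code{GRanges} of 12-class hits from \code{\link{scanRS}}.
#' @param hits23 \code{GRanges} of 23-class hits.
#' @param minGap,maxGap D-region length bounds in bases (defaults 8 and 25).
#' @return A \code{data.frame} with one row per pair: indices \code{i12},
#'   \code{i23} into the inputs, \code{gene_strand}, \code{d_start},
#'   \code{d_end} (the D region between the heptamers), \code{gap} and
#'   \code{score}.
#' @export
pairRS1223 <- function(hits12, hits23, minGap = 8L, maxGap = 25L) {
  if (length(hits12) == 0L || length(hits23) == 0L) {
    return(data.frame(i12 = integer(0), i23 = integer(0),
                      gene_strand = character(0), d_start = integer(0),
                      d_end = integer(0), gap = integer(0), score = integer(0)))
  }
  s12 <- as.character(BiocGenerics::strand(hits12))
  s23 <- as.character(BiocGenerics::strand(hits23))
  g12 <- .impliedGeneStrand(s12, 12L)
  g23 <- .impliedGeneStrand(s23, 23L)
  cand <- list(); k <- 1L
  for (i in seq_along(hits12)) {
    for (j in seq_along(hits23)) {
      if (g12[i] != g23[j]) next
      if (as.character(GenomicRanges::seqnames(hits12))[i] !=
          as.character(GenomicRanges::seqnames(hits23))[j]) next
      if (g12[i] == "+") {
        ds <- hits12$heptamer_end[i] + 1L
        de <- hits23$heptamer_start[j] - 1L
      } else {
        ds <- hits23$heptamer_end[j] + 1L
        de <- hits12$heptamer_start[i] - 1L
      }
      gap <- de - ds + 1L
      if (gap < minGap || gap > maxGap) next
      cand[[k]] <- data.frame(i12 = i, i23 = j, gene_strand = g12[i],
                              d_start = ds, d_end = de, gap = gap,
                              score = hits12$score[i] + hits23$score[j])
      k <- k + 1L
    }
  }
  if (!length(cand)) {
    return(data.frame(i12 = integer(0), i23 = integer(0),
                      gene_strand = character(0), d_start = integer(0),
                      d_end = integer(0), gap = integer(0), score = integer(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$score, cand$gap, cand$d_start), , drop = FALSE]
  used12 <- logical(length(hits12)); used23 <- logical(length(hits23))
  keep <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    if (!used12[cand$i12[r]] && !used23[cand$i23[r]]) {
      keep[r] <- TRUE
      used12[cand$i12[r]] <- TRUE
      used23[cand$i23[r]] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$d_start), , drop = FALSE]
}

#' Scan for splice donor or acceptor signals
#'
#' Donor sites are \code{GT} dinucleotides, scored by similarity of the
#' six bases from the site to the conserved donor hexamer \code{GTAAGT}
#' (a full hexamer outranks a bare GT). Acceptor sites are \code{AG}
#' dinucleotides preceded by a pyrimidine-rich tract (at least
#' \code{minPyrimidines} of the \code{tract} preceding bases C or T),
#' scored by the pyrimidine count.
#'
#' @param seq DNA sequence (character or \code{DNAString}), read on the
#'   strand of the gene being delimited.
#' @param kind \code{"donor"} or \code{"acceptor"}.
#' @param from,to 1-based window within \code{seq} (defaults: whole sequence).
#' @param tract,minPyrimidines Acceptor pyrimidine-tract parameters.
#' @return A \code{data.frame} sorted by score (descending) then position:
#'   \code{pos} (first intron base for donors; the G of the terminal AG for
#'   acceptors), \code{motif}, \code{score}.
#' @export
scanSplice <- function(seq, kind = c("donor", "acceptor"), from = 1L, to = NULL,
                       tract = 8L, minPyrimidines = 5L) {
  kind <- match.arg(kind)
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (is.null(to)) to <- L
  from <- max(1L, from); to <- min(L, to)
  if (from > to) {
    return(data.frame(pos = integer(0), motif = character(0),
                      score = numeric(0)))
  }
  chars <- strsplit(s, "")[[1L]]
  if (kind == "donor") {
    p <- from:(to - 1L)
    p <- p[chars[p] == "G" & chars[p + 1L] == "T"]
    if (!length(p)) {
      return(data.frame(pos = integer(0), motif = character(0),
                        score = numeric(0)))
    }
    hex <- substring(s, p, pmin(p + 5L, L))
    target <- strsplit("GTAAGT", "")[[1L]]
    score <- vapply(hex, function(h) {
      hc <- strsplit(h, "")[[1L]]
      sum(hc == target[seq_along(hc)])
    }, numeric(1L), USE.NAMES = FALSE)
    df <- data.frame(pos = p, motif = hex, score = score)
  } else {
    p <- (from + 1L):to
    p <- p[p >= tract + 2L]                    # room for the tract
    p <- p[chars[p - 1L] == "A" & chars[p] == "G"]
    if (!length(p)) {
      return(data.frame(pos = integer(0), motif = character(0),
                        score = numeric(0)))
    }
    py <- vapply(p, function(q) {
      tr <- chars[(q - 1L - tract):(q - 2L)]
      sum(tr %in% c("C", "T"))
    }, numeric(1L))
    keep <- which(py >= minPyrimidines)
    if (!length(keep)) {
      return(data.frame(pos = integer(0), motif = character(0),
                        score = numeric(0)))
    }
    df <- data.frame(pos = p[keep],
                     motif = substring(s, p[keep] - 1L, p[keep]),
                     score = py[keep])
  }
  df[order(-df$score, df$pos), , drop = FALSE]
}
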