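## Gene callers: C, J, D and V gene segments from motif evidence plus
## similarity to reference libraries, followed by locus assembly and
## duplication-pattern classification.
##
## Internally a "gene record" is a list with absolute (contig) coordinates:
##   gene_id, type, contig, strand, range, exons (list of c(s,e), in gene
##   5'->3' order), rs (list of RS evidence), flags, evidence, protein.

## local (gene-strand, 1-based within window) -> genomic range
.l2g <- function(r, ws, we, strand) {
  if (strand == "+") c(ws + r[1L] - 1L, ws + r[2L] - 1L)
  else c(we - r[2L] + 1L, we - r[1L] + 1L)
}

.flipStrand <- function(s) ifelse(s == "+", "-", "+")

## Extract the gene-strand sequence of [ws, we] on `strand`.
.localSeq <- function(genome, contig, ws, we, strand) {
  gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(ws, we),
                               strand = strand)
  as.character(extractSeq(genome, gr)[[1L]])
}

## Group similarity hits into candidate gene regions (one per gene):
## same contig+strand, merged when within `gap`; the best-identity query
## is retained for each region.
.hitRegions <- function(hits, gap = 250L) {
  if (!nrow(hits)) return(hits[0, ])
  out <- list()
  for (key in unique(paste(hits$contig, hits$strand))) {
    sub <- hits[paste(hits$contig, hits$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    grp <- cumsum(c(1L, as.integer(sub$start[-1L] >
                                     cummax(sub$end)[-nrow(sub)] + gap)))
    for (g in unique(grp)) {
      ss <- sub[grp == g, , drop = FALSE]
      best <- ss[which.max(ss$identity), , drop = FALSE]
      best$start <- min(ss$start); best$end <- max(ss$end)
      out[[length(out) + 1L]] <- best
    }
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start), , drop = FALSE]
}

## Strict-then-relaxed RS search near a coding end in local space.
## codingEnd: local position of the last coding base; the heptamer is
## expected to begin at codingEnd + 1 (within rsSlack).
.findRSAtEnd <- function(w, codingEnd, spacerClass, config) {
  ws <- max(1L, codingEnd - 12L)
  wend <- min(nchar(w), codingEnd + 70L)
  if (wend - ws + 1L < 7L + spacerClass + 9L) return(NULL)
  sub <- substr(w, ws, wend)
  pick <- function(h) {
    h <- h[as.character(BiocGenerics::strand(h)) == "+"]
    if (!length(h)) return(NULL)
    hs <- ws - 1L + h$heptamer_start
    d <- abs(hs - (codingEnd + 1L))
    keep <- d <= config$rsSlack
    if (!any(keep)) return(NULL)
    h <- h[keep]; d <- d[keep]
    i <- order(d, h$score)[1L]
    list(heptamer = c(ws - 1L + h$heptamer_start[i], ws - 1L + h$heptamer_end[i]),
         nonamer = c(ws - 1L + h$nonamer_start[i], ws - 1L + h$nonamer_end[i]),
         class = spacerClass, scanStrand = "+",
         hept_mm = h$hept_mm[i], nona_mm = h$nona_mm[i])
  }
  strict <- pick(scanRS(sub, spacerClass, config$maxHeptamerMM,
                        config$maxNonamerMM, config$spacerSlack,
                        config$requireCacCore))
  if (!is.null(strict)) { strict$relaxed <- FALSE; return(strict) }
  rel <- pick(scanRS(sub, spacerClass, config$relaxedHeptamerMM,
                     config$relaxedNonamerMM, config$spacerSlack,
                     config$requireCacCore))
  if (!is.null(rel)) rel$relaxed <- TRUE
  rel
}

.hexamerScores <- function(chars, positions, target = "GTAAGT") {
  tg <- strsplit(target, "")[[1L]]
  vapply(positions, function(p) {
    hx <- chars[p + 0:5]
    sum(hx == tg, na.rm = TRUE)
  }, numeric(1L))
}

## ------------------------------------------------------------------ C genes

#' Call C genes from similarity to spliced C references
#'
#' For each similarity cluster the reference coding sequence is placed onto
#' the genome with intron interruptions resolved at donor/acceptor signals;
#' a valid C gene has 4 exons with splice frames 1, 1, 0 (EX1/EX2, EX2/EX3,
#' EX3/EX4). Calls violating the exon count or frame rules carry the flag
#' \code{incomplete_exon_structure}. The translated product is annotated
#' with the conserved C-domain positions (1st-CYS 23, CONSERVED-TRP 41,
#' hydrophobic 89, 2nd-CYS 104).
#'
#' @param genome Named \code{DNAStringSet}.
#' @param cRefs Named \code{DNAStringSet} of spliced C coding references.
#' @param config See \code{\link{trbConfig}}.
#' @param hits Optional precomputed similarity hits (the shape returned by
#'   \code{\link{similaritySearch}} or \code{\link{readHitTable}}),
#'   replacing the internal search.
#' @return List of gene records (internal representation; see
#'   \code{\link{annotateGenome}} for the user-level entry point).
#' @export
callCGenes <- function(genome, cRefs, config = trbConfig(), hits = NULL) {
  if (length(cRefs) == 0L) stop("cRefs must contain at least one reference")
  if (is.null(hits))
    hits <- similaritySearch(cRefs, genome, config$minIdentity, config$minCov,
                             config$k, config$mergeGap)
  regions <- .hitRegions(hits)
  recs <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    L <- width(genome)[match(rg$contig, names(genome))]
    ws <- max(1L, rg$start - 500L); we <- min(L, rg$end + 500L)
    w <- .localSeq(genome, rg$contig, ws, we, rg$strand)
    ref <- as.character(cRefs[[rg$query]])
    anchor <- .bestHamming(substr(ref, 1L, 60L), w)
    if (is.null(anchor)) next
    walk <- .walkSpliced(ref, w, anchor$start, allowIntrons = TRUE,
                         maxIntrons = 3L)
    flags <- character(0)
    exLens <- vapply(walk$exons, function(r) r[2L] - r[1L] + 1L, integer(1L))
    if (length(walk$exons) != 4L || !walk$complete) {
      flags <- c(flags, "incomplete_exon_structure")
    } else {
      frames <- cumsum(exLens)[1:3] %% 3L
      if (!identical(as.integer(frames), as.integer(config$cExonFrames)))
        flags <- c(flags, "incomplete_exon_structure")
    }
    chars <- strsplit(w, "")[[1L]]
    donors <- character(0); acceptors <- character(0)
    if (length(walk$exons) > 1L) {
      for (k in seq_len(length(walk$exons) - 1L)) {
        dpos <- walk$exons[[k]][2L] + 1L
        apos <- walk$exons[[k + 1L]][1L]
        donors <- c(donors, paste(chars[dpos + 0:1], collapse = ""))
        acceptors <- c(acceptors, paste(chars[apos - 2:1], collapse = ""))
      }
    }
    coding <- paste(vapply(walk$exons, function(r)
      substr(w, r[1L], r[2L]), character(1L)), collapse = "")
    protein <- translateDNA(coding)
    aa <- strsplit(protein, "")[[1L]]
    conserved <- c(`23` = aa[23], `41` = aa[41], `89` = aa[89], `104` = aa[104])
    if (grepl("N", coding, fixed = TRUE)) flags <- c(flags, "contains_N")
    exonsG <- lapply(walk$exons, .l2g, ws = ws, we = we, strand = rg$strand)
    rngL <- c(walk$exons[[1L]][1L], walk$exons[[length(walk$exons)]][2L])
    recs[[length(recs) + 1L]] <- list(
      type = "C", contig = rg$contig, strand = rg$strand,
      range = .l2g(rngL, ws, we, rg$strand), exons = exonsG, rs = list(),
      flags = flags, protein = protein,
      evidence = list(ref = rg$query, donors = donors, acceptors = acceptors,
                      conserved = conserved, coding = coding,
                      identity = 100 * (1 - walk$mismatches /
                                          max(1L, walk$consumedRef))))
  }
  recs
}

## ------------------------------------------------------------------ J genes

#' Call J genes within a region from motif evidence
#'
#' A J gene is called where a 12-spacer RS (at the J-discovery motif gates)
#' is followed by an open J-REGION ending at a donor splice site; the donor
#' is located as the best match to the conserved \code{GTAAGT} hexamer in
#' the donor window (a degenerate donor yields a flagged call). The FGXG
#' J-motif is located in the translated J-REGION when present.
#'
#' @param genome Named \code{DNAStringSet}.
#' @param region A length-1 \code{GRanges} (with strand) to scan, typically
#'   between a D and a C call.
#' @param config See \code{\link{trbConfig}}.
#' @return List of gene records, ordered 5' to 3' on the gene strand.
#' @export
callJGenes <- function(genome, region, config = trbConfig()) {
  ct <- as.character(GenomicRanges::seqnames(region))[1L]
  strand <- as.character(BiocGenerics::strand(region))[1L]
  ws <- GenomicRanges::start(region)[1L]; we <- GenomicRanges::end(region)[1L]
  w <- .localSeq(genome, ct, ws, we, strand)
  if (nchar(w) < 7L + config$jSpacer + 9L + 30L) return(list())
  hits <- scanRS(w, config$jSpacer, config$jMaxHeptamerMM,
                 config$jMaxNonamerMM, config$spacerSlack,
                 config$requireCacCore)
  ## a minus-strand scan hit licenses coding immediately right of its
  ## heptamer, i.e. a J gene on the local forward (gene) strand
  hits <- hits[as.character(BiocGenerics::strand(hits)) == "-"]
  if (!length(hits)) return(list())
  chars <- strsplit(w, "")[[1L]]
  recs <- list()
  for (i in seq_along(hits)) {
    jStart <- hits$heptamer_end[i] + 1L
    dLo <- jStart + config$jDonorWindow[1L]
    dHi <- min(nchar(w) - 5L, jStart + config$jDonorWindow[2L])
    if (dLo > dHi) next
    sc <- .hexamerScores(chars, dLo:dHi)
    if (max(sc) < config$jMinDonorScore) next
    donorPos <- (dLo:dHi)[which.max(sc)]
    jEnd <- donorPos - 1L
    jr <- substr(w, jStart, jEnd)
    aa0 <- translateDNA(jr, 0L)
    if (grepl("*", aa0, fixed = TRUE)) next          # not an open J-REGION
    fg <- regexpr("FG.G", aa0)
    fgxg <- if (fg > 0L) as.integer(fg) else NA_integer_
    donorMotif <- paste(chars[donorPos + 0:5], collapse = "")
    flags <- character(0)
    if (substr(donorMotif, 1L, 2L) != "GT") flags <- c(flags, "defective_donor")
    else if (donorMotif != "GTAAGT") flags <- c(flags, "noncanonical_donor")
    if (is.na(fgxg)) flags <- c(flags, "no_fgxg")
    rs <- list(heptamer = c(hits$heptamer_start[i], hits$heptamer_end[i]),
               nonamer = c(hits$nonamer_start[i], hits$nonamer_end[i]),
               class = config$jSpacer, scanStrand = "-",
               hept_mm = hits$hept_mm[i], nona_mm = hits$nona_mm[i],
               relaxed = FALSE)
    rs <- .mapRSLocal(rs, ws, we, strand)
    recs[[length(recs) + 1L]] <- list(
      type = "J", contig = ct, strand = strand,
      range = .l2g(c(jStart, jEnd), ws, we, strand),
      exons = list(.l2g(c(jStart, jEnd), ws, we, strand)),
      rs = list(rs), flags = flags, protein = aa0,
      evidence = list(donorMotif = donorMotif, donorScore = max(sc),
                      fgxgPos = fgxg, jLocalStart = jStart))
  }
  o <- order(vapply(recs, function(r) r$range[1L], integer(1L)))
  if (strand == "-") o <- rev(o)
  recs[o]
}

.mapRSLocal <- function(rs, ws, we, strand) {
  rs$heptamer <- .l2g(rs$heptamer, ws, we, strand)
  rs$nonamer <- .l2g(rs$nonamer, ws, we, strand)
  if (strand == "-") rs$scanStrand <- .flipStrand(rs$scanStrand)
  rs
}

## ------------------------------------------------------------------ D genes

#' Call D genes within a region from paired 12/23 RS evidence
#'
#' One D gene is called per valid (12-spacer, 23-spacer) RS pair flanking a
#' D region of the configured length bounds (default 8 to 25 bases);
#' competing overlapping pairs are resolved by lowest combined mismatch
#' count. The D region is checked for productive reading (no stop in at
#' least one frame).
#'
#' @inheritParams callJGenes
#' @return List of gene records.
#' @export
callDGenes <- function(genome, region, config = trbConfig()) {
  ct <- as.character(GenomicRanges::seqnames(region))[1L]
  strand <- as.character(BiocGenerics::strand(region))[1L]
  ws <- GenomicRanges::start(region)[1L]; we <- GenomicRanges::end(region)[1L]
  w <- .localSeq(genome, ct, ws, we, strand)
  if (nchar(w) < 100L) return(list())
  h12 <- scanRS(w, 12L, config$maxHeptamerMM, config$maxNonamerMM,
                config$spacerSlack, config$requireCacCore)
  h23 <- scanRS(w, 23L, config$maxHeptamerMM, config$maxNonamerMM,
                config$spacerSlack, config$requireCacCore)
  pairs <- pairRS1223(h12, h23, config$dRegionMin, config$dRegionMax)
  pairs <- pairs[pairs$gene_strand == "+", , drop = FALSE]  # region strand
  recs <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    dSeq <- substr(w, p$d_start, p$d_end)
    open <- vapply(0:2, function(f) {
      !grepl("*", translateDNA(dSeq, f), fixed = TRUE)
    }, logical(1L))
    flags <- if (!any(open)) "no_open_frame" else character(0)
    i12 <- p$i12; i23 <- p$i23
    rs12 <- .mapRSLocal(list(
      heptamer = c(h12$heptamer_start[i12], h12$heptamer_end[i12]),
      nonamer = c(h12$nonamer_start[i12], h12$nonamer_end[i12]),
      class = 12L, scanStrand = as.character(BiocGenerics::strand(h12))[i12],
      hept_mm = h12$hept_mm[i12], nona_mm = h12$nona_mm[i12],
      relaxed = FALSE), ws, we, strand)
    rs23 <- .mapRSLocal(list(
      heptamer = c(h23$heptamer_start[i23], h23$heptamer_end[i23]),
      nonamer = c(h23$nonamer_start[i23], h23$nonamer_end[i23]),
      class = 23L, scanStrand = as.character(BiocGenerics::strand(h23))[i23],
      hept_mm = h23$hept_mm[i23], nona_mm = h23$nona_mm[i23],
      relaxed = FALSE), ws, we, strand)
    recs[[length(recs) + 1L]] <- list(
      type = "D", contig = ct, strand = strand,
      range = .l2g(c(p$d_start, p$d_end), ws, we, strand),
      exons = list(.l2g(c(p$d_start, p$d_end), ws, we, strand)),
      rs = list(rs12, rs23), flags = flags,
      protein = translateDNA(dSeq, which(open)[1L] - 1L),
      evidence = list(openFrames = which(open) - 1L, dLength = nchar(dSeq)))
  }
  recs
}

## ------------------------------------------------------------------ V genes

#' Call V genes from similarity plus RS and splice evidence
#'
#' For each similarity cluster against the V-EXON references, the best
#' reference is placed onto the genome (resolving the split V-EXON of
#' TRBV6-like genes when \code{allowSplicedVExon}), the 3' end is anchored
#' at the 23-spacer RS, and the leader exon (L-PART1) is located upstream
#' via the leader reference and its donor site.
#'
#' @param genome Named \code{DNAStringSet}.
#' @param vRefs Named \code{DNAStringSet} of V-EXON references (one
#'   exemplar per subgroup).
#' @param leaderRefs Named \code{DNAStringSet} of L-PART1 references,
#'   names matching \code{vRefs}.
#' @param allowSplicedVExon Try multi-exon V-EXON models when the
#'   single-exon placement is poor (default TRUE).
#' @param config See \code{\link{trbConfig}}.
#' @param hits Optional precomputed similarity hits (see
#'   \code{\link{readHitTable}}), replacing the internal search.
#' @return List of gene records.
#' @export
callVGenes <- function(genome, vRefs, leaderRefs = NULL,
                       allowSplicedVExon = TRUE, config = trbConfig(),
                       hits = NULL) {
  if (length(vRefs) == 0L) stop("vRefs must be nonempty")
  if (is.null(hits))
    hits <- similaritySearch(vRefs, genome, config$minIdentity, config$minCov,
                             config$k, config$mergeGap)
  regions <- .hitRegions(hits)
  recs <- list()
  for (i in seq_len(nrow(regions))) {
    rg <- regions[i, ]
    L <- width(genome)[match(rg$contig, names(genome))]
    pad <- config$leaderWindow + 250L
    ws <- max(1L, rg$start - pad); we <- min(L, rg$end + pad)
    w <- .localSeq(genome, rg$contig, ws, we, rg$strand)
    ref <- as.character(vRefs[[rg$query]])
    anchor <- .bestHamming(substr(ref, 1L, 60L), w)
    if (is.null(anchor)) next
    walk <- .walkSpliced(ref, w, anchor$start,
                         allowIntrons = allowSplicedVExon, maxIntrons = 2L)
    flags <- character(0)
    identity <- 100 * (1 - walk$mismatches / max(1L, walk$consumedRef))
    if (!walk$complete || identity < config$singleExonIdentity)
      flags <- c(flags, "incomplete_vexon_model")
    vexons <- walk$exons
    lastEnd <- vexons[[length(vexons)]][2L]
    rs <- .findRSAtEnd(w, lastEnd, config$vSpacer, config)
    if (!is.null(rs) && !rs$relaxed) {
      ## anchor the coding end at the RS heptamer
      vexons[[length(vexons)]][2L] <- rs$heptamer[1L] - 1L
      lastEnd <- rs$heptamer[1L] - 1L
    }
    chars <- strsplit(w, "")[[1L]]
    vStart <- vexons[[1L]][1L]
    acceptorMotif <- if (vStart >= 3L)
      paste(chars[vStart - 2:1], collapse = "") else ""
    ## leader exon via the leader reference
    leader <- NULL; donorMotif <- ""
    lref <- if (!is.null(leaderRefs) && rg$query %in% names(leaderRefs))
      as.character(leaderRefs[[rg$query]]) else NULL
    if (!is.null(lref)) {
      lwLo <- max(1L, vStart - config$leaderWindow)
      lwHi <- vStart - 20L
      if (lwHi - lwLo + 1L >= nchar(lref)) {
        sub <- substr(w, lwLo, lwHi)
        pl <- .bestHamming(lref, sub)
        if (!is.null(pl) && pl$mismatches <= 0.4 * nchar(lref)) {
          ls <- lwLo - 1L + pl$start
          leader <- c(ls, ls + nchar(lref) - 1L)
          if (leader[2L] + 6L <= nchar(w))
            donorMotif <- paste(chars[leader[2L] + 1:6], collapse = "")
        }
      }
    }
    if (is.null(leader)) flags <- c(flags, "leader_not_found")
    exonsLocal <- c(if (!is.null(leader)) list(leader) else NULL, vexons)
    coding <- paste(vapply(exonsLocal, function(r) substr(w, r[1L], r[2L]),
                           character(1L)), collapse = "")
    vexonSpliced <- paste(vapply(vexons, function(r) substr(w, r[1L], r[2L]),
                                 character(1L)), collapse = "")
    if (grepl("N", coding, fixed = TRUE)) flags <- c(flags, "contains_N")
    rsList <- if (!is.null(rs)) list(.mapRSLocal(rs, ws, we, rg$strand)) else
      list()
    rngL <- c(exonsLocal[[1L]][1L], lastEnd)
    recs[[length(recs) + 1L]] <- list(
      type = "V", contig = rg$contig, strand = rg$strand,
      range = .l2g(rngL, ws, we, rg$strand),
      exons = lapply(exonsLocal, .l2g, ws = ws, we = we, strand = rg$strand),
      rs = rsList, flags = flags,
      protein = translateDNA(coding),
      evidence = list(ref = rg$query, identity = identity,
                      donorMotif = donorMotif, acceptorMotif = acceptorMotif,
                      coding = coding, vexonSpliced = vexonSpliced,
                      nVExonPieces = length(vexons),
                      refLen = nchar(ref)))
  }
  recs
}

## ------------------------------------------------------------ locus assembly

#' Assemble gene calls into V-D-J-C loci
#'
#' Each C gene seeds a locus; the nearest upstream (in gene orientation)
#' same-strand D within the configured window joins it, J genes between the
#' D and the C join, and every V gene is assigned to the locus of the
#' nearest same-strand downstream D. Genes assignable to no locus are
#' returned as orphans.
#'
#' @param recs List of gene records from the callers.
#' @param config See \code{\link{trbConfig}}.
#' @return A list with \code{recs} (records with a \code{locus} field set;
#'   orphans get \code{NA}), and \code{loci}, a \code{data.frame} per locus
#'   (contig, idx, strand, start, end, n_v, n_d, n_j, n_c, complete).
#' @export
assembleLoci <- function(recs, config = trbConfig()) {
  if (!length(recs)) {
    return(list(recs = recs, loci = data.frame()))
  }
  type <- vapply(recs, `[[`, character(1L), "type")
  ct <- vapply(recs, `[[`, character(1L), "contig")
  strand <- vapply(recs, `[[`, character(1L), "strand")
  st <- vapply(recs, function(r) r$range[1L], integer(1L))
  en <- vapply(recs, function(r) r$range[2L], integer(1L))
  locus <- rep(NA_integer_, length(recs))
  lociRows <- list(); locusIdx <- 0L
  for (contig in unique(ct)) {
    cIdx <- which(type == "C" & ct == contig)
    cIdx <- cIdx[order(st[cIdx])]
    dOf <- integer(0)                     # D record per locus
    for (ci in cIdx) {
      locusIdx <- locusIdx + 1L
      locus[ci] <- locusIdx
      s <- strand[ci]
      dCand <- which(type == "D" & ct == contig & strand == s &
                       is.na(locus))
      if (s == "+") {
        dCand <- dCand[en[dCand] < st[ci] &
                         en[dCand] >= st[ci] - config$djcWindow]
        ## do not cross another C on the same strand
        dCand <- dCand[vapply(dCand, function(di) {
          !any(type == "C" & ct == contig & strand == s &
                 st > en[di] & en < st[ci] & seq_along(recs) != ci)
        }, logical(1L))]
        di <- if (length(dCand)) dCand[which.max(en[dCand])] else NA_integer_
      } else {
        dCand <- dCand[st[dCand] > en[ci] &
                         st[dCand] <= en[ci] + config$djcWindow]
        dCand <- dCand[vapply(dCand, function(di) {
          !any(type == "C" & ct == contig & strand == s &
                 en < st[di] & st > en[ci] & seq_along(recs) != ci)
        }, logical(1L))]
        di <- if (length(dCand)) dCand[which.min(st[dCand])] else NA_integer_
      }
      if (!is.na(di)) {
        locus[di] <- locusIdx
        jCand <- which(type == "J" & ct == contig & strand == s & is.na(locus))
        lo <- min(en[di], en[ci]); hi <- max(st[di], st[ci])
        jIn <- jCand[st[jCand] > lo & en[jCand] < hi]
        locus[jIn] <- locusIdx
      }
      dOf[locusIdx] <- if (is.na(di)) NA_integer_ else di
    }
    ## V genes: nearest same-strand downstream D
    vIdx <- which(type == "V" & ct == contig)
    dAll <- which(type == "D" & ct == contig & !is.na(locus))
    for (vi in vIdx) {
      s <- strand[vi]
      dSame <- dAll[strand[dAll] == s]
      if (s == "+") {
        dDown <- dSame[st[dSame] > en[vi]]
        di <- if (length(dDown)) dDown[which.min(st[dDown])] else NA_integer_
      } else {
        dDown <- dSame[en[dSame] < st[vi]]
        di <- if (length(dDown)) dDown[which.max(en[dDown])] else NA_integer_
      }
      if (!is.na(di)) locus[vi] <- locus[di]
    }
  }
  for (li in seq_len(locusIdx)) {
    members <- which(locus == li)
    lociRows[[li]] <- data.frame(
      contig = ct[members[1L]], idx = li, strand = strand[members[1L]],
      start = min(st[members]), end = max(en[members]),
      n_v = sum(type[members] == "V"), n_d = sum(type[members] == "D"),
      n_j = sum(type[members] == "J"), n_c = sum(type[members] == "C"),
      complete = sum(type[members] == "V") > 0L &&
        sum(type[members] == "D") > 0L && sum(type[members] == "J") > 0L &&
        sum(type[members] == "C") > 0L)
  }
  for (i in seq_along(recs)) recs[[i]]$locus <- locus[i]
  list(recs = recs,
       loci = if (length(lociRows)) do.call(rbind, lociRows) else data.frame())
}

#' Classify the locus-level duplication pattern of a contig
#'
#' Rules, applied in order: an extra V-less D-J-C cluster adjacent to a
#' complete locus is a tandem D-J-C duplication; two complete loci in
#' opposite orientation with their V genes between the two C genes are a
#' head-to-head pair; orphan inverted V genes beside a single complete
#' locus are a remnant; one complete locus alone is single.
#'
#' @param loci The \code{loci} data.frame from \code{\link{assembleLoci}},
#'   restricted to one contig.
#' @param orphans List of orphan gene records on the contig.
#' @param recs All gene records on the contig (with locus assignments).
#' @return A \code{\linkS4class{TRBLocusStructure}}.
#' @export
detectDuplicationPattern <- function(loci, orphans = list(), recs = list()) {
  toGR <- function(df) {
    if (!nrow(df)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(df$contig, IRanges::IRanges(df$start, df$end),
                           strand = df$strand, locus_id = paste0("L", df$idx),
                           orientation = df$strand, n_v = df$n_v,
                           n_d = df$n_d, n_j = df$n_j, n_c = df$n_c,
                           complete = df$complete)
  }
  orphGR <- if (length(orphans)) {
    GenomicRanges::GRanges(
      vapply(orphans, `[[`, character(1L), "contig"),
      IRanges::IRanges(vapply(orphans, function(r) r$range[1L], integer(1L)),
                       vapply(orphans, function(r) r$range[2L], integer(1L))),
      strand = vapply(orphans, `[[`, character(1L), "strand"),
      type = vapply(orphans, `[[`, character(1L), "type"))
  } else GenomicRanges::GRanges()
  notes <- character(0)
  nComplete <- if (nrow(loci)) sum(loci$complete) else 0L
  vless <- if (nrow(loci))
    sum(!loci$complete & loci$n_v == 0L & loci$n_d > 0L &
          loci$n_j > 0L & loci$n_c > 0L) else 0L
  pattern <- "none"
  ## geometry check for a head-to-head pair: V genes of the two loci lie
  ## between the two C genes (C genes at the outer ends of the region)
  h2hGeometry <- function() {
    if (!length(recs)) return(TRUE)
    li <- loci$idx[loci$complete]
    typ <- vapply(recs, `[[`, character(1L), "type")
    lid <- vapply(recs, function(r)
      if (is.null(r$locus) || is.na(r$locus)) NA_integer_ else r$locus,
      integer(1L))
    mid <- vapply(recs, function(r) mean(r$range), numeric(1L))
    cPos <- sort(mid[typ == "C" & lid %in% li])
    vPos <- mid[typ == "V" & lid %in% li]
    if (length(cPos) < 2L || !length(vPos)) return(FALSE)
    all(vPos > cPos[1L] & vPos < cPos[length(cPos)])
  }
  if (vless >= 1L && nComplete >= 1L) {
    pattern <- "tandem_DJC_duplication"
  } else if (nComplete >= 2L &&
             length(unique(loci$strand[loci$complete])) == 2L &&
             h2hGeometry()) {
    pattern <- "head_to_head_pair"
    notes <- c(notes, "two complete opposite-orientation loci, V genes between the C genes")
  } else if (nComplete >= 1L && length(orphGR) &&
             any(orphGR$type == "V")) {
    pattern <- "remnant"
    notes <- c(notes, sprintf("%d orphan V gene(s) without a D-J-C cluster",
                              sum(orphGR$type == "V")))
  } else if (nComplete >= 1L) {
    pattern <- "single"
  }
  methods::new("TRBLocusStructure", loci = toGR(loci), orphans = orphGR,
               pattern = pattern, notes = notes)
}
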