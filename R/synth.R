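## Synthetic TRB locus generator.
##
## Generates ground-truthed genomes that emulate the salmonid TRB
## architecture: translocon V...V-D-J...J-C loci, optionally duplicated
## head-to-head (two loci in opposite orientation with the V genes in the
## middle and the C genes at the outer ends), a remnant set of inverted V
## genes without a D-J-C cluster, or a tandem duplication of a D-J-C
## cluster. Genes carry canonical recombination signals (V: 23-spacer 3'RS;
## J: 12-spacer 5'RS; D: 12-spacer 5'RS and 23-spacer 3'RS), canonical
## splice signals (GTAAGT donors, pyrimidine-tract acceptors), FGXG J
## motifs, and CYS23/TRP41/CYS104 V anchors, so that a mutation-free genome
## is recoverable exactly. Mutation operators plant labelled F/ORF/P
## variants.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.REV_CODON <- local({
  tab <- .CODON_TABLE
  split(names(tab), unname(tab))
})

.randCodons <- function(aa) {
  vapply(aa, function(a) {
    opts <- .REV_CODON[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1L), USE.NAMES = FALSE)
}

.randDNA <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## i.i.d. substitutions at `rate`, skipping `protect` (positions), always to
## a different base.
.mutateDNA <- function(seqStr, rate, protect = integer(0)) {
  chars <- strsplit(seqStr, "")[[1L]]
  n <- length(chars)
  hit <- which(stats::runif(n) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

## Revert any codon that became a stop to the ancestral codon. `codingStr`
## is read in frame 0.
.fixStops <- function(codingStr, ancestorStr) {
  aa <- translateDNA(codingStr)
  stops <- which(strsplit(aa, "")[[1L]] == "*")
  if (!length(stops)) return(codingStr)
  chars <- strsplit(codingStr, "")[[1L]]
  anc <- strsplit(ancestorStr, "")[[1L]]
  for (k in stops) {
    idx <- ((k - 1L) * 3L + 1L):(k * 3L)
    chars[idx] <- anc[idx]
  }
  paste(chars, collapse = "")
}

.hexamerMaxScore <- function(seqStr, target = "GTAAGT") {
  chars <- strsplit(seqStr, "")[[1L]]
  tg <- strsplit(target, "")[[1L]]
  n <- length(chars) - 5L
  if (n < 1L) return(0L)
  best <- 0L
  for (p in seq_len(n)) best <- max(best, sum(chars[p + 0:5] == tg))
  best
}

.pyTract <- function(n = 8L) paste(sample(c("C", "T"), n, replace = TRUE),
                                   collapse = "")

.makeIntron <- function(len = NULL) {
  if (is.null(len)) len <- sample(70:140, 1L)
  core <- len - 6L - 8L - 2L
  paste0("GTAAGT", .randDNA(core), .pyTract(8L), "AG")
}

#' Configuration for the synthetic TRB locus generator
#'
#' The defaults describe the study conditions the package is validated
#' under: two complete V-D-J-C loci duplicated head-to-head on one contig
#' (20 V genes per locus over three subgroups, one D, ten J, one C), with a
#' second contig carrying a single locus plus a remnant pair of inverted V
#' genes when \code{pattern = "trout"}. Within-subgroup divergence 0.10 and
#' between-subgroup divergence 0.35 substitutions per site place subgroup
#' identities on either side of the 75\% clustering threshold; the two C
#' ancestors diverge at 0.12 substitutions per site so that their products
#' fall in distinct C subgroups (about 70\% amino-acid identity), while
#' same-chromosome C copies stay near-identical (0.005).
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param pattern Locus architecture: \code{"head_to_head"} (one contig, two
#'   opposite-orientation loci), \code{"single"}, \code{"remnant"} (single
#'   locus plus inverted orphan V genes), \code{"tandem_djc"} (an extra
#'   V-less C-J-D cluster beside a head-to-head pair), or \code{"trout"}
#'   (head-to-head contig plus a single+remnant contig).
#' @param nVPerSubgroup Named integer vector: V genes per subgroup per locus.
#' @param nJ J genes per locus.
#' @param intergenicMean Mean intergenic distance between V genes (bases).
#' @param jSpacing Mean spacing within the J cluster (bases).
#' @param withinDivergence,betweenDivergence Substitutions/site within and
#'   between V subgroups (within must be smaller).
#' @param cWithinDivergence,cBetweenDivergence Same for C genes (within a
#'   chromosome vs between C subgroups).
#' @param jDivergence Substitutions/site between locus copies of a J gene.
#' @param remnantV Number of inverted orphan V genes for remnant patterns.
#' @param includeV6 Plant one 4-exon V gene (split V-EXON) in the first
#'   locus, mirroring the atypical salmonid TRBV6 structure.
#' @param mutations Character vector of mutation operators applied to the
#'   first \code{length(mutations)} V genes of the first locus (in build
#'   order); see \code{\link{applyGeneMutation}} for the operator set.
#' @param readLength,nReads,errorRate,c1c2Ratio Read-simulation settings
#'   (see \code{\link{simulateReads}}).
#' @return A validated config list of class \code{trb_synth_config}.
#' @export
synthConfig <- function(seed = 1L,
                        pattern = c("trout", "head_to_head", "single",
                                    "remnant", "tandem_djc"),
                        nVPerSubgroup = c(TRBV1 = 8L, TRBV2 = 7L, TRBV3 = 5L),
                        nJ = 10L,
                        intergenicMean = 3500L,
                        jSpacing = 400L,
                        withinDivergence = 0.10,
                        betweenDivergence = 0.35,
                        cWithinDivergence = 0.005,
                        cBetweenDivergence = 0.12,
                        jDivergence = 0.02,
                        remnantV = 2L,
                        includeV6 = TRUE,
                        mutations = character(0),
                        readLength = 75L,
                        nReads = 10000L,
                        errorRate = 0.01,
                        c1c2Ratio = 3) {
  pattern <- match.arg(pattern)
  if (withinDivergence >= betweenDivergence)
    stop("within-subgroup divergence must be below between-subgroup divergence")
  if (cWithinDivergence >= cBetweenDivergence)
    stop("within-chromosome C divergence must be below between-subgroup divergence")
  stopifnot(all(c(withinDivergence, betweenDivergence, errorRate) >= 0),
            all(c(withinDivergence, betweenDivergence, errorRate) <= 1),
            nJ >= 1L, all(nVPerSubgroup >= 0L))
  ops <- c("none", "stop", "frameshift", "ablate_rs", "degrade_rs",
           "break_donor", "break_acceptor", "anchor_change")
  if (length(mutations) && !all(mutations %in% ops))
    stop("unknown mutation op(s): ",
         paste(setdiff(mutations, ops), collapse = ", "))
  structure(list(seed = as.integer(seed), pattern = pattern,
                 nVPerSubgroup = nVPerSubgroup, nJ = as.integer(nJ),
                 intergenicMean = intergenicMean, jSpacing = jSpacing,
                 withinDivergence = withinDivergence,
                 betweenDivergence = betweenDivergence,
                 cWithinDivergence = cWithinDivergence,
                 cBetweenDivergence = cBetweenDivergence,
                 jDivergence = jDivergence,
                 remnantV = as.integer(remnantV),
                 includeV6 = isTRUE(includeV6),
                 mutations = mutations,
                 readLength = as.integer(readLength),
                 nReads = as.integer(nReads),
                 errorRate = errorRate, c1c2Ratio = c1c2Ratio),
            class = "trb_synth_config")
}

## ------------------------------------------------------------------ templates

.LPART1_LEN <- 49L      # leader exon; ends 1 nt into a codon (frame-1 donor)
.LPART2_LEN <- 11L      # completes the 20-codon signal region
.VREGION_AA <- 106L     # V-REGION length in codons; anchors at 23/41/104
.VEXON_LEN <- .LPART2_LEN + 3L * .VREGION_AA   # 329
.V_ANCHORS <- c(23L, 41L, 104L)
.V6_PIECES <- c(110L, 120L, 99L)               # split V-EXON piece lengths
.C_EXON_LENS <- c(391L, 45L, 104L, 27L)        # splice frames 1, 1, 0
.C_ANCHORS <- c(23L, 41L, 89L, 104L)
.D_REGION <- "GGGACAGGGGGC"                     # 12 bp G-rich, open in all frames
.J_REGION_AA <- 16L
.J_FGXG_AA <- 9L                                # FGXG at aa 9-12 of J-REGION

## protected coding positions (1-based within the frame-0 coding string)
.vProtect <- function() {
  anch <- unlist(lapply(.V_ANCHORS, function(k) {
    base <- 60L + (k - 1L) * 3L
    base + 1:3
  }))
  c(1:3, anch)
}

.cProtect <- function() {
  anch <- unlist(lapply(.C_ANCHORS, function(k) {
    base <- (k - 1L) * 3L
    base + 1:3
  }))
  c(anch, (sum(.C_EXON_LENS) - 2L):sum(.C_EXON_LENS))   # keep the stop codon
}

## Root V coding (60 nt signal + 318 nt V-REGION), then subgroup ancestors.
.makeVRoot <- function() {
  sigAA <- c("M", sample(.AA20, 19L, replace = TRUE))
  vAA <- sample(.AA20, .VREGION_AA, replace = TRUE)
  vAA[23L] <- "C"; vAA[41L] <- "W"; vAA[104L] <- "C"
  paste(c(.randCodons(sigAA), .randCodons(vAA)), collapse = "")
}

.deriveAncestor <- function(root, rate, protect) {
  x <- .mutateDNA(root, rate, protect)
  .fixStops(x, root)
}

.makeJTemplate <- function() {
  repeat {
    aa <- sample(.AA20, .J_REGION_AA, replace = TRUE)
    aa[.J_FGXG_AA] <- "F"; aa[.J_FGXG_AA + 1L] <- "G"
    aa[.J_FGXG_AA + 3L] <- "G"
    nt <- paste(c(.randCodons(aa), sample(c("A", "C", "G", "T"), 1L)),
                collapse = "")
    if (.hexamerMaxScore(nt) <= 4L) return(nt)   # keep the donor unambiguous
  }
}

.makeCRoot <- function() {
  aa <- sample(.AA20, 188L, replace = TRUE)
  aa[23L] <- "C"; aa[41L] <- "W"; aa[89L] <- "L"; aa[104L] <- "C"
  paste0(paste(.randCodons(aa), collapse = ""), "TAA")
}

## --------------------------------------------------------------- gene builds
## A build is a local, gene-strand description: seq plus landmark offsets.

.buildVGene <- function(ancestorCoding, withinDiv, subgroup, spliced = FALSE) {
  coding <- .fixStops(.mutateDNA(ancestorCoding, withinDiv, .vProtect()),
                      ancestorCoding)
  leader <- substr(coding, 1L, .LPART1_LEN)
  vexon <- substr(coding, .LPART1_LEN + 1L, nchar(coding))
  intron1 <- .makeIntron()
  pieces <- if (spliced) .V6_PIECES else nchar(vexon)
  vparts <- character(0); cuts <- cumsum(c(0L, pieces))
  for (i in seq_along(pieces)) {
    vparts <- c(vparts, substr(vexon, cuts[i] + 1L, cuts[i + 1L]))
  }
  vintrons <- if (spliced) replicate(length(pieces) - 1L, .makeIntron()) else
    character(0)
  spacer <- .randDNA(23L)

  seqParts <- c(leader, intron1)
  exonRanges <- list(c(1L, .LPART1_LEN))
  pos <- .LPART1_LEN + nchar(intron1)
  vexonRanges <- list()
  for (i in seq_along(vparts)) {
    s <- pos + 1L; e <- pos + nchar(vparts[i])
    vexonRanges[[i]] <- c(s, e)
    seqParts <- c(seqParts, vparts[i])
    pos <- e
    if (i < length(vparts)) {
      seqParts <- c(seqParts, vintrons[i])
      pos <- pos + nchar(vintrons[i])
    }
  }
  hept <- c(pos + 1L, pos + 7L)
  seqParts <- c(seqParts, RS_HEPTAMER, spacer, RS_NONAMER)
  nona <- c(pos + 7L + 23L + 1L, pos + 7L + 23L + 9L)

  list(type = "V", seq = paste(seqParts, collapse = ""),
       subgroup = subgroup, label = "F", op = "none",
       exons = c(exonRanges, vexonRanges),
       codingStart = 1L, codingEnd = pos,
       donor = c(.LPART1_LEN + 1L, .LPART1_LEN + 2L),
       acceptors = lapply(vexonRanges, function(r) c(r[1L] - 2L, r[1L] - 1L)),
       rs = list(list(heptamer = hept, nonamer = nona, class = 23L,
                      scanStrand = "+")),
       geneRange = c(1L, pos))
}

.buildJGene <- function(template, divergence) {
  for (try in 1:25) {
    jr <- template
    if (divergence > 0) {
      prot <- ((.J_FGXG_AA - 1L) * 3L + 1L):((.J_FGXG_AA + 3L) * 3L)
      jr <- .fixStops2(.mutateDNA(jr, divergence, prot), template)
      if (.hexamerMaxScore(jr) > 4L) next
    }
    break
  }
  spacer <- .randDNA(12L)
  rcN <- revcomp(RS_NONAMER)   # GGTTTTTGT
  rcH <- revcomp(RS_HEPTAMER)  # CACTGTG
  pre <- paste0(rcN, spacer, rcH)
  jStart <- nchar(pre) + 1L
  jEnd <- jStart + nchar(jr) - 1L
  seqStr <- paste0(pre, jr, "GTAAGT")
  list(type = "J", seq = seqStr, subgroup = NA_character_,
       label = "F", op = "none",
       exons = list(c(jStart, jEnd)),
       donor = c(jEnd + 1L, jEnd + 2L),
       rs = list(list(heptamer = c(10L + 12L, 10L + 12L + 6L),
                      nonamer = c(1L, 9L), class = 12L, scanStrand = "-")),
       geneRange = c(jStart, jEnd))
}

## stop-fix for a sequence whose trailing base is not part of a codon
.fixStops2 <- function(x, ancestor) {
  n <- nchar(x) - nchar(x) %% 3L
  head <- .fixStops(substr(x, 1L, n), substr(ancestor, 1L, n))
  paste0(head, substr(x, n + 1L, nchar(x)))
}

.buildDGene <- function() {
  sp12 <- .randDNA(12L); sp23 <- .randDNA(23L)
  pre <- paste0(revcomp(RS_NONAMER), sp12, revcomp(RS_HEPTAMER))
  dStart <- nchar(pre) + 1L
  dEnd <- dStart + nchar(.D_REGION) - 1L
  seqStr <- paste0(pre, .D_REGION, RS_HEPTAMER, sp23, RS_NONAMER)
  list(type = "D", seq = seqStr, subgroup = NA_character_,
       label = "F", op = "none",
       exons = list(c(dStart, dEnd)),
       rs = list(list(heptamer = c(22L, 28L), nonamer = c(1L, 9L),
                      class = 12L, scanStrand = "-"),
                 list(heptamer = c(dEnd + 1L, dEnd + 7L),
                      nonamer = c(dEnd + 7L + 23L + 1L, dEnd + 7L + 23L + 9L),
                      class = 23L, scanStrand = "+")),
       geneRange = c(dStart, dEnd))
}

.buildCGene <- function(ancestorCoding, withinDiv, subgroup) {
  coding <- .fixStops(.mutateDNA(ancestorCoding, withinDiv, .cProtect()),
                      ancestorCoding)
  cuts <- cumsum(c(0L, .C_EXON_LENS))
  exSeq <- vapply(seq_along(.C_EXON_LENS), function(i) {
    substr(coding, cuts[i] + 1L, cuts[i + 1L])
  }, character(1L))
  introns <- replicate(3L, .makeIntron())
  parts <- character(0); pos <- 0L
  exonRanges <- list(); acceptors <- list(); donors <- list()
  for (i in 1:4) {
    s <- pos + 1L; e <- pos + nchar(exSeq[i])
    exonRanges[[i]] <- c(s, e)
    if (i > 1L) acceptors[[i - 1L]] <- c(s - 2L, s - 1L)
    parts <- c(parts, exSeq[i]); pos <- e
    if (i < 4L) {
      donors[[i]] <- c(pos + 1L, pos + 2L)
      parts <- c(parts, introns[i]); pos <- pos + nchar(introns[i])
    }
  }
  list(type = "C", seq = paste(parts, collapse = ""), subgroup = subgroup,
       label = "F", op = "none", exons = exonRanges,
       donor = donors, acceptors = acceptors, rs = list(),
       geneRange = c(1L, pos), coding = coding)
}

## ------------------------------------------------------------ mutation ops

.shiftBuild <- function(build, at, delta) {
  sh <- function(r) {
    r + ifelse(r >= at, delta, 0L)
  }
  build$exons <- lapply(build$exons, sh)
  build$geneRange <- sh(build$geneRange)
  if (!is.null(build$donor)) {
    build$donor <- if (is.list(build$donor)) lapply(build$donor, sh) else
      sh(build$donor)
  }
  if (!is.null(build$acceptors)) build$acceptors <- lapply(build$acceptors, sh)
  build$rs <- lapply(build$rs, function(r) {
    r$heptamer <- sh(r$heptamer); r$nonamer <- sh(r$nonamer); r
  })
  if (!is.null(build$codingEnd)) build$codingEnd <- sh(build$codingEnd)
  build
}

.replaceAt <- function(seqStr, at, replacement) {
  paste0(substr(seqStr, 1L, at - 1L), replacement,
         substr(seqStr, at + nchar(replacement), nchar(seqStr)))
}

#' Apply a labelled mutation operator to a synthetic V gene
#'
#' Operators plant the gene-defect classes used in germline functionality
#' curation, together with the expected classification:
#' \code{stop} (earliest in-frame codon to TAA; expected P),
#' \code{frameshift} (1-base deletion mid V-REGION; P),
#' \code{ablate_rs} (heptamer and nonamer randomised until undetectable
#' even at relaxed thresholds; P),
#' \code{degrade_rs} (3 heptamer mismatches outside the CAC core; ORF),
#' \code{break_donor} (leader donor GT to AT; ORF),
#' \code{break_acceptor} (V-EXON acceptor AG to AC; ORF),
#' \code{anchor_change} (2nd-CYS 104 to glycine; ORF),
#' \code{none} (expected F).
#'
#' @param build A V gene build as produced by the generator (internal
#'   layout list).
#' @param op Operator name.
#' @return The modified build with \code{label} and \code{op} set.
#' @export
applyGeneMutation <- function(build, op) {
  if (build$type != "V") stop("mutation ops are defined for V gene builds")
  if (op == "none") return(build)
  s <- build$seq
  if (op == "stop") {
    build$seq <- .replaceAt(s, 4L, "TAA")    # codon 2 of the leader
    build$label <- "P"
  } else if (op == "frameshift") {
    vex <- build$exons[[2L]]
    at <- vex[1L] + 150L
    build$seq <- paste0(substr(s, 1L, at - 1L), substr(s, at + 1L, nchar(s)))
    build <- .shiftBuild(build, at + 1L, -1L)
    build$label <- "P"
  } else if (op == "ablate_rs") {
    rs <- build$rs[[1L]]
    lastEx <- build$exons[[length(build$exons)]]
    for (try in 1:80) {
      s2 <- .replaceAt(s, rs$heptamer[1L], .randDNA(7L))
      s2 <- .replaceAt(s2, rs$nonamer[1L], .randDNA(9L))
      ## context in which the classifier will look for a relaxed RS
      ws <- max(1L, lastEx[2L] - 12L)
      ctx <- substr(s2, ws, nchar(s2))
      rel <- scanRS(ctx, 23L, maxHeptamerMM = 3L, maxNonamerMM = 4L,
                    spacerSlack = 1L, requireCacCore = TRUE)
      rel <- rel[as.character(BiocGenerics::strand(rel)) == "+"]
      near <- abs((ws - 1L + rel$heptamer_start) - (lastEx[2L] + 1L)) <= 8L
      if (!any(near)) { build$seq <- s2; break }
    }
    build$rs <- list()
    build$label <- "P"
  } else if (op == "degrade_rs") {
    rs <- build$rs[[1L]]
    build$seq <- .replaceAt(s, rs$heptamer[1L] + 3L, "CTA")  # AGT -> CTA
    build$label <- "ORF"
  } else if (op == "break_donor") {
    build$seq <- .replaceAt(s, build$donor[1L], "A")         # GT -> AT
    build$label <- "ORF"
  } else if (op == "break_acceptor") {
    acc <- build$acceptors[[1L]]
    build$seq <- .replaceAt(s, acc[2L], "C")                 # AG -> AC
    build$label <- "ORF"
  } else if (op == "anchor_change") {
    vex <- build$exons[[2L]]
    at <- vex[1L] + .LPART2_LEN + (104L - 1L) * 3L
    ## for a split V-EXON locate the anchor across pieces
    if (length(build$exons) > 2L) {
      off <- .LPART2_LEN + (104L - 1L) * 3L
      for (i in 2:length(build$exons)) {
        w <- build$exons[[i]][2L] - build$exons[[i]][1L] + 1L
        if (off < w) { at <- build$exons[[i]][1L] + off; break }
        off <- off - w
      }
    }
    build$seq <- .replaceAt(s, at, "GGT")                    # CYS104 -> GLY
    build$label <- "ORF"
  } else {
    stop("unknown mutation op: ", op)
  }
  build$op <- op
  build
}

## ---------------------------------------------------------- locus assembly

.gapLen <- function(mean) max(200L, as.integer(round(mean * stats::runif(1, 0.6, 1.4))))

## Assemble one locus on its gene strand; returns seq + local gene records.
.buildLocus <- function(locusName, templates, config, cSubgroup,
                        nV = config$nVPerSubgroup, includeV6 = FALSE,
                        mutationOps = character(0), includeVBlock = TRUE) {
  parts <- character(0); pos <- 0L
  recs <- list()
  add <- function(build, id) {
    gap <- .gapLen(if (build$type == "V") config$intergenicMean else
                   if (build$type == "J") config$jSpacing else 700L)
    parts <<- c(parts, .randDNA(gap), build$seq)
    off <- pos + gap
    pos <<- off + nchar(build$seq)
    build$offset <- off
    build$id <- id
    recs[[length(recs) + 1L]] <<- build
  }
  vIdx <- 0L
  if (includeVBlock) {
    v6At <- if (includeV6) max(1L, floor(sum(nV) / 2L)) else -1L
    for (sg in names(nV)) {
      for (k in seq_len(nV[[sg]])) {
        vIdx <- vIdx + 1L
        b <- .buildVGene(templates$vAncestors[[sg]], config$withinDivergence,
                         sg)
        if (vIdx <= length(mutationOps))
          b <- applyGeneMutation(b, mutationOps[vIdx])
        add(b, sprintf("%s.V%02d", locusName, vIdx))
        if (vIdx == v6At) {
          b6 <- .buildVGene(templates$vAncestors[["TRBV6"]],
                            config$withinDivergence / 2, "TRBV6",
                            spliced = TRUE)
          vIdx <- vIdx + 1L
          add(b6, sprintf("%s.V%02d", locusName, vIdx))
        }
      }
    }
  }
  add(.buildDGene(), paste0(locusName, ".D"))
  for (k in seq_len(config$nJ)) {
    add(.buildJGene(templates$jTemplates[[k]], config$jDivergence),
        sprintf("%s.J%02d", locusName, k))
  }
  add(.buildCGene(templates$cAncestors[[cSubgroup]],
                  config$cWithinDivergence, cSubgroup),
      paste0(locusName, ".C"))
  parts <- c(parts, .randDNA(.gapLen(700L)))
  list(seq = paste(parts, collapse = ""), recs = recs, name = locusName)
}

## Place a locus (possibly reverse-complemented) into a contig at `offset`.
.placeLocus <- function(locus, orientation, offset, contig) {
  L <- nchar(locus$seq)
  seqStr <- if (orientation == "-") revcomp(locus$seq) else locus$seq
  mapR <- function(r) {
    if (orientation == "+") r + offset else c(L - r[2L] + 1L, L - r[1L] + 1L) + offset
  }
  flip <- function(s) if (orientation == "+") s else ifelse(s == "+", "-", "+")
  recs <- lapply(locus$recs, function(b) {
    sh <- function(r) mapR(r + b$offset)
    list(gene_id = paste0(contig, ".", b$id), type = b$type,
         label = b$label, subgroup = b$subgroup, locus = locus$name,
         op = b$op, strand = orientation,
         range = sh(b$geneRange),
         exons = lapply(b$exons, sh),
         rs = lapply(b$rs, function(r) {
           list(heptamer = sh(r$heptamer), nonamer = sh(r$nonamer),
                class = r$class, scanStrand = flip(r$scanStrand))
         }))
  })
  list(seq = seqStr, recs = recs)
}

.emptyRSGRanges <- function() {
  GenomicRanges::GRanges(
    seqnames = character(0), ranges = IRanges::IRanges(),
    strand = character(0),
    heptamer_start = integer(0), heptamer_end = integer(0),
    nonamer_start = integer(0), nonamer_end = integer(0),
    spacer_class = integer(0))
}

.recsToGRanges <- function(recs, contig) {
  if (!length(recs)) {
    return(list(features = GenomicRanges::GRanges(),
                exons = GenomicRanges::GRangesList(),
                rs = GenomicRanges::GRangesList()))
  }
  feat <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(
      start = vapply(recs, function(r) r$range[1L], integer(1L)),
      end = vapply(recs, function(r) r$range[2L], integer(1L))),
    strand = vapply(recs, function(r) r$strand, character(1L)),
    gene_id = vapply(recs, function(r) r$gene_id, character(1L)),
    type = vapply(recs, function(r) r$type, character(1L)),
    label = vapply(recs, function(r) r$label, character(1L)),
    subgroup = vapply(recs, function(r) r$subgroup, character(1L)),
    locus = vapply(recs, function(r) r$locus, character(1L)),
    op = vapply(recs, function(r) r$op, character(1L))
  )
  exl <- lapply(recs, function(r) {
    GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(
        start = vapply(r$exons, `[`, integer(1L), 1L),
        end = vapply(r$exons, `[`, integer(1L), 2L)),
      strand = r$strand)
  })
  names(exl) <- feat$gene_id
  rsl <- lapply(recs, function(r) {
    if (!length(r$rs)) return(.emptyRSGRanges())
    GenomicRanges::GRanges(
      seqnames = contig,
      ranges = IRanges::IRanges(
        start = vapply(r$rs, function(x) min(x$heptamer, x$nonamer), integer(1L)),
        end = vapply(r$rs, function(x) max(x$heptamer, x$nonamer), integer(1L))),
      strand = vapply(r$rs, function(x) x$scanStrand, character(1L)),
      heptamer_start = vapply(r$rs, function(x) x$heptamer[1L], integer(1L)),
      heptamer_end = vapply(r$rs, function(x) x$heptamer[2L], integer(1L)),
      nonamer_start = vapply(r$rs, function(x) x$nonamer[1L], integer(1L)),
      nonamer_end = vapply(r$rs, function(x) x$nonamer[2L], integer(1L)),
      spacer_class = vapply(r$rs, function(x) x$class, integer(1L)))
  })
  names(rsl) <- feat$gene_id
  list(features = feat, exons = exl, rs = rsl)
}

#' Generate a ground-truthed synthetic TRB genome
#'
#' Builds the genome described by a \code{\link{synthConfig}}: subgroup
#' ancestor sequences are derived from a common root at the configured
#' between-subgroup divergence, individual genes from their ancestor at the
#' within-subgroup divergence (substitution-only, so truth coordinates are
#' exact), and loci are assembled in the configured architecture. All
#' randomness is governed by the config seed; the same config yields a
#' byte-identical genome.
#'
#' @param config A \code{\link{synthConfig}}.
#' @return A \code{\linkS4class{TRBTruthSet}}.
#' @export
generateLocusGenome <- function(config) {
  if (!inherits(config, "trb_synth_config"))
    stop("config must be created with synthConfig()")
  set.seed(config$seed)

  vRoot <- .makeVRoot()
  sgs <- names(config$nVPerSubgroup)
  vAncestors <- lapply(sgs, function(s)
    .deriveAncestor(vRoot, config$betweenDivergence / 2, .vProtect()))
  names(vAncestors) <- sgs
  vAncestors$TRBV6 <- .deriveAncestor(vRoot, config$betweenDivergence / 2,
                                      .vProtect())
  cRoot <- .makeCRoot()
  cAncestors <- list(
    C1 = cRoot,
    C2 = .fixStops(.mutateDNA(cRoot, config$cBetweenDivergence, .cProtect()),
                   cRoot))
  jTemplates <- lapply(seq_len(config$nJ), function(i) .makeJTemplate())
  templates <- list(vAncestors = vAncestors, cAncestors = cAncestors,
                    jTemplates = jTemplates)

  allRecs <- list(); seqs <- character(0); patterns <- character(0)

  buildH2H <- function(contig, names2 = c("TRB1", "TRB2"), extraDJC = FALSE) {
    locA <- .buildLocus(names2[1L], templates, config, "C1",
                        includeV6 = config$includeV6,
                        mutationOps = config$mutations)
    locB <- .buildLocus(names2[2L], templates, config, "C1")
    flank <- .randDNA(.gapLen(2000L))
    mid <- .randDNA(.gapLen(1500L))
    pos <- nchar(flank)
    recs <- list(); parts <- flank
    if (extraDJC) {
      locX <- .buildLocus("TRBx", templates, config, "C1",
                          includeVBlock = FALSE)
      pX <- .placeLocus(locX, "-", pos, contig)
      parts <- c(parts, pX$seq); pos <- pos + nchar(pX$seq)
      recs <- c(recs, pX$recs)
      gap <- .randDNA(.gapLen(1500L))
      parts <- c(parts, gap); pos <- pos + nchar(gap)
    }
    pA <- .placeLocus(locA, "-", pos, contig)
    parts <- c(parts, pA$seq); pos <- pos + nchar(pA$seq)
    recs <- c(recs, pA$recs)
    parts <- c(parts, mid); pos <- pos + nchar(mid)
    pB <- .placeLocus(locB, "+", pos, contig)
    parts <- c(parts, pB$seq); pos <- pos + nchar(pB$seq)
    recs <- c(recs, pB$recs)
    parts <- c(parts, .randDNA(.gapLen(2000L)))
    list(seq = paste(parts, collapse = ""), recs = recs)
  }

  buildSingle <- function(contig, locusName = "TRB3", cSub = "C2",
                          remnant = 0L, muts = character(0)) {
    loc <- .buildLocus(locusName, templates, config, cSub,
                       mutationOps = muts)
    flank <- .randDNA(.gapLen(2000L))
    pos <- nchar(flank)
    p <- .placeLocus(loc, "+", pos, contig)
    parts <- c(flank, p$seq); pos <- pos + nchar(p$seq)
    recs <- p$recs
    if (remnant > 0L) {
      for (k in seq_len(remnant)) {
        b <- .buildVGene(templates$vAncestors[[sgs[1L]]],
                         config$withinDivergence, sgs[1L])
        gap <- .randDNA(.gapLen(config$intergenicMean))
        parts <- c(parts, gap); pos <- pos + nchar(gap)
        ## place inverted (opposite orientation, no D-J-C downstream)
        lseq <- revcomp(b$seq)
        L <- nchar(b$seq)
        mapR <- function(r) c(L - r[2L] + 1L, L - r[1L] + 1L) + pos
        rec <- list(gene_id = sprintf("%s.TRB4.V%02d", contig, k), type = "V",
                    label = b$label, subgroup = b$subgroup, locus = "remnant",
                    op = "none", strand = "-", range = mapR(b$geneRange),
                    exons = lapply(b$exons, mapR),
                    rs = lapply(b$rs, function(r) {
                      list(heptamer = mapR(r$heptamer), nonamer = mapR(r$nonamer),
                           class = r$class,
                           scanStrand = ifelse(r$scanStrand == "+", "-", "+"))
                    }))
        parts <- c(parts, lseq); pos <- pos + L
        recs <- c(recs, list(rec))
      }
      parts <- c(parts, .randDNA(.gapLen(2000L)))
    }
    list(seq = paste(parts, collapse = ""), recs = recs)
  }

  if (config$pattern %in% c("head_to_head", "tandem_djc")) {
    b <- buildH2H("chr25", extraDJC = config$pattern == "tandem_djc")
    seqs["chr25"] <- b$seq
    allRecs$chr25 <- b$recs
    patterns["chr25"] <- if (config$pattern == "tandem_djc")
      "tandem_DJC_duplication" else "head_to_head_pair"
  } else if (config$pattern == "single") {
    b <- buildSingle("chr19", muts = config$mutations)
    seqs["chr19"] <- b$seq
    allRecs$chr19 <- b$recs
    patterns["chr19"] <- "single"
  } else if (config$pattern == "remnant") {
    b <- buildSingle("chr19", remnant = config$remnantV,
                     muts = config$mutations)
    seqs["chr19"] <- b$seq
    allRecs$chr19 <- b$recs
    patterns["chr19"] <- "remnant"
  } else {                                   # trout
    b1 <- buildH2H("chr25")
    b2 <- buildSingle("chr19", remnant = config$remnantV)
    seqs["chr25"] <- b1$seq; seqs["chr19"] <- b2$seq
    allRecs$chr25 <- b1$recs; allRecs$chr19 <- b2$recs
    patterns["chr25"] <- "head_to_head_pair"
    patterns["chr19"] <- if (config$remnantV > 0L) "remnant" else "single"
  }

  grs <- lapply(names(allRecs), function(ct) .recsToGRanges(allRecs[[ct]], ct))
  features <- suppressWarnings(do.call(c, lapply(grs, `[[`, "features")))
  exons <- suppressWarnings(do.call(c, lapply(grs, function(g)
    GenomicRanges::GRangesList(g$exons))))
  rs <- suppressWarnings(do.call(c, lapply(grs, function(g)
    GenomicRanges::GRangesList(g$rs))))

  genome <- Biostrings::DNAStringSet(seqs)
  transcripts <- Biostrings::DNAStringSet(c(TRBC1 = cAncestors$C1,
                                            TRBC2 = cAncestors$C2))

  profiles <- Biostrings::AAStringSet(vapply(vAncestors, function(a) {
    translateDNA(substr(a, 61L, nchar(a)))
  }, character(1L)))
  refs <- list(
    v = Biostrings::DNAStringSet(vapply(vAncestors, function(a)
      substr(a, .LPART1_LEN + 1L, nchar(a)), character(1L))),
    leader = Biostrings::DNAStringSet(vapply(vAncestors, function(a)
      substr(a, 1L, .LPART1_LEN), character(1L))),
    c = transcripts,
    profiles = profiles,
    profileAnchors = c(`23` = 23L, `41` = 41L, `104` = 104L),
    lPart2Len = .LPART2_LEN
  )

  methods::new("TRBTruthSet", genome = genome, features = features,
               exons = exons, rs = rs, transcripts = transcripts,
               refs = refs,
               config = c(unclass(config), list(patterns = patterns)))
}

#' Simulate RNA-seq reads from C transcripts at a known expression ratio
#'
#' Reads are allocated across transcripts proportionally to the target RPKM
#' ratio times transcript length (so that the realised RPKM ratio equals the
#' target), using deterministic largest-remainder rounding. Read start
#' positions and strands are uniform; sequencing errors are i.i.d.
#' substitutions at \code{errorRate}.
#'
#' @param transcripts \code{DNAStringSet} of at least 2 transcripts; the
#'   first is treated as TRBC1 and the second as TRBC2 for ratio purposes.
#' @param readLength,nReads,errorRate Simulation settings.
#' @param ratio Target TRBC1/TRBC2 RPKM ratio.
#' @param seed Integer seed.
#' @return A list: \code{reads} (\code{DNAStringSet}, named read_0001...),
#'   \code{truth} (character vector of source transcript names),
#'   \code{targetCounts} (the deterministic allocation).
#' @export
simulateReads <- function(transcripts, readLength = 75L, nReads = 10000L,
                          errorRate = 0.01, ratio = 3, seed = 1L) {
  if (length(transcripts) < 2L)
    stop("at least 2 transcripts are required for ratio studies")
  if (any(width(transcripts) < readLength))
    stop("read length exceeds a transcript length")
  set.seed(seed)
  lens <- width(transcripts)
  w <- c(ratio * lens[1L], lens[2L])
  if (length(transcripts) > 2L) w <- c(w, lens[-(1:2)])
  w <- w / sum(w)
  exact <- w * nReads
  counts <- floor(exact)
  rem <- nReads - sum(counts)
  if (rem > 0L) {
    o <- order(exact - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1L
  }
  counts <- as.integer(counts)
  src <- rep(names(transcripts), counts)
  tseq <- as.character(transcripts)
  reads <- character(0)
  bases <- c("A", "C", "G", "T")
  for (tn in names(transcripts)) {
    n <- counts[match(tn, names(transcripts))]
    if (n == 0L) next
    chars <- strsplit(tseq[[tn]], "")[[1L]]
    tl <- length(chars)
    sts <- sample.int(tl - readLength + 1L, n, replace = TRUE)
    mat <- matrix(chars[outer(sts - 1L, seq_len(readLength), `+`)], nrow = n)
    if (errorRate > 0) {
      nerr <- stats::rbinom(n, readLength, errorRate)
      for (i in which(nerr > 0L)) {
        for (p in sample.int(readLength, nerr[i])) {
          mat[i, p] <- sample(setdiff(bases, mat[i, p]), 1L)
        }
      }
    }
    rstr <- do.call(paste0, lapply(seq_len(readLength), function(j) mat[, j]))
    flip <- stats::runif(n) < 0.5
    if (any(flip)) rstr[flip] <- revcomp(rstr[flip])
    reads <- c(reads, rstr)
  }
  perm <- sample.int(length(reads))
  reads <- reads[perm]; src <- src[perm]
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("read_%05d", seq_along(reads))
  list(reads = out, truth = src,
       targetCounts = stats::setNames(counts, names(transcripts)))
}

#' Write a truth set to disk as plain-text files
#'
#' Writes genome FASTA, truth GFF3, transcript FASTA and a truth TSV.
#'
#' @param truth A \code{TRBTruthSet}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeTruthSet <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeGenomeFasta(truth@genome, file.path(dir, "genome.fa"))
  writeGenomeFasta(truth@transcripts, file.path(dir, "transcripts.fa"))
  f <- truth@features
  df <- data.frame(gene_id = f$gene_id, type = f$type, label = f$label,
                   subgroup = f$subgroup, locus = f$locus, op = f$op,
                   contig = as.character(GenomicRanges::seqnames(f)),
                   start = GenomicRanges::start(f), end = GenomicRanges::end(f),
                   strand = as.character(BiocGenerics::strand(f)))
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ann <- methods::new("TRBAnnotation", genome = truth@genome,
                      genes = local({
                        g <- truth@features
                        S4Vectors::mcols(g) <- S4Vectors::DataFrame(
                          gene_id = f$gene_id, type = f$type,
                          functionality = f$label)
                        g
                      }),
                      exons = truth@exons, rs = truth@rs)
  writeAnnotationGFF3(ann, file.path(dir, "truth.gff3"))
  invisible(dir)
}
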