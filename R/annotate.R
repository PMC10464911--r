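## End-to-end annotation pipeline: similarity + motif evidence -> gene
## calls -> loci -> functionality -> subgroups -> names.

#' Annotate TRB loci in a genome
#'
#' Runs the full pipeline: C genes are called from similarity to spliced C
#' references; for each C, the upstream region (in gene orientation) is
#' scanned for the D gene (paired 12/23 RS) and the J cluster (12-RS plus
#' donor evidence); V genes are called genome-wide from similarity plus
#' 23-RS and splice evidence; calls are assembled into loci, classified
#' F/ORF/P, clustered into subgroups at the >75\% identity threshold,
#' mapped onto the reference subgroup set, and named positionally.
#'
#' @param genome Named \code{DNAStringSet} (or path to a FASTA file).
#' @param refs Reference library list: \code{v} (V-EXON exemplars, one per
#'   subgroup), \code{leader} (L-PART1 exemplars, same names), \code{c}
#'   (spliced C references named TRBC1/TRBC2), \code{profiles} (AA
#'   numbering profiles per subgroup), \code{profileAnchors},
#'   \code{lPart2Len}. A \code{\linkS4class{TRBTruthSet}} provides this
#'   via \code{\link{refLibrary}}.
#' @param config See \code{\link{trbConfig}}.
#' @param allowSplicedVExon Try split V-EXON models (TRBV6-like genes).
#' @param contigOrder Contig order for locus numbering (default: genome
#'   order).
#' @return A list: \code{annotation} (\code{\linkS4class{TRBAnnotation}}),
#'   \code{structures} (named list of
#'   \code{\linkS4class{TRBLocusStructure}}, one per contig), \code{loci}
#'   (locus summary data.frame) and \code{recs} (gene records).
#' @export
annotateGenome <- function(genome, refs, config = trbConfig(),
                           allowSplicedVExon = TRUE, contigOrder = NULL) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- readGenomeFasta(genome)
  cRecs <- callCGenes(genome, refs$c, config)
  djRecs <- list()
  for (cr in cRecs) {
    L <- width(genome)[match(cr$contig, names(genome))]
    if (cr$strand == "+") {
      from <- max(1L, cr$range[1L] - config$djcWindow)
      to <- cr$range[1L] - 1L
      ## do not cross another C gene
      others <- Filter(function(x) x$contig == cr$contig &&
                         x$range[2L] < cr$range[1L], cRecs)
      if (length(others))
        from <- max(from, max(vapply(others, function(x) x$range[2L],
                                     integer(1L))) + 1L)
    } else {
      from <- cr$range[2L] + 1L
      to <- min(L, cr$range[2L] + config$djcWindow)
      others <- Filter(function(x) x$contig == cr$contig &&
                         x$range[1L] > cr$range[2L], cRecs)
      if (length(others))
        to <- min(to, min(vapply(others, function(x) x$range[1L],
                                 integer(1L))) - 1L)
    }
    if (to - from < 200L) next
    region <- GenomicRanges::GRanges(cr$contig, IRanges::IRanges(from, to),
                                     strand = cr$strand)
    dR <- callDGenes(genome, region, config)
    if (length(dR)) {
      ## nearest D to the C in gene orientation
      dPos <- vapply(dR, function(r) r$range[1L], integer(1L))
      pick <- if (cr$strand == "+") which.max(dPos) else which.min(dPos)
      dR <- dR[pick]
      d <- dR[[1L]]
      jFrom <- if (cr$strand == "+") d$range[2L] + 40L else from
      jTo <- if (cr$strand == "+") to else d$range[1L] - 40L
      if (jTo > jFrom + 100L) {
        jRegion <- GenomicRanges::GRanges(cr$contig,
                                          IRanges::IRanges(jFrom, jTo),
                                          strand = cr$strand)
        djRecs <- c(djRecs, callJGenes(genome, jRegion, config))
      }
      djRecs <- c(djRecs, dR)
    } else {
      djRecs <- c(djRecs, callJGenes(genome, region, config))
    }
  }
  vRecs <- callVGenes(genome, refs$v, refs$leader, allowSplicedVExon, config)
  recs <- c(vRecs, djRecs, cRecs)
  asm <- assembleLoci(recs, config)
  recs <- asm$recs

  ## functionality
  for (i in seq_along(recs)) {
    fc <- classifyFunctionality(recs[[i]], config, profiles = refs$profiles,
                                profileAnchors = refs$profileAnchors)
    recs[[i]]$functionality <- fc$label
    recs[[i]]$reasons <- fc$reasons
  }

  ## V subgroups
  vIdx <- which(vapply(recs, `[[`, character(1L), "type") == "V")
  if (length(vIdx)) {
    vreg <- Biostrings::DNAStringSet(vapply(vIdx, function(i) {
      vx <- recs[[i]]$evidence$vexonSpliced
      substr(vx, config$lPart2Len + 1L, nchar(vx))
    }, character(1L)))
    names(vreg) <- paste0("v", vIdx)
    refLib <- Biostrings::subseq(refs$v, config$lPart2Len + 1L)
    if (length(vreg) >= 2L) {
      idm <- pairwiseIdentity(vreg)
      cl <- clusterSubgroups(idm, threshold = config$subgroupThreshold)
      mp <- mapToReferenceSubgroups(cl$membership, vreg, refLib,
                                    threshold = config$subgroupThreshold)
      for (z in seq_along(vIdx)) {
        i <- vIdx[z]
        recs[[i]]$subgroup <- mp$subgroup[match(paste0("v", i), mp$gene)]
        recs[[i]]$subgroup_number <-
          mp$subgroup_number[match(paste0("v", i), mp$gene)]
      }
    } else {
      i <- vIdx[1L]
      recs[[i]]$subgroup <- recs[[i]]$evidence$ref
      recs[[i]]$subgroup_number <-
        suppressWarnings(as.integer(sub("^\\D*", "",
                                        recs[[i]]$evidence$ref)))
    }
  }

  ## C subgroups
  cIdx <- which(vapply(recs, `[[`, character(1L), "type") == "C")
  if (length(cIdx)) {
    exemplars <- Biostrings::AAStringSet(vapply(refs$c, function(s) {
      translateDNA(as.character(s))
    }, character(1L)))
    names(exemplars) <- sub("^TRB", "", names(refs$c))   # C1, C2
    if (length(cIdx) >= 2L) {
      prot <- Biostrings::AAStringSet(vapply(cIdx, function(i)
        sub("\\*$", "", recs[[i]]$protein), character(1L)))
      names(prot) <- paste0("c", cIdx)
      cs <- classifyCSubgroups(prot, exemplars,
                               threshold = config$cSubgroupThreshold)
      for (i in cIdx) {
        lab <- cs$assignment[[paste0("c", i)]]
        recs[[i]]$subgroup <- lab
        recs[[i]]$subgroup_number <- as.integer(sub("^C", "", lab))
      }
    } else {
      i <- cIdx[1L]
      pids <- .pidAgainst(exemplars,
                          Biostrings::AAString(sub("\\*$", "",
                                                   recs[[i]]$protein)), TRUE)
      lab <- names(exemplars)[which.max(pids)]
      recs[[i]]$subgroup <- lab
      recs[[i]]$subgroup_number <- as.integer(sub("^C", "", lab))
    }
  }

  recs <- assignNames(recs, contigOrder = contigOrder)

  ## structures per contig
  contigs <- unique(vapply(recs, `[[`, character(1L), "contig"))
  structures <- lapply(contigs, function(ctg) {
    onCt <- vapply(recs, function(r) r$contig == ctg, logical(1L))
    lociCt <- if (nrow(asm$loci)) asm$loci[asm$loci$contig == ctg, ] else
      asm$loci
    orph <- Filter(function(r) is.na(r$locus), recs[onCt])
    detectDuplicationPattern(lociCt, orph, recs[onCt])
  })
  names(structures) <- contigs

  ann <- .recsToAnnotation(genome, recs)
  list(annotation = ann, structures = structures, loci = asm$loci,
       recs = recs)
}

## Convert internal gene records to a TRBAnnotation.
.recsToAnnotation <- function(genome, recs) {
  if (!length(recs)) {
    return(methods::new("TRBAnnotation", genome = genome,
                        genes = GenomicRanges::GRanges(),
                        exons = GenomicRanges::GRangesList(),
                        rs = GenomicRanges::GRangesList()))
  }
  ct <- vapply(recs, `[[`, character(1L), "contig")
  type <- vapply(recs, `[[`, character(1L), "type")
  st <- vapply(recs, function(r) r$range[1L], integer(1L))
  o <- order(ct, st)
  recs <- recs[o]
  ct <- ct[o]; type <- type[o]; st <- st[o]
  ids <- character(length(recs))
  for (ctg in unique(ct)) {
    for (tp in c("V", "D", "J", "C")) {
      w <- which(ct == ctg & type == tp)
      if (length(w)) ids[w] <- sprintf("%s.%s%02d", ctg, tp, seq_along(w))
    }
  }
  getc <- function(f, default = NA_character_) {
    vapply(recs, function(r) {
      v <- r[[f]]
      if (is.null(v) || length(v) == 0L || is.na(v)[1L]) default else
        as.character(v)[1L]
    }, character(1L))
  }
  locusLab <- vapply(recs, function(r) {
    if ((is.null(r$locus) || is.na(r$locus)) && r$type == "V") "remnant"
    else if (!is.null(r$locusNumber) && !is.na(r$locusNumber))
      paste0("TRB", r$locusNumber)
    else if (!is.null(r$locus) && !is.na(r$locus)) paste0("L", r$locus)
    else NA_character_
  }, character(1L))
  genes <- GenomicRanges::GRanges(
    seqnames = ct,
    ranges = IRanges::IRanges(
      start = st, end = vapply(recs, function(r) r$range[2L], integer(1L))),
    strand = vapply(recs, `[[`, character(1L), "strand"),
    gene_id = ids, type = type,
    name = getc("name"),
    functionality = getc("functionality"),
    reasons = IRanges::CharacterList(lapply(recs, function(r)
      if (is.null(r$reasons)) character(0) else r$reasons)),
    subgroup = getc("subgroup"),
    locus = locusLab,
    flags = IRanges::CharacterList(lapply(recs, function(r)
      if (is.null(r$flags)) character(0) else r$flags)),
    protein = getc("protein", NA_character_)
  )
  exl <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    GenomicRanges::GRanges(
      ct[i],
      IRanges::IRanges(start = vapply(r$exons, `[`, integer(1L), 1L),
                       end = vapply(r$exons, `[`, integer(1L), 2L)),
      strand = r$strand)
  })
  names(exl) <- ids
  rsl <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$rs) || !length(r$rs)) return(.emptyRSGRanges())
    GenomicRanges::GRanges(
      ct[i],
      IRanges::IRanges(
        start = vapply(r$rs, function(x) min(x$heptamer, x$nonamer), integer(1L)),
        end = vapply(r$rs, function(x) max(x$heptamer, x$nonamer), integer(1L))),
      strand = vapply(r$rs, `[[`, character(1L), "scanStrand"),
      heptamer_start = vapply(r$rs, function(x) x$heptamer[1L], integer(1L)),
      heptamer_end = vapply(r$rs, function(x) x$heptamer[2L], integer(1L)),
      nonamer_start = vapply(r$rs, function(x) x$nonamer[1L], integer(1L)),
      nonamer_end = vapply(r$rs, function(x) x$nonamer[2L], integer(1L)),
      spacer_class = vapply(r$rs, function(x) as.integer(x$class), integer(1L)))
  })
  names(rsl) <- ids
  methods::new("TRBAnnotation", genome = genome, genes = genes,
               exons = GenomicRanges::GRangesList(exl),
               rs = GenomicRanges::GRangesList(rsl))
}
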