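#' Annotation pipeline configuration
#'
#' Central place for the tunable thresholds of the annotation pipeline.
#' All values are overridable; the defaults are the declared conditions
#' under which the package's validation suite runs.
#'
#' RS detection operates at three levels: the scan defaults (heptamer
#' \code{CACAGTG} within 2 mismatches with the CAC core exact, nonamer
#' \code{ACAAAAACC} within 3) define an intact RS; an RS found only at the
#' relaxed thresholds (3 heptamer mismatches, CAC exact, 4 nonamer
#' mismatches) is defective (ORF); an RS not found even relaxed within
#' \code{rsSlack} bases of the coding end is missing (pseudogene). J-gene
#' discovery uses stricter motif gates (1 heptamer / 2 nonamer mismatches)
#' because J genes are called from motif evidence alone, without
#' similarity support.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of configuration values.
#' @export
trbConfig <- function(...) {
  cfg <- list(
    ## similarity search
    minIdentity = 70, minCov = 50, k = 12L, mergeGap = 600L,
    ## RS scanning: per-gene-type spacer classes (12/23 rule)
    vSpacer = 23L, jSpacer = 12L, d5Spacer = 12L, d3Spacer = 23L,
    maxHeptamerMM = 2L, maxNonamerMM = 3L, spacerSlack = 1L,
    requireCacCore = TRUE,
    relaxedHeptamerMM = 3L, relaxedNonamerMM = 4L,
    rsSlack = 8L,                 # RS-to-coding-end search slack (bases)
    ## J gene discovery gates
    jMaxHeptamerMM = 1L, jMaxNonamerMM = 2L,
    jDonorWindow = c(20L, 70L),   # donor search window after J start
    jMinDonorScore = 4,           # of 6 GTAAGT positions
    ## D region length bounds
    dRegionMin = 8L, dRegionMax = 25L,
    ## structure models
    lPart2Len = 11L,
    leaderLen = 49L,
    leaderWindow = 500L,
    singleExonIdentity = 80,      # below this, try the spliced V-EXON model
    cExonFrames = c(1L, 1L, 0L),  # splice frames EX1/2, EX2/3, EX3/4
    ## functionality
    hydrophobic89 = c("A", "V", "L", "I", "M", "F", "W", "C", "Y"),
    numberingMinIdentity = 30,
    ## subgroups & naming
    subgroupThreshold = 75,       # strictly greater than
    cSubgroupThreshold = 85,      # amino-acid identity, C subgroups
    ## locus assembly
    djcWindow = 12000L            # search span upstream of C for D and J
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config option(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}
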