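test_that("numbering transfer maps anchors through alignments", {
  set.seed(61)
  prof <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], 110,
                       replace = TRUE), collapse = "")
  ch <- strsplit(prof, "")[[1L]]
  ch[23] <- "C"; ch[41] <- "W"; ch[104] <- "C"
  prof <- paste(ch, collapse = "")

  ## profile against itself: identity map, anchors C/W/C
  nm <- numberVDomain(prof, prof)
  expect_equal(unname(nm$map), seq_len(110))
  expect_equal(unname(nm$anchors), c("C", "W", "C"))

  ## one residue inserted between positions 30 and 31: anchors unchanged
  ins <- paste0(substr(prof, 1, 30), "G", substr(prof, 31, 110))
  nm2 <- numberVDomain(ins, prof)
  expect_equal(unname(nm2$anchors), c("C", "W", "C"))
  expect_equal(unname(nm2$map[23]), 23L)
  expect_equal(unname(nm2$map[41]), 42L)    # shifted by the insertion
  expect_equal(unname(nm2$map[104]), 105L)

  ## unrelated sequences are refused
  junk <- paste(rep("P", 110), collapse = "")
  expect_error(numberVDomain(junk, prof, minIdentity = 30), "unalignable")
})

test_that("the mutant panel classifies with the expected labels and reasons", {
  ops <- c("none", "stop", "frameshift", "ablate_rs", "degrade_rs",
           "break_donor", "break_acceptor", "anchor_change")
  wantLabel <- c(none = "F", stop = "P", frameshift = "P", ablate_rs = "P",
                 degrade_rs = "ORF", break_donor = "ORF",
                 break_acceptor = "ORF", anchor_change = "ORF")
  wantReason <- c(stop = "stop_codon", frameshift = "frameshift",
                  ablate_rs = "missing_rs", degrade_rs = "defective_rs",
                  break_donor = "defective_splice",
                  break_acceptor = "defective_splice",
                  anchor_change = "anchor_change")
  cfg <- synthConfig(seed = 202, pattern = "single",
                     nVPerSubgroup = c(TRBV1 = 4L, TRBV2 = 4L), nJ = 3L,
                     intergenicMean = 1200L, includeV6 = FALSE,
                     mutations = ops)
  ts <- suppressWarnings(generateLocusGenome(cfg))
  res <- suppressWarnings(annotateGenome(genomeSeq(ts), refLibrary(ts)))
  g <- geneCalls(res$annotation)
  tf <- truthFeatures(ts)
  vt <- tf[tf$type == "V"]
  vg <- g[g$type == "V"]
  ov <- GenomicRanges::findOverlaps(vt, vg, ignore.strand = TRUE)
  expect_equal(length(ov), length(vt))
  for (k in seq_along(ov)) {
    op <- vt$op[S4Vectors::queryHits(ov)[k]]
    got <- vg$functionality[S4Vectors::subjectHits(ov)[k]]
    reasons <- unlist(vg$reasons[S4Vectors::subjectHits(ov)[k]])
    expect_equal(got, unname(wantLabel[op]), label = op)
    if (op == "none") expect_length(reasons, 0L)
    else expect_true(wantReason[op] %in% reasons,
                     label = paste(op, "->", paste(reasons, collapse = ",")))
  }
})

test_that("severity is monotone: adding a stop never improves a label", {
  set.seed(77)
  root <- trbloci:::.makeVRoot()
  build <- trbloci:::.buildVGene(root, 0.05, "TRBV1")
  refs <- list(
    v = Biostrings::DNAStringSet(c(TRBV1 = substr(root, 50, nchar(root)))),
    leader = Biostrings::DNAStringSet(c(TRBV1 = substr(root, 1, 49))),
    profiles = Biostrings::AAStringSet(c(TRBV1 = translateDNA(
      substr(root, 61, nchar(root))))),
    profileAnchors = c(`23` = 23L, `41` = 41L, `104` = 104L))
  classifyOf <- function(b) {
    genome <- Biostrings::DNAStringSet(c(
      ctg = paste0(randomDNA(200), b$seq, randomDNA(200))))
    recs <- callVGenes(genome, refs$v, refs$leader)
    expect_length(recs, 1L)
    classifyFunctionality(recs[[1L]], profiles = refs$profiles,
                          profileAnchors = refs$profileAnchors)
  }
  base <- classifyOf(build)
  expect_equal(base$label, "F")
  orf <- classifyOf(applyGeneMutation(build, "degrade_rs"))
  expect_equal(orf$label, "ORF")
  worst <- classifyOf(applyGeneMutation(applyGeneMutation(build,
                                                          "degrade_rs"),
                                        "stop"))
  expect_equal(worst$label, "P")
  onlyStop <- classifyOf(applyGeneMutation(build, "stop"))
  expect_equal(onlyStop$label, "P")
})

test_that("N in the coding span blocks a functional certification", {
  set.seed(78)
  root <- trbloci:::.makeVRoot()
  build <- trbloci:::.buildVGene(root, 0, "TRBV1")
  ## plant an N inside the V-EXON
  ch <- strsplit(build$seq, "")[[1L]]
  ch[build$exons[[2L]][1L] + 30L] <- "N"
  genome <- Biostrings::DNAStringSet(c(
    ctg = paste0(randomDNA(200), paste(ch, collapse = ""), randomDNA(200))))
  refs <- Biostrings::DNAStringSet(c(TRBV1 = substr(root, 50, nchar(root))))
  leaders <- Biostrings::DNAStringSet(c(TRBV1 = substr(root, 1, 49)))
  recs <- callVGenes(genome, refs, leaders)
  expect_length(recs, 1L)
  fc <- classifyFunctionality(recs[[1L]])
  expect_equal(fc$label, "ORF")
  expect_true("contains_N" %in% fc$reasons)
})
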