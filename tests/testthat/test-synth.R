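test_that("the generator is deterministic and validates its config", {
  cfg <- synthConfig(seed = 12, pattern = "single",
                     nVPerSubgroup = c(TRBV1 = 2L), nJ = 2L,
                     intergenicMean = 800L, includeV6 = FALSE)
  ts1 <- suppressWarnings(generateLocusGenome(cfg))
  ts2 <- suppressWarnings(generateLocusGenome(cfg))
  expect_identical(as.character(genomeSeq(ts1)), as.character(genomeSeq(ts2)))
  expect_identical(as.character(truthTranscripts(ts1)),
                   as.character(truthTranscripts(ts2)))
  ts3 <- suppressWarnings(generateLocusGenome(synthConfig(
    seed = 13, pattern = "single", nVPerSubgroup = c(TRBV1 = 2L), nJ = 2L,
    intergenicMean = 800L, includeV6 = FALSE)))
  expect_false(identical(as.character(genomeSeq(ts1)),
                         as.character(genomeSeq(ts3))))

  expect_error(synthConfig(withinDivergence = 0.4, betweenDivergence = 0.3),
               "divergence")
  expect_error(synthConfig(mutations = "explode"), "unknown mutation")
  expect_error(generateLocusGenome(list(seed = 1)), "synthConfig")
})

test_that("planted features cite real genome content", {
  ts <- smallTruth()
  tf <- truthFeatures(ts)
  genome <- genomeSeq(ts)
  ## every planted feature is inside its contig and the V RS heptamers read
  ## as the consensus on their scan strand
  expect_true(all(GenomicRanges::end(tf) <=
                    width(genome)[match(as.character(
                      GenomicRanges::seqnames(tf)), names(genome))]))
  for (id in tf$gene_id[tf$type == "V"]) {
    rs <- ts@rs[[id]]
    gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(rs),
                                 IRanges::IRanges(rs$heptamer_start,
                                                  rs$heptamer_end),
                                 strand = BiocGenerics::strand(rs))
    expect_equal(as.character(extractSeq(genome, gr)), RS_HEPTAMER)
  }
  ## planted labels are within the allowed set
  expect_true(all(tf$label %in% c("F", "ORF", "P")))
})

test_that("mutation operators change the planted evidence as labelled", {
  set.seed(88)
  root <- trbloci:::.makeVRoot()
  build <- trbloci:::.buildVGene(root, 0.02, "TRBV1")

  stopb <- applyGeneMutation(build, "stop")
  expect_equal(stopb$label, "P")
  expect_equal(substr(stopb$seq, 4, 6), "TAA")

  fs <- applyGeneMutation(build, "frameshift")
  expect_equal(nchar(fs$seq), nchar(build$seq) - 1L)
  expect_equal(fs$label, "P")

  dg <- applyGeneMutation(build, "degrade_rs")
  hept <- substr(dg$seq, dg$rs[[1]]$heptamer[1], dg$rs[[1]]$heptamer[2])
  expect_equal(substr(hept, 1, 3), "CAC")
  expect_equal(sum(strsplit(hept, "")[[1]] !=
                     strsplit(RS_HEPTAMER, "")[[1]]), 3L)

  ab <- applyGeneMutation(build, "ablate_rs")
  ## no relaxed-threshold RS remains near the coding end
  lastEx <- ab$exons[[length(ab$exons)]]
  ctx <- substr(ab$seq, lastEx[2] - 12, nchar(ab$seq))
  rel <- scanRS(ctx, 23L, maxHeptamerMM = 3L, maxNonamerMM = 4L)
  rel <- rel[as.character(BiocGenerics::strand(rel)) == "+"]
  near <- abs((lastEx[2] - 13 + rel$heptamer_start) - (lastEx[2] + 1)) <= 8
  expect_false(any(near))

  bd <- applyGeneMutation(build, "break_donor")
  expect_equal(substr(bd$seq, bd$donor[1], bd$donor[2]), "AT")

  ba <- applyGeneMutation(build, "break_acceptor")
  acc <- ba$acceptors[[1]]
  expect_equal(substr(ba$seq, acc[1], acc[2]), "AC")

  expect_equal(applyGeneMutation(build, "none")$label, "F")
  expect_error(applyGeneMutation(build, "nonsense"), "unknown")
  dbuild <- trbloci:::.buildDGene()
  expect_error(applyGeneMutation(dbuild, "stop"), "V gene")
})

test_that("read simulation allocates proportionally and errors are bounded", {
  tx <- Biostrings::DNAStringSet(c(TRBC1 = strrep("ACGT", 150),
                                   TRBC2 = strrep("TGCA", 150)))
  sim <- simulateReads(tx, readLength = 100, nReads = 4000, errorRate = 0,
                       ratio = 3, seed = 2)
  expect_equal(unname(sim$targetCounts), c(3000L, 1000L))
  expect_equal(unname(table(sim$truth)[c("TRBC1", "TRBC2")]),
               c(3000L, 1000L), ignore_attr = TRUE)
  expect_equal(unique(width(sim$reads)), 100L)

  ## unequal lengths: allocation is ratio x length weighted
  tx2 <- Biostrings::DNAStringSet(c(TRBC1 = strrep("ACGT", 200),
                                    TRBC2 = strrep("TGCA", 100)))
  sim2 <- simulateReads(tx2, readLength = 80, nReads = 1000, errorRate = 0,
                        ratio = 2, seed = 3)
  expect_equal(unname(sim2$targetCounts),
               c(800L, 200L))  # 2*800 : 400 -> 4:1
  expect_error(simulateReads(tx2, readLength = 500, nReads = 10), "length")
  expect_error(simulateReads(tx2[1], nReads = 10), "at least 2")
})

test_that("truth sets serialise to plain-text files", {
  ts <- smallTruth()
  dir <- file.path(tempdir(), "truthset")
  writeTruthSet(ts, dir)
  expect_true(file.exists(file.path(dir, "genome.fa")))
  expect_true(file.exists(file.path(dir, "transcripts.fa")))
  expect_true(file.exists(file.path(dir, "truth.tsv")))
  expect_true(file.exists(file.path(dir, "truth.gff3")))
  back <- readGenomeFasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(back), as.character(genomeSeq(ts)))
  tsv <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(nrow(tsv), length(truthFeatures(ts)))
})
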