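test_that("pairwise identity matches direct counts and a DP score oracle", {
  s <- Biostrings::DNAStringSet(c(a = "ACGT", b = "ACGA"))
  m <- pairwiseIdentity(s)
  expect_equal(m["a", "b"], 75)
  expect_equal(diag(m), c(a = 100, b = 100))

  twin <- Biostrings::DNAStringSet(c(x = strrep("ACGT", 75),
                                     y = strrep("ACGT", 75)))
  expect_equal(pairwiseIdentity(twin)["x", "y"], 100)

  expect_error(pairwiseIdentity(Biostrings::DNAStringSet(c(a = "ACG",
                                                           b = ""))),
               "empty sequence.*b")

  ## equal-length random pairs: the optimal global alignment is gapless at
  ## these penalties, so identity equals the direct positional count, and
  ## the alignment score matches an independent affine-gap DP oracle
  set.seed(91)
  for (k in 1:10) {
    a <- randomDNA(60); b <- mutateString(a, sample(60, 8))
    ss <- Biostrings::DNAStringSet(c(a = a, b = b))
    m <- pairwiseIdentity(ss)
    direct <- 100 * mean(strsplit(a, "")[[1L]] == strsplit(b, "")[[1L]])
    expect_equal(m["a", "b"], direct, tolerance = 1e-9)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1,
                                                                    baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    expect_equal(BiocGenerics::score(aln), oracleGlobalScore(a, b))
  }
  ## unequal lengths: scores still agree with the DP oracle
  for (k in 1:3) {
    a <- randomDNA(50); b <- paste0(substr(a, 1, 20), substr(a, 26, 50))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -1,
                                                                    baseOnly = FALSE),
      gapOpening = 4, gapExtension = 1)
    expect_equal(BiocGenerics::score(aln), oracleGlobalScore(a, b))
  }
})

test_that("subgroup clustering is single-linkage with a strict 75% boundary", {
  mkMat <- function(vals, ids) {
    n <- length(ids)
    m <- matrix(100, n, n, dimnames = list(ids, ids))
    for (v in vals) m[v[[1L]], v[[2L]]] <- m[v[[2L]], v[[1L]]] <- v[[3L]]
    m
  }
  ## transitive closure: AB 90, BC 80, AC 60 -> one subgroup
  m <- mkMat(list(list("A", "B", 90), list("B", "C", 80),
                  list("A", "C", 60)), c("A", "B", "C"))
  cl <- clusterSubgroups(m)
  expect_equal(length(unique(cl$membership)), 1L)

  ## all pairwise 50% -> singletons
  m2 <- mkMat(list(list("A", "B", 50), list("B", "C", 50),
                   list("A", "C", 50)), c("A", "B", "C"))
  expect_equal(length(unique(clusterSubgroups(m2)$membership)), 3L)

  ## exactly 75 is NOT linked (the definition is strictly more than 75)
  m3 <- mkMat(list(list("A", "B", 75)), c("A", "B"))
  expect_equal(length(unique(clusterSubgroups(m3)$membership)), 2L)
  m4 <- mkMat(list(list("A", "B", 75 + 1e-6)), c("A", "B"))
  expect_equal(length(unique(clusterSubgroups(m4)$membership)), 1L)

  ## label canonicalisation: permuting input order permutes nothing
  set.seed(13)
  ids <- paste0("g", 1:9)
  truthGrp <- rep(1:3, each = 3)
  m5 <- matrix(50, 9, 9, dimnames = list(ids, ids))
  for (i in 1:9) for (j in 1:9) if (truthGrp[i] == truthGrp[j]) m5[i, j] <- 92
  diag(m5) <- 100
  cl5 <- clusterSubgroups(m5)
  perm <- sample(9)
  cl5p <- clusterSubgroups(m5[perm, perm])
  ## the partition is invariant to input order
  expect_equal(adjustedRand(cl5p$membership[ids], cl5$membership[ids]), 1)

  ## threshold monotonicity: lowering the threshold can only merge
  cl70 <- clusterSubgroups(m, threshold = 70)
  cl85 <- clusterSubgroups(m, threshold = 85)
  expect_lte(length(unique(cl70$membership)),
             length(unique(cl85$membership)))
})

test_that("clusters map onto reference subgroups or get novel numbers", {
  set.seed(14)
  base13 <- randomDNA(240)
  ref <- Biostrings::DNAStringSet(c(TRBV13 = base13, TRBV2 = randomDNA(240)))
  near <- mutateString(base13, sample(240, 18))     # ~92% to TRBV13
  far <- randomDNA(240)
  seqs <- Biostrings::DNAStringSet(c(g1 = near, g2 = far))
  membership <- stats::setNames(c(1L, 2L), c("g1", "g2"))
  mp <- mapToReferenceSubgroups(membership, seqs, ref)
  expect_equal(mp$subgroup[mp$gene == "g1"], "TRBV13")
  expect_equal(mp$subgroup_number[mp$gene == "g1"], 13L)
  expect_true(mp$novel[mp$gene == "g2"])
  expect_equal(mp$subgroup_number[mp$gene == "g2"], 14L)  # next free number
})

test_that("generated subgroups are recovered exactly from sequence identity", {
  ## within 0.10 / between 0.35 substitutions per site straddle the 75%
  ## threshold; clustering must reproduce the generating partition
  for (seed in c(5, 6, 7)) {
    cfg <- synthConfig(seed = seed, pattern = "single",
                       nVPerSubgroup = c(TRBV1 = 3L, TRBV2 = 3L, TRBV3 = 3L),
                       nJ = 2L, intergenicMean = 900L, includeV6 = FALSE)
    ts <- suppressWarnings(generateLocusGenome(cfg))
    tf <- truthFeatures(ts)
    vIdx <- which(tf$type == "V")
    vseq <- Biostrings::DNAStringSet(vapply(vIdx, function(i) {
      ex <- ts@exons[[tf$gene_id[i]]]
      paste(as.character(extractSeq(genomeSeq(ts), sort(ex)[-1L])),
            collapse = "")
    }, character(1L)))
    names(vseq) <- tf$gene_id[vIdx]
    cl <- clusterSubgroups(pairwiseIdentity(vseq))
    expect_equal(adjustedRand(cl$membership, tf$subgroup[vIdx]), 1,
                 label = paste("seed", seed))
  }
})

test_that("positional names follow the locus/subgroup/rank convention", {
  mkRec <- function(type, contig, strand, start, end, locus, sub = NA) {
    list(type = type, contig = contig, strand = strand,
         range = c(start, end), locus = locus, subgroup_number = sub,
         gene_id = paste0(type, start))
  }
  ## locus 1: one V (subgroup 1), D, J, C; locus 2: four subgroup-13 V genes
  recs <- c(
    list(mkRec("V", "chr", "+", 100, 500, 1L, 1L),
         mkRec("D", "chr", "+", 1000, 1012, 1L),
         mkRec("J", "chr", "+", 1100, 1150, 1L),
         mkRec("C", "chr", "+", 2000, 2800, 1L, 1L)),
    lapply(1:4, function(k) mkRec("V", "chr", "+", 4000 + k * 600,
                                  4400 + k * 600, 2L, 13L)),
    list(mkRec("D", "chr", "+", 8000, 8012, 2L),
         mkRec("C", "chr", "+", 9000, 9800, 2L, 1L)))
  named <- assignNames(recs)
  nm <- vapply(named, `[[`, character(1L), "name")
  ## the 4th subgroup-13 V gene of locus 2, counted 5'->3'
  expect_equal(nm[8], "TRB2V13-4")
  expect_equal(nm[1], "TRB1V1-1")
  ## C genes rank across loci within the C subgroup
  expect_equal(nm[recs_idx <- 4], "TRB1C1-1")
  expect_equal(nm[10], "TRB2C1-2")
  expect_equal(nm[2], "TRB1D")
  expect_equal(nm[3], "TRB1J1")

  ## a minus-strand locus ranks 5'->3' in transcriptional orientation
  recsM <- list(
    mkRec("C", "chr", "-", 100, 900, 1L, 2L),
    mkRec("D", "chr", "-", 1500, 1512, 1L),
    mkRec("V", "chr", "-", 2000, 2400, 1L, 3L),   # nearer D: rank 2
    mkRec("V", "chr", "-", 3000, 3400, 1L, 3L))   # 5'-most: rank 1
  nmM <- vapply(assignNames(recsM), `[[`, character(1L), "name")
  expect_equal(nmM[4], "TRB1V3-1")
  expect_equal(nmM[3], "TRB1V3-2")
  expect_equal(nmM[1], "TRB1C2-1")

  ## an unassigned V gene is an error
  bad <- list(mkRec("V", "chr", "+", 1, 10, 1L, NA))
  expect_error(assignNames(bad), "without subgroup")
})
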