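test_that("a mutation-free synthetic locus is recovered exactly", {
  ts <- smallTruth()
  res <- smallAnnotation()
  m <- matchTruth(res$annotation, ts)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)

  ## exon structures match truth exactly, gene by gene
  g <- geneCalls(res$annotation)
  tf <- truthFeatures(ts)
  idx <- match(paste(GenomicRanges::seqnames(g), GenomicRanges::start(g)),
               paste(GenomicRanges::seqnames(tf), GenomicRanges::start(tf)))
  for (i in seq_along(g)) {
    a <- sort(geneExons(res$annotation)[[g$gene_id[i]]])
    b <- sort(ts@exons[[tf$gene_id[idx[i]]]])
    expect_equal(GenomicRanges::start(a), GenomicRanges::start(b))
    expect_equal(GenomicRanges::end(a), GenomicRanges::end(b))
  }

  ## evidence invariants: every V has a 23-RS, every J a 12-RS, every D both
  for (i in seq_along(g)) {
    rs <- geneRS(res$annotation)[[g$gene_id[i]]]
    if (g$type[i] == "V") expect_true(23L %in% rs$spacer_class)
    if (g$type[i] == "J") expect_true(12L %in% rs$spacer_class)
    if (g$type[i] == "D") expect_setequal(rs$spacer_class, c(12L, 23L))
  }

  ## C gene structure: 4 exons, splice frames 1,1,0, conserved anchors
  cid <- g$gene_id[g$type == "C"]
  cex <- sort(geneExons(res$annotation)[[cid]])
  expect_equal(length(cex), 4L)
  lens <- GenomicRanges::width(cex)
  expect_equal(as.integer(cumsum(lens)[1:3] %% 3L), c(1L, 1L, 0L))
  prot <- g$protein[g$gene_id == cid]
  aa <- strsplit(prot, "")[[1L]]
  expect_equal(aa[23], "C"); expect_equal(aa[41], "W"); expect_equal(aa[104], "C")

  ## functional J products contain the FGXG motif
  jprot <- g$protein[g$type == "J" & g$functionality == "F"]
  expect_true(all(grepl("FG.G", jprot)))
})

test_that("J calling flags a degenerate donor and D calling needs an RS pair", {
  set.seed(411)
  sp12 <- "GCATGCATGCAT"
  jreg <- paste0(strrep("GCT", 8L), "TTTGGAGCTGGA", strrep("GCT", 4L), "A")
  mkJ <- function(donor) paste0(randomDNA(80), "GGTTTTTGT", sp12, "CACTGTG",
                                jreg, donor, randomDNA(80))
  genome <- Biostrings::DNAStringSet(c(ctg = mkJ("GTAAGT")))
  region <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, width(genome)),
                                   strand = "+")
  recs <- callJGenes(genome, region)
  expect_equal(length(recs), 1L)
  expect_equal(recs[[1L]]$range[2L] - recs[[1L]]$range[1L] + 1L, 49L)
  expect_length(recs[[1L]]$flags, 0L)
  expect_false(is.na(recs[[1L]]$evidence$fgxgPos))

  genome2 <- Biostrings::DNAStringSet(c(ctg = mkJ("GTAACT")))
  recs2 <- callJGenes(genome2, region)
  expect_equal(length(recs2), 1L)
  expect_true("noncanonical_donor" %in% recs2[[1L]]$flags)

  ## a region without an RS pair yields no D call
  noD <- Biostrings::DNAStringSet(c(ctg = randomDNA(400)))
  expect_length(callDGenes(noD, GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(1, 400), strand = "+")), 0L)

  ## planted D unit: one call, 12-base G-rich D region, open in all frames
  dUnit <- paste0("GGTTTTTGT", sp12, "CACTGTG", "GGGACAGGGGGC",
                  "CACAGTG", randomDNA(23), "ACAAAAACC")
  gD <- Biostrings::DNAStringSet(c(ctg = paste0(randomDNA(100), dUnit,
                                                randomDNA(100))))
  dr <- callDGenes(gD, GenomicRanges::GRanges(
    "ctg", IRanges::IRanges(1, width(gD)), strand = "+"))
  expect_equal(length(dr), 1L)
  expect_equal(dr[[1L]]$evidence$dLength, 12L)
  expect_setequal(dr[[1L]]$evidence$openFrames, 0:2)
})

test_that("C calling flags a broken splice-frame structure", {
  set.seed(421)
  ## hand-built C gene with exon lengths violating the 1,1,0 frame rule
  coding <- trbloci:::.makeCRoot()
  lens <- c(392L, 45L, 104L, 26L)             # frames become 2, 1, 1
  cuts <- cumsum(c(0L, lens))
  intron <- function() paste0("GTAAGT", randomDNA(70), "TTTCTTCC", "AG")
  parts <- character(0)
  for (i in 1:4) {
    parts <- c(parts, substr(coding, cuts[i] + 1L, cuts[i + 1L]))
    if (i < 4L) parts <- c(parts, intron())
  }
  genome <- Biostrings::DNAStringSet(c(
    ctg = paste0(randomDNA(150), paste(parts, collapse = ""), randomDNA(150))))
  recs <- callCGenes(genome, Biostrings::DNAStringSet(c(TRBC1 = coding)))
  expect_equal(length(recs), 1L)
  expect_equal(length(recs[[1L]]$exons), 4L)
  expect_true("incomplete_exon_structure" %in% recs[[1L]]$flags)
})

test_that("the split V-EXON gene model is recovered when enabled and flagged when not", {
  cfg <- synthConfig(seed = 81, pattern = "head_to_head",
                     nVPerSubgroup = c(TRBV1 = 2L, TRBV2 = 2L), nJ = 3L,
                     intergenicMean = 1500L, includeV6 = TRUE)
  ts <- suppressWarnings(generateLocusGenome(cfg))
  tf <- truthFeatures(ts)
  v6id <- tf$gene_id[which(tf$subgroup == "TRBV6")]
  expect_length(v6id, 1L)
  expect_equal(length(ts@exons[[v6id]]), 4L)   # leader + 3 V-EXON pieces

  res <- suppressWarnings(annotateGenome(genomeSeq(ts), refLibrary(ts),
                                         allowSplicedVExon = TRUE))
  m <- matchTruth(res$annotation, ts)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  g <- geneCalls(res$annotation)
  v6 <- which(g$subgroup == "TRBV6")
  expect_length(v6, 1L)
  expect_equal(length(geneExons(res$annotation)[[g$gene_id[v6]]]), 4L)
  expect_equal(g$functionality[v6], "F")

  ## without the spliced model the gene is a flagged, pseudogene-like call
  res2 <- suppressWarnings(annotateGenome(genomeSeq(ts), refLibrary(ts),
                                          allowSplicedVExon = FALSE))
  g2 <- geneCalls(res2$annotation)
  tfv6 <- tf[tf$gene_id == v6id]
  ov <- GenomicRanges::findOverlaps(tfv6, g2[g2$type == "V"],
                                    ignore.strand = TRUE)
  hit <- which(g2$type == "V")[S4Vectors::subjectHits(ov)]
  expect_length(hit, 1L)
  expect_true("incomplete_vexon_model" %in% unlist(g2$flags[hit]))
  expect_equal(g2$functionality[hit], "P")
})

test_that("annotation is strand-covariant and names follow transcription", {
  ts <- smallTruth()
  res <- smallAnnotation()
  g <- geneCalls(res$annotation)

  rcGenome <- Biostrings::reverseComplement(genomeSeq(ts))
  names(rcGenome) <- names(genomeSeq(ts))
  res2 <- suppressWarnings(annotateGenome(rcGenome, refLibrary(ts)))
  g2 <- geneCalls(res2$annotation)
  expect_equal(length(g2), length(g))
  L <- width(genomeSeq(ts))[1L]
  mirStart <- L - GenomicRanges::end(g) + 1L
  expect_setequal(GenomicRanges::start(g2), mirStart)
  ## gene names are unchanged: ranks follow the transcriptional orientation
  expect_setequal(g2$name, g$name)
  expect_setequal(as.character(BiocGenerics::strand(g2)),
                  ifelse(as.character(BiocGenerics::strand(g)) == "+",
                         "-", "+"))
})

test_that("duplication patterns are classified from locus geometry", {
  cfgs <- list(
    head_to_head = synthConfig(seed = 55, pattern = "head_to_head",
                               nVPerSubgroup = c(TRBV1 = 2L, TRBV2 = 2L),
                               nJ = 3L, intergenicMean = 1200L,
                               includeV6 = FALSE),
    remnant = synthConfig(seed = 56, pattern = "remnant",
                          nVPerSubgroup = c(TRBV1 = 2L, TRBV2 = 2L),
                          nJ = 3L, intergenicMean = 1200L,
                          includeV6 = FALSE),
    tandem_djc = synthConfig(seed = 57, pattern = "tandem_djc",
                             nVPerSubgroup = c(TRBV1 = 2L, TRBV2 = 2L),
                             nJ = 3L, intergenicMean = 1200L,
                             includeV6 = FALSE))
  want <- c(head_to_head = "head_to_head_pair", remnant = "remnant",
            tandem_djc = "tandem_DJC_duplication")
  for (nm in names(cfgs)) {
    ts <- suppressWarnings(generateLocusGenome(cfgs[[nm]]))
    res <- suppressWarnings(annotateGenome(genomeSeq(ts), refLibrary(ts)))
    expect_equal(res$structures[[1L]]@pattern, unname(want[nm]),
                 label = nm)
    if (nm == "remnant") {
      orph <- res$structures[[1L]]@orphans
      expect_equal(sum(orph$type == "V"), 2L)
      g <- geneCalls(res$annotation)
      expect_equal(sum(g$locus == "remnant", na.rm = TRUE), 2L)
    }
  }
})

test_that("locus membership partitions non-orphan genes", {
  res <- smallAnnotation()
  lid <- vapply(res$recs, function(r)
    if (is.null(r$locus) || is.na(r$locus)) NA_integer_ else r$locus,
    integer(1L))
  expect_true(all(table(lid) >= 1L))
  ## every assigned gene belongs to exactly one locus by construction of
  ## the assignment vector; check the loci summary reconciles
  expect_equal(sum(res$loci$n_v + res$loci$n_d + res$loci$n_j + res$loci$n_c),
               sum(!is.na(lid)))
})

test_that("external hit tables can replace the internal search", {
  ts <- smallTruth()
  genome <- genomeSeq(ts)
  refs <- refLibrary(ts)
  internal <- similaritySearch(refs$v, genome)
  ## write as a 12-column table and re-import
  f <- tempfile(fileext = ".tsv")
  rows <- apply(internal, 1L, function(r) {
    sstart <- if (r[["strand"]] == "+") r[["start"]] else r[["end"]]
    send <- if (r[["strand"]] == "+") r[["end"]] else r[["start"]]
    paste(r[["query"]], r[["contig"]], r[["identity"]], "300", "0", "0",
          "1", "300", sstart, send, "0", "500", sep = "\t")
  })
  writeLines(rows, f)
  imported <- readHitTable(f)
  vi <- callVGenes(genome, refs$v, refs$leader, hits = internal)
  ve <- callVGenes(genome, refs$v, refs$leader, hits = imported)
  expect_equal(length(ve), length(vi))
  expect_equal(vapply(ve, function(r) r$range[1L], integer(1L)),
               vapply(vi, function(r) r$range[1L], integer(1L)))
  expect_equal(vapply(ve, function(r) r$range[2L], integer(1L)),
               vapply(vi, function(r) r$range[2L], integer(1L)))
})
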