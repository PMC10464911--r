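test_that("a planted exact RS is found with zero mismatches", {
  set.seed(21)
  s <- paste0(randomDNA(49), "CACAGTG", randomDNA(23), "ACAAAAACC",
              randomDNA(112))
  hits <- scanRS(s, 23L)
  plus <- hits[as.character(BiocGenerics::strand(hits)) == "+" &
                 hits$score == 0]
  expect_true(any(plus$heptamer_start == 50 & plus$spacer_length == 23))
  ## minimal spacer-length invariant
  expect_true(all(abs(hits$spacer_length - 23L) <= 1L))
  expect_error(scanRS(s, 15L), "12 or 23")
  expect_error(scanRS("ACGT", 23L), "shorter")
})

test_that("scanRS equals the brute-force oracle on random kilobase sequences", {
  set.seed(99)
  for (k in 1:20) {
    s <- randomDNA(1000)
    ## plant a few motifs with 0-2 heptamer mismatches
    for (p in sample(seq(10, 900, by = 120), 3)) {
      hept <- mutateString("CACAGTG", if (k %% 3 == 0) 6:7 else integer(0))
      s <- paste0(substr(s, 1, p - 1), hept, randomDNA(23), "ACAAAAACC",
                  substr(s, p + 39, 1000))
      s <- substr(s, 1, 1000)
    }
    got <- scanRS(s, 23L)
    want <- oracleScanRS(s, 23L)
    expect_identical(rsGRangesKey(got), rsHitKey(want))
  }
})

test_that("scanRS is strand-symmetric and monotone in its tolerances", {
  set.seed(33)
  s <- paste0(randomDNA(30), "CACAGTG", randomDNA(12), "ACAAAAACC",
              randomDNA(200), "GGTTTTTGT", randomDNA(12), "CACTGTG",
              randomDNA(40))
  h <- scanRS(s, 12L)
  hRC <- scanRS(revcomp(s), 12L)
  ## mirror: a + hit at heptamer_start p maps to a - hit in the revcomp
  L <- nchar(s)
  keys <- sort(paste(ifelse(as.character(BiocGenerics::strand(h)) == "+",
                            "-", "+"),
                     L - h$heptamer_end + 1L, h$spacer_length))
  keysRC <- sort(paste(as.character(BiocGenerics::strand(hRC)),
                       hRC$heptamer_start, hRC$spacer_length))
  expect_identical(keys, keysRC)

  loose <- scanRS(s, 12L, maxHeptamerMM = 2L)
  tight <- scanRS(s, 12L, maxHeptamerMM = 1L)
  keyOf <- function(x) paste(BiocGenerics::strand(x), x$heptamer_start,
                             x$spacer_length)
  expect_true(all(keyOf(tight) %in% keyOf(loose)))
  slack0 <- scanRS(s, 12L, spacerSlack = 0L)
  slack1 <- scanRS(s, 12L, spacerSlack = 1L)
  expect_true(all(keyOf(slack0) %in% keyOf(slack1)))
})

test_that("12/23 pairing forms D units and resolves competition", {
  ## D-unit geometry on the + gene strand: 12-RS (minus scan hit) then a
  ## 12-base D region then 23-RS (plus scan hit)
  set.seed(7)
  dUnit <- paste0("GGTTTTTGT", randomDNA(12), "CACTGTG", "GGGACAGGGGGC",
                  "CACAGTG", randomDNA(23), "ACAAAAACC")
  s <- paste0(randomDNA(60), dUnit, randomDNA(60))
  h12 <- scanRS(s, 12L); h23 <- scanRS(s, 23L)
  pairs <- pairRS1223(h12, h23)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$gap, 12L)
  expect_equal(pairs$gene_strand, "+")
  dseq <- substr(s, pairs$d_start, pairs$d_end)
  expect_equal(dseq, "GGGACAGGGGGC")

  ## empty input -> empty output
  expect_equal(nrow(pairRS1223(h12[0], h23)), 0L)

  ## two 23-hits competing for one 12-hit (overlapping candidates): the
  ## pair with the lower combined mismatch count wins even at a wider gap
  fill <- function(n) strrep("T", n)
  hept1 <- "CACATTG"                        # 1 heptamer mismatch
  A <- paste0(hept1, fill(6), "CACAGTG", fill(10), "ACAAAAACC", fill(4),
              "ACAAAAACC")
  s2 <- paste0(fill(20), "GGTTTTTGT", "GCATGCATGCAT", "CACTGTG",
               "GGGACAGGGGGC", A, fill(20))
  h12b <- scanRS(s2, 12L); h23b <- scanRS(s2, 23L)
  pb <- pairRS1223(h12b, h23b)
  expect_equal(nrow(pb), 1L)
  expect_equal(pb$gap, 25L)   # exact-motif pair beats the nearer mismatched one
  expect_equal(pb$score, 0L)

  ## inconsistent implied gene strands do not pair: both motifs read on the
  ## plus strand imply a minus-strand gene for the 12 and a plus-strand
  ## gene for the 23 only when in the D-unit layout; a 12-RS in V-RS
  ## orientation (plus scan) cannot pair with a plus-scan 23-RS
  s3 <- paste0(randomDNA(20), "CACAGTG", randomDNA(12), "ACAAAAACC",
               randomDNA(12), "CACAGTG", randomDNA(23), "ACAAAAACC",
               randomDNA(20))
  h12c <- scanRS(s3, 12L)
  h12c <- h12c[as.character(BiocGenerics::strand(h12c)) == "+"]
  h23c <- scanRS(s3, 23L)
  h23c <- h23c[as.character(BiocGenerics::strand(h23c)) == "+"]
  expect_equal(nrow(pairRS1223(h12c, h23c)), 0L)
})

test_that("splice scanning ranks canonical donors and acceptors first", {
  set.seed(13)
  exon <- randomDNA(40)
  s <- paste0(exon, "GTAAGT", randomDNA(60))
  d <- scanSplice(s, "donor")
  expect_equal(d$pos[1L], 41L)
  expect_equal(d$motif[1L], "GTAAGT")
  expect_equal(d$score[1L], 6)

  expect_equal(nrow(scanSplice("AAAACAAAC", "donor")), 0L)

  ## full-hexamer hits outrank bare GT, and the hit set matches a regex scan
  s2 <- paste0(randomDNA(50), "GTAAGT", randomDNA(50), "GTAAGT",
               randomDNA(50), "GTCCAA", randomDNA(50))
  d2 <- scanSplice(s2, "donor")
  gtPos <- which(vapply(seq_len(nchar(s2) - 1L), function(p)
    substr(s2, p, p + 1L) == "GT", logical(1L)))
  expect_setequal(d2$pos, gtPos)
  nFull <- sum(d2$motif == "GTAAGT")
  expect_true(all(d2$score[seq_len(nFull)] == 6))

  ## acceptors need AG after a pyrimidine-rich tract
  a <- scanSplice(paste0(randomDNA(10), "TTTCTCTC", "AG", randomDNA(10)),
                  "acceptor")
  expect_true(nrow(a) >= 1L)
  expect_equal(a$motif[1L], "AG")
  noTract <- scanSplice(paste0(strrep("A", 12), "AG", strrep("A", 6)),
                        "acceptor")
  expect_equal(nrow(noTract), 0L)
})
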