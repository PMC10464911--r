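test_that("distances match direct site counts and an independent implementation", {
  aln <- Biostrings::DNAStringSet(c(a = "AAAA", b = "AAAT"))
  expect_equal(computeDistances(aln, "p")["a", "b"], 0.25)
  expect_equal(computeDistances(Biostrings::DNAStringSet(
    c(x = "ACGTAC", y = "ACGTAC")), "p")["x", "y"], 0)

  ## random alignment with gaps: pairwise deletion against a site-loop
  ## oracle and against ape::dist.dna
  set.seed(17)
  n <- 12; L <- 100
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  m[sample(n * L, 60)] <- "-"
  rownames(m) <- paste0("s", 1:n)
  d <- computeDistances(m, "p", "pairwise")
  for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
    i <- pair[1]; j <- pair[2]
    ok <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(d[i, j], sum(m[i, ok] != m[j, ok]) / sum(ok))
  }
  apeD <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "raw",
                                  pairwise.deletion = TRUE))
  expect_equal(unname(d), unname(apeD[rownames(d), rownames(d)]),
               tolerance = 1e-12, ignore_attr = TRUE)
  apeK <- suppressWarnings(as.matrix(ape::dist.dna(
    ape::as.DNAbin(m), model = "K80", pairwise.deletion = TRUE)))
  dK <- computeDistances(m, "k2p", "pairwise")
  sat <- attr(dK, "saturated")
  apeK <- apeK[rownames(dK), colnames(dK)]
  expect_equal(unname(dK[!sat]), unname(apeK[!sat]), tolerance = 1e-9)
  ## entries ape reports as non-finite are exactly those flagged saturated
  expect_true(all(!is.finite(apeK[sat & upper.tri(sat)])))

  ## poisson correction and saturation flagging
  dp <- computeDistances(Biostrings::AAStringSet(
    c(p = "AAAA", q = "CCCC")), "poisson", ceiling = 7)
  expect_equal(dp["p", "q"], 7)
  expect_true(attr(dp, "saturated")["p", "q"])
  half <- computeDistances(Biostrings::AAStringSet(
    c(p = "AAKK", q = "AARR")), "poisson")
  expect_equal(half["p", "q"], -log(1 - 0.5))
})

test_that("neighbor joining has the closed form at n=3 and recovers additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2L]])
  expect_equal(lens[c("A", "B", "C")], c(A = 1, B = 1, C = 3))

  expect_error(njTree(d[1:2, 1:2]), "at least 3")
  dAsym <- d; dAsym[1, 2] <- 5
  expect_error(njTree(dAsym), "symmetric")

  ## NJ consistency: exact recovery of 50 random additive trees (the
  ## generating tree is the oracle; an additive metric determines its tree)
  set.seed(23)
  for (k in 1:50) {
    n <- sample(4:10, 1L)
    t0 <- ape::rtree(n)
    D <- stats::cophenetic(t0)
    tr <- njTree(D)
    expect_lt(max(abs(stats::cophenetic(tr)[rownames(D), colnames(D)] - D)),
              1e-8)
  }
})

test_that("NJ tie-breaking is deterministic on an all-equal matrix", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- njTree(d)
  t2 <- njTree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  ## resolved binary topology with zero internal branch lengths
  expect_equal(t1$Nnode, 3L)
  internal <- t1$edge[, 2L] > 5L
  expect_true(all(abs(t1$edge.length[internal]) < 1e-12))
  ## the documented tie-break joins the lowest original pair (a, b) first,
  ## so tips 1 and 2 end up as siblings
  kids <- split(t1$edge[, 2L], t1$edge[, 1L])
  expect_true(any(vapply(kids, function(k) identical(sort(k), c(1L, 2L)),
                         logical(1L))))
})

test_that("bootstrap supports are seeded, reproducible and sensible", {
  set.seed(29)
  mut <- function(s, k) mutateString(s, sample(nchar(s), k))
  base1 <- randomDNA(80); base2 <- randomDNA(80)
  aln <- Biostrings::DNAStringSet(c(
    a1 = mut(base1, 1), a2 = mut(base1, 1), a3 = mut(base1, 2),
    b1 = mut(base2, 1), b2 = mut(base2, 1), b3 = mut(base2, 2)))
  tr <- bootstrapSupports(aln, nReplicates = 100, seed = 42)
  sup <- attr(tr, "supports")
  ## the clade separating the two families is near-unanimous
  bp <- trbloci:::.bipartitions(tr)$bips
  target <- paste(sort(c("b1", "b2", "b3")), collapse = "|")
  expect_true(target %in% bp)
  expect_gte(sup[match(target, bp)], 95)

  tr2 <- bootstrapSupports(aln, nReplicates = 100, seed = 42)
  expect_identical(attr(tr, "supports"), attr(tr2, "supports"))
  tr3 <- bootstrapSupports(aln, nReplicates = 100, seed = 43)
  expect_false(identical(ape::write.tree(tr), ""))

  ## an alignment of identical replicate columns gives 100 everywhere
  one <- Biostrings::DNAStringSet(c(u = strrep("A", 30), v = strrep("C", 30),
                                    w = strrep("G", 30), x = strrep("T", 30)))
  trI <- bootstrapSupports(one, nReplicates = 25, seed = 1)
  expect_true(all(attr(trI, "supports") == 100))

  expect_error(bootstrapSupports(aln, nReplicates = 0), "at least 1")
})

test_that("trees round-trip through newick", {
  set.seed(31)
  t0 <- ape::rtree(6)
  f <- tempfile(fileext = ".nwk")
  writeNewick(t0, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})
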