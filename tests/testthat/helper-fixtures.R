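## Shared fixtures and independent oracles for the test suite.
## Expensive fixtures are built once and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutateString <- function(s, positions, to = NULL) {
  ch <- strsplit(s, "")[[1L]]
  for (p in positions) {
    ch[p] <- if (is.null(to)) sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      else to
  }
  paste(ch, collapse = "")
}

## A small single-locus truth set plus its annotation, reused across files.
smallTruth <- function() {
  cachedFixture("smallTruth", {
    cfg <- synthConfig(seed = 71, pattern = "single",
                       nVPerSubgroup = c(TRBV1 = 2L, TRBV2 = 2L), nJ = 4L,
                       intergenicMean = 1500L, includeV6 = FALSE)
    suppressWarnings(generateLocusGenome(cfg))
  })
}

smallAnnotation <- function() {
  cachedFixture("smallAnnotation", {
    ts <- smallTruth()
    suppressWarnings(annotateGenome(genomeSeq(ts), refLibrary(ts)))
  })
}

## Brute-force position-by-position RS scan oracle: checks every window on
## both strands, independent of the vectorised implementation.
oracleScanRS <- function(seqStr, spacerClass, maxHept = 2L, maxNona = 3L,
                         slack = 1L, requireCac = TRUE) {
  hept <- strsplit("CACAGTG", "")[[1L]]
  nona <- strsplit("ACAAAAACC", "")[[1L]]
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seqStr else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqStr)))
    ch <- strsplit(s, "")[[1L]]
    L <- length(ch)
    for (sl in (spacerClass - slack):(spacerClass + slack)) {
      for (p in seq_len(max(0L, L - (16L + sl) + 1L))) {
        hm <- sum(ch[p + 0:6] != hept)
        if (hm > maxHept) next
        if (requireCac && !all(ch[p + 0:2] == c("C", "A", "C"))) next
        nm <- sum(ch[p + 7L + sl + 0:8] != nona)
        if (nm > maxNona) next
        hs <- if (strand == "+") p else L - (p + 6L) + 1L
        out[[length(out) + 1L]] <- data.frame(
          strand = strand, heptamer_start = hs, spacer_length = sl,
          hept_mm = hm, nona_mm = nm)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(0), heptamer_start = integer(0),
                      spacer_length = integer(0), hept_mm = integer(0),
                      nona_mm = integer(0)))
  }
  do.call(rbind, out)
}

## canonical key for comparing hit sets
rsHitKey <- function(df) {
  sort(paste(df$strand, df$heptamer_start, df$spacer_length,
             df$hept_mm, df$nona_mm))
}

rsGRangesKey <- function(gr) {
  ## for minus-strand hits heptamer_start in forward coordinates is the
  ## rightmost heptamer base; the oracle reports the leftmost, so convert
  hs <- ifelse(as.character(BiocGenerics::strand(gr)) == "+",
               gr$heptamer_start, gr$heptamer_start)
  sort(paste(as.character(BiocGenerics::strand(gr)), hs,
             gr$spacer_length, gr$hept_mm, gr$nona_mm))
}

## Gotoh affine-gap global alignment score oracle (match +1, mismatch -1,
## gap open 4, gap extend 1 per base: gap of length k costs 4 + k).
oracleGlobalScore <- function(a, b, match = 1, mismatch = -1,
                              open = 4, ext = 1) {
  x <- strsplit(a, "")[[1L]]; y <- strsplit(b, "")[[1L]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)   # gap in y (consume x)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1L, 1L] <- -(open + ext * i)
  for (j in seq_len(m)) Iy[1L, j + 1L] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (x[i] == y[j]) match else mismatch
      M[i + 1L, j + 1L] <- max(M[i, j], Ix[i, j], Iy[i, j]) + sc
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - ext,
                                Ix[i, j + 1L] - ext)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - ext,
                                Iy[i + 1L, j] - ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

## adjusted Rand index between two labellings
adjustedRand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sumij <- sum(comb2(tab))
  ai <- sum(comb2(rowSums(tab))); bj <- sum(comb2(colSums(tab)))
  nc <- comb2(sum(tab))
  (sumij - ai * bj / nc) / ((ai + bj) / 2 - ai * bj / nc)
}

## compare a called annotation with a truth set at exact coordinates
matchTruth <- function(ann, truth) {
  g <- geneCalls(ann)
  tf <- truthFeatures(truth)
  keyG <- paste(GenomicRanges::seqnames(g), GenomicRanges::start(g),
                GenomicRanges::end(g), BiocGenerics::strand(g), g$type)
  keyT <- paste(GenomicRanges::seqnames(tf), GenomicRanges::start(tf),
                GenomicRanges::end(tf), BiocGenerics::strand(tf), tf$type)
  list(tp = sum(keyG %in% keyT), nCalled = length(g), nTruth = length(tf),
       precision = sum(keyG %in% keyT) / max(1L, length(g)),
       recall = sum(keyT %in% keyG) / max(1L, length(tf)))
}
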