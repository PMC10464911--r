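## Internal alignment utilities: ungapped (Hamming) placements and
## spliced placement of a reference coding sequence onto genomic sequence.

## Mismatch count of `refStr` placed at every position of `subjectStr`
## given in `starts` (byte comparison; assumes uppercase A/C/G/T/N).
.hammingAt <- function(refStr, subjectStr, starts) {
  refRaw <- charToRaw(refStr)
  subRaw <- charToRaw(subjectStr)
  nr <- length(refRaw)
  ok <- starts >= 1L & starts + nr - 1L <= length(subRaw)
  out <- rep.int(NA_integer_, length(starts))
  if (!any(ok)) return(out)
  st <- starts[ok]
  idx <- outer(st - 1L, seq_len(nr), `+`)
  m <- matrix(subRaw[idx], nrow = length(st))
  cmp <- m != matrix(refRaw, nrow = length(st), ncol = nr, byrow = TRUE)
  out[ok] <- as.integer(rowSums(cmp))
  out
}

## Best ungapped placement of refStr within subjectStr; returns list(start,
## mismatches) or NULL.
.bestHamming <- function(refStr, subjectStr) {
  n <- nchar(subjectStr) - nchar(refStr) + 1L
  if (n < 1L) return(NULL)
  mm <- .hammingAt(refStr, subjectStr, seq_len(n))
  i <- which.min(mm)
  list(start = i, mismatches = mm[i])
}

## Walk a reference coding sequence along genomic sequence from an anchored
## start, detecting intron interruptions by a jump in local mismatch
## density and resolving each junction with donor (GT) / acceptor (AG)
## signals under the constraint that exon lengths sum to the reference
## length. Substitution-only divergence is assumed (no indels), which keeps
## recovered boundaries exact on such data.
##
## ref, subject: character strings (gene-strand orientation).
## startPos: subject position aligned to ref[1].
## Returns list(exons = list of c(start, end) in subject coordinates,
##              introns, mismatches, complete, consumedRef).
.walkSpliced <- function(ref, subject, startPos, allowIntrons = TRUE,
                         maxIntrons = 3L, minIntron = 40L, maxIntron = 400L,
                         juncBack = 20L, juncFwd = 12L,
                         checkWin = 20L, checkThresh = 12L,
                         lookahead = 40L, minLookMatch = 0.75) {
  refc <- charToRaw(ref)
  subc <- charToRaw(subject)
  nr <- length(refc); ns <- length(subc)
  exons <- list(); introns <- list()
  curRef <- 1L; g <- startPos; mmTotal <- 0L; nIntrons <- 0L
  repeat {
    remaining <- nr - curRef + 1L
    avail <- ns - g + 1L
    n <- min(remaining, avail)
    if (n <= 0L) break
    mism <- refc[curRef + 0:(n - 1L)] != subc[g + 0:(n - 1L)]
    jz <- NA_integer_
    if (allowIntrons && nIntrons < maxIntrons && n >= checkWin) {
      cs <- cumsum(as.integer(mism))
      roll <- cs[checkWin:n] - c(0L, cs)[1:(n - checkWin + 1L)]
      hit <- which(roll >= checkThresh)
      if (length(hit)) jz <- hit[1L]          # ref-relative offset in exon
    }
    if (is.na(jz)) {
      exons[[length(exons) + 1L]] <- c(g, g + n - 1L)
      mmTotal <- mmTotal + sum(mism)
      curRef <- curRef + n
      break
    }
    ## search the junction: cut c = exon piece length consumed here
    cLo <- max(1L, jz - juncBack); cHi <- min(n - 1L, jz + juncFwd)
    best <- NULL
    for (cc in cLo:cHi) {
      dp <- g + cc                             # first intron base
      if (dp + 1L > ns) next
      if (subc[dp] != charToRaw("G") || subc[dp + 1L] != charToRaw("T")) next
      donorBonus <- if (dp + 5L <= ns &&
                        rawToChar(subc[dp + 0:5]) == "GTAAGT") 2 else 0
      aLo <- dp + minIntron - 1L; aHi <- min(ns - 1L, dp + maxIntron)
      if (aLo > aHi) next
      aCand <- which(subc[aLo:aHi] == charToRaw("G")) + aLo - 1L
      aCand <- aCand[aCand > dp + 1L & subc[aCand - 1L] == charToRaw("A")]
      for (a in aCand) {
        L2 <- min(lookahead, nr - (curRef + cc) + 1L, ns - a)
        if (L2 < 10L) next
        sc <- sum(refc[curRef + cc + 0:(L2 - 1L)] == subc[a + 1L + 0:(L2 - 1L)])
        if (sc < minLookMatch * L2) next
        val <- sc + donorBonus
        if (is.null(best) || val > best$val ||
            (val == best$val && cc < best$cc)) {
          best <- list(cc = cc, a = a, val = val)
        }
      }
    }
    if (is.null(best)) {                       # no credible junction: consume
      exons[[length(exons) + 1L]] <- c(g, g + n - 1L)
      mmTotal <- mmTotal + sum(mism)
      curRef <- curRef + n
      break
    }
    exons[[length(exons) + 1L]] <- c(g, g + best$cc - 1L)
    introns[[length(introns) + 1L]] <- c(g + best$cc, best$a)
    mmTotal <- mmTotal + sum(mism[seq_len(best$cc)])
    curRef <- curRef + best$cc
    g <- best$a + 1L
    nIntrons <- nIntrons + 1L
  }
  list(exons = exons, introns = introns, mismatches = mmTotal,
       consumedRef = curRef - 1L, complete = curRef - 1L == nr)
}
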