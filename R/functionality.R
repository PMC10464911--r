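## IMGT-style numbering transfer and F/ORF/P functionality classification.

#' Map a V-domain protein onto reference numbering
#'
#' Globally aligns the query V-domain protein to a numbered reference
#' profile (affine gaps) and transfers position numbers through aligned
#' columns. Anchor residues (1st-CYS 23, CONSERVED-TRP 41, 2nd-CYS 104)
#' are read off the transferred numbering.
#'
#' @param protein Query amino-acid string.
#' @param profile Reference profile amino-acid string (an \code{AAString},
#'   \code{AAStringSet} element or character) with known numbering.
#' @param profilePositions Integer vector, one per profile residue, giving
#'   its position number (default: 1..nchar(profile)).
#' @param anchors Named integer vector of anchor positions
#'   (default 23, 41, 104).
#' @param minIdentity Alignment identity (percent) below which numbering is
#'   refused with an error.
#' @return A list: \code{map} (integer vector over profile positions giving
#'   the 1-based query residue index, NA at gaps), \code{anchors} (named
#'   character of anchor residues, NA where gapped), \code{identity}.
#' @export
numberVDomain <- function(protein, profile,
                          profilePositions = NULL,
                          anchors = c(`23` = 23L, `41` = 41L, `104` = 104L),
                          minIdentity = 30) {
  q <- as.character(protein); p <- as.character(profile)
  if (!nchar(q) || !nchar(p)) stop("empty protein or profile")
  if (is.null(profilePositions)) profilePositions <- seq_len(nchar(p))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(p), type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  ident <- 100 * sum(qa == pa & qa != "-") / length(qa)
  if (ident < minIdentity)
    stop("unalignable: identity ", round(ident, 1),
         "% below threshold ", minIdentity, "%")
  qi <- 0L; pi <- 0L
  map <- rep(NA_integer_, nchar(p))
  for (k in seq_along(qa)) {
    if (qa[k] != "-") qi <- qi + 1L
    if (pa[k] != "-") {
      pi <- pi + 1L
      if (qa[k] != "-") map[pi] <- qi
    }
  }
  names(map) <- as.character(profilePositions)
  qc <- strsplit(q, "")[[1L]]
  anch <- vapply(anchors, function(a) {
    i <- map[match(a, profilePositions)]
    if (is.na(i)) NA_character_ else qc[i]
  }, character(1L))
  names(anch) <- names(anchors)
  list(map = map, anchors = anch, identity = ident)
}

#' Classify a gene call as F, ORF or P
#'
#' Applies the germline functionality criteria: a gene is functional (F)
#' when the coding region has an open reading frame, no defect in splice
#' sites or RS, and carries the key conserved amino acids; an open reading
#' frame (ORF) when the frame is intact but splice sites or RS are
#' defective, or conserved residues are changed; a pseudogene (P) on stop
#' codons, frameshifts, or a missing RS. Reason codes: \code{stop_codon},
#' \code{frameshift}, \code{missing_rs}, \code{defective_rs},
#' \code{defective_splice}, \code{anchor_change}, \code{contains_N}.
#' Genes whose coding span contains N cannot be certified functional and
#' are reported as ORF with reason \code{contains_N}.
#'
#' @param rec A gene record from the callers.
#' @param config See \code{\link{trbConfig}}.
#' @param profiles Optional named \code{AAStringSet} of V-domain numbering
#'   profiles (one per subgroup reference, names matching the similarity
#'   references).
#' @param profileAnchors Anchor positions in the profiles (default
#'   23/41/104).
#' @return A list: \code{label} (\code{"F"}, \code{"ORF"} or \code{"P"}) and
#'   \code{reasons} (character vector of codes, empty for a clean F).
#' @export
classifyFunctionality <- function(rec, config = trbConfig(), profiles = NULL,
                                  profileAnchors = c(`23` = 23L, `41` = 41L,
                                                     `104` = 104L)) {
  reasons <- character(0)
  type <- rec$type
  prot <- rec$protein
  hasStop <- function(aa) grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE) ||
    (type != "C" && endsWith(aa, "*"))

  if (type == "V") {
    if (!is.null(rec$evidence$coding) &&
        grepl("N", rec$evidence$coding, fixed = TRUE))
      reasons <- c(reasons, "contains_N")
    if (hasStop(prot)) reasons <- c(reasons, "stop_codon")
    ## frameshift: coding length off-frame, or the V-EXON placement needs a
    ## non-multiple-of-3 indel against the reference
    codingLen <- nchar(rec$evidence$coding)
    frameOff <- codingLen %% 3L != 0L
    indelOff <- FALSE
    if (!is.null(rec$evidence$vexonSpliced) && !is.null(rec$evidence$ref)) {
      obs <- nchar(rec$evidence$vexonSpliced)
      expct <- rec$evidence$refLen
      if (obs != expct && (obs - expct) %% 3L != 0L) indelOff <- TRUE
    }
    if (frameOff || indelOff) reasons <- c(reasons, "frameshift")
    ## RS status
    if (!length(rec$rs)) {
      reasons <- c(reasons, "missing_rs")
    } else if (isTRUE(rec$rs[[1L]]$relaxed)) {
      reasons <- c(reasons, "defective_rs")
    }
    ## splice status
    if ("leader_not_found" %in% rec$flags) {
      reasons <- c(reasons, "defective_splice")
    } else {
      if (substr(rec$evidence$donorMotif, 1L, 2L) != "GT")
        reasons <- c(reasons, "defective_splice")
      if (rec$evidence$acceptorMotif != "AG")
        reasons <- c(reasons, "defective_splice")
    }
    ## anchors via numbering transfer
    if (!is.null(profiles) && !("stop_codon" %in% reasons)) {
      ## V-domain protein: spliced V-EXON minus L-PART2
      vdom <- translateDNA(substr(rec$evidence$vexonSpliced,
                                  config$lPart2Len + 1L,
                                  nchar(rec$evidence$vexonSpliced)))
      prof <- if (rec$evidence$ref %in% names(profiles))
        profiles[[rec$evidence$ref]] else profiles[[1L]]
      nm <- tryCatch(
        numberVDomain(vdom, prof, anchors = profileAnchors,
                      minIdentity = config$numberingMinIdentity),
        error = function(e) NULL)
      if (!is.null(nm)) {
        want <- c(`23` = "C", `41` = "W", `104` = "C")
        got <- nm$anchors[names(want)]
        if (any(is.na(got) | got != want))
          reasons <- c(reasons, "anchor_change")
      }
    }
  } else if (type == "J") {
    if (hasStop(prot)) reasons <- c(reasons, "stop_codon")
    if (!length(rec$rs)) reasons <- c(reasons, "missing_rs")
    else if (isTRUE(rec$rs[[1L]]$relaxed)) reasons <- c(reasons, "defective_rs")
    if ("defective_donor" %in% rec$flags)
      reasons <- c(reasons, "defective_splice")
    if (is.na(rec$evidence$fgxgPos)) reasons <- c(reasons, "anchor_change")
  } else if (type == "D") {
    if ("no_open_frame" %in% rec$flags) reasons <- c(reasons, "stop_codon")
    cls <- vapply(rec$rs, `[[`, integer(1L), "class")
    if (!(12L %in% cls) || !(23L %in% cls))
      reasons <- c(reasons, "missing_rs")
    else if (any(vapply(rec$rs, function(r) isTRUE(r$relaxed), logical(1L))))
      reasons <- c(reasons, "defective_rs")
  } else if (type == "C") {
    if (hasStop(prot)) reasons <- c(reasons, "stop_codon")
    if ("incomplete_exon_structure" %in% rec$flags)
      reasons <- c(reasons, "defective_splice")
    if (length(rec$evidence$donors) &&
        any(substr(rec$evidence$donors, 1L, 2L) != "GT"))
      reasons <- c(reasons, "defective_splice")
    if (length(rec$evidence$acceptors) && any(rec$evidence$acceptors != "AG"))
      reasons <- c(reasons, "defective_splice")
    cons <- rec$evidence$conserved
    if (!is.null(cons)) {
      bad <- is.na(cons["23"]) || cons[["23"]] != "C" ||
        is.na(cons["41"]) || cons[["41"]] != "W" ||
        is.na(cons["104"]) || cons[["104"]] != "C" ||
        is.na(cons["89"]) || !(cons[["89"]] %in% config$hydrophobic89)
      if (bad) reasons <- c(reasons, "anchor_change")
    }
    if ("contains_N" %in% rec$flags) reasons <- c(reasons, "contains_N")
  }

  reasons <- unique(reasons)
  pReasons <- c("stop_codon", "frameshift", "missing_rs")
  orfReasons <- c("defective_rs", "defective_splice", "anchor_change",
                  "contains_N")
  label <- if (any(reasons %in% pReasons)) "P"
  else if (any(reasons %in% orfReasons)) "ORF"
  else "F"
  list(label = label, reasons = reasons)
}
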