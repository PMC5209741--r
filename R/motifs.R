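#' The three conserved angiosperm 5.8S motifs
#'
#' M1 (16 nt), M2 (14 nt) and M3 (10 nt) are short sequence blocks that are
#' essentially invariant across functional angiosperm 5.8S genes; lesions in
#' them are a primary pseudogene diagnostic.
#'
#' @return Named character vector c(M1 = ..., M2 = ..., M3 = ...).
#' @export
motifDefs <- function() {
  c(M1 = "CGATGAAGAACGTAGC",
    M2 = "GAATTGCAGAATCC",
    M3 = "TTTGAACGCA")
}

# Global alignment of a clone 5.8S against the reference 5.8S; returns, for
# every reference position, the aligned clone base (NA where the clone has a
# gap) and its 1-based position on the clone, plus percent identity.
.mapToRef <- function(s58, ref58) {
  s58 <- .degap(toupper(s58))
  nref <- nchar(ref58)
  if (nchar(s58) == 0L)
    return(list(charAt = rep(NA_character_, nref),
                posAt = rep(NA_integer_, nref), pid = 0))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref58), Biostrings::DNAString(s58),
    type = "global", substitutionMatrix = .subMat(),
    gapOpening = 4, gapExtension = 1)
  p <- .chars(Biostrings::alignedPattern(pa))
  s <- .chars(Biostrings::alignedSubject(pa))
  charAt <- rep(NA_character_, nref)
  posAt <- rep(NA_integer_, nref)
  ri <- 0L; si <- 0L
  for (t in seq_along(p)) {
    if (p[t] != "-") ri <- ri + 1L
    if (s[t] != "-") si <- si + 1L
    if (p[t] != "-" && s[t] != "-") {
      charAt[ri] <- s[t]
      posAt[ri] <- si
    }
  }
  list(charAt = charAt, posAt = posAt, pid = Biostrings::pid(pa))
}

# Expected motif start offsets on the reference 5.8S (exact matches by the
# ReferenceSet invariant).
.motifOffsets <- function(refs) {
  vapply(motifDefs(), function(m) {
    BiocGenerics::start(Biostrings::matchPattern(
      m, Biostrings::DNAString(refs@ref58)))[1L]
  }, integer(1))
}

#' Scan a clone 5.8S for one conserved motif
#'
#' If the exact motif occurs anywhere in the clone 5.8S it is conserved,
#' irrespective of flanking context.  Otherwise the motif window is the
#' alignment image (clone vs reference 5.8S) of the motif's span on the
#' reference: substituted positions are reported 1-based within the motif
#' ("nt-" notation); positions falling on clone gaps (deletions/truncations)
#' are missing, yielding status \code{partially_missing} (with the missing
#' range) or \code{all_missing}.  Ambiguity codes count as mismatches.
#'
#' @param s58Seq The delimited clone 5.8S sequence (character; gaps stripped).
#' @param motif Motif name ("M1", "M2", "M3") or an explicit sequence found in
#'   \code{motifDefs()}.
#' @param refs A \code{\link{ReferenceSet}}.
#' @param map Optional precomputed result of the internal reference alignment
#'   (shared across the three motifs by \code{\link{scanMotifs}}).
#' @return A list (class \code{MotifReport}): name, status (one of conserved /
#'   changed / partially_missing / all_missing), changePositions,
#'   missingRange, label (the printed form, e.g. "nt-7,12").
#' @examples
#' unit <- makeReferenceUnit(seed = 1)
#' scanMotif(unit$refs@ref58, "M1", unit$refs)$status
#' @export
scanMotif <- function(s58Seq, motif, refs, map = NULL) {
  defs <- motifDefs()
  if (motif %in% names(defs)) {
    name <- motif
  } else {
    name <- names(defs)[match(toupper(motif), defs)]
    if (is.na(name)) stop("unknown motif: ", motif)
  }
  mseq <- .chars(defs[[name]])
  mlen <- length(mseq)
  s58Seq <- .degap(toupper(as.character(s58Seq)))

  report <- function(status, changes = integer(0), missing = NULL) {
    label <- switch(status,
      conserved = "conserved",
      changed = paste0("nt-", paste(changes, collapse = ",")),
      partially_missing = paste0("missing ", missing[1L], "-", missing[2L]),
      all_missing = "all missing")
    structure(list(name = name, status = status,
                   changePositions = changes, missingRange = missing,
                   label = label),
              class = "MotifReport")
  }

  if (nchar(s58Seq) >= mlen &&
      length(Biostrings::matchPattern(defs[[name]],
                                      Biostrings::DNAString(s58Seq))) > 0L)
    return(report("conserved"))

  if (is.null(map)) map <- .mapToRef(s58Seq, refs@ref58)
  off <- .motifOffsets(refs)[[name]]
  cc <- map$charAt[off:(off + mlen - 1L)]
  missing <- which(is.na(cc))
  changes <- which(!is.na(cc) & cc != mseq)
  if (length(missing) == mlen) return(report("all_missing"))
  if (length(missing) > 0L)
    return(report("partially_missing", changes,
                  c(min(missing), max(missing))))
  if (length(changes) > 0L) return(report("changed", changes))
  report("conserved")
}

#' Scan all three conserved motifs at once
#'
#' @inheritParams scanMotif
#' @return Named list of three \code{MotifReport}s (M1, M2, M3).
#' @export
scanMotifs <- function(s58Seq, refs, map = NULL) {
  if (is.null(map)) map <- .mapToRef(s58Seq, refs@ref58)
  stats::setNames(lapply(names(motifDefs()), scanMotif, s58Seq = s58Seq,
                         refs = refs, map = map), names(motifDefs()))
}

#' @export
print.MotifReport <- function(x, ...) {
  cat(x$name, ":", x$label, "\n")
  invisible(x)
}
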