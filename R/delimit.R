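#' Delimit ITS1 / 5.8S / ITS2 on each clone by anchor alignment
#'
#' Region boundaries are placed the way they are placed in practice with
#' published reference sequences: the reference 5.8S, a trailing 18S fragment,
#' and a leading 26S fragment are each locally aligned to the clone
#' (match +1, mismatch -1, gap -2).  The 5.8S interval is the aligned span of
#' the reference 5.8S on the clone; ITS1 is everything between the 18S-tail
#' end and the 5.8S start; ITS2 between the 5.8S end and the 26S-head start.
#' When a flank anchor is absent (below the acceptance thresholds or on the
#' wrong side of the 5.8S span), the corresponding region is extended to the
#' sequence end and a truncation flag is set.
#'
#' The 5.8S anchor must align at \code{idFloor} percent identity or better
#' over its aligned span (default 50, permissive enough for pseudogenes
#' carrying 5.8S deletions) and contribute at least \code{minAnchorMatch}
#' matching bases, so that a short spurious local hit cannot delimit a
#' sequence; otherwise the clone cannot be delimited and an error is
#' raised.
#'
#' @param x An \code{\link{ItsCloneSet}} (ungapped sequences) or a single
#'   character sequence.
#' @param refs A \code{\link{ReferenceSet}}.
#' @param idFloor Minimum percent identity for the 5.8S anchor alignment.
#' @param minAnchorMatch Minimum number of matching bases in the 5.8S
#'   anchor alignment (default 25).
#' @return For an \code{ItsCloneSet}: the set with its partition slot filled.
#'   For a single sequence: a one-row partition data.frame.
#' @examples
#' unit <- makeReferenceUnit(seed = 1)
#' x <- ItsCloneSet(c("S1-1" = unit$unit))
#' partitions(delimitRegions(x, unit$refs))
#' @export
delimitRegions <- function(x, refs, idFloor = 50, minAnchorMatch = 25) {
  stopifnot(methods::is(refs, "ReferenceSet"))
  if (methods::is(x, "ItsCloneSet")) {
    rows <- lapply(as.character(x@seqs), .delimitOne, refs = refs,
                   idFloor = idFloor, minAnchorMatch = minAnchorMatch)
    part <- do.call(rbind, rows)
    rownames(part) <- NULL
    x@partition <- part
    methods::validObject(x)
    return(x)
  }
  .delimitOne(as.character(x), refs, idFloor, minAnchorMatch)
}

# Local alignment of one anchor against the clone; returns the subject span
# plus acceptance diagnostics.  Flank anchors are accepted when they cover at
# least 60% of the anchor at >= 70% identity.
.anchorHit <- function(anchor, cloneSeq) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(anchor), Biostrings::DNAString(cloneSeq),
    type = "local", substitutionMatrix = .subMat(),
    gapOpening = 0, gapExtension = 2)
  sj <- Biostrings::subject(pa)
  list(start = BiocGenerics::start(sj), end = BiocGenerics::end(sj),
       pid = Biostrings::pid(pa),
       nmatch = Biostrings::nmatch(pa),
       coverage = 100 * Biostrings::nchar(pa) / nchar(anchor),
       score = Biostrings::score(pa))
}

.delimitOne <- function(cloneSeq, refs, idFloor = 50, minAnchorMatch = 25) {
  cloneSeq <- .degap(toupper(cloneSeq))
  L <- nchar(cloneSeq)
  h58 <- .anchorHit(refs@ref58, cloneSeq)
  if (h58$pid < idFloor || h58$nmatch < minAnchorMatch)
    stop("cannot delimit: 5.8S anchor aligns below the identity floor (",
         sprintf("%.1f", h58$pid), "% identity over ", h58$nmatch,
         " matching bases)")
  s58s <- h58$start; s58e <- h58$end

  .flankOK <- function(h) h$pid >= 70 && h$coverage >= 60
  hT <- .anchorHit(refs@tail18S, cloneSeq)
  hH <- .anchorHit(refs@head26S, cloneSeq)

  trunc5 <- !(.flankOK(hT) && hT$end < s58s)
  trunc3 <- !(.flankOK(hH) && hH$start > s58e)
  its1s <- if (trunc5) 1L else hT$end + 1L
  its2e <- if (trunc3) L else hH$start - 1L

  data.frame(its1Start = its1s, its1End = s58s - 1L,
             s58Start = s58s, s58End = s58e,
             its2Start = s58e + 1L, its2End = its2e,
             trunc5 = trunc5, trunc3 = trunc3)
}
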