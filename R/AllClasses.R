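#' ItsCloneSet: a set of cloned ITS sequences with sample membership
#'
#' The central container of the package: one DNA sequence per sequenced clone,
#' each clone assigned to the individual (sample) it was amplified from, plus
#' an optional region partition (ITS1 / 5.8S / ITS2 boundaries) filled in by
#' \code{\link{delimitRegions}}.
#'
#' @slot seqs A \link[Biostrings]{DNAStringSet}; names are the clone IDs and
#'   must be unique.
#' @slot sampleID Character vector parallel to \code{seqs}: the sample each
#'   clone belongs to.
#' @slot partition A data.frame with one row per clone and columns
#'   \code{its1Start, its1End, s58Start, s58End, its2Start, its2End}
#'   (1-based inclusive on the ungapped sequence) and logical
#'   \code{trunc5, trunc3} flags, or a zero-row placeholder before
#'   delimitation.
#'
#' @seealso \code{\link{readClones}}, \code{\link{delimitRegions}},
#'   \code{\link{classifyClones}}
#' @export
setClass("ItsCloneSet",
  representation(seqs = "DNAStringSet",
                 sampleID = "character",
                 partition = "data.frame"))

setValidity("ItsCloneSet", function(object) {
  msg <- character()
  n <- length(object@seqs)
  ids <- names(object@seqs)
  if (n == 0L) msg <- c(msg, "clone set is empty")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "every clone must have a non-empty ID")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    msg <- c(msg, paste0("duplicate clone ID(s): ", paste(dup, collapse = ", ")))
  }
  if (length(object@sampleID) != n)
    msg <- c(msg, "sampleID must have one entry per clone")
  else if (anyNA(object@sampleID) || any(object@sampleID == ""))
    msg <- c(msg, "sample_id present for every clone is required")
  if (n > 0L && any(Biostrings::width(object@seqs) == 0L))
    msg <- c(msg, "sequences must be non-empty")
  p <- object@partition
  if (nrow(p) > 0L) {
    need <- c("its1Start", "its1End", "s58Start", "s58End",
              "its2Start", "its2End", "trunc5", "trunc3")
    if (!all(need %in% colnames(p)))
      msg <- c(msg, "partition is missing required columns")
    if (nrow(p) != n)
      msg <- c(msg, "partition must have one row per clone")
  }
  if (length(msg)) msg else TRUE
})

#' ReferenceSet: anchor sequences for region delimitation and 5.8S checks
#'
#' Holds a 5.8S reference that carries the three conserved angiosperm motifs
#' (M1, M2, M3) exactly once each, in order, and satisfies every forced base
#' pair of helices B4-B8, plus short 18S-tail / 26S-head flank anchors.  The
#' packaged reference is synthetic (constraint-satisfying by construction, see
#' \code{\link{makeReferenceUnit}}); users working with real clones should
#' supply their own reference drawn from a published functional sequence.
#'
#' @slot ref58 Character: the reference 5.8S sequence.
#' @slot tail18S Character: trailing 18S fragment expected upstream of ITS1.
#' @slot head26S Character: leading 26S fragment expected downstream of ITS2.
#' @export
setClass("ReferenceSet",
  representation(ref58 = "character",
                 tail18S = "character",
                 head26S = "character"))

setValidity("ReferenceSet", function(object) {
  msg <- character()
  for (slot in c("ref58", "tail18S", "head26S")) {
    v <- methods::slot(object, slot)
    if (length(v) != 1L || is.na(v) || nchar(v) == 0L)
      msg <- c(msg, paste0(slot, " must be a single non-empty sequence"))
  }
  if (!length(msg)) {
    ref <- Biostrings::DNAString(object@ref58)
    offs <- integer(0)
    for (m in motifDefs()) {
      hits <- Biostrings::matchPattern(m, ref)
      if (length(hits) != 1L) {
        msg <- c(msg, paste0("motif ", m, " must occur exactly once in ref58"))
      } else {
        offs <- c(offs, BiocGenerics::start(hits)[1L])
      }
    }
    if (length(offs) == 3L && is.unsorted(offs))
      msg <- c(msg, "motifs M1, M2, M3 must appear in order")
    hc <- helixConstraints()
    rc <- .chars(object@ref58)
    if (max(hc$j) > length(rc)) {
      msg <- c(msg, "ref58 shorter than the helix constraint span")
    } else {
      for (r in seq_len(nrow(hc))) {
        for (t in seq_len(hc$k[r]) - 1L) {
          if (!.isPairing(rc[hc$i[r] + t], rc[hc$j[r] - t]))
            msg <- c(msg, paste0("forced pair of helix ", hc$helix[r],
                                 " not Watson-Crick/G.U on ref58"))
        }
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' SimulatedCloneSet: generator output with ground truth
#'
#' Result of \code{\link{simulateCloneSet}}: the emitted clones (ungapped), the
#' exact alignment in ancestral coordinates (deletions become gaps), per-clone
#' truth labels with lesion records, the reference set the unit was built
#' around, the ancestral region coordinates, and an echo of the parameters.
#'
#' @slot clones An \code{\link{ItsCloneSet}} of the emitted (ungapped) clones.
#' @slot alignment A \link[Biostrings]{DNAStringSet}: the true alignment, one
#'   equal-width gapped row per clone in ancestral unit coordinates.
#' @slot truth data.frame: cloneID, sampleID, label
#'   (functional/pseudogene/recombinant), parentA/parentB + breakpoint for
#'   recombinants, lesion list, deletion count.
#' @slot refs The \code{\link{ReferenceSet}} used.
#' @slot regions Named list of c(start, end) ancestral coordinates for
#'   tail18S, ITS1, S58, ITS2, head26S and the combined ITS span.
#' @slot params Named list echoing the simulation parameters.
#' @export
setClass("SimulatedCloneSet",
  representation(clones = "ItsCloneSet",
                 alignment = "DNAStringSet",
                 truth = "data.frame",
                 refs = "ReferenceSet",
                 regions = "list",
                 params = "list"))

setValidity("SimulatedCloneSet", function(object) {
  msg <- character()
  n <- length(object@clones@seqs)
  if (nrow(object@truth) != n)
    msg <- c(msg, "every emitted clone needs exactly one truth record")
  if (!identical(sort(object@truth$cloneID), sort(names(object@clones@seqs))))
    msg <- c(msg, "truth clone IDs must match emitted clones")
  if (length(object@alignment) != n)
    msg <- c(msg, "alignment must have one row per clone")
  if (n > 0L && length(unique(Biostrings::width(object@alignment))) != 1L)
    msg <- c(msg, "alignment rows must have equal width")
  if (length(msg)) msg else TRUE
})
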