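#' Forced base-pair constraints of 5.8S helices B4-B8
#'
#' The five conserved stems of the angiosperm 5.8S secondary structure are
#' tested through forced base pairs at fixed reference positions: a block
#' (i, j, k) means reference positions i..i+k-1 pair with j..j-k+1.  Helix B8
#' carries two blocks; all blocks of a helix must be satisfiable for the helix
#' to count as foldable.
#'
#' @return data.frame with columns helix, i, j, k.
#' @export
helixConstraints <- function() {
  data.frame(helix = c("B4", "B5", "B6", "B7", "B8", "B8"),
             i = c(45L, 48L, 69L, 110L, 119L, 126L),
             j = c(105L, 61L, 96L, 118L, 142L, 135L),
             k = c(3L, 3L, 3L, 3L, 4L, 3L),
             stringsAsFactors = FALSE)
}

.HELIX_NAMES <- c("B4", "B5", "B6", "B7", "B8")

#' Constrained helix foldability check for a clone 5.8S
#'
#' The clone 5.8S is globally aligned to the reference 5.8S and every forced
#' pair position is mapped through the alignment.  A helix folds ("X") iff
#' every forced pair of every one of its blocks maps to two non-gap clone
#' bases forming a Watson-Crick or G-U wobble pair; otherwise it is "-".
#' This is a deterministic base-pairing feasibility check at the published
#' forced positions: the diagnostic question is whether the helix can form at
#' all, so no thermodynamic energy model is involved.  Ambiguity codes never
#' pair.  If the alignment identity falls below 40% the pattern is all "-"
#' and a warning flag is set.
#'
#' @param s58Seq The delimited clone 5.8S (character).
#' @param refs A \code{\link{ReferenceSet}}.
#' @param constraints Forced-pair table, default \code{helixConstraints()}.
#' @param map Optional precomputed reference alignment (see
#'   \code{\link{scanMotifs}}).
#' @return A list: \code{pattern} (5-character string over X/- ordered
#'   B4..B8), \code{perHelix} (named logical), \code{alignmentWarning}.
#' @examples
#' unit <- makeReferenceUnit(seed = 1)
#' checkHelices(unit$refs@ref58, unit$refs)$pattern  # "XXXXX"
#' @export
checkHelices <- function(s58Seq, refs, constraints = helixConstraints(),
                         map = NULL) {
  if (is.null(map)) map <- .mapToRef(.degap(toupper(s58Seq)), refs@ref58)
  if (map$pid < 40) {
    return(list(pattern = paste(rep("-", length(.HELIX_NAMES)), collapse = ""),
                perHelix = stats::setNames(rep(FALSE, length(.HELIX_NAMES)),
                                           .HELIX_NAMES),
                alignmentWarning = TRUE))
  }
  ok <- stats::setNames(rep(TRUE, length(.HELIX_NAMES)), .HELIX_NAMES)
  for (r in seq_len(nrow(constraints))) {
    h <- constraints$helix[r]
    for (t in seq_len(constraints$k[r]) - 1L) {
      a <- map$charAt[constraints$i[r] + t]
      b <- map$charAt[constraints$j[r] - t]
      if (!.isPairing(a, b)) ok[h] <- FALSE
    }
  }
  list(pattern = paste(ifelse(ok, "X", "-"), collapse = ""),
       perHelix = ok,
       alignmentWarning = FALSE)
}
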