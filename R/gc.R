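#' GC content of DNA sequences
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T).  Gaps and ambiguity codes are
#' excluded from both numerator and denominator.  Values are reported to two
#' decimals by the evidence table; this function returns full precision.
#'
#' @param x Character vector of sequences, or a
#'   \link[Biostrings]{DNAStringSet}.
#' @return Numeric vector of GC percentages (0-100).
#' @examples
#' gcContent(c("GCGC", "ATATAT"))
#' @export
gcContent <- function(x) {
  if (methods::is(x, "XStringSet")) {
    ss <- Biostrings::DNAStringSet(x)
  } else {
    ss <- Biostrings::DNAStringSet(.degap(toupper(as.character(x))))
  }
  f <- Biostrings::letterFrequency(ss, letters = .BASES)
  tot <- rowSums(f)
  if (any(tot == 0))
    stop("sequence(s) with zero unambiguous bases: ",
         paste(which(tot == 0), collapse = ", "))
  out <- unname(100 * (f[, "C"] + f[, "G"]) / tot)
  if (!is.null(names(x))) names(out) <- names(x)
  out
}

#' Flag clones with reduced GC content relative to their sample
#'
#' Operationalises "significantly lower GC content in at least one region
#' compared with others from the same sample" as a median-minus-delta rule,
#' applied in two passes: the baseline for each sample and region is the
#' median GC over co-sample clones that pass the motif and helix criteria
#' ("clean" clones), so that decayed copies do not drag the baseline down.
#' Fallbacks: if a sample has no clean clone, all co-sample clones define the
#' baseline; samples with fewer than 3 clones use the global (clean) median.
#' A clone is flagged in a region iff its GC is below baseline - deltaPP.
#'
#' @param profiles data.frame with columns cloneID, sampleID, and one numeric
#'   GC column per region (any subset of ITS1, X5.8S/`5.8S`, ITS2; NA allowed
#'   for regions that could not be computed).
#' @param clean Logical vector: TRUE for clones whose motifs are all
#'   conserved and whose helix pattern is intact (defaults to all TRUE, i.e.
#'   a single-pass baseline).
#' @param deltaPP Flagging margin in GC percentage points (default 2).
#' @return Logical matrix (clones x regions); NA GC never flags.
#' @export
flagLowGC <- function(profiles, clean = NULL, deltaPP = 2) {
  stopifnot(deltaPP > 0)
  regions <- intersect(c("ITS1", "5.8S", "ITS2"), colnames(profiles))
  if (!length(regions))
    stop("profiles must contain at least one of ITS1, 5.8S, ITS2")
  n <- nrow(profiles)
  if (is.null(clean)) clean <- rep(TRUE, n)
  stopifnot(length(clean) == n)
  sampleSize <- table(profiles$sampleID)
  flags <- matrix(FALSE, n, length(regions),
                  dimnames = list(profiles$cloneID, regions))
  for (rg in regions) {
    gc <- profiles[[rg]]
    globalBase <- if (any(clean & !is.na(gc))) {
      stats::median(gc[clean], na.rm = TRUE)
    } else {
      stats::median(gc, na.rm = TRUE)
    }
    for (s in unique(profiles$sampleID)) {
      inS <- profiles$sampleID == s
      base <- if (sampleSize[[s]] < 3L) {
        globalBase
      } else if (any(inS & clean & !is.na(gc))) {
        stats::median(gc[inS & clean], na.rm = TRUE)
      } else {
        stats::median(gc[inS], na.rm = TRUE)
      }
      flags[inS, rg] <- !is.na(gc[inS]) & gc[inS] < base - deltaPP
    }
  }
  flags
}
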