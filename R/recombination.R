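#' Configuration for the recombination scan
#'
#' @param window Similarity-profile window in alignment columns (>= 10,
#'   default 30).
#' @param step Profile step in columns (default 5).
#' @param maxchiWindow MaxChi half-window, measured in informative sites per
#'   side of a candidate split (default 10; clipped to half the number of
#'   informative sites of a triplet).
#' @param permutations Number of label permutations for the null (>= 100,
#'   default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed RNG seed used for the permutation null.
#' @param maxPairs Cap on candidate parent pairs evaluated per child in
#'   \code{\link{scanRecombinants}} (default 200).
#' @return A list of class \code{ScanConfig}.
#' @export
scanConfig <- function(window = 30L, step = 5L, maxchiWindow = 10L,
                       permutations = 1000L, alpha = 0.05, seed = 1L,
                       maxPairs = 200L) {
  stopifnot(window >= 10L, step >= 1L, permutations >= 100L,
            maxchiWindow >= 2L, alpha > 0, alpha < 1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 maxchiWindow = as.integer(maxchiWindow),
                 permutations = as.integer(permutations), alpha = alpha,
                 seed = as.integer(seed), maxPairs = as.integer(maxPairs)),
            class = "ScanConfig")
}

#' Sliding-window similarity profile of a child against two parents
#'
#' Percent identity of the child to each candidate parent in windows along
#' the alignment, the visual "sharp discontinuity" diagnostic for chimeric
#' sequences.  Only columns where both sequences carry unambiguous bases are
#' comparable; windows with fewer than 50\% comparable sites are masked.
#'
#' @param child,parentA,parentB Aligned sequences (character) of equal
#'   length.
#' @param config A \code{\link{scanConfig}}.
#' @return data.frame: windowStart, windowCenter, idA, idB, maskedA, maskedB.
#' @export
similarityProfile <- function(child, parentA, parentB,
                              config = scanConfig()) {
  ch <- .chars(toupper(child)); pa <- .chars(toupper(parentA))
  pb <- .chars(toupper(parentB))
  L <- length(ch)
  if (length(pa) != L || length(pb) != L)
    stop("the three aligned sequences must have equal length")
  w <- config$window
  if (L < w) stop("alignment shorter than one window")
  starts <- seq(1L, L - w + 1L, by = config$step)
  okc <- ch %in% .BASES
  compA <- okc & pa %in% .BASES
  compB <- okc & pb %in% .BASES
  matchA <- compA & ch == pa
  matchB <- compB & ch == pb
  winSum <- function(v) {
    cs <- c(0, cumsum(v))
    cs[starts + w] - cs[starts]
  }
  nA <- winSum(compA); nB <- winSum(compB)
  idA <- ifelse(nA > 0, 100 * winSum(matchA) / nA, NA_real_)
  idB <- ifelse(nB > 0, 100 * winSum(matchB) / nB, NA_real_)
  maskedA <- nA < w / 2
  maskedB <- nB < w / 2
  if (all(maskedA) && all(maskedB))
    stop("all windows masked: too few comparable sites")
  data.frame(windowStart = starts, windowCenter = starts + (w - 1L) / 2,
             idA = idA, idB = idB, maskedA = maskedA, maskedB = maskedB)
}

# Informative sites of an aligned triplet: columns where the parents differ,
# all three states are unambiguous bases, and the child matches exactly one
# parent.  Returns alignment columns and the child-matches-A labels.
.informativeSites <- function(ch, pa, pb) {
  ok <- ch %in% .BASES & pa %in% .BASES & pb %in% .BASES
  inf <- ok & pa != pb & (ch == pa | ch == pb)
  list(cols = which(inf), matchesA = ch[inf] == pa[inf])
}

# MaxChi 2x2 statistic for every candidate split, from the cumulative sum of
# 0/1 labels.  With equal half-windows of w sites the chi-squared of the
# (side x matched-parent) table collapses to 2w(a-b)^2/((a+b)(2w-a-b)).
# `S` may be a matrix (one column per permutation).
.maxchiProfile <- function(S, n, w) {
  S0 <- rbind(0, S)
  splits <- w:(n - w)
  a <- S0[splits + 1L, , drop = FALSE] - S0[splits - w + 1L, , drop = FALSE]
  b <- S0[splits + w + 1L, , drop = FALSE] - S0[splits + 1L, , drop = FALSE]
  num <- 2 * w * (a - b)^2
  den <- (a + b) * (2 * w - a - b)
  chi <- ifelse(den > 0, num / den, 0)
  list(splits = splits, chi = chi)
}

#' MaxChi breakpoint test for one aligned triplet
#'
#' Implements the maximum chi-squared recombination test: among the
#' informative sites (parents differ, child matches exactly one parent), every
#' candidate split with \code{maxchiWindow} informative sites on each side is
#' scored by the 2x2 chi-squared of side x matched-parent; the maximum over
#' splits is the statistic, and its significance is assessed by permuting the
#' informative-site match labels.  The breakpoint estimate is the alignment
#' column midway between the two informative sites flanking the best split.
#'
#' @inheritParams similarityProfile
#' @param childID,parentAID,parentBID Optional IDs carried into the report.
#' @param profile Attach the similarity profile to the report (default TRUE).
#' @return A list of class \code{ChimeraReport}: childID, parentAID,
#'   parentBID, nInformative, breakpoint, maxChi2, pValue, verdict
#'   ("recombinant"/"clean"), reason, profile.  Fewer than 8 informative
#'   sites yields a clean verdict with reason "insufficient signal".
#' @examples
#' sim <- simulateCloneSet(nSamples = 3, clonesPerSample = 2,
#'                         pseudoFraction = 0, recombinantFraction = 0,
#'                         seed = 7)
#' aln <- as.character(simAlignment(sim))
#' rep <- maxChiBreakpoint(aln[[1]], aln[[3]], aln[[5]])
#' rep$verdict
#' @export
maxChiBreakpoint <- function(child, parentA, parentB, config = scanConfig(),
                             childID = "child", parentAID = "parentA",
                             parentBID = "parentB", profile = TRUE) {
  ch <- .chars(toupper(child)); pa <- .chars(toupper(parentA))
  pb <- .chars(toupper(parentB))
  if (length(pa) != length(ch) || length(pb) != length(ch))
    stop("the three aligned sequences must have equal length")
  prof <- if (profile) {
    tryCatch(similarityProfile(child, parentA, parentB, config),
             error = function(e) NULL)
  } else NULL
  inf <- .informativeSites(ch, pa, pb)
  n <- length(inf$cols)
  rep0 <- function(verdict, reason, breakpoint = NA_integer_,
                   stat = 0, p = 1) {
    structure(list(childID = childID, parentAID = parentAID,
                   parentBID = parentBID, nInformative = n,
                   breakpoint = breakpoint, maxChi2 = stat, pValue = p,
                   verdict = verdict, reason = reason, profile = prof),
              class = "ChimeraReport")
  }
  if (n < 8L) return(rep0("clean", "insufficient signal"))
  lab <- as.integer(inf$matchesA)
  w <- max(2L, min(config$maxchiWindow, n %/% 2L))
  obs <- .maxchiProfile(matrix(cumsum(lab), ncol = 1), n, w)
  maxObs <- max(obs$chi[, 1])
  sStar <- obs$splits[which.max(obs$chi[, 1])]
  bp <- as.integer(floor((inf$cols[sStar] + inf$cols[sStar + 1L]) / 2))

  P <- config$permutations
  set.seed(config$seed)
  perm <- vapply(seq_len(P), function(i) cumsum(sample(lab)),
                 integer(n))
  permChi <- .maxchiProfile(perm, n, w)$chi
  permMax <- apply(permChi, 2L, max)
  p <- (1 + sum(permMax >= maxObs - 1e-12)) / (P + 1)
  verdict <- if (p <= config$alpha) "recombinant" else "clean"
  rep0(verdict, if (verdict == "recombinant") "maxchi significant" else
    "not significant", bp, maxObs, p)
}

#' @export
print.ChimeraReport <- function(x, ...) {
  cat("ChimeraReport:", x$childID, "vs (", x$parentAID, ",", x$parentBID,
      ")\n  informative sites:", x$nInformative,
      "\n  maxChi2:", sprintf("%.3f", x$maxChi2),
      " p:", format(x$pValue, digits = 3),
      " breakpoint:", x$breakpoint,
      "\n  verdict:", x$verdict, "(", x$reason, ")\n")
  invisible(x)
}

# Observed MaxChi statistic only (no permutations), for cheap pair ranking.
.maxchiStat <- function(ch, pa, pb, maxchiWindow) {
  inf <- .informativeSites(ch, pa, pb)
  n <- length(inf$cols)
  if (n < 8L) return(-Inf)
  w <- max(2L, min(maxchiWindow, n %/% 2L))
  max(.maxchiProfile(matrix(cumsum(as.integer(inf$matchesA)), ncol = 1),
                     n, w)$chi[, 1])
}

#' Scan an aligned clone set for recombinant (chimeric) clones
#'
#' For each clone (child), candidate parents are the other distinct clones.
#' Parent pairs are enumerated in a deterministic order -- parents ranked by
#' identity to the child (ties broken by clone ID), pairs by rank sum -- and
#' capped at \code{maxPairs}.  The observed MaxChi statistic is computed for
#' every pair and the permutation test is then run on the best-supported
#' pair; p-values are Bonferroni-corrected across children.
#'
#' @param aln Aligned clones: named equal-length character vector or
#'   \link[Biostrings]{DNAStringSet}.
#' @param config A \code{\link{scanConfig}}.
#' @param candidateParents Optional character vector restricting the parent
#'   pool (clone IDs).
#' @return data.frame (one row per child): child, parentA, parentB,
#'   nInformative, breakpoint, maxChi2, pRaw, pCorrected, verdict, reason.
#' @export
scanRecombinants <- function(aln, config = scanConfig(),
                             candidateParents = NULL) {
  m <- .alnMatrix(aln)
  ids <- rownames(m)
  n <- nrow(m)
  seqKey <- apply(m, 1L, paste, collapse = "")
  distinctIDs <- ids[!duplicated(seqKey)]
  pool0 <- if (is.null(candidateParents)) distinctIDs else candidateParents

  # identity matrix over unambiguous, shared columns (for parent ranking)
  rows <- list()
  for (childIdx in seq_len(n)) {
    child <- ids[childIdx]
    pool <- setdiff(pool0, ids[seqKey == seqKey[childIdx]])
    if (length(pool) < 2L) {
      rows[[childIdx]] <- data.frame(
        child = child, parentA = NA_character_, parentB = NA_character_,
        nInformative = 0L, breakpoint = NA_integer_, maxChi2 = 0,
        pRaw = 1, pCorrected = 1, verdict = "clean",
        reason = "insufficient parents", stringsAsFactors = FALSE)
      next
    }
    ident <- vapply(pool, function(p) {
      comp <- m[childIdx, ] %in% .BASES & m[p, ] %in% .BASES
      if (!any(comp)) return(0)
      mean(m[childIdx, comp] == m[p, comp])
    }, numeric(1))
    ranked <- pool[order(-ident, pool)]
    nr <- length(ranked)
    pairIdx <- utils::combn(nr, 2L)
    ord <- order(pairIdx[1L, ] + pairIdx[2L, ], pairIdx[1L, ], pairIdx[2L, ])
    pairIdx <- pairIdx[, ord, drop = FALSE]
    if (ncol(pairIdx) > config$maxPairs)
      pairIdx <- pairIdx[, seq_len(config$maxPairs), drop = FALSE]

    stats <- vapply(seq_len(ncol(pairIdx)), function(q) {
      .maxchiStat(m[childIdx, ], m[ranked[pairIdx[1L, q]], ],
                  m[ranked[pairIdx[2L, q]], ], config$maxchiWindow)
    }, numeric(1))
    if (all(!is.finite(stats))) {
      rows[[childIdx]] <- data.frame(
        child = child, parentA = NA_character_, parentB = NA_character_,
        nInformative = 0L, breakpoint = NA_integer_, maxChi2 = 0,
        pRaw = 1, pCorrected = 1, verdict = "clean",
        reason = "insufficient signal", stringsAsFactors = FALSE)
      next
    }
    best <- which.max(stats)
    pA <- ranked[pairIdx[1L, best]]; pB <- ranked[pairIdx[2L, best]]
    rep <- maxChiBreakpoint(
      paste(m[childIdx, ], collapse = ""), paste(m[pA, ], collapse = ""),
      paste(m[pB, ], collapse = ""), config, childID = child,
      parentAID = pA, parentBID = pB, profile = FALSE)
    rows[[childIdx]] <- data.frame(
      child = child, parentA = pA, parentB = pB,
      nInformative = rep$nInformative, breakpoint = rep$breakpoint,
      maxChi2 = rep$maxChi2, pRaw = rep$pValue, pCorrected = NA_real_,
      verdict = NA_character_, reason = rep$reason,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$pCorrected <- pmin(1, out$pRaw * n)
  undecided <- is.na(out$verdict)
  rec <- undecided & out$pCorrected <= config$alpha
  out$verdict[rec] <- "recombinant"
  out$reason[rec] <- "maxchi significant"
  out$verdict[undecided & !rec] <- "clean"
  out$reason[undecided & !rec] <- "not significant"
  rownames(out) <- NULL
  out
}
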