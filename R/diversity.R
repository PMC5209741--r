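#' Count variable and parsimony-informative sites
#'
#' A column is variable iff at least two distinct unambiguous bases (A, C, G,
#' T) occur among its non-gap, non-ambiguous states; it is parsimony
#' informative iff at least two distinct bases each occur in at least two
#' sequences.  Percentages are reported to one decimal.
#'
#' @param aln An alignment: \link[Biostrings]{DNAStringSet} of equal widths,
#'   equal-length character vector, or character matrix.
#' @return list(S, PI, length, pctVariable, pctInformative).
#' @examples
#' countSiteClasses(c(a = "AAT", b = "AAT", c = "ATT", d = "ATA"))
#' @export
countSiteClasses <- function(aln) {
  m <- .alnMatrix(aln)
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  L <- ncol(m)
  if (L == 0L) stop("alignment has length 0")
  counts <- vapply(.BASES, function(b) .colSums(m == b, nrow(m), L),
                   numeric(L))
  counts <- matrix(counts, nrow = L)
  S <- sum(rowSums(counts > 0L) >= 2L)
  PI <- sum(rowSums(counts >= 2L) >= 2L)
  list(S = S, PI = PI, length = L,
       pctVariable = .fmt1(100 * S / L),
       pctInformative = .fmt1(100 * PI / L))
}

#' Average pairwise differences (k) and nucleotide diversity (Pi)
#'
#' k is the mean, over all unordered sequence pairs, of the number of
#' differing unambiguous sites; Pi is the per-site version (mean over pairs of
#' differences / comparable sites).  Under the default complete-deletion
#' policy every column containing any gap or ambiguity code is excluded
#' globally before counting, so Pi = k / lengthUsed exactly; under pairwise
#' deletion each pair is compared over its own gap-free columns.
#'
#' @param aln Alignment (as in \code{\link{countSiteClasses}}).
#' @param deletion "complete" (default) or "pairwise".
#' @return list(n, lengthUsed, S, PI, k, Pi).
#' @examples
#' pairwiseDiversity(c(a = "AACCGGTTAA", b = "AACCGGTTCC"))
#' @export
pairwiseDiversity <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .alnMatrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  good <- matrix(m %in% .BASES, nrow = n)
  if (deletion == "complete") {
    keep <- colSums(good) == n
    if (!any(keep)) stop("no comparable sites under complete deletion")
    mm <- m[, keep, drop = FALSE]
    L <- ncol(mm)
    diffs <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) diffs <- c(diffs, sum(mm[i, ] != mm[j, ]))
    }
    k <- mean(diffs)
    Pi <- k / L
    sc <- countSiteClasses(mm)
  } else {
    L <- ncol(m)
    diffs <- numeric(0)
    ratios <- numeric(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        comp <- good[i, ] & good[j, ]
        nc <- sum(comp)
        if (nc == 0L) next
        d <- sum(m[i, comp] != m[j, comp])
        diffs <- c(diffs, d)
        ratios <- c(ratios, d / nc)
      }
    }
    if (!length(diffs)) stop("no comparable sites for any sequence pair")
    k <- mean(diffs)
    Pi <- mean(ratios)
    sc <- countSiteClasses(m)
  }
  list(n = n, lengthUsed = L, S = sc$S, PI = sc$PI, k = k, Pi = Pi)
}

#' Diversity contrast between functional and pseudogene classes
#'
#' Computes \code{\link{pairwiseDiversity}} separately for the F (presumed
#' functional) and P (putative pseudogene) subsets over each alignment-column
#' partition (typically ITS1 / 5.8S / ITS2 / entire ITS), the layout of the
#' published functional-versus-pseudogene diversity tables.  Classes with
#' fewer than two members yield NA cells.
#'
#' @param aln Alignment; rows named by clone ID.
#' @param labels Named character vector (or F/P factor) mapping clone IDs to
#'   "F" or "P"; clones with NA labels are dropped.
#' @param regions Named list of c(firstColumn, lastColumn) 1-based inclusive
#'   column ranges; default: the entire alignment as region "ITS".
#' @param deletion Deletion policy, see \code{\link{pairwiseDiversity}}.
#' @return data.frame: region, class, n, lengthUsed, S, PI, k, Pi.
#' @export
classContrast <- function(aln, labels, regions = NULL,
                          deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- .alnMatrix(aln)
  ids <- rownames(m)
  lab <- as.character(labels)[match(ids, names(labels))]
  keep <- !is.na(lab)
  m <- m[keep, , drop = FALSE]
  lab <- lab[keep]
  if (!all(lab %in% c("F", "P")))
    stop("labels must be 'F' or 'P'")
  if (is.null(regions)) regions <- list(ITS = c(1L, ncol(m)))
  out <- list()
  for (rg in names(regions)) {
    rr <- regions[[rg]]
    sub <- m[, rr[1L]:rr[2L], drop = FALSE]
    for (cl in c("F", "P")) {
      rows <- lab == cl
      if (sum(rows) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          region = rg, class = cl, n = sum(rows), lengthUsed = NA_integer_,
          S = NA_integer_, PI = NA_integer_, k = NA_real_, Pi = NA_real_)
      } else {
        d <- pairwiseDiversity(sub[rows, , drop = FALSE], deletion)
        out[[length(out) + 1L]] <- data.frame(
          region = rg, class = cl, n = d$n, lengthUsed = d$lengthUsed,
          S = d$S, PI = d$PI, k = d$k, Pi = d$Pi)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simple indel coding of alignment gaps
#'
#' Every distinct gap (identical start and end columns) observed in at least
#' one sequence becomes one binary character, ordered by (start, end).  A
#' sequence scores "1" iff it carries exactly that gap, "0" if it has
#' contiguous bases across the whole span, and "?" (inapplicable) if one of
#' its gaps strictly contains, is nested within, or partially overlaps the
#' span without being identical to it.
#'
#' @param aln Gapped alignment.
#' @return Character matrix (sequences x gap characters) over "0"/"1"/"?",
#'   with columns named \code{g<start>_<end>}; zero columns for a gap-free
#'   alignment.
#' @examples
#' simpleIndelCode(c(a = "AC---GT", b = "AC---GT", c = "ACTTTGT"))
#' @export
simpleIndelCode <- function(aln) {
  m <- .alnMatrix(aln)
  n <- nrow(m)
  gapsOf <- function(row) {
    r <- rle(row == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(start = starts[r$values], end = ends[r$values])
  }
  perSeq <- lapply(seq_len(n), function(i) gapsOf(m[i, ]))
  allGaps <- unique(do.call(rbind, perSeq))
  if (is.null(allGaps) || nrow(allGaps) == 0L) {
    return(matrix(character(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(m), NULL)))
  }
  allGaps <- allGaps[order(allGaps[, "start"], allGaps[, "end"]), ,
                     drop = FALSE]
  out <- matrix("0", n, nrow(allGaps),
                dimnames = list(rownames(m),
                                paste0("g", allGaps[, "start"], "_",
                                       allGaps[, "end"])))
  for (g in seq_len(nrow(allGaps))) {
    s <- allGaps[g, "start"]; e <- allGaps[g, "end"]
    for (i in seq_len(n)) {
      gi <- perSeq[[i]]
      if (nrow(gi) == 0L) next
      exact <- any(gi[, "start"] == s & gi[, "end"] == e)
      overlap <- any(gi[, "start"] <= e & gi[, "end"] >= s)
      out[i, g] <- if (exact) "1" else if (overlap) "?" else "0"
    }
  }
  out
}

#' Format an indel character matrix as a NEXUS-style characters block
#'
#' @param mat Output of \code{\link{simpleIndelCode}}.
#' @return Character vector of NEXUS lines (standard datatype, missing '?').
#' @export
formatIndelNexus <- function(mat) {
  taxa <- rownames(mat)
  rows <- vapply(seq_len(nrow(mat)), function(i) {
    paste0("    ", taxa[i], " ", paste(mat[i, ], collapse = ""))
  }, character(1))
  c("#NEXUS", "BEGIN CHARACTERS;",
    paste0("  DIMENSIONS NCHAR=", ncol(mat), ";"),
    "  FORMAT DATATYPE=STANDARD MISSING=? SYMBOLS=\"01\";",
    "  MATRIX", rows, "  ;", "END;")
}
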