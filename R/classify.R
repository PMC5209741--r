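#' Classify clones as functional or pseudogene from three evidence streams
#'
#' Runs the full pseudogene screen on a delimited clone set: per-region GC
#' content with within-sample low-GC flagging (\code{\link{flagLowGC}}),
#' conserved-motif scanning of the 5.8S (\code{\link{scanMotifs}}), and the
#' helix foldability check (\code{\link{checkHelices}}).  Under the default
#' policy a clone is a pseudogene iff at least one evidence stream triggers:
#' a GC flag in any region, any motif not conserved, or any helix unable to
#' fold.  \code{minCriteria} raises the number of distinct streams required.
#'
#' @param x A delimited \code{\link{ItsCloneSet}}.
#' @param refs A \code{\link{ReferenceSet}}.
#' @param deltaPP GC flagging margin in percentage points (default 2).
#' @param minCriteria Minimum number of triggered evidence streams (1-3) for
#'   a pseudogene verdict (default 1).
#' @return data.frame (one row per clone): cloneID, sampleID, gcITS1, gc58S,
#'   gcITS2 (two decimals), flagITS1/flag58S/flagITS2, M1/M2/M3 (printed
#'   motif labels), helixPattern, helixWarning, verdict, reasons
#'   (";"-separated triggered criteria).
#' @examples
#' sim <- simulateCloneSet(nSamples = 2, clonesPerSample = 4, seed = 1)
#' x <- delimitRegions(simClones(sim), referenceSet(sim))
#' table(classifyClones(x, referenceSet(sim))$verdict)
#' @export
classifyClones <- function(x, refs, deltaPP = 2, minCriteria = 1) {
  stopifnot(methods::is(x, "ItsCloneSet"), methods::is(refs, "ReferenceSet"))
  if (!nrow(x@partition))
    stop("clones are not delimited; run delimitRegions() first")
  ids <- names(x@seqs)
  n <- length(ids)

  s58 <- regionSeqs(x, "5.8S")
  regs <- list(ITS1 = regionSeqs(x, "ITS1"), `5.8S` = s58,
               ITS2 = regionSeqs(x, "ITS2"))
  gc <- vapply(regs, function(v) {
    vapply(v, function(s) {
      s <- .degap(s)
      bases <- sum(.chars(s) %in% .BASES)
      if (nchar(s) == 0L || bases == 0L) NA_real_ else gcContent(s)
    }, numeric(1), USE.NAMES = FALSE)
  }, numeric(n))
  if (n == 1L) gc <- matrix(gc, nrow = 1, dimnames = list(NULL, names(regs)))

  motifLab <- matrix("", n, 3L, dimnames = list(ids, names(motifDefs())))
  motifClean <- rep(TRUE, n)
  helixPat <- character(n)
  helixWarn <- logical(n)
  for (i in seq_len(n)) {
    map <- .mapToRef(s58[[i]], refs@ref58)
    reps <- scanMotifs(s58[[i]], refs, map = map)
    motifLab[i, ] <- vapply(reps, `[[`, character(1), "label")
    motifClean[i] <- all(vapply(reps, `[[`, character(1), "status") ==
                           "conserved")
    hx <- checkHelices(s58[[i]], refs, map = map)
    helixPat[i] <- hx$pattern
    helixWarn[i] <- hx$alignmentWarning
  }
  helixClean <- helixPat == "XXXXX"

  profiles <- data.frame(cloneID = ids, sampleID = x@sampleID,
                         ITS1 = gc[, "ITS1"], `5.8S` = gc[, "5.8S"],
                         ITS2 = gc[, "ITS2"], check.names = FALSE)
  flags <- flagLowGC(profiles, clean = motifClean & helixClean,
                     deltaPP = deltaPP)

  verdict <- character(n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    rs <- character(0)
    if (any(flags[i, ]))
      rs <- c(rs, paste0("low_gc:", colnames(flags)[flags[i, ]]))
    bad <- motifLab[i, ] != "conserved"
    if (any(bad)) rs <- c(rs, paste0("motif:", colnames(motifLab)[bad]))
    hbad <- .chars(helixPat[i]) == "-"
    if (any(hbad)) rs <- c(rs, paste0("helix:", .HELIX_NAMES[hbad]))
    nStreams <- sum(any(flags[i, ]), any(bad), any(hbad))
    verdict[i] <- if (nStreams >= minCriteria && length(rs) > 0L)
      "pseudogene" else "functional"
    reasons[i] <- paste(rs, collapse = ";")
  }

  data.frame(cloneID = ids, sampleID = x@sampleID,
             gcITS1 = .fmt2(gc[, "ITS1"]), gc58S = .fmt2(gc[, "5.8S"]),
             gcITS2 = .fmt2(gc[, "ITS2"]),
             flagITS1 = flags[, "ITS1"], flag58S = flags[, "5.8S"],
             flagITS2 = flags[, "ITS2"],
             M1 = motifLab[, "M1"], M2 = motifLab[, "M2"],
             M3 = motifLab[, "M3"],
             helixPattern = helixPat, helixWarning = helixWarn,
             verdict = verdict, reasons = reasons,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Render the evidence table as TSV text
#'
#' One row per clone in the layout of the published pseudogene evidence
#' tables: GC columns to two decimals with a "*" suffix marking the
#' within-sample low-GC flag (in place of boldface), motif columns using
#' "conserved" / "nt-..." / "missing i-j" / "all missing", the five-character
#' helix pattern, and the verdict.
#'
#' @param evidence Output of \code{\link{classifyClones}}.
#' @param path Optional output file.
#' @return The TSV text as a character vector of lines (invisibly when
#'   written to file).
#' @export
renderEvidenceTable <- function(evidence, path = NULL) {
  hdr <- paste(c("clone_id", "GC_ITS1", "GC_5.8S", "GC_ITS2",
                 "M1", "M2", "M3", "helices", "verdict"), collapse = "\t")
  starred <- function(v, f) {
    out <- ifelse(is.na(v), "NA", sprintf("%.2f", v))
    paste0(out, ifelse(!is.na(f) & f, "*", ""))
  }
  if (nrow(evidence) == 0L) {
    lines <- hdr
  } else {
    rows <- paste(evidence$cloneID,
                  starred(evidence$gcITS1, evidence$flagITS1),
                  starred(evidence$gc58S, evidence$flag58S),
                  starred(evidence$gcITS2, evidence$flagITS2),
                  evidence$M1, evidence$M2, evidence$M3,
                  evidence$helixPattern, evidence$verdict, sep = "\t")
    lines <- c(hdr, rows)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse an evidence TSV back into records
#'
#' Inverse of \code{\link{renderEvidenceTable}} for the columns it renders.
#'
#' @param path File path, or a character vector of TSV lines.
#' @return data.frame with cloneID, gcITS1/gc58S/gcITS2, flagITS1/flag58S/
#'   flagITS2, M1, M2, M3, helixPattern, verdict.
#' @export
parseEvidenceTable <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path) else path
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, colClasses = "character",
                          check.names = FALSE)
  splitGC <- function(v) {
    flag <- endsWith(v, "*")
    num <- suppressWarnings(as.numeric(sub("\\*$", "", v)))
    list(gc = num, flag = flag)
  }
  g1 <- splitGC(df[["GC_ITS1"]]); g2 <- splitGC(df[["GC_5.8S"]])
  g3 <- splitGC(df[["GC_ITS2"]])
  data.frame(cloneID = df$clone_id,
             gcITS1 = g1$gc, gc58S = g2$gc, gcITS2 = g3$gc,
             flagITS1 = g1$flag, flag58S = g2$flag, flagITS2 = g3$flag,
             M1 = df$M1, M2 = df$M2, M3 = df$M3,
             helixPattern = df$helices, verdict = df$verdict,
             stringsAsFactors = FALSE)
}
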