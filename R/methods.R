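#' Construct an ItsCloneSet
#'
#' @param seqs Sequences: a \link[Biostrings]{DNAStringSet} or a named
#'   character vector.  Names are clone IDs.  Lowercase letters and RNA "U"
#'   are normalised to uppercase DNA.
#' @param sampleID Character vector of sample memberships (recycled if length
#'   one); if \code{NULL}, sample IDs are derived from clone IDs by stripping
#'   the trailing \code{-<cloneNumber>} (so clone "A.alba-1-3" belongs to
#'   sample "A.alba-1").
#' @param partition Optional partition data.frame (see class docs).
#' @return An \code{\link{ItsCloneSet}}.
#' @examples
#' x <- ItsCloneSet(c("sampleA-1" = "ACGTACGT", "sampleA-2" = "ACGAACGT"))
#' sampleIDs(x)
#' @export
ItsCloneSet <- function(seqs, sampleID = NULL, partition = NULL) {
  if (!methods::is(seqs, "DNAStringSet")) {
    ids <- names(seqs)
    norm <- chartr("u", "t", tolower(as.character(seqs)))
    seqs <- Biostrings::DNAStringSet(toupper(norm))
    names(seqs) <- ids
  } else {
    # uppercase + U->T normalisation also for DNAStringSet input
    ids <- names(seqs)
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
    names(seqs) <- ids
  }
  if (is.null(sampleID)) sampleID <- sampleFromCloneID(names(seqs))
  sampleID <- rep_len(as.character(sampleID), length(seqs))
  if (is.null(partition)) partition <- .emptyPartition()
  methods::new("ItsCloneSet", seqs = seqs, sampleID = sampleID,
               partition = partition)
}

.emptyPartition <- function() {
  data.frame(its1Start = integer(0), its1End = integer(0),
             s58Start = integer(0), s58End = integer(0),
             its2Start = integer(0), its2End = integer(0),
             trunc5 = logical(0), trunc3 = logical(0))
}

#' Derive the sample ID from a clone ID
#'
#' Default clone-to-sample rule: strip the trailing \code{-<number>} clone
#' counter, mirroring IDs of the form "A.alba-1-3" (clone 3 of sample
#' "A.alba-1").  IDs without such a suffix map to themselves.
#'
#' @param cloneID Character vector of clone IDs.
#' @return Character vector of sample IDs.
#' @export
sampleFromCloneID <- function(cloneID) {
  sub("-[0-9]+$", "", cloneID)
}

#' @rdname ItsCloneSet-class
#' @param object,x An \code{ItsCloneSet}.
#' @export
setMethod("show", "ItsCloneSet", function(object) {
  n <- length(object@seqs)
  cat("ItsCloneSet with", n, "clone(s) from",
      length(unique(object@sampleID)), "sample(s)\n")
  w <- Biostrings::width(object@seqs)
  cat("  lengths:", min(w), "-", max(w), "bp;",
      if (nrow(object@partition)) "delimited" else "not delimited", "\n")
})

#' @rdname ItsCloneSet-class
#' @export
setMethod("length", "ItsCloneSet", function(x) length(x@seqs))

#' @rdname ItsCloneSet-class
#' @export
setMethod("names", "ItsCloneSet", function(x) names(x@seqs))

#' @rdname ItsCloneSet-class
#' @export
setMethod("cloneIDs", "ItsCloneSet", function(x) names(x@seqs))

#' @rdname ItsCloneSet-class
#' @export
setMethod("sampleIDs", "ItsCloneSet", function(x) {
  stats::setNames(x@sampleID, names(x@seqs))
})

#' @rdname ItsCloneSet-class
#' @export
setMethod("cloneSeqs", "ItsCloneSet", function(x) x@seqs)

#' @rdname ItsCloneSet-class
#' @export
setMethod("partitions", "ItsCloneSet", function(x) {
  p <- x@partition
  if (nrow(p)) rownames(p) <- names(x@seqs)
  p
})

#' @rdname ItsCloneSet-class
#' @export
setMethod("partitions<-", "ItsCloneSet", function(x, value) {
  x@partition <- as.data.frame(value)
  methods::validObject(x)
  x
})

#' @rdname ItsCloneSet-class
#' @param i Index (numeric, logical, or clone IDs).
#' @param j,drop,... Ignored (matrix-style subsetting is not supported).
#' @export
setMethod("[", "ItsCloneSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@seqs))
  part <- x@partition
  if (nrow(part)) part <- part[i, , drop = FALSE]
  methods::new("ItsCloneSet", seqs = x@seqs[i], sampleID = x@sampleID[i],
               partition = part)
})

#' @rdname ItsCloneSet-class
#' @export
setMethod("regionSeqs", "ItsCloneSet", function(x, region) {
  region <- match.arg(region, c("ITS1", "5.8S", "ITS2"))
  p <- x@partition
  if (!nrow(p)) stop("clones are not delimited; run delimitRegions() first")
  cols <- switch(region,
                 "ITS1" = c("its1Start", "its1End"),
                 "5.8S" = c("s58Start", "s58End"),
                 "ITS2" = c("its2Start", "its2End"))
  s <- p[[cols[1L]]]; e <- p[[cols[2L]]]
  out <- character(length(x@seqs))
  full <- as.character(x@seqs)
  ok <- !is.na(s) & !is.na(e) & e >= s
  out[ok] <- substr(full[ok], s[ok], e[ok])
  stats::setNames(out, names(x@seqs))
})

#' @rdname ReferenceSet-class
#' @param ref58,tail18S,head26S Sequences (character).
#' @export
ReferenceSet <- function(ref58, tail18S, head26S) {
  methods::new("ReferenceSet", ref58 = toupper(ref58),
               tail18S = toupper(tail18S), head26S = toupper(head26S))
}

#' @rdname ReferenceSet-class
#' @param object A \code{ReferenceSet}.
#' @export
setMethod("show", "ReferenceSet", function(object) {
  cat("ReferenceSet: 5.8S", nchar(object@ref58), "bp; 18S tail",
      nchar(object@tail18S), "bp; 26S head", nchar(object@head26S), "bp\n")
  cat("  motifs M1/M2/M3 at:",
      paste(vapply(motifDefs(), function(m) {
        BiocGenerics::start(Biostrings::matchPattern(
          m, Biostrings::DNAString(object@ref58)))[1L]
      }, integer(1)), collapse = ", "), "\n")
})

#' @rdname SimulatedCloneSet-class
#' @param object A \code{SimulatedCloneSet}.
#' @export
setMethod("show", "SimulatedCloneSet", function(object) {
  tab <- table(object@truth$label)
  cat("SimulatedCloneSet:", length(object@clones@seqs), "clones (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  cat("  alignment width:", Biostrings::width(object@alignment)[1L], "\n")
})

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("simClones", "SimulatedCloneSet", function(x) x@clones)

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("simAlignment", "SimulatedCloneSet", function(x) x@alignment)

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("simTruth", "SimulatedCloneSet", function(x) x@truth)

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("referenceSet", "SimulatedCloneSet", function(x) x@refs)

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("regionRanges", "SimulatedCloneSet", function(x) x@regions)

#' @rdname SimulatedCloneSet-class
#' @export
setMethod("simParams", "SimulatedCloneSet", function(x) x@params)
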