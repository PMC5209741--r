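#' Read cloned ITS sequences and their sample membership
#'
#' Reads a (possibly gzipped) multi-FASTA of cloned sequences and attaches a
#' sample ID to every clone, either from a two-column TSV map
#' (clone_id, sample_id) or, when no map is given, by the default ID-pattern
#' rule of \code{\link{sampleFromCloneID}}.  Sequences are uppercased and RNA
#' "U" is normalised to "T"; record order is preserved.
#'
#' @param fastaPath Path to the FASTA file.
#' @param sampleMapPath Optional path to the clone-to-sample TSV
#'   (no header, columns clone_id and sample_id).
#' @return An \code{\link{ItsCloneSet}}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">S1-1", "acgtacgt", ">S1-2", "ACGAACGU"), fa)
#' readClones(fa)
#' @export
readClones <- function(fastaPath, sampleMapPath = NULL) {
  if (!file.exists(fastaPath)) stop("FASTA file not found: ", fastaPath)
  # read as raw strings first: RNA "U" and lowercase are normalised before
  # the DNA container is built
  raw <- Biostrings::readBStringSet(fastaPath)
  if (length(raw) == 0L) stop("empty FASTA file: ", fastaPath)
  seqs <- Biostrings::DNAStringSet(
    chartr("U", "T", toupper(as.character(raw))))
  # FASTA descriptions may carry annotation after the first token
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicated FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(seqs) <- ids
  if (!is.null(sampleMapPath)) {
    map <- readSampleMap(sampleMapPath)
    miss <- setdiff(ids, names(map))
    if (length(miss))
      stop("clone(s) missing from the sample map: ",
           paste(miss, collapse = ", "))
    samp <- unname(map[ids])
  } else {
    samp <- sampleFromCloneID(ids)
  }
  ItsCloneSet(seqs, sampleID = samp)
}

#' Read a clone-to-sample map
#'
#' @param path Two-column TSV (clone_id, sample_id), no header.
#' @return Named character vector: sample ID per clone ID.
#' @export
readSampleMap <- function(path) {
  if (!file.exists(path)) stop("sample map not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("cloneID", "sampleID"),
                          colClasses = "character", comment.char = "#")
  if (anyDuplicated(df$cloneID))
    stop("duplicate clone ID(s) in sample map: ",
         paste(unique(df$cloneID[duplicated(df$cloneID)]), collapse = ", "))
  stats::setNames(df$sampleID, df$cloneID)
}

#' Collapse identical clones into distinct haplotypes
#'
#' Exact-string grouping of (ungapped, uppercased) clone sequences, the
#' operation behind tallies such as "290 out of 450 clones were distinct".
#' Groups are ordered by first occurrence; each group's representative is its
#' first member.
#'
#' @param x An \code{\link{ItsCloneSet}} or a character vector of sequences
#'   (named by clone ID).
#' @return A list: \code{nTotal}, \code{nDistinct}, \code{groups} (list of
#'   clone-ID vectors), \code{representative} (first clone of each group),
#'   \code{membership} (group index per clone).
#' @export
collapseDistinct <- function(x) {
  if (methods::is(x, "ItsCloneSet")) {
    seqs <- stats::setNames(as.character(x@seqs), names(x@seqs))
  } else {
    seqs <- x
    if (is.null(names(seqs))) names(seqs) <- paste0("clone", seq_along(seqs))
  }
  seqs <- toupper(seqs)
  key <- match(seqs, unique(seqs))
  groups <- split(names(seqs), key)
  names(groups) <- NULL
  list(nTotal = length(seqs),
       nDistinct = length(groups),
       groups = groups,
       representative = vapply(groups, `[`, character(1), 1L),
       membership = stats::setNames(key, names(seqs)))
}

#' Per-region length ranges across a delimited clone set
#'
#' Reports the minimum and maximum length (bp) of ITS1, 5.8S, ITS2 and of the
#' entire cloned region (including any retained 18S/26S flank), together with
#' the clone IDs attaining each extreme.
#'
#' @param x A delimited \code{\link{ItsCloneSet}}.
#' @return data.frame with columns region, min, minClone, max, maxClone.
#' @export
regionLengthSummary <- function(x) {
  stopifnot(methods::is(x, "ItsCloneSet"))
  if (!nrow(x@partition))
    stop("clones are not delimited; run delimitRegions() first")
  ids <- names(x@seqs)
  lens <- list(
    ITS1 = nchar(regionSeqs(x, "ITS1")),
    `5.8S` = nchar(regionSeqs(x, "5.8S")),
    ITS2 = nchar(regionSeqs(x, "ITS2")),
    entire = Biostrings::width(x@seqs))
  do.call(rbind, lapply(names(lens), function(r) {
    v <- lens[[r]]
    data.frame(region = r,
               min = min(v), minClone = ids[which.min(v)],
               max = max(v), maxClone = ids[which.max(v)],
               stringsAsFactors = FALSE)
  }))
}

#' Write region partitions as a BED-like TSV
#'
#' One row per clone and region with 0-based half-open coordinates
#' (columns clone_id, region, start, end), the interchange convention of
#' BED; printed reports elsewhere in the package are 1-based.
#'
#' @param x A delimited \code{\link{ItsCloneSet}}.
#' @param path Output file; when NULL the data.frame is returned only.
#' @return The BED-like data.frame, invisibly when written to file.
#' @export
writePartitions <- function(x, path = NULL) {
  p <- partitions(x)
  if (!nrow(p)) stop("clones are not delimited")
  ids <- names(x@seqs)
  bed <- rbind(
    data.frame(clone_id = ids, region = "ITS1",
               start = p$its1Start - 1L, end = p$its1End),
    data.frame(clone_id = ids, region = "5.8S",
               start = p$s58Start - 1L, end = p$s58End),
    data.frame(clone_id = ids, region = "ITS2",
               start = p$its2Start - 1L, end = p$its2End))
  bed <- bed[order(match(bed$clone_id, ids)), ]
  rownames(bed) <- NULL
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(bed))
  }
  bed
}
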