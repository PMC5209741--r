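# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

# Watson-Crick or G.U wobble (DNA representation: U == T).
.PAIRS <- c("AT", "TA", "CG", "GC", "GT", "TG")

.isPairing <- function(a, b) {
  !is.na(a) & !is.na(b) & paste0(a, b) %in% .PAIRS
}

.chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1]]

.degap <- function(x) gsub("-", "", x, fixed = TRUE)

# match +1 / mismatch -1 over the full IUPAC alphabet, used by all anchor and
# 5.8S alignments (ambiguity codes never score as matches).
.subMat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

# Coerce an aligned input (DNAStringSet, named character vector, or character
# matrix) to a character matrix with one row per sequence.
.alnMatrix <- function(aln) {
  if (is.matrix(aln)) {
    m <- aln
  } else if (methods::is(aln, "XStringSet")) {
    m <- as.matrix(aln)
  } else if (is.character(aln)) {
    if (length(unique(nchar(aln))) != 1L)
      stop("aligned sequences must all have the same length")
    m <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    rownames(m) <- names(aln)
  } else {
    stop("unsupported alignment representation: ", class(aln)[1L])
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("seq", seq_len(nrow(m)))
  toupper(m)
}

.fmt1 <- function(x) as.numeric(sprintf("%.1f", x))
.fmt2 <- function(x) as.numeric(sprintf("%.2f", x))
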