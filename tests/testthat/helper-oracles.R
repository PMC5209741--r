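# Independent brute-force oracles. These deliberately use naive
# character-level loops, separate from the package's code paths.

bfGC <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- sum(ch %in% c("A", "C", "G", "T"))
  100 * sum(ch %in% c("G", "C")) / n
}

bfSiteClasses <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  S <- 0L; PI <- 0L
  for (col in seq_len(ncol(m))) {
    v <- m[, col]
    v <- v[v %in% c("A", "C", "G", "T")]
    tab <- table(v)
    if (length(tab) >= 2L) S <- S + 1L
    if (sum(tab >= 2L) >= 2L) PI <- PI + 1L
  }
  list(S = S, PI = PI)
}

# k and Pi under complete deletion, via an explicit all-pairs double loop.
bfDiversityComplete <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  ok <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  m <- m[, ok, drop = FALSE]
  n <- nrow(m)
  tot <- 0; np <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 0L
      for (c in seq_len(ncol(m))) if (m[i, c] != m[j, c]) d <- d + 1L
      tot <- tot + d; np <- np + 1L
    }
  }
  k <- tot / np
  list(k = k, Pi = k / ncol(m), lengthUsed = ncol(m))
}

# Exhaustive MaxChi: enumerate every split, build the 2x2 table explicitly,
# compute chi-squared from first principles.
bfMaxChi <- function(labels01, w) {
  n <- length(labels01)
  best <- -Inf
  for (s in w:(n - w)) {
    left <- labels01[(s - w + 1L):s]
    right <- labels01[(s + 1L):(s + w)]
    a <- sum(left); b <- sum(right)
    tab <- matrix(c(a, w - a, b, w - b), 2, 2, byrow = TRUE)
    N <- sum(tab)
    rs <- rowSums(tab); cs <- colSums(tab)
    if (any(cs == 0)) { chi <- 0 } else {
      E <- outer(rs, cs) / N
      chi <- sum((tab - E)^2 / E)
    }
    if (chi > best) best <- chi
  }
  best
}

# Enumerate every forced pair of every helix directly on an ungapped mutant
# of the reference (positions map 1:1), checking WC/G.U pairing.
bfHelixPattern <- function(s58chars) {
  hc <- helixConstraints()
  pairsOK <- c("AT", "TA", "CG", "GC", "GT", "TG")
  ok <- setNames(rep(TRUE, 5), c("B4", "B5", "B6", "B7", "B8"))
  for (r in seq_len(nrow(hc))) {
    for (t in seq_len(hc$k[r]) - 1L) {
      duo <- paste0(s58chars[hc$i[r] + t], s58chars[hc$j[r] - t])
      if (!duo %in% pairsOK) ok[hc$helix[r]] <- FALSE
    }
  }
  paste(ifelse(ok, "X", "-"), collapse = "")
}

randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

writeTempFasta <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}
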