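#' Build a synthetic ancestral rDNA unit and its ReferenceSet
#'
#' Constructs, deterministically from a seed, a functional-looking
#' 18S-tail + ITS1 + 5.8S + ITS2 + 26S-head unit: a 160 bp 5.8S carrying the
#' exact motifs M1/M2/M3 at fixed offsets with every forced base pair of
#' helices B4-B8 Watson-Crick complementary by construction and GC nudged
#' into the 54-56\% band typical of functional copies; spacers of 230 bp
#' (ITS1) and 210 bp (ITS2) at ~62\% GC; and 25 bp flanks.  The returned
#' \code{\link{ReferenceSet}} is synthetic: it stands in for a published
#' functional reference so that the whole pipeline is testable without
#' downloads.
#'
#' @param seed Integer seed; identical seeds give byte-identical units.
#' @return A list: \code{refs} (\code{\link{ReferenceSet}}), \code{unit}
#'   (character, 650 bp), \code{regions} (named list of c(start, end)
#'   1-based coordinates for tail18S, ITS1, S58, ITS2, head26S, ITS),
#'   \code{constrained} (integer vector of unit positions under functional
#'   constraint: motif and forced-pair sites), \code{s58Constrained}
#'   (the same, 5.8S-local coordinates).
#' @examples
#' unit <- makeReferenceUnit(seed = 1)
#' checkHelices(unit$refs@ref58, unit$refs)$pattern
#' @export
makeReferenceUnit <- function(seed = 1L) {
  set.seed(seed)
  lens <- c(tail18S = 25L, ITS1 = 230L, S58 = 160L, ITS2 = 210L,
            head26S = 25L)
  rand <- function(n, gc) {
    sample(.BASES, n, replace = TRUE,
           prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  }
  motifs <- motifDefs()
  motifOff <- c(M1 = 6L, M2 = 76L, M3 = 145L)
  hc <- helixConstraints()
  forced <- integer(0)
  for (r in seq_len(nrow(hc))) {
    t <- seq_len(hc$k[r]) - 1L
    forced <- c(forced, hc$i[r] + t, hc$j[r] - t)
  }
  motifPos <- unlist(lapply(names(motifs), function(m) {
    motifOff[[m]]:(motifOff[[m]] + nchar(motifs[[m]]) - 1L)
  }))
  protected <- sort(unique(c(forced, motifPos)))

  gcBand <- function(chars, lo, hi, protect) {
    free <- setdiff(seq_along(chars), protect)
    repeat {
      gc <- 100 * mean(chars %in% c("G", "C"))
      if (gc < lo) {
        cand <- free[chars[free] %in% c("A", "T")]
        if (!length(cand)) break
        chars[sample(cand, 1L)] <- sample(c("G", "C"), 1L)
      } else if (gc > hi) {
        cand <- free[chars[free] %in% c("G", "C")]
        if (!length(cand)) break
        chars[sample(cand, 1L)] <- sample(c("A", "T"), 1L)
      } else break
    }
    chars
  }

  repeat {
    s58 <- rand(lens[["S58"]], 0.55)
    for (m in names(motifs)) {
      span <- motifOff[[m]]:(motifOff[[m]] + nchar(motifs[[m]]) - 1L)
      s58[span] <- .chars(motifs[[m]])
    }
    for (r in seq_len(nrow(hc))) {
      for (t in seq_len(hc$k[r]) - 1L) {
        s58[hc$j[r] - t] <- .COMP[[s58[hc$i[r] + t]]]
      }
    }
    s58 <- gcBand(s58, 54, 56, protected)
    s58str <- paste(s58, collapse = "")
    counts <- vapply(motifs, function(m) {
      length(Biostrings::matchPattern(m, Biostrings::DNAString(s58str)))
    }, integer(1))
    if (all(counts == 1L)) break
  }

  its1 <- gcBand(rand(lens[["ITS1"]], 0.62), 61, 63, integer(0))
  its2 <- gcBand(rand(lens[["ITS2"]], 0.63), 62, 64, integer(0))
  tail18 <- rand(lens[["tail18S"]], 0.52)
  head26 <- rand(lens[["head26S"]], 0.56)

  unit <- c(tail18, its1, s58, its2, head26)
  cs <- cumsum(lens)
  regions <- list(
    tail18S = c(1L, cs[["tail18S"]]),
    ITS1 = c(cs[["tail18S"]] + 1L, cs[["ITS1"]]),
    S58 = c(cs[["ITS1"]] + 1L, cs[["S58"]]),
    ITS2 = c(cs[["S58"]] + 1L, cs[["ITS2"]]),
    head26S = c(cs[["ITS2"]] + 1L, cs[["head26S"]]),
    ITS = c(cs[["tail18S"]] + 1L, cs[["ITS2"]]))
  s58Start <- regions$S58[1L]
  list(refs = ReferenceSet(s58str, paste(tail18, collapse = ""),
                           paste(head26, collapse = "")),
       unit = paste(unit, collapse = ""),
       regions = regions,
       constrained = protected + s58Start - 1L,
       s58Constrained = protected)
}

# CpG/GpC-aware substitution: positions in a CpG or GpC dinucleotide context
# undergo the deamination-type change (C->T / G->A) with probability
# cpgBias, otherwise (and at all other sites) a uniform change to one of the
# three alternative bases.  GC content strictly decreases in expectation.
.mutateChars <- function(chars, pos, cpgBias) {
  L <- length(chars)
  for (p in pos) {
    b <- chars[p]
    if (!(b %in% .BASES)) next
    prevB <- if (p > 1L) chars[p - 1L] else ""
    nextB <- if (p < L) chars[p + 1L] else ""
    inCtx <- (b == "C" && (nextB == "G" || prevB == "G")) ||
             (b == "G" && (nextB == "C" || prevB == "C"))
    if (inCtx && stats::runif(1) < cpgBias) {
      chars[p] <- if (b == "C") "T" else "A"
    } else {
      chars[p] <- sample(setdiff(.BASES, b), 1L)
    }
  }
  chars
}

# Draw mutated positions for one clone: spacers/flanks at `rate`, 5.8S at a
# tenth of it, fully constrained sites never (functional model), or every
# site at `rate` (pseudogene model).
.drawSites <- function(L, rate, s58Range, constrained, protect) {
  if (rate <= 0) return(integer(0))
  u <- stats::runif(L)
  if (protect) {
    inS58 <- seq(s58Range[1L], s58Range[2L])
    thr <- rep(rate, L)
    thr[inS58] <- rate * 0.1
    thr[constrained] <- 0
    which(u < thr)
  } else {
    which(u < rate)
  }
}

#' Simulate a labelled set of cloned ITS sequences
#'
#' Generates the data structure the screen assumes: per-sample ancestral
#' haplotypes diverged from a common root (neutral spacer divergence;
#' 5.8S held at a tenth of the spacer rate with motif and forced-pair sites
#' fully protected, i.e. purifying selection), from which each clone is
#' drawn as
#' \itemize{
#'   \item functional: substitutions at \code{baseRate} on unconstrained
#'     sites only;
#'   \item pseudogene: substitutions at \code{baseRate * pseudoRateMultiplier}
#'     over all sites with CpG-deamination bias (GC erosion), plus optional
#'     explicit motif lesions, helix-pair disruptions, and geometric
#'     deletions (mean 8 bp; deletions only, so the true alignment is the
#'     ancestral coordinate frame);
#'   \item recombinant: two distinct sample ancestors spliced at a recorded
#'     breakpoint, then functional-style noise.
#' }
#' Class counts are deterministic (round(n * fraction)) and assigned to
#' random clone slots; every emitted clone has exactly one truth record.
#'
#' @param nSamples,clonesPerSample Sampling design (default 10 x 10).
#' @param baseRate Substitutions/site for functional copies (default 0.005).
#' @param pseudoRateMultiplier Rate multiplier for pseudogenes (default 5).
#' @param cpgTransitionBias Probability that a substitution hitting a CpG/GpC
#'   context is the deamination change C->T or G->A (default 0.8).
#' @param pseudoFraction,recombinantFraction Class fractions (defaults 0.3
#'   and 0.05; their sum must not exceed 1).
#' @param indelRate Expected deletions per pseudogene clone (Poisson,
#'   default 0.2); deletion lengths are 1 + Geometric(mean 7) bp.
#' @param lineageRate Spacer substitutions/site between each sample ancestor
#'   and the root (default 0.03).
#' @param motifLesionProb,helixLesionProb Per-pseudogene probability of an
#'   explicit motif substitution lesion / forced-pair disruption
#'   (defaults 0.4).
#' @param largeDeletionProb Per-pseudogene probability of one 50-140 bp
#'   deletion, emulating the large deletions seen in decayed copies
#'   (default 0).
#' @param seed Mandatory integer seed; identical seeds give byte-identical
#'   output.
#' @return A \code{\link{SimulatedCloneSet}}.
#' @examples
#' sim <- simulateCloneSet(nSamples = 2, clonesPerSample = 5, seed = 1)
#' table(simTruth(sim)$label)
#' @export
simulateCloneSet <- function(nSamples = 10L, clonesPerSample = 10L,
                             baseRate = 0.005, pseudoRateMultiplier = 5,
                             cpgTransitionBias = 0.8, pseudoFraction = 0.3,
                             recombinantFraction = 0.05, indelRate = 0.2,
                             lineageRate = 0.03, motifLesionProb = 0.4,
                             helixLesionProb = 0.4, largeDeletionProb = 0,
                             seed) {
  if (missing(seed)) stop("a seed is mandatory for simulateCloneSet()")
  stopifnot(nSamples >= 1L, clonesPerSample >= 1L, baseRate >= 0,
            pseudoRateMultiplier >= 0, indelRate >= 0, lineageRate >= 0,
            cpgTransitionBias >= 0, cpgTransitionBias <= 1,
            pseudoFraction >= 0, pseudoFraction <= 1,
            recombinantFraction >= 0, recombinantFraction <= 1)
  if (pseudoFraction + recombinantFraction > 1)
    stop("contradictory parameters: pseudoFraction + recombinantFraction > 1")

  unitInfo <- makeReferenceUnit(seed)
  set.seed(seed + 1L)
  root <- .chars(unitInfo$unit)
  L <- length(root)
  s58Range <- unitInfo$regions$S58
  constrained <- unitInfo$constrained
  hc <- helixConstraints()
  motifs <- motifDefs()
  motifOff <- .motifOffsets(unitInfo$refs)

  ancestors <- lapply(seq_len(nSamples), function(s) {
    pos <- .drawSites(L, lineageRate, s58Range, constrained, protect = TRUE)
    .mutateChars(root, pos, cpgBias = 0)
  })

  nTotal <- nSamples * clonesPerSample
  nRec <- round(nTotal * recombinantFraction)
  nPseudo <- round(nTotal * pseudoFraction)
  labels <- rep("functional", nTotal)
  slots <- sample.int(nTotal, nRec + nPseudo)
  if (nRec > 0L) labels[slots[seq_len(nRec)]] <- "recombinant"
  if (nPseudo > 0L) labels[slots[nRec + seq_len(nPseudo)]] <- "pseudogene"

  alnRows <- character(nTotal)
  truth <- vector("list", nTotal)
  idx <- 0L
  for (s in seq_len(nSamples)) {
    sID <- paste0("S", s)
    anc <- ancestors[[s]]
    for (cl in seq_len(clonesPerSample)) {
      idx <- idx + 1L
      cloneID <- paste0(sID, "-", cl)
      label <- labels[idx]
      lesions <- character(0)
      parentA <- NA_character_; parentB <- NA_character_
      breakpoint <- NA_integer_
      nDel <- 0L

      if (label == "recombinant") {
        pr <- if (nSamples >= 2L) sample(setdiff(seq_len(nSamples), s), 1L)
              else s
        breakpoint <- sample(150:(L - 150L), 1L)
        chars <- c(anc[seq_len(breakpoint)],
                   ancestors[[pr]][(breakpoint + 1L):L])
        parentA <- paste0("anc:S", s)
        parentB <- paste0("anc:S", pr)
        pos <- .drawSites(L, baseRate, s58Range, constrained, protect = TRUE)
        chars <- .mutateChars(chars, pos, cpgBias = 0)
      } else if (label == "pseudogene") {
        rate <- baseRate * pseudoRateMultiplier
        pos <- .drawSites(L, rate, s58Range, constrained, protect = FALSE)
        chars <- .mutateChars(anc, pos, cpgBias = cpgTransitionBias)
        if (stats::runif(1) < motifLesionProb) {
          m <- sample(names(motifs), 1L)
          nHit <- sample(1:2, 1L)
          hit <- sort(sample.int(nchar(motifs[[m]]), nHit))
          for (h in hit) {
            up <- s58Range[1L] - 1L + motifOff[[m]] + h - 1L
            chars[up] <- sample(setdiff(.BASES, chars[up]), 1L)
          }
          lesions <- c(lesions,
                       paste0("motif:", m, "@", paste(hit, collapse = ",")))
        }
        if (stats::runif(1) < helixLesionProb) {
          hName <- sample(.HELIX_NAMES, 1L)
          blocks <- hc[hc$helix == hName, , drop = FALSE]
          b <- blocks[sample.int(nrow(blocks), 1L), ]
          t <- sample.int(b$k, 1L) - 1L
          iPos <- s58Range[1L] - 1L + b$i + t
          jPos <- s58Range[1L] - 1L + b$j - t
          partner <- chars[iPos]
          bad <- .BASES[!vapply(.BASES, function(x)
            .isPairing(partner, x), logical(1))]
          bad <- setdiff(bad, chars[jPos])
          if (length(bad)) {
            chars[jPos] <- sample(bad, 1L)
            lesions <- c(lesions, paste0("helix:", hName))
          }
        }
        nDel <- stats::rpois(1L, indelRate)
        delLens <- if (nDel > 0L) 1L + stats::rgeom(nDel, 1 / 8) else integer(0)
        if (stats::runif(1) < largeDeletionProb) {
          delLens <- c(delLens, sample(50:140, 1L))
          nDel <- nDel + 1L
        }
        for (dl in delLens) {
          dl <- min(dl, L - 1L)
          start <- sample.int(L - dl + 1L, 1L)
          chars[start:(start + dl - 1L)] <- "-"
        }
      } else {
        pos <- .drawSites(L, baseRate, s58Range, constrained, protect = TRUE)
        chars <- .mutateChars(anc, pos, cpgBias = 0)
      }

      alnRows[idx] <- paste(chars, collapse = "")
      truth[[idx]] <- data.frame(
        cloneID = cloneID, sampleID = sID, label = label,
        parentA = parentA, parentB = parentB, breakpoint = breakpoint,
        lesions = paste(lesions, collapse = ";"), nDeletions = nDel,
        stringsAsFactors = FALSE)
    }
  }

  truth <- do.call(rbind, truth)
  alignment <- Biostrings::DNAStringSet(alnRows)
  names(alignment) <- truth$cloneID
  clones <- ItsCloneSet(stats::setNames(.degap(alnRows), truth$cloneID),
                        sampleID = truth$sampleID)
  params <- list(nSamples = nSamples, clonesPerSample = clonesPerSample,
                 baseRate = baseRate,
                 pseudoRateMultiplier = pseudoRateMultiplier,
                 cpgTransitionBias = cpgTransitionBias,
                 pseudoFraction = pseudoFraction,
                 recombinantFraction = recombinantFraction,
                 indelRate = indelRate, lineageRate = lineageRate,
                 motifLesionProb = motifLesionProb,
                 helixLesionProb = helixLesionProb,
                 largeDeletionProb = largeDeletionProb, seed = seed)
  methods::new("SimulatedCloneSet", clones = clones, alignment = alignment,
               truth = truth, refs = unitInfo$refs,
               regions = unitInfo$regions, params = params)
}

#' F/P class labels from simulation truth
#'
#' Maps truth labels to the diversity-contrast classes: functional -> "F",
#' pseudogene -> "P"; recombinants get NA (excluded), since a chimera belongs
#' to neither diversity class.
#'
#' @param sim A \code{\link{SimulatedCloneSet}}.
#' @return Named character vector over c("F", "P", NA).
#' @export
truthClassLabels <- function(sim) {
  tr <- simTruth(sim)
  lab <- c(functional = "F", pseudogene = "P",
           recombinant = NA_character_)[tr$label]
  stats::setNames(unname(lab), tr$cloneID)
}

#' Simulate an aligned (child, parentA, parentB) triplet
#'
#' Fixture generator for the recombination test: three lineages diverge
#' independently from a common root at \code{divergence} substitutions/site
#' (pairwise divergence is therefore about twice that).  With
#' \code{breakpoint = NULL} the child is a clean third lineage -- the null
#' situation of a non-recombinant clone evaluated against two candidate
#' parents, under which the informative-site labels are exchangeable.  With
#' a breakpoint, the child is parent A up to that column and parent B after
#' it, plus \code{childNoise} substitutions/site of post-recombination
#' noise.
#'
#' @param length Alignment length (default 700).
#' @param divergence Per-lineage substitutions/site from the root
#'   (default 0.03).
#' @param breakpoint NULL for a clean child; an alignment column (or
#'   "random", drawn uniformly from the middle of the alignment) for a
#'   chimera.
#' @param childNoise Substitutions/site added to the child (default 0.002).
#' @param seed Integer seed.
#' @return list(child, parentA, parentB, breakpoint) of aligned character
#'   sequences.
#' @export
simulateTriplet <- function(length = 700L, divergence = 0.03,
                            breakpoint = NULL, childNoise = 0.002,
                            seed = 1L) {
  set.seed(seed)
  root <- sample(.BASES, length, replace = TRUE)
  mut <- function(x, r) .mutateChars(x, which(stats::runif(length) < r), 0)
  a <- mut(root, divergence)
  b <- mut(root, divergence)
  if (is.null(breakpoint)) {
    ch <- mut(root, divergence)
    bp <- NA_integer_
  } else {
    bp <- if (identical(breakpoint, "random")) {
      sample(seq(ceiling(length * 0.2), floor(length * 0.8)), 1L)
    } else as.integer(breakpoint)
    ch <- c(a[seq_len(bp)], b[(bp + 1L):length])
  }
  ch <- mut(ch, childNoise)
  list(child = paste(ch, collapse = ""),
       parentA = paste(a, collapse = ""),
       parentB = paste(b, collapse = ""),
       breakpoint = bp)
}

#' Build an alignment with exact variable / parsimony-informative counts
#'
#' Emits an alignment with exactly \code{nVariable} variable columns of which
#' exactly \code{nPI} are parsimony informative: PI columns carry a 2+2 (or
#' 2 + rest) base split, variable-but-not-PI columns a singleton difference,
#' and all remaining columns are constant.  Column positions and base
#' identities are randomised from the seed.
#'
#' @param length Alignment length (columns).
#' @param nVariable Number of variable columns (<= length).
#' @param nPI Number of parsimony-informative columns (<= nVariable).
#' @param nSeqs Number of sequences (>= 4).
#' @param seed Integer seed.
#' @return A named character vector alignment (one element per sequence).
#' @examples
#' aln <- makeCountFixture(808, 546, 442, 8, seed = 1)
#' countSiteClasses(aln)[c("S", "PI")]
#' @export
makeCountFixture <- function(length, nVariable, nPI, nSeqs = 8L, seed = 1L) {
  if (nPI > nVariable || nVariable > length)
    stop("infeasible counts: need nPI <= nVariable <= length")
  if (nSeqs < 4L) stop("need at least 4 sequences")
  set.seed(seed)
  m <- matrix("", nSeqs, length)
  for (col in seq_len(length)) m[, col] <- sample(.BASES, 1L)
  varCols <- sample.int(length, nVariable)
  piCols <- varCols[seq_len(nPI)]
  singleCols <- setdiff(varCols, piCols)
  for (col in piCols) {
    alt <- sample(setdiff(.BASES, m[1L, col]), 1L)
    rows <- sample.int(nSeqs, 2L)
    m[rows, col] <- alt
  }
  for (col in singleCols) {
    alt <- sample(setdiff(.BASES, m[1L, col]), 1L)
    m[sample.int(nSeqs, 1L), col] <- alt
  }
  stats::setNames(apply(m, 1L, paste, collapse = ""),
                  paste0("seq", seq_len(nSeqs)))
}

#' Write a simulated clone set to disk
#'
#' Emits the clone FASTA, the true alignment FASTA, the truth TSV, and a JSON
#' echo of the parameters.
#'
#' @param sim A \code{\link{SimulatedCloneSet}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulatedCloneSet <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(clones = file.path(dir, "clones.fasta"),
             alignment = file.path(dir, "alignment.fasta"),
             truth = file.path(dir, "truth.tsv"),
             params = file.path(dir, "params.json"))
  Biostrings::writeXStringSet(cloneSeqs(simClones(sim)), paths[["clones"]])
  Biostrings::writeXStringSet(simAlignment(sim), paths[["alignment"]])
  utils::write.table(simTruth(sim), paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(simParams(sim), paths[["params"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
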