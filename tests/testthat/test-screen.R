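unitS <- makeReferenceUnit(seed = 2)
refsS <- unitS$refs

test_that("gcContent matches the definition and an independent tally", {
  expect_equal(gcContent("GCGC"), 100)
  expect_equal(gcContent("ATATAT"), 0)
  expect_error(gcContent("NNNN"), "zero unambiguous")
  set.seed(31)
  for (i in 1:5) {
    s <- randomDNA(300)
    expect_equal(gcContent(s), bfGC(s))
  }
  # ambiguity codes excluded from numerator and denominator
  expect_equal(gcContent("GCNNRY"), 100)
  # reverse-complement invariance
  s <- randomDNA(200)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(gcContent(s), gcContent(rc))
})

test_that("flagLowGC applies the median-minus-delta rule within samples", {
  prof <- data.frame(cloneID = paste0("c", 1:4), sampleID = "s1",
                     ITS2 = c(65.1, 65.3, 64.9, 55.0), check.names = FALSE)
  fl <- flagLowGC(prof, deltaPP = 2)
  expect_identical(unname(fl[, "ITS2"]), c(FALSE, FALSE, FALSE, TRUE))

  prof2 <- data.frame(cloneID = paste0("c", 1:4), sampleID = "s1",
                      ITS2 = rep(60, 4), check.names = FALSE)
  expect_false(any(flagLowGC(prof2, deltaPP = 2)))

  # two-pass: unclean clones do not define the baseline
  prof3 <- data.frame(cloneID = paste0("c", 1:4), sampleID = "s1",
                      ITS2 = c(65, 65, 55, 55), check.names = FALSE)
  fl3 <- flagLowGC(prof3, clean = c(TRUE, TRUE, FALSE, FALSE), deltaPP = 2)
  expect_identical(unname(fl3[, "ITS2"]), c(FALSE, FALSE, TRUE, TRUE))
})

test_that("scanMotif reports substitutions in paper notation", {
  ref <- refsS@ref58
  # exact motif present anywhere -> conserved irrespective of context
  m1 <- motifDefs()[["M1"]]
  expect_identical(scanMotif(paste0("TTTT", m1, "AAAA"), "M1", refsS)$status,
                   "conserved")
  expect_identical(scanMotif(ref, "M1", refsS)$status, "conserved")

  # substitution at motif position 12 -> "nt-12"
  mutate58 <- function(s58, motif, posInMotif) {
    o <- as.integer(regexpr(motifDefs()[[motif]], s58))
    ch <- strsplit(s58, "")[[1]]
    for (p in posInMotif) {
      ch[o + p - 1] <- setdiff(c("A", "C", "G", "T"), ch[o + p - 1])[1]
    }
    paste(ch, collapse = "")
  }
  r1 <- scanMotif(mutate58(ref, "M1", 12), "M1", refsS)
  expect_identical(r1$status, "changed")
  expect_identical(r1$label, "nt-12")

  # two substitutions at M2 positions 7 and 12 -> "nt-7,12"
  r2 <- scanMotif(mutate58(ref, "M2", c(7, 12)), "M2", refsS)
  expect_identical(r2$label, "nt-7,12")
})

test_that("scanMotif reports missing spans for deletions and truncations", {
  ref <- refsS@ref58
  o1 <- as.integer(regexpr(motifDefs()[["M1"]], ref))
  # delete M1 positions 4..16 -> "missing 4-16"
  del <- paste0(substr(ref, 1, o1 + 2), substr(ref, o1 + 16, nchar(ref)))
  r <- scanMotif(del, "M1", refsS)
  expect_identical(r$status, "partially_missing")
  expect_identical(r$label, "missing 4-16")

  # truncation removing all of M3 -> all missing
  o3 <- as.integer(regexpr(motifDefs()[["M3"]], ref))
  trunc <- substr(ref, 1, o3 - 1)
  r3 <- scanMotif(trunc, "M3", refsS)
  expect_identical(r3$status, "all_missing")
  expect_identical(r3$label, "all missing")
})

test_that("checkHelices matches brute-force pair enumeration on mutants", {
  expect_identical(checkHelices(refsS@ref58, refsS)$pattern, "XXXXX")

  # disrupting both blocks of B8 flips only B8
  ch <- strsplit(refsS@ref58, "")[[1]]
  nonPartner <- function(partner) {
    bad <- c("A", "C", "G", "T")
    bad[!paste0(partner, bad) %in%
          c("AT", "TA", "CG", "GC", "GT", "TG")][1]
  }
  hc <- helixConstraints()
  b8 <- hc[hc$helix == "B8", ]
  for (r in seq_len(nrow(b8))) ch[b8$j[r]] <- nonPartner(ch[b8$i[r]])
  expect_identical(checkHelices(paste(ch, collapse = ""), refsS)$pattern,
                   "XXXX-")

  # 200 seeded random mutants vs the brute-force checker (ungapped mutants,
  # so reference coordinates map 1:1)
  set.seed(13)
  refCh <- strsplit(refsS@ref58, "")[[1]]
  for (i in 1:200) {
    mut <- refCh
    pos <- sample(160, sample(1:8, 1))
    for (p in pos) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1)
    got <- checkHelices(paste(mut, collapse = ""), refsS)$pattern
    expect_identical(got, bfHelixPattern(mut))
  }
})

test_that("classifyClones combines the three evidence streams (OR policy)", {
  unit <- unitS
  r <- unit$regions
  base <- unit$unit
  ch <- strsplit(base, "")[[1]]

  # clone with GC-only evidence: deaminate many ITS2 C/G sites
  its2pos <- seq(r$ITS2[1], r$ITS2[2])
  low <- ch
  gcPos <- its2pos[low[its2pos] %in% c("C", "G")]
  set.seed(4)
  hit <- sample(gcPos, 25)
  low[hit] <- ifelse(low[hit] == "C", "T", "A")

  # clone with motif evidence only: M1 deletion 4-16 plus M2 destroyed
  o1 <- r$S58[1] - 1 + as.integer(regexpr(motifDefs()[["M1"]], unit$refs@ref58))
  mot <- ch[-(seq(o1 + 3, o1 + 15))]

  seqs <- c("S1-1" = base, "S1-2" = base, "S1-3" = base,
            "S1-4" = paste(low, collapse = ""),
            "S1-5" = paste(mot, collapse = ""))
  x <- delimitRegions(ItsCloneSet(seqs), unit$refs)
  ev <- classifyClones(x, unit$refs)

  expect_identical(ev$verdict[1:3], rep("functional", 3))
  # GC-only pseudogene: motifs conserved, helices intact, flagged on GC alone
  expect_identical(ev$verdict[4], "pseudogene")
  expect_identical(unname(unlist(ev[4, c("M1", "M2", "M3")])),
                   rep("conserved", 3))
  expect_identical(ev$helixPattern[4], "XXXXX")
  expect_true(ev$flagITS2[4])
  # motif-lesion pseudogene
  expect_identical(ev$verdict[5], "pseudogene")
  expect_match(ev$M1[5], "missing")
})

test_that("verdicts are monotone: extra lesions never rescue a pseudogene", {
  sim <- simulateCloneSet(nSamples = 3, clonesPerSample = 5, seed = 21)
  x <- delimitRegions(simClones(sim), referenceSet(sim))
  ev1 <- classifyClones(x, referenceSet(sim))
  pseudo <- ev1$cloneID[ev1$verdict == "pseudogene"]
  expect_gt(length(pseudo), 0)
  # add a further motif lesion to every clone and re-screen
  seqs <- as.character(cloneSeqs(x))
  p <- partitions(x)
  o2 <- as.integer(regexpr(motifDefs()[["M2"]], referenceSet(sim)@ref58))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    pos <- p$s58Start[i] - 1 + o2 + 5
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    seqs[i] <- paste(ch, collapse = "")
  }
  x2 <- delimitRegions(ItsCloneSet(setNames(seqs, cloneIDs(x)),
                                   sampleID = unname(sampleIDs(x))),
                       referenceSet(sim))
  ev2 <- classifyClones(x2, referenceSet(sim))
  expect_true(all(ev2$verdict[match(pseudo, ev2$cloneID)] == "pseudogene"))
})

test_that("evidence table renders and round-trips", {
  sim <- simulateCloneSet(nSamples = 2, clonesPerSample = 5, seed = 8)
  x <- delimitRegions(simClones(sim), referenceSet(sim))
  ev <- classifyClones(x, referenceSet(sim))
  path <- tempfile(fileext = ".tsv")
  renderEvidenceTable(ev, path)
  back <- parseEvidenceTable(path)
  expect_identical(back$cloneID, ev$cloneID)
  expect_equal(back$gcITS1, ev$gcITS1)
  expect_equal(back$gc58S, ev$gc58S)
  expect_identical(back$flagITS2, ev$flagITS2)
  expect_identical(back$M1, ev$M1)
  expect_identical(back$helixPattern, ev$helixPattern)
  expect_identical(back$verdict, ev$verdict)
  # empty input -> header-only
  expect_length(renderEvidenceTable(ev[0, ]), 1L)
})
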