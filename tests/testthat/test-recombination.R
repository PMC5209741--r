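cfgFast <- scanConfig(permutations = 200, seed = 9)

test_that("similarity profile tracks identity and masks sparse windows", {
  trip <- simulateTriplet(length = 300, divergence = 0.05,
                          childNoise = 0, seed = 3)
  # child identical to parent A
  prof <- similarityProfile(trip$parentA, trip$parentA, trip$parentB)
  expect_true(all(prof$idA[!prof$maskedA] == 100))

  # constructed chimera: identity to A high then low, crossing near the
  # breakpoint
  trip2 <- simulateTriplet(length = 300, divergence = 0.05,
                           breakpoint = 150, childNoise = 0, seed = 4)
  prof2 <- similarityProfile(trip2$child, trip2$parentA, trip2$parentB)
  left <- prof2$windowCenter < 120
  right <- prof2$windowCenter > 180
  expect_gt(mean(prof2$idA[left]), mean(prof2$idB[left]))
  expect_lt(mean(prof2$idA[right]), mean(prof2$idB[right]))

  # identical parents -> profiles coincide, no discontinuity callable
  prof3 <- similarityProfile(trip$child, trip$parentA, trip$parentA)
  expect_equal(prof3$idA, prof3$idB)

  # heavily gapped windows are masked
  gappy <- paste(rep("-", 300), collapse = "")
  expect_error(similarityProfile(gappy, trip$parentA, trip$parentB),
               "masked")
})

test_that("maxChi matches exhaustive split enumeration on a toy", {
  # 40 informative sites constructed directly: parents differ everywhere,
  # child switches parent at site 23
  set.seed(77)
  pa <- strsplit(strrep("A", 40), "")[[1]]
  pb <- strsplit(strrep("C", 40), "")[[1]]
  ch <- c(pa[1:23], pb[24:40])
  flip <- sample(40, 6)  # noise labels
  ch[flip] <- ifelse(ch[flip] == "A", "C", "A")
  rep <- maxChiBreakpoint(paste(ch, collapse = ""), paste(pa, collapse = ""),
                          paste(pb, collapse = ""), cfgFast, profile = FALSE)
  labels <- as.integer(ch == pa)
  w <- min(cfgFast$maxchiWindow, length(labels) %/% 2)
  expect_equal(rep$maxChi2, bfMaxChi(labels, w), tolerance = 1e-12)
})

test_that("clean and degenerate triplets come back clean", {
  trip <- simulateTriplet(length = 400, divergence = 0.04, childNoise = 0,
                          seed = 5)
  # child identical to parent A: every informative site matches A, the
  # statistic is flat and the verdict clean
  rep <- maxChiBreakpoint(trip$parentA, trip$parentA, trip$parentB, cfgFast,
                          profile = FALSE)
  expect_identical(rep$verdict, "clean")
  expect_equal(rep$maxChi2, 0)

  # nearly identical parents leave too few informative sites to test
  trip2 <- simulateTriplet(length = 400, divergence = 0.002, childNoise = 0,
                           seed = 5)
  rep2 <- maxChiBreakpoint(trip2$parentA, trip2$parentA, trip2$parentB,
                           cfgFast, profile = FALSE)
  expect_identical(rep2$verdict, "clean")
  expect_identical(rep2$reason, "insufficient signal")
})

test_that("swapping parents mirrors the profile but not the test", {
  trip <- simulateTriplet(length = 500, divergence = 0.05, breakpoint = 250,
                          seed = 6)
  r1 <- maxChiBreakpoint(trip$child, trip$parentA, trip$parentB, cfgFast)
  r2 <- maxChiBreakpoint(trip$child, trip$parentB, trip$parentA, cfgFast)
  expect_equal(r1$maxChi2, r2$maxChi2, tolerance = 1e-12)
  expect_equal(r1$pValue, r2$pValue)
  expect_equal(r1$breakpoint, r2$breakpoint)
  expect_equal(r1$profile$idA, r2$profile$idB)
  # adding columns where the parents agree changes nothing
  pad <- strrep("G", 60)
  r3 <- maxChiBreakpoint(paste0(trip$child, pad),
                         paste0(trip$parentA, pad),
                         paste0(trip$parentB, pad), cfgFast,
                         profile = FALSE)
  expect_equal(r3$maxChi2, r1$maxChi2, tolerance = 1e-12)
  expect_equal(r3$pValue, r1$pValue)
})

test_that("determinism: identical config and seed give identical reports", {
  trip <- simulateTriplet(length = 500, divergence = 0.05, breakpoint = 200,
                          seed = 10)
  r1 <- maxChiBreakpoint(trip$child, trip$parentA, trip$parentB, cfgFast)
  r2 <- maxChiBreakpoint(trip$child, trip$parentA, trip$parentB, cfgFast)
  expect_identical(r1[setdiff(names(r1), "profile")],
                   r2[setdiff(names(r2), "profile")])
})

test_that("scanRecombinants finds planted chimeras and nothing else on identical clones", {
  # mutually identical clones: everything clean
  same <- setNames(rep(randomDNA(200), 5), paste0("c", 1:5))
  res0 <- scanRecombinants(same, cfgFast)
  expect_true(all(res0$verdict == "clean"))

  sim <- simulateCloneSet(nSamples = 6, clonesPerSample = 5,
                          pseudoFraction = 0.2, recombinantFraction = 0.1,
                          seed = 3)
  tr <- simTruth(sim)
  planted <- tr$cloneID[tr$label == "recombinant"]
  expect_equal(length(planted), 3L)
  aln <- setNames(as.character(simAlignment(sim)), names(simAlignment(sim)))
  res <- scanRecombinants(aln, scanConfig(seed = 11))
  called <- res$child[res$verdict == "recombinant"]
  expect_true(all(planted %in% called))
  # the planted chimeras carry the smallest p-values
  ord <- res$child[order(res$pRaw)]
  expect_setequal(ord[1:3], planted)
  # determinism contract
  res2 <- scanRecombinants(aln, scanConfig(seed = 11))
  expect_identical(res, res2)
})
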