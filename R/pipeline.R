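.inputError <- function(...) {
  stop(structure(class = c("itsscreen_input_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Run the full screening pipeline
#'
#' Wires the stages in order delimit -> screen -> diversity -> recomb and
#' writes machine-readable artifacts to \code{outDir}: partitions TSV
#' (BED-like), evidence TSV, diversity TSV, recombination TSV, a JSON
#' summary, and a MANIFEST recording the completion state of each stage.
#' Every TSV artifact starts with a comment header echoing the package
#' version and configuration.
#'
#' Inputs are either files (\code{fasta} + optional \code{sampleMap},
#' optional \code{aligned} FASTA for the diversity and recombination stages)
#' or, with \code{simulate = TRUE}, a simulated clone set generated from
#' \code{simArgs} and \code{seed}, whose exact alignment and truth labels
#' feed the downstream stages.  When no class labels are available the
#' screen's own verdicts (F = functional, P = pseudogene) label the
#' diversity contrast.
#'
#' @param outDir Output directory (created).
#' @param fasta,sampleMap,aligned Input paths (see above).
#' @param labels Optional named F/P vector for the diversity contrast.
#' @param refs A \code{\link{ReferenceSet}}; defaults to the packaged
#'   synthetic reference (\code{makeReferenceUnit(1)}), which is only
#'   meaningful for simulated data -- supply a real reference for real
#'   clones.
#' @param seed Seed for stochastic stages (simulation, permutation null).
#' @param simulate Generate the inputs with \code{\link{simulateCloneSet}}.
#' @param simArgs List of arguments for the generator.
#' @param stages Character subset of c("delimit", "screen", "diversity",
#'   "recomb") to run (always executed in that order).
#' @param deltaPP,minCriteria Screen policy, see
#'   \code{\link{classifyClones}}.
#' @param config A \code{\link{scanConfig}} for the recombination stage.
#' @return Invisibly, the summary list (also written as summary.json).
#' @export
runPipeline <- function(outDir, fasta = NULL, sampleMap = NULL,
                        aligned = NULL, labels = NULL, refs = NULL,
                        seed = 1L, simulate = FALSE, simArgs = list(),
                        stages = c("delimit", "screen", "diversity",
                                   "recomb"),
                        deltaPP = 2, minCriteria = 1,
                        config = scanConfig(seed = seed)) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(outDir, "MANIFEST")
  note <- function(stage, state) {
    cat(sprintf("%s\t%s\n", stage, state), file = manifest, append = TRUE)
  }
  cat("# ITSscreen pipeline manifest\n", file = manifest)

  version <- as.character(utils::packageVersion("ITSscreen"))
  hdr <- sprintf("# ITSscreen %s | seed=%d | deltaPP=%g | minCriteria=%d",
                 version, as.integer(seed), deltaPP, as.integer(minCriteria))
  writeTSV <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }

  regions <- NULL
  truth <- NULL
  if (simulate) {
    sim <- do.call(simulateCloneSet, c(simArgs, list(seed = seed)))
    clones <- simClones(sim)
    alnSet <- stats::setNames(as.character(simAlignment(sim)),
                              names(simAlignment(sim)))
    refs <- referenceSet(sim)
    rr <- regionRanges(sim)
    regions <- list(ITS1 = rr$ITS1, `5.8S` = rr$S58, ITS2 = rr$ITS2,
                    ITS = rr$ITS)
    truth <- simTruth(sim)
    if (is.null(labels)) labels <- truthClassLabels(sim)
    writeSimulatedCloneSet(sim, file.path(outDir, "simulated"))
    note("simulate", "done")
  } else {
    if (is.null(fasta)) .inputError("no input FASTA given")
    if (!file.exists(fasta)) .inputError("input FASTA not found: ", fasta)
    sz <- file.size(fasta)
    clones <- tryCatch(readClones(fasta, sampleMap),
                       error = function(e) .inputError(conditionMessage(e)))
    alnSet <- NULL
    if (!is.null(aligned)) {
      if (!file.exists(aligned))
        .inputError("aligned FASTA not found: ", aligned)
      a <- Biostrings::readDNAStringSet(aligned)
      alnSet <- stats::setNames(as.character(a),
                                sub("\\s.*$", "", names(a)))
    }
    if (is.null(refs)) refs <- makeReferenceUnit(1L)$refs
  }

  summary <- list(package = paste0("ITSscreen ", version),
                  seed = as.integer(seed),
                  nClones = length(clones),
                  nSamples = length(unique(sampleIDs(clones))))
  cd <- collapseDistinct(clones)
  summary$nDistinct <- cd$nDistinct

  evidence <- NULL
  if ("delimit" %in% stages) {
    clones <- tryCatch(delimitRegions(clones, refs), error = function(e) {
      note("delimit", "failed")
      stop(e)
    })
    writeTSV(writePartitions(clones), file.path(outDir, "partitions.tsv"))
    rls <- regionLengthSummary(clones)
    summary$regionLengths <- stats::setNames(
      lapply(seq_len(nrow(rls)), function(i) c(rls$min[i], rls$max[i])),
      rls$region)
    note("delimit", "done")
  }

  if ("screen" %in% stages) {
    if (!nrow(clones@partition)) {
      note("screen", "skipped (no partition)")
    } else {
      evidence <- classifyClones(clones, refs, deltaPP = deltaPP,
                                 minCriteria = minCriteria)
      con <- file(file.path(outDir, "evidence.tsv"), "w")
      writeLines(hdr, con)
      writeLines(renderEvidenceTable(evidence), con)
      close(con)
      summary$nPseudogenes <- sum(evidence$verdict == "pseudogene")
      reasonTypes <- sub(":.*$", "",
                         unlist(strsplit(evidence$reasons[
                           evidence$reasons != ""], ";")))
      summary$reasonHistogram <- as.list(table(reasonTypes))
      if (is.null(labels) && !is.null(evidence)) {
        labels <- stats::setNames(
          ifelse(evidence$verdict == "pseudogene", "P", "F"),
          evidence$cloneID)
      }
      note("screen", "done")
    }
  }

  if ("diversity" %in% stages) {
    if (is.null(alnSet) || is.null(labels)) {
      note("diversity", "skipped (no alignment or labels)")
    } else {
      div <- classContrast(alnSet, labels, regions = regions)
      writeTSV(div, file.path(outDir, "diversity.tsv"))
      summary$diversity <- lapply(seq_len(nrow(div)), function(i) {
        as.list(div[i, ])
      })
      note("diversity", "done")
    }
  }

  if ("recomb" %in% stages) {
    if (is.null(alnSet)) {
      note("recomb", "skipped (no alignment)")
    } else {
      rec <- scanRecombinants(alnSet, config)
      writeTSV(rec, file.path(outDir, "recombination.tsv"))
      summary$nRecombinants <- sum(rec$verdict == "recombinant")
      note("recomb", "done")
    }
  }

  if (!is.null(truth)) {
    summary$truthCounts <- as.list(table(truth$label))
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(summary)
}

#' Summarise pipeline artifacts
#'
#' Re-reads the artifacts in a pipeline output directory and recomputes the
#' headline counts (clones, distinct clones, pseudogenes with a reason
#' histogram, recombinants, region length ranges), per sample and overall.
#'
#' @param outDir A directory written by \code{\link{runPipeline}}.
#' @return A list of summary counts.
#' @export
summarizeRun <- function(outDir) {
  evPath <- file.path(outDir, "evidence.tsv")
  recPath <- file.path(outDir, "recombination.tsv")
  sumPath <- file.path(outDir, "summary.json")
  out <- list()
  if (file.exists(sumPath)) out <- jsonlite::read_json(sumPath,
                                                       simplifyVector = TRUE)
  if (file.exists(evPath)) {
    ev <- parseEvidenceTable(evPath)
    out$nClones <- nrow(ev)
    out$nPseudogenes <- sum(ev$verdict == "pseudogene")
    out$perSample <- as.list(table(sampleFromCloneID(ev$cloneID)))
  }
  if (file.exists(recPath)) {
    rec <- utils::read.table(recPath, sep = "\t", header = TRUE,
                             comment.char = "#")
    out$nRecombinants <- sum(rec$verdict == "recombinant")
  }
  out
}
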