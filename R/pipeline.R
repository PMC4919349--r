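## Orchestration: one call reproducing the fixture-based survey
## accounting, and one call running the synthetic validation loop
## (simulate -> classify/compare -> score against truth).

#' Reproduce the survey accounting from the packaged fixtures
#'
#' Loads the fixture tables, summarizes the Osc homolog inventory, runs
#' pathway prediction and discrepancy analysis for every lipid-tested
#' strain, and aggregates cohort counts. Every number in the summary
#' block is recomputed from the fixtures at run time.
#'
#' @param fixtureDir Fixture directory (defaults to the packaged
#'   tables).
#' @param mode Pathway mode.
#' @return A list of class \code{"sterolscanReproduction"} with elements
#'   \code{fixtures}, \code{survey}, \code{profiles}, \code{reports},
#'   \code{cohort} and \code{summary}. The summary holds: total homolog
#'   records and counts per phylum/taxon group, the number of tested
#'   strains, the number of tested strains observing no cyclized sterol,
#'   the canonical C-4 demethylation family count, per-taxon zero-family
#'   C-4 orphan counts, per-strain C-4 family homolog counts, and
#'   compound prevalence among tested strains.
#' @examples
#' rep <- runPaperReproduction()
#' rep$summary$oscHomologTotal  # 34
#' @export
runPaperReproduction <- function(fixtureDir = system.file(
                                   "extdata", package = "sterolscan"),
                                 mode = c("canonical", "relaxed")) {
  mode <- match.arg(mode)
  fixtures <- loadFixtures(fixtureDir)
  survey <- surveySummary(fixtures$homologs)

  lipids <- fixtures$lipids
  tested <- lipids$strain_name[lipids$study_section == "this_study"]
  testedObserved <- lapply(setNames(tested, tested),
                           function(st) observedCompounds(lipids, st))
  noCyclized <- sum(vapply(testedObserved, function(obs)
    length(intersect(obs, cyclizedVocabulary())) == 0L, logical(1)))

  complements <- complementsFromTable(fixtures$complements, tested)
  profiles <- lapply(complements, reachableCompounds, mode = mode)
  reports <- compareAllStrains(fixtures, mode = mode)
  cohort <- cohortCounts(reports,
                         lipids[lipids$study_section == "this_study", ])

  c4Families <- requiredFamilies("C-4 demethylation", mode = "canonical")
  c4HomologCounts <- vapply(complements, function(cmp)
    length(intersect(presentFamilies(cmp), c4Families)), integer(1))

  groups <- cohort$groups
  summary <- list(
    oscHomologTotal = survey$total,
    homologsPerPhylum = survey$phylum,
    homologsPerTaxonGroup = survey$taxon_group,
    homologsPerEnvironment = survey$environment_class,
    testedStrains = length(tested),
    testedStrainsWithoutCyclizedSterols = noCyclized,
    c4DemethylationFamilyCount = length(c4Families),
    zeroFamilyC4OrphansPerGroup = setNames(
      groups$orphan_c4_zero_family, groups$taxon_group),
    c4HomologCountsPerStrain = c4HomologCounts,
    compoundPrevalence = cohort$prevalence,
    fullAgreementStrains = sum(groups$full_agreement),
    silentCapacityStrains = sum(groups$any_silent))

  structure(list(fixtures = fixtures, survey = survey, mode = mode,
                 profiles = profiles, reports = reports,
                 cohort = cohort, summary = summary),
            class = "sterolscanReproduction")
}

#' @export
print.sterolscanReproduction <- function(x, ...) {
  s <- x$summary
  cat("sterolscan fixture reproduction (", x$mode, " mode)\n", sep = "")
  cat("  Osc homolog records:", s$oscHomologTotal, "\n")
  cat("  tested strains:", s$testedStrains,
      "| without cyclized sterols:",
      s$testedStrainsWithoutCyclizedSterols, "\n")
  cat("  zero-family C-4 orphans per group:",
      paste(names(s$zeroFamilyC4OrphansPerGroup),
            s$zeroFamilyC4OrphansPerGroup, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Synthetic validation of the classifier and discrepancy analysis
#'
#' Runs the generators and scores recovery against their truth tables:
#' (1) simulates a cyclase family with pinned diagnostic residues,
#' classifies every member and every member's fragment, and reports
#' class-recovery accuracy for full-length members; (2) simulates a
#' strain cohort with injected orphan compounds and silent families and
#' reports exact precision/recall of the discrepancy flags against the
#' injections.
#'
#' @param seed Integer seed driving both simulations.
#' @param nFamily Family size.
#' @param divergence Divergence levels cycled over family members.
#' @param nStrains Cohort size.
#' @param orphanRate,silentRate Injection rates.
#' @return A list of class \code{"sterolscanValidation"} with elements
#'   \code{classifier} (accuracy, per-member calls) and \code{cohort}
#'   (precision/recall for orphan and silent flags).
#' @export
runSyntheticValidation <- function(seed = 1L, nFamily = 50,
                                   divergence = c(0.05, 0.2, 0.3),
                                   nStrains = 100, orphanRate = 0.2,
                                   silentRate = 0.2) {
  fam <- simulateFamily(n = nFamily,
                        divergence = rep_len(divergence, nFamily),
                        seed = seed)
  calls <- vapply(seq_along(fam$records), function(i)
    oscCall(classifyOsc(fam$records[i], fam$annotation)), character(1))
  accuracy <- mean(calls == fam$truth$class)

  cohort <- simulateCohort(nStrains = nStrains, orphanRate = orphanRate,
                           silentRate = silentRate, seed = seed)
  tag <- function(st, v)
    if (length(v)) paste(st, v, sep = ":") else character(0)
  foundOrphans <- character(0); foundSilent <- character(0)
  trueOrphans <- character(0); trueSilent <- character(0)
  for (st in names(cohort$observed)) {
    report <- compareProfile(cohort$observed[[st]],
                             cohort$complements[[st]],
                             mode = "canonical")
    foundOrphans <- c(foundOrphans,
                      tag(st, orphanModifications(report)$compound))
    foundSilent <- c(foundSilent, tag(st, silentCapacities(report)))
    tr <- cohort$truth[cohort$truth$strain == st, ]
    if (!is.na(tr$injected_orphan))
      trueOrphans <- c(trueOrphans, tag(st, tr$injected_orphan))
    if (!is.na(tr$injected_silent))
      trueSilent <- c(trueSilent, tag(st, tr$injected_silent))
  }
  pr <- function(found, truth) {
    tp <- length(intersect(found, truth))
    list(precision = if (length(found)) tp / length(found) else 1,
         recall = if (length(truth)) tp / length(truth) else 1,
         nFound = length(found), nTrue = length(truth),
         exact = setequal(found, truth))
  }
  structure(list(
    classifier = list(accuracy = accuracy, calls = calls,
                      truth = fam$truth),
    cohort = list(orphans = pr(foundOrphans, trueOrphans),
                  silent = pr(foundSilent, trueSilent)),
    seed = seed), class = "sterolscanValidation")
}

#' @export
print.sterolscanValidation <- function(x, ...) {
  cat("sterolscan synthetic validation (seed ", x$seed, ")\n", sep = "")
  cat("  classifier accuracy:", x$classifier$accuracy, "\n")
  cat(sprintf("  orphan flags: precision %.3f recall %.3f (n=%d)\n",
              x$cohort$orphans$precision, x$cohort$orphans$recall,
              x$cohort$orphans$nTrue))
  cat(sprintf("  silent flags: precision %.3f recall %.3f (n=%d)\n",
              x$cohort$silent$precision, x$cohort$silent$recall,
              x$cohort$silent$nTrue))
  invisible(x)
}
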