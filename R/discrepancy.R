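## Genotype-vs-lipid discrepancy analysis: which observed sterols could
## the genome's enzyme complement actually have produced, which observed
## modifications have no genetic explanation (orphans), and which present
## families leave no trace in the lipid profile (silent capacities).

# the reactions needed to produce a named cyclized compound, from its
# feature vector; returns reaction names in pathway order
neededReactions <- function(compound) {
  states <- namedCompoundStates(includeIntermediates = TRUE)
  if (!compound %in% names(states))
    stop("compound not nameable by the pathway model: ", compound)
  s <- states[[compound]]
  if (s@stage == "linear") return(character(0))
  needed <- "squalene oxygenation"
  if (s@stage == "epoxide") return(needed)
  cyclization <- if (s@cyclopropane) "oxidosqualene cyclization (CAS)"
  else if (s@delta9_11) "oxidosqualene cyclization (parkeol)"
  else "oxidosqualene cyclization (LAS)"
  needed <- c(needed, cyclization)
  if (!s@c14Methyl) needed <- c(needed, "C-14 demethylation")
  if (!s@c14Methyl && !s@delta14) needed <- c(needed, "C-14 reduction")
  if (s@c4Methyl < 2L) needed <- c(needed, "C-4 demethylation")
  if (!s@delta24) needed <- c(needed, "C-24(28) reduction")
  if (s@delta7) needed <- c(needed, "delta-8(9) to delta-7(8) isomerization")
  needed
}

# family sets of needed reactions, including the parkeol spectrum variant
reactionFamilyTable <- function() {
  reactions <- sterolReactions(parkeolSpectrum = TRUE,
                               includeIsomerization = TRUE)
  lapply(reactions, function(r) r[c("families", "anyOne")])
}

#' Compare an observed lipid profile with predicted capability
#'
#' Classifies every observed compound as an agreement (reachable under
#' the strain's enzyme complement) or an orphan modification (observed
#' but not reachable). Squalene and oxidosqualene are excluded from the
#' accounting — their observation carries no information about the
#' modeled enzymes. Each orphan is annotated with the smallest set of
#' absent families whose addition would make it reachable
#' (\code{\link{minimalMissingFamilies}}), the unsatisfied reaction
#' categories that cause it, and a zero-family flag set when some
#' causing reaction has no present member of its required family set at
#' all (the survey's strongest discrepancy: a modification with no
#' candidate gene whatsoever). Silent capacities are present families
#' that lie on no route from squalene to any observed compound.
#'
#' @param observed Character vector of observed compound names (from the
#'   controlled vocabulary).
#' @param complement An \code{\link{enzymeComplement}} or character
#'   vector of families.
#' @param mode \code{"canonical"} or \code{"relaxed"}.
#' @param strain Optional strain name; must match the complement's
#'   strain when both are given.
#' @param ... Reaction-set options, see \code{\link{sterolReactions}}.
#' @return A \code{\link{DiscrepancyReport-class}} object.
#' @examples
#' fx <- loadFixtures()
#' cmp <- complementsFromTable(fx$complements, "Fluviicola taffensis")[[1]]
#' compareProfile(observedCompounds(fx$lipids, "Fluviicola taffensis"), cmp)
#' @export
compareProfile <- function(observed, complement,
                           mode = c("canonical", "relaxed"),
                           strain = NULL, ...) {
  mode <- match.arg(mode)
  if (is.character(complement))
    complement <- enzymeComplement(strain %||% "complement", complement)
  if (!is.null(strain) && !identical(strain, complement@strain))
    stop("strain mismatch: observed profile is '", strain,
         "' but complement is '", complement@strain, "'")
  nameable <- names(namedCompoundStates(includeIntermediates = TRUE))
  unknown <- setdiff(observed, nameable)
  if (length(unknown))
    stop("observed compound(s) not nameable by the pathway model: ",
         paste(unknown, collapse = ", "))

  present <- complement@families
  profile <- reachableCompounds(complement, mode = mode, ...)
  accountable <- setdiff(observed, c("squalene", "oxidosqualene"))
  agree <- intersect(accountable, reachableNames(profile))
  orphanCompounds <- setdiff(accountable, reachableNames(profile))

  famTable <- reactionFamilyTable()
  orphanRows <- lapply(orphanCompounds, function(cmp) {
    needed <- neededReactions(cmp)
    causes <- character(0)
    zeroCauses <- character(0)
    for (rn in needed) {
      spec <- famTable[[rn]]
      if (length(spec$families) == 0L) next
      satisfied <- if (mode == "relaxed" && spec$anyOne)
        any(spec$families %in% present)
      else all(spec$families %in% present)
      if (!satisfied) {
        causes <- c(causes, rn)
        if (!any(spec$families %in% present))
          zeroCauses <- c(zeroCauses, rn)
      }
    }
    missing <- minimalMissingFamilies(complement, cmp, mode = mode, ...)
    list(compound = cmp,
         missingFamilies = if (identical(missing, NA)) "infeasible"
         else paste(missing, collapse = ","),
         categories = paste(causes, collapse = ","),
         zeroCategories = paste(zeroCauses, collapse = ","),
         zeroFamily = length(zeroCauses) > 0L)
  })
  orphans <- DataFrame(
    compound = vapply(orphanRows, `[[`, character(1), "compound"),
    missingFamilies = vapply(orphanRows, `[[`, character(1),
                             "missingFamilies"),
    categories = vapply(orphanRows, `[[`, character(1), "categories"),
    zeroCategories = vapply(orphanRows, `[[`, character(1),
                            "zeroCategories"),
    zeroFamily = vapply(orphanRows, `[[`, logical(1), "zeroFamily"))

  used <- character(0)
  for (cmp in accountable)
    for (rn in neededReactions(cmp))
      used <- union(used, intersect(famTable[[rn]]$families, present))
  silent <- sort(setdiff(present, used))

  new("DiscrepancyReport", strain = complement@strain, mode = mode,
      observed = accountable, agreements = sort(agree),
      orphans = orphans, silentCapacities = silent)
}

#' Discrepancy reports for every tested strain of a fixture set
#'
#' @param fixtures Fixture list from \code{\link{loadFixtures}} (or any
#'   list with \code{lipids} and \code{complements} tables).
#' @param mode Pathway mode.
#' @param section Which lipid-table section to analyze.
#' @param ... Reaction-set options.
#' @return Named list of \code{DiscrepancyReport} objects.
#' @export
compareAllStrains <- function(fixtures, mode = c("canonical", "relaxed"),
                              section = "this_study", ...) {
  mode <- match.arg(mode)
  lipids <- fixtures$lipids
  strains <- lipids$strain_name[lipids$study_section == section]
  strains <- intersect(strains, fixtures$complements$strain_name)
  complements <- complementsFromTable(fixtures$complements, strains)
  reports <- lapply(strains, function(st)
    compareProfile(observedCompounds(lipids, st), complements[[st]],
                   mode = mode, strain = st, ...))
  setNames(reports, strains)
}

#' Cohort-level discrepancy counts
#'
#' Aggregates discrepancy reports by taxon group: strains with at least
#' one orphan caused by C-4 demethylation, at least one caused by C-14
#' reduction, at least one zero-family C-4 orphan, at least one silent
#' capacity, and strains in full agreement (no orphans). Also reports
#' compound prevalence (number of strains observing each vocabulary
#' compound) when a lipid table is supplied.
#'
#' @param reports List of \code{\link{DiscrepancyReport-class}} objects.
#' @param lipids Optional lipid table supplying \code{taxon_group} and
#'   compound prevalence (restricted to the strains in \code{reports}).
#' @return List with elements \code{groups} (data frame of per-group
#'   counts), \code{prevalence} (named integer vector) and
#'   \code{nStrains}.
#' @export
cohortCounts <- function(reports, lipids = NULL) {
  strains <- vapply(reports, strainName, character(1))
  groups <- rep("all", length(strains))
  if (!is.null(lipids))
    groups <- vapply(strains, function(st) {
      g <- lipids$taxon_group[lipids$strain_name == st]
      if (length(g)) g[1L] else "unknown"
    }, character(1))

  hasCategory <- function(r, category) {
    tab <- orphanModifications(r)
    any(vapply(strsplit(tab$categories, ",", fixed = TRUE),
               function(cc) category %in% cc, logical(1)))
  }
  hasZeroFamilyCategory <- function(r, category) {
    tab <- orphanModifications(r)
    any(vapply(strsplit(tab$zeroCategories, ",", fixed = TRUE),
               function(cc) category %in% cc, logical(1)))
  }
  flags <- data.frame(
    strain = strains, taxon_group = groups,
    orphan_c4 = vapply(reports, hasCategory, logical(1),
                       category = "C-4 demethylation"),
    orphan_c4_zero_family = vapply(reports, hasZeroFamilyCategory,
                                   logical(1),
                                   category = "C-4 demethylation"),
    orphan_c14_reduction = vapply(reports, hasCategory, logical(1),
                                  category = "C-14 reduction"),
    any_silent = vapply(reports, function(r)
      length(silentCapacities(r)) > 0L, logical(1)),
    full_agreement = vapply(reports, function(r)
      nrow(orphanModifications(r)) == 0L, logical(1)),
    stringsAsFactors = FALSE)

  agg <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    sub <- flags[flags$taxon_group == g, , drop = FALSE]
    data.frame(taxon_group = g, n = nrow(sub),
               orphan_c4 = sum(sub$orphan_c4),
               orphan_c4_zero_family = sum(sub$orphan_c4_zero_family),
               orphan_c14_reduction = sum(sub$orphan_c14_reduction),
               any_silent = sum(sub$any_silent),
               full_agreement = sum(sub$full_agreement),
               stringsAsFactors = FALSE)
  }))

  prevalence <- NULL
  if (!is.null(lipids)) {
    cols <- intersect(colnames(lipids), compoundVocabulary())
    sub <- lipids[lipids$strain_name %in% strains, , drop = FALSE]
    prevalence <- setNames(vapply(cols, function(cc)
      sum(sub[[cc]] == "+"), integer(1)), cols)
  }
  list(groups = agg, strains = flags, prevalence = prevalence,
       nStrains = length(reports))
}
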