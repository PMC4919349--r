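## Synthetic data with ground truth: divergent cyclase families with
## pinned diagnostic residues, metagenome-like fragments, and strain
## cohorts pairing enzyme complements with forward-simulated lipid
## profiles (optionally with injected discrepancies). All generators are
## pure functions of their arguments including the seed.

# residues for the simulators: the 20 standard letters (no X)
standardResidues <- function() setdiff(aminoAlphabet(), "X")

# replace residues at given positions: each site independently replaced
# by a different residue with the given probability
mutateSequence <- function(chars, prob, biased = FALSE, mat = NULL) {
  hit <- runif(length(chars)) < prob
  if (!any(hit)) return(chars)
  res <- standardResidues()
  for (k in which(hit)) {
    alternatives <- setdiff(res, chars[k])
    w <- NULL
    if (biased) {
      sc <- mat[chars[k], alternatives]
      w <- exp(sc)  # favor positive-scoring replacements
    }
    chars[k] <- sample(alternatives, 1L, prob = w)
  }
  chars
}

#' Simulate a divergent cyclase family with known class labels
#'
#' Draws a uniform-random ancestor of the stated length (cyclases run
#' about 600-650 residues), assigns it LAS-state diagnostic residues,
#' then evolves each descendant independently: every site is replaced by
#' a different residue with probability equal to its divergence level,
#' so the expected identity to the ancestor is 1 - divergence. Each
#' descendant's diagnostic residues (positions 381/449/453 by default)
#' are pinned to its intended class (LAS: T/Q/V; CAS: Y/H/I) after
#' mutation when \code{pinSites} is set. Deterministic under the seed.
#'
#' @param n Number of descendants.
#' @param divergence Per-descendant expected replaced-site fraction
#'   (scalar or length-n vector, each in [0, 0.95]).
#' @param classes Per-descendant intended class, \code{"LAS"} or
#'   \code{"CAS"}; recycled.
#' @param ancestorLength Ancestor length in residues.
#' @param seed Integer seed.
#' @param pinSites Pin diagnostic residues to the intended class.
#' @param biased Weight replacements toward positive-scoring partners
#'   (lets similarity exceed identity).
#' @param diagnosticPositions Positions to pin (reference numbering =
#'   ancestor position here).
#' @return List with \code{records} (an \code{AAStringSet} of
#'   descendants), \code{annotation} (a
#'   \code{\link{referenceAnnotation}} built on the ancestor) and
#'   \code{truth} (data frame: id, class, divergence).
#' @export
simulateFamily <- function(n = 50, divergence = 0.2,
                           classes = c("LAS", "CAS"),
                           ancestorLength = 650L, seed = 1L,
                           pinSites = TRUE, biased = FALSE,
                           diagnosticPositions = c(381L, 449L, 453L)) {
  divergence <- rep_len(divergence, n)
  if (any(divergence < 0) || any(divergence > 0.95))
    stop("divergence must lie in [0, 0.95]; above that the pinned ",
         "diagnostic states are meaningless")
  classes <- rep_len(classes, n)
  stopifnot(all(classes %in% c("LAS", "CAS")),
            ancestorLength >= max(diagnosticPositions))
  set.seed(seed)
  mat <- resolveSubstitutionMatrix("BLOSUM62")
  pinned <- list(LAS = c("T", "Q", "V"), CAS = c("Y", "H", "I"))

  ancestor <- sample(standardResidues(), ancestorLength, replace = TRUE)
  ancestor[diagnosticPositions] <- pinned$LAS
  descendants <- character(n)
  for (i in seq_len(n)) {
    d <- mutateSequence(ancestor, divergence[i], biased = biased,
                        mat = mat)
    if (pinSites) d[diagnosticPositions] <- pinned[[classes[i]]]
    descendants[i] <- paste(d, collapse = "")
  }
  ids <- sprintf("sim%03d_%s", seq_len(n), classes)
  records <- AAStringSet(setNames(descendants, ids))
  refSet <- AAStringSet(setNames(paste(ancestor, collapse = ""),
                                 "ancestor"))
  annotation <- referenceAnnotation(refSet,
                                    diagnosticPositions =
                                      diagnosticPositions,
                                    referenceClass = "LAS")
  truth <- data.frame(id = ids, class = classes,
                      divergence = divergence,
                      stringsAsFactors = FALSE)
  list(records = records, annotation = annotation, truth = truth)
}

#' Truncate records into metagenome-like fragments
#'
#' Cuts each record to a contiguous substring: fragment lengths are
#' sampled uniformly from \code{lengths} (capped at the source length)
#' and offsets uniformly over the admissible range. Deterministic under
#' the seed.
#'
#' @param records An \code{AAStringSet}.
#' @param lengths Candidate fragment lengths.
#' @param seed Integer seed.
#' @return List with \code{records} (fragments, ids suffixed
#'   \code{_frag}) and \code{truth} (data frame: id, source id, start,
#'   end, length).
#' @export
fragmentRecords <- function(records, lengths = c(350L, 450L),
                            seed = 1L) {
  set.seed(seed)
  ids <- names(records)
  n <- length(records)
  fragLen <- integer(n); fragStart <- integer(n)
  out <- character(n)
  for (i in seq_len(n)) {
    src <- as.character(records[[i]])
    len <- min(sample(rep(lengths, 2L), 1L), nchar(src))
    start <- sample.int(nchar(src) - len + 1L, 1L)
    out[i] <- substr(src, start, start + len - 1L)
    fragLen[i] <- len; fragStart[i] <- start
  }
  fragIds <- paste0(ids, "_frag")
  frags <- AAStringSet(setNames(out, fragIds))
  truth <- data.frame(id = fragIds, source_id = ids,
                      start = fragStart, end = fragStart + fragLen - 1L,
                      length = fragLen, stringsAsFactors = FALSE)
  list(records = frags, truth = truth)
}

# base complements for cohort simulation: every family present is used
# on a route to some observable compound, so the only silent capacities
# and orphans in a simulated cohort are the injected ones
cohortBaseComplements <- function() {
  list(
    cas_basic = c("SE", "CAS"),
    las_basic = c("SE", "LAS"),
    las_c14 = c("SE", "LAS", "ERG11", "ERG24"),
    las_c14_c24 = c("SE", "LAS", "ERG11", "ERG24", "ERG4_DHCR24"),
    las_zymosterol = c("SE", "LAS", "ERG11", "ERG24", "ERG25", "ERG26",
                       "ERG27"),
    las_full = c("SE", "LAS", "ERG11", "ERG24", "ERG25", "ERG26",
                 "ERG27", "ERG4_DHCR24"))
}

# vocabulary compounds reachable under a family set (canonical mode),
# excluding squalene (always present, uninformative)
reachableVocabulary <- function(families) {
  intersect(cyclizedVocabulary(),
            reachableNames(reachableCompounds(families,
                                              mode = "canonical")))
}

#' Simulate a strain cohort with known discrepancies
#'
#' Builds strains from a pool of base enzyme complements whose observed
#' lipid profile is, by construction, exactly the vocabulary compounds
#' reachable under the complement (canonical mode). With the stated
#' rates, a strain receives an injected orphan compound (an observed
#' compound not reachable under its complement) and/or an injected
#' silent family (a family added to the complement without extending
#' the observable compound set). The truth table records every
#' injection, so discrepancy analysis can be scored exactly.
#'
#' @param nStrains Number of strains.
#' @param orphanRate,silentRate Injection probabilities per strain.
#' @param seed Integer seed.
#' @param bases Named list of base family sets; defaults to complements
#'   in which every family is used.
#' @return List with \code{observed} (named list of compound vectors),
#'   \code{complements} (named list of \code{EnzymeComplement}) and
#'   \code{truth} (data frame: strain, base, injected orphan, injected
#'   silent family).
#' @export
simulateCohort <- function(nStrains = 100, orphanRate = 0.2,
                           silentRate = 0.2, seed = 1L,
                           bases = cohortBaseComplements()) {
  set.seed(seed)
  vocabulary <- setdiff(cyclizedVocabulary(), "parkeol")
  observed <- vector("list", nStrains)
  complements <- vector("list", nStrains)
  truth <- data.frame(strain = sprintf("strain%03d", seq_len(nStrains)),
                      base = character(nStrains),
                      injected_orphan = NA_character_,
                      injected_silent = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(nStrains)) {
    baseName <- sample(names(bases), 1L)
    fams <- bases[[baseName]]
    baseVocab <- reachableVocabulary(fams)

    silentFam <- NA_character_
    if (runif(1) < silentRate) {
      candidates <- Filter(function(f)
        setequal(reachableVocabulary(c(fams, f)), baseVocab),
        setdiff(enzymeFamilies(), fams))
      if (length(candidates)) {
        silentFam <- sample(rep(candidates, 2L), 1L)
        fams <- c(fams, silentFam)
      }
    }

    orphan <- NA_character_
    if (runif(1) < orphanRate) {
      candidates <- setdiff(vocabulary, reachableVocabulary(fams))
      if (!is.na(silentFam)) {
        # keep injections independent: an orphan whose route involves
        # the injected silent family would un-silence it
        famTable <- reactionFamilyTable()
        recruits <- vapply(candidates, function(cmp)
          silentFam %in% unlist(lapply(neededReactions(cmp),
                                       function(rn)
                                         famTable[[rn]]$families)),
          logical(1))
        candidates <- candidates[!recruits]
      }
      if (length(candidates))
        orphan <- sample(rep(candidates, 2L), 1L)
    }

    obs <- baseVocab
    if (!is.na(orphan)) {
      if (orphan %in% reachableVocabulary(fams))
        stop("scenario error: injected orphan already reachable")
      obs <- c(obs, orphan)
    }
    observed[[i]] <- sort(obs)
    complements[[i]] <- enzymeComplement(truth$strain[i], sort(fams))
    truth$base[i] <- baseName
    truth$injected_orphan[i] <- orphan
    truth$injected_silent[i] <- silentFam
  }
  names(observed) <- truth$strain
  names(complements) <- truth$strain
  list(observed = observed, complements = complements, truth = truth)
}
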