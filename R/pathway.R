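## The sterol biosynthesis reaction graph. Compounds are feature vectors
## (CompoundState); reactions are deterministic state maps guarded by an
## applicability predicate and an enzyme-family requirement. Reachability
## is the closure of satisfied reactions from squalene.

#' Construct a compound state
#'
#' @param stage \code{"linear"}, \code{"epoxide"} or \code{"cyclized"}.
#' @param c4Methyl Number of C-4 methyl groups (0-2).
#' @param c14Methyl C-14 methyl present?
#' @param delta7,delta8,delta9_11,delta14,delta24 Unsaturation flags.
#' @param cyclopropane 9,19-cyclopropane ring (cycloartenol route)?
#' @return A validated \code{\link{CompoundState-class}} object.
#' @examples
#' compoundName(compoundState("cyclized", c4Methyl = 0, c14Methyl = FALSE,
#'                            delta8 = TRUE, delta24 = TRUE))  # zymosterol
#' @export
compoundState <- function(stage, c4Methyl = 2L, c14Methyl = TRUE,
                          delta7 = FALSE, delta8 = FALSE,
                          delta9_11 = FALSE, delta14 = FALSE,
                          delta24 = TRUE, cyclopropane = FALSE) {
  new("CompoundState", stage = stage, c4Methyl = as.integer(c4Methyl),
      c14Methyl = c14Methyl, delta7 = delta7, delta8 = delta8,
      delta9_11 = delta9_11, delta14 = delta14, delta24 = delta24,
      cyclopropane = cyclopropane)
}

# canonical serialization for set membership
stateKey <- function(s) {
  paste(s@stage, s@c4Methyl, s@c14Methyl, s@delta7, s@delta8,
        s@delta9_11, s@delta14, s@delta24, s@cyclopropane, sep = "|")
}

#' Name a compound state
#'
#' Maps a valid state to its compound name. The named set covers the
#' compounds of the survey vocabulary (squalene, oxidosqualene,
#' lanosterol, cycloartenol, parkeol, the 4,4-dimethyl and 4-methyl
#' cholestenols, zymosterol) plus the delta-14 intermediates; every
#' other valid state receives a systematic cholestane/lanostane-style
#' descriptor, so naming is total and invertible over the named set.
#'
#' @param state A \code{\link{compoundState}} object.
#' @return Compound name string.
#' @export
compoundName <- function(state) {
  validObject(state)
  if (state@stage == "linear") return("squalene")
  if (state@stage == "epoxide") return("oxidosqualene")

  trivial <- c(
    "cyclized|2|TRUE|FALSE|TRUE|FALSE|FALSE|TRUE|FALSE" = "lanosterol",
    "cyclized|2|TRUE|FALSE|FALSE|FALSE|FALSE|TRUE|TRUE" = "cycloartenol",
    "cyclized|2|TRUE|FALSE|FALSE|TRUE|FALSE|TRUE|FALSE" = "parkeol",
    "cyclized|0|FALSE|FALSE|TRUE|FALSE|FALSE|TRUE|FALSE" = "zymosterol")
  key <- stateKey(state)
  if (key %in% names(trivial)) return(unname(trivial[key]))

  # systematic name on the cholestane skeleton (C-14 methyl absent) or a
  # lanostane/cycloartane skeleton otherwise
  unsat <- c(if (state@delta7) "7", if (state@delta8) "8",
             if (state@delta9_11) "9(11)", if (state@delta14) "14",
             if (state@delta24) "24")
  suffix <- if (length(unsat) == 0L) "an-3-ol"
  else paste0("-", paste(unsat, collapse = ","), "-",
              c("en", "dien", "trien", "tetraen")[length(unsat)], "-3-ol")
  if (!state@c14Methyl) {
    prefix <- c("", "4-methyl", "4,4-dimethyl")[state@c4Methyl + 1L]
    base <- if (length(unsat)) "cholesta" else "cholest"
    return(paste0(prefix, base, suffix))
  }
  base <- if (state@cyclopropane) "9,19-cyclolanost" else "lanost"
  if (state@c4Methyl == 2L) {
    if (length(unsat)) base <- paste0(base, "a")
    return(paste0(base, suffix))
  }
  # demethylated-at-C4 lanostane variants (non-canonical orderings)
  paste0(c("4,4-didemethyl", "4-demethyl")[state@c4Methyl + 1L],
         if (length(unsat)) paste0(base, "a") else base, suffix)
}

#' Named compound states of the pathway model
#'
#' @param includeIntermediates Include the delta-14 intermediates and
#'   oxidosqualene alongside the observation vocabulary.
#' @return Named list of \code{CompoundState} objects.
#' @export
namedCompoundStates <- function(includeIntermediates = TRUE) {
  cyc <- function(...) compoundState("cyclized", ...)
  states <- list(
    squalene = compoundState("linear"),
    oxidosqualene = compoundState("epoxide"),
    lanosterol = cyc(c4Methyl = 2, c14Methyl = TRUE, delta8 = TRUE),
    cycloartenol = cyc(c4Methyl = 2, c14Methyl = TRUE,
                       cyclopropane = TRUE),
    parkeol = cyc(c4Methyl = 2, c14Methyl = TRUE, delta9_11 = TRUE),
    `4,4-dimethylcholesta-8,24-dien-3-ol` =
      cyc(c4Methyl = 2, c14Methyl = FALSE, delta8 = TRUE),
    `4,4-dimethylcholesta-8-en-3-ol` =
      cyc(c4Methyl = 2, c14Methyl = FALSE, delta8 = TRUE,
          delta24 = FALSE),
    `4-methylcholesta-8,24-dien-3-ol` =
      cyc(c4Methyl = 1, c14Methyl = FALSE, delta8 = TRUE),
    `4-methylcholesta-8-en-3-ol` =
      cyc(c4Methyl = 1, c14Methyl = FALSE, delta8 = TRUE,
          delta24 = FALSE),
    zymosterol = cyc(c4Methyl = 0, c14Methyl = FALSE, delta8 = TRUE))
  if (includeIntermediates) {
    states[["4,4-dimethylcholesta-8,14,24-trien-3-ol"]] <-
      cyc(c4Methyl = 2, c14Methyl = FALSE, delta8 = TRUE, delta14 = TRUE)
    states[["4,4-dimethylcholesta-8,14-dien-3-ol"]] <-
      cyc(c4Methyl = 2, c14Methyl = FALSE, delta8 = TRUE,
          delta14 = TRUE, delta24 = FALSE)
  }
  states
}

#' The reaction table of the pathway model
#'
#' Returns the reaction set as a named list. Each reaction carries the
#' enzyme families it requires (in canonical mode all are required; in
#' relaxed mode the C-4 demethylation step accepts any non-empty subset
#' of ERG25/ERG26/ERG27), an applicability predicate on compound states,
#' and the state transformation. The default reaction order follows the
#' eukaryotic pathway: C-14 demethylation precedes C-4 demethylation;
#' \code{allowC4First} lifts that ordering. Delta-24 reduction applies to
#' any cyclized delta-24 state. The delta-8 to delta-7 isomerization
#' (product: lathosterol-type sterols) has no assigned enzyme family and
#' is excluded unless requested.
#'
#' @param allowC4First Permit C-4 demethylation before C-14 events.
#' @param includeIsomerization Include the family-less delta-8/delta-7
#'   isomerization.
#' @param parkeolSpectrum Let LAS also emit parkeol (product-spectrum
#'   option for parkeol producers).
#' @return Named list of reactions.
#' @export
sterolReactions <- function(allowC4First = FALSE,
                            includeIsomerization = FALSE,
                            parkeolSpectrum = FALSE) {
  rxn <- function(families, anyOne, applicable, transform)
    list(families = families, anyOne = anyOne,
         applicable = applicable, transform = transform)
  set <- function(s, ...) {
    mods <- list(...)
    for (nm in names(mods)) slot(s, nm) <- mods[[nm]]
    s
  }
  reactions <- list(
    "squalene oxygenation" = rxn(
      "SE", FALSE,
      function(s) s@stage == "linear",
      function(s) set(s, stage = "epoxide")),
    "oxidosqualene cyclization (LAS)" = rxn(
      "LAS", FALSE,
      function(s) s@stage == "epoxide",
      function(s) set(s, stage = "cyclized", delta8 = TRUE)),
    "oxidosqualene cyclization (CAS)" = rxn(
      "CAS", FALSE,
      function(s) s@stage == "epoxide",
      function(s) set(s, stage = "cyclized", cyclopropane = TRUE)),
    "C-14 demethylation" = rxn(
      "ERG11", FALSE,
      function(s) s@stage == "cyclized" && s@c14Methyl && s@delta8,
      function(s) set(s, c14Methyl = FALSE, delta14 = TRUE)),
    "C-14 reduction" = rxn(
      "ERG24", FALSE,
      function(s) s@stage == "cyclized" && s@delta14,
      function(s) set(s, delta14 = FALSE)),
    "C-4 demethylation" = rxn(
      c("ERG25", "ERG26", "ERG27"), TRUE,
      if (allowC4First)
        function(s) s@stage == "cyclized" && s@c4Methyl > 0L && s@delta8
      else
        function(s) s@stage == "cyclized" && s@c4Methyl > 0L &&
          s@delta8 && !s@c14Methyl && !s@delta14,
      function(s) set(s, c4Methyl = s@c4Methyl - 1L)),
    "C-24(28) reduction" = rxn(
      "ERG4_DHCR24", FALSE,
      function(s) s@stage == "cyclized" && s@delta24,
      function(s) set(s, delta24 = FALSE)))
  if (parkeolSpectrum)
    reactions[["oxidosqualene cyclization (parkeol)"]] <- rxn(
      "LAS", FALSE,
      function(s) s@stage == "epoxide",
      function(s) set(s, stage = "cyclized", delta9_11 = TRUE))
  if (includeIsomerization)
    reactions[["delta-8(9) to delta-7(8) isomerization"]] <- rxn(
      character(0), FALSE,
      function(s) s@stage == "cyclized" && s@delta8,
      function(s) set(s, delta8 = FALSE, delta7 = TRUE))
  reactions
}

#' Enzyme families required by a pathway reaction
#'
#' @param reaction Reaction name as in \code{\link{sterolReactions}}.
#' @param mode \code{"canonical"} (all listed families required) or
#'   \code{"relaxed"} (for C-4 demethylation, any one of the three
#'   suffices; the returned set carries attribute \code{anyOne = TRUE}).
#' @param ... Passed to \code{\link{sterolReactions}}.
#' @return Character vector of families, with attribute \code{anyOne}.
#' @examples
#' requiredFamilies("C-4 demethylation")  # ERG25, ERG26, ERG27
#' @export
requiredFamilies <- function(reaction, mode = c("canonical", "relaxed"),
                             ...) {
  mode <- match.arg(mode)
  reactions <- sterolReactions(...)
  if (!reaction %in% names(reactions))
    stop("unknown reaction: ", reaction)
  r <- reactions[[reaction]]
  structure(r$families, anyOne = (mode == "relaxed") && r$anyOne)
}

# does the complement satisfy a reaction's family requirement?
familiesSatisfied <- function(reaction, present, mode) {
  fams <- reaction$families
  if (length(fams) == 0L) return(TRUE)
  if (mode == "relaxed" && reaction$anyOne)
    any(fams %in% present)
  else
    all(fams %in% present)
}

#' Construct an enzyme complement
#'
#' @param strain Strain name.
#' @param families Character vector of present families (a subset of
#'   \code{\link{enzymeFamilies}}), or a named character vector of locus
#'   tags (names = families).
#' @return An \code{\link{EnzymeComplement-class}} object.
#' @export
enzymeComplement <- function(strain, families) {
  loci <- character(0)
  if (!is.null(names(families))) {
    loci <- families
    families <- names(families)
  }
  new("EnzymeComplement", strain = strain,
      families = unname(families), loci = loci)
}

#' Enzyme complements from a gene-complement table
#'
#' Converts the fixture complement table (one locus-tag column per
#' family, \code{"."} marking absence) into \code{EnzymeComplement}
#' objects.
#'
#' @param complements Complement table from \code{\link{loadFixtures}}.
#' @param strains Optional subset of strain names.
#' @return Named list of \code{EnzymeComplement} objects.
#' @export
complementsFromTable <- function(complements, strains = NULL) {
  strains <- strains %||% complements$strain_name
  out <- lapply(strains, function(st) {
    row <- complements[complements$strain_name == st, , drop = FALSE]
    if (nrow(row) == 0L)
      stop("strain not found in complement table: ", st)
    row <- row[1L, , drop = FALSE]
    fams <- intersect(colnames(complements), enzymeFamilies())
    present <- fams[vapply(fams, function(f) row[[f]] != ".", logical(1))]
    loci <- vapply(present, function(f) row[[f]], character(1))
    enzymeComplement(st, setNames(loci, present))
  })
  setNames(out, strains)
}

#' Compounds reachable from squalene under an enzyme complement
#'
#' Breadth-first closure from squalene: every reaction whose family
#' requirement the complement satisfies (under the given mode) and whose
#' applicability predicate holds is applied until no new state appears.
#' Squalene is always the root — the model assumes squalene itself is
#' available and does not track its synthesis. Terminal compounds are
#' reachable states to which no satisfied reaction applies.
#'
#' @param complement An \code{\link{enzymeComplement}} or character
#'   vector of families.
#' @param mode \code{"canonical"} or \code{"relaxed"}.
#' @param ... Reaction-set options, see \code{\link{sterolReactions}}.
#' @return A \code{\link{PredictedProfile-class}} object.
#' @examples
#' reachableNames(reachableCompounds(c("SE", "CAS")))
#' @export
reachableCompounds <- function(complement,
                               mode = c("canonical", "relaxed"), ...) {
  mode <- match.arg(mode)
  if (is.character(complement))
    complement <- enzymeComplement("complement", complement)
  present <- complement@families
  reactions <- sterolReactions(...)
  satisfied <- reactions[vapply(reactions, familiesSatisfied,
                                logical(1), present = present,
                                mode = mode)]
  root <- compoundState("linear")
  states <- list(root)
  keys <- stateKey(root)
  queue <- list(root)
  while (length(queue)) {
    s <- queue[[1L]]; queue <- queue[-1L]
    for (r in satisfied) {
      if (r$applicable(s)) {
        nxt <- r$transform(s)
        k <- stateKey(nxt)
        if (!k %in% keys) {
          keys <- c(keys, k)
          states <- c(states, nxt)
          queue <- c(queue, nxt)
        }
      }
    }
  }
  nms <- vapply(states, compoundName, character(1))
  isTerminal <- vapply(states, function(s)
    !any(vapply(satisfied, function(r) r$applicable(s), logical(1))),
    logical(1))
  ord <- order(nms)
  new("PredictedProfile", strain = complement@strain, mode = mode,
      states = states[ord], compounds = nms[ord],
      terminals = sort(nms[isTerminal]))
}

#' Smallest set of absent families making a target compound reachable
#'
#' Exhaustively searches subsets of the absent enzyme families, by
#' increasing size and in lexicographic order within each size, for the
#' first subset whose addition makes the target reachable. Returns
#' \code{NA} (the infeasible signal) when even the full family set
#' cannot reach the target under the given reaction options.
#'
#' @inheritParams reachableCompounds
#' @param target Target compound name (must be nameable by the model).
#' @return Character vector of families (possibly empty), or \code{NA}
#'   if infeasible.
#' @examples
#' minimalMissingFamilies(c("SE", "LAS"), "zymosterol")
#' @export
minimalMissingFamilies <- function(complement, target,
                                   mode = c("canonical", "relaxed"),
                                   ...) {
  mode <- match.arg(mode)
  if (is.character(complement))
    complement <- enzymeComplement("complement", complement)
  present <- complement@families
  canReach <- function(fams)
    target %in% reachableNames(reachableCompounds(fams, mode = mode, ...))
  if (!canReach(enzymeFamilies())) return(NA)
  absent <- sort(setdiff(enzymeFamilies(), present))
  for (k in 0:length(absent)) {
    subsets <- if (k == 0L) list(character(0))
    else combn(absent, k, simplify = FALSE)
    for (sub in subsets)
      if (canReach(c(present, sub))) return(sub)
  }
  NA  # unreachable even with all families (cannot happen after the guard)
}
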