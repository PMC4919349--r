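setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' AlignmentResult: a scored pairwise residue correspondence
#'
#' Produced by \code{\link{alignPair}}. Holds the optimal traceback as a
#' two-column matrix of 1-based residue indices, the raw score under the
#' substitution matrix and affine gap penalties used, and summary
#' statistics computed over aligned (gap-free) columns: percent identity
#' (exact matches) and percent similarity (columns with a positive
#' substitution score, the BLAST "positives" convention).
#'
#' @slot queryId,subjectId Sequence identifiers.
#' @slot alignedPairs Integer matrix, columns \code{query}/\code{subject},
#'   strictly increasing down both columns.
#' @slot rawScore Alignment score.
#' @slot percentIdentity,percentSimilarity Percentages in [0, 100], with
#'   identity <= similarity.
#' @slot evalue Expected number of chance hits at this score, \code{NA}
#'   until \code{\link{estimateEvalue}} is applied.
#' @slot alignmentLength Number of alignment columns including gaps.
#' @slot type \code{"local"} or \code{"global"}.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(
    queryId = "character",
    subjectId = "character",
    alignedPairs = "matrix",
    rawScore = "numeric",
    percentIdentity = "numeric",
    percentSimilarity = "numeric",
    evalue = "numeric",
    alignmentLength = "integer",
    type = "character"
  )
)

setValidity("AlignmentResult", function(object) {
  msg <- character()
  ap <- object@alignedPairs
  if (nrow(ap) > 1) {
    if (any(diff(ap[, 1]) <= 0) || any(diff(ap[, 2]) <= 0))
      msg <- c(msg, "aligned pair indices must be strictly increasing")
  }
  pid <- object@percentIdentity
  psim <- object@percentSimilarity
  if (!is.na(pid) && !is.na(psim) && pid > psim + 1e-9)
    msg <- c(msg, "percent identity cannot exceed percent similarity")
  if (!is.na(psim) && (psim < 0 || psim > 100))
    msg <- c(msg, "percent similarity outside [0, 100]")
  if (!is.na(object@evalue) && object@evalue < 0)
    msg <- c(msg, "evalue must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SearchThresholds: criteria of a thresholded homolog screen
#'
#' A screen passes a candidate only if every present criterion holds:
#' e-value at or below \code{maxEvalue} (inclusive, "equal to or lower"),
#' similarity strictly greater than \code{minSimilarity}, identity at or
#' above \code{minIdentity}, and candidate length at or above
#' \code{minLength} (inclusive by default; set \code{strictLength} for a
#' strict comparison). Absent criteria are \code{NA}.
#'
#' @slot name Preset or user label.
#' @slot maxEvalue,minIdentity,minSimilarity,minLength Numeric criteria,
#'   \code{NA} when unused.
#' @slot strictLength Use strictly-greater length comparison.
#' @exportClass SearchThresholds
setClass("SearchThresholds",
  representation(
    name = "character",
    maxEvalue = "numeric",
    minIdentity = "numeric",
    minSimilarity = "numeric",
    minLength = "numeric",
    strictLength = "logical"
  )
)

setValidity("SearchThresholds", function(object) {
  crit <- c(object@maxEvalue, object@minIdentity,
            object@minSimilarity, object@minLength)
  if (all(is.na(crit)))
    return("at least one criterion must be present")
  if (!is.na(object@maxEvalue) && object@maxEvalue <= 0)
    return("maxEvalue must be positive")
  ok <- function(x) is.na(x) || (x >= 0 && x <= 100)
  if (!ok(object@minIdentity) || !ok(object@minSimilarity))
    return("identity/similarity thresholds must lie in [0, 100]")
  if (!is.na(object@minLength) && object@minLength < 1)
    return("minLength must be a positive integer")
  TRUE
})

#' ReferenceAnnotation: an annotated reference cyclase
#'
#' Bundles a reference protein with the residue positions (in reference
#' numbering, human-Osc style) used for LAS/CAS classification and for
#' functional-residue audits. The diagnostic triple defaults to positions
#' 381/449/453 with LAS expectations T-or-C/Q/V and CAS expectations
#' Y/H/I; the residue at 453 is the discriminator.
#'
#' @slot reference An \code{AAStringSet} of length 1 (named).
#' @slot numberingOffset Integer added to 1-based sequence positions to
#'   obtain reference numbering.
#' @slot diagnosticPositions Integer triple in reference numbering.
#' @slot lasStates,casStates Named lists (by position) of acceptable
#'   residues for each class.
#' @slot functionalPositions \code{DataFrame} with columns
#'   \code{position} and \code{expected} (comma-separated residue set) for
#'   the functional-residue audit; may have zero rows.
#' @slot referenceClass Class of the reference itself
#'   (\code{"LAS"}, \code{"CAS"} or \code{NA}).
#' @exportClass ReferenceAnnotation
setClass("ReferenceAnnotation",
  representation(
    reference = "AAStringSet",
    numberingOffset = "integer",
    diagnosticPositions = "integer",
    lasStates = "list",
    casStates = "list",
    functionalPositions = "DataFrame",
    referenceClass = "character"
  )
)

setValidity("ReferenceAnnotation", function(object) {
  if (length(object@reference) != 1L)
    return("reference must contain exactly one sequence")
  if (length(object@diagnosticPositions) != 3L)
    return("diagnosticPositions must be a triple")
  seqPos <- object@diagnosticPositions - object@numberingOffset
  if (any(seqPos < 1L) || any(seqPos > width(object@reference)))
    return("diagnostic positions fall outside the reference sequence")
  p453 <- as.character(object@diagnosticPositions[3L])
  las <- object@lasStates[[p453]]
  cas <- object@casStates[[p453]]
  if (length(intersect(las, cas)))
    return("LAS and CAS expectations overlap at the discriminator position")
  TRUE
})

#' DiagnosticProfile: residues at the diagnostic triple and the class call
#'
#' Result of \code{\link{classifyOsc}}. The call is \code{"LAS"} iff the
#' residue mapped to the discriminator position (453 by default) is V,
#' \code{"CAS"} iff it is I, and \code{"indeterminate"} otherwise
#' (including fragments that do not cover the position).
#' \code{supportingAgreement} counts how many of the two supporting
#' positions (381/449) agree with the called class.
#'
#' @slot queryId Query identifier.
#' @slot residues Named character vector of observed residues at the
#'   diagnostic positions (\code{"-"} where unmapped).
#' @slot mapped Named logical vector: did the reference position align to
#'   a query residue?
#' @slot call \code{"LAS"}, \code{"CAS"} or \code{"indeterminate"}.
#' @slot supportingAgreement Integer in 0..2 (\code{NA} when the call is
#'   indeterminate).
#' @exportClass DiagnosticProfile
setClass("DiagnosticProfile",
  representation(
    queryId = "character",
    residues = "character",
    mapped = "logical",
    call = "character",
    supportingAgreement = "integer"
  )
)

setValidity("DiagnosticProfile", function(object) {
  if (!object@call %in% c("LAS", "CAS", "indeterminate"))
    return("call must be LAS, CAS or indeterminate")
  TRUE
})

#' FunctionalAudit: conservation check of functional residues
#'
#' Result of \code{\link{auditFunctionalResidues}}: each annotated
#' position is looked up through the reference mapping and compared to its
#' expected residue set. The verdict is \code{"all_conserved"} iff no
#' position diverges.
#'
#' @slot queryId Query identifier.
#' @slot table \code{DataFrame} with columns \code{position},
#'   \code{expected}, \code{observed}, \code{conserved}.
#' @slot verdict \code{"all_conserved"} or \code{"divergent"}.
#' @slot divergentPositions Integer vector of non-conserved positions.
#' @exportClass FunctionalAudit
setClass("FunctionalAudit",
  representation(
    queryId = "character",
    table = "DataFrame",
    verdict = "character",
    divergentPositions = "integer"
  )
)

setValidity("FunctionalAudit", function(object) {
  allCons <- length(object@divergentPositions) == 0L
  if (allCons != (object@verdict == "all_conserved"))
    return("verdict inconsistent with divergentPositions")
  TRUE
})

#' CompoundState: a sterol-pathway intermediate as a feature vector
#'
#' Pathway intermediates are encoded by their biosynthetically relevant
#' features rather than by name: the processing stage (linear squalene,
#' the 2,3-epoxide, or a cyclized sterol), the number of C-4 methyl
#' groups remaining (0-2), presence of the C-14 methyl, ring
#' unsaturations (delta-7, delta-8(9), delta-9(11), delta-14), the side
#' chain delta-24 unsaturation, and the 9,19-cyclopropane ring that
#' distinguishes the cycloartenol route. \code{\link{compoundName}} maps
#' valid states to compound names.
#'
#' @slot stage \code{"linear"}, \code{"epoxide"} or \code{"cyclized"}.
#' @slot c4Methyl Integer 0, 1 or 2.
#' @slot c14Methyl,delta7,delta8,delta9_11,delta14,delta24,cyclopropane
#'   Logical feature flags.
#' @exportClass CompoundState
setClass("CompoundState",
  representation(
    stage = "character",
    c4Methyl = "integer",
    c14Methyl = "logical",
    delta7 = "logical",
    delta8 = "logical",
    delta9_11 = "logical",
    delta14 = "logical",
    delta24 = "logical",
    cyclopropane = "logical"
  )
)

setValidity("CompoundState", function(object) {
  s <- object@stage
  if (!s %in% c("linear", "epoxide", "cyclized"))
    return("stage must be linear, epoxide or cyclized")
  if (!object@c4Methyl %in% 0:2)
    return("c4Methyl must be 0, 1 or 2")
  if (s %in% c("linear", "epoxide")) {
    # precursors carry the full methyl complement and the delta-24-like
    # side-chain unsaturation; no ring features yet
    if (object@c4Methyl != 2L || !object@c14Methyl || !object@delta24 ||
        object@delta7 || object@delta8 || object@delta9_11 ||
        object@delta14 || object@cyclopropane)
      return("linear/epoxide states must carry precursor features only")
  }
  if (object@delta14 && object@c14Methyl)
    return("delta-14 unsaturation requires prior C-14 demethylation")
  if (object@cyclopropane && (object@delta8 || object@delta9_11 || object@delta7))
    return("9,19-cyclopropane excludes ring unsaturations")
  if (sum(object@delta7, object@delta8, object@delta9_11) > 1L)
    return("at most one of delta-7/delta-8/delta-9(11) may be set")
  TRUE
})

#' EnzymeComplement: the sterol-pathway families present in a strain
#'
#' @slot strain Strain name.
#' @slot families Character subset of \code{\link{enzymeFamilies}}.
#' @slot loci Named character vector mapping present families to locus
#'   tags (may be empty for synthetic complements).
#' @exportClass EnzymeComplement
setClass("EnzymeComplement",
  representation(
    strain = "character",
    families = "character",
    loci = "character"
  )
)

setValidity("EnzymeComplement", function(object) {
  bad <- setdiff(object@families, enzymeFamilies())
  if (length(bad))
    return(paste0("unknown enzyme families: ", paste(bad, collapse = ", ")))
  if (anyDuplicated(object@families))
    return("at most one entry per family")
  TRUE
})

#' PredictedProfile: compounds reachable from squalene
#'
#' Result of \code{\link{reachableCompounds}}: the closure of pathway
#' reactions whose family requirements a complement satisfies, starting
#' from squalene. Terminal compounds admit no further satisfied reaction.
#'
#' @slot strain Strain name.
#' @slot mode \code{"canonical"} or \code{"relaxed"} (relaxed: any one of
#'   ERG25/ERG26/ERG27 suffices for C-4 demethylation).
#' @slot states List of reachable \code{CompoundState}s.
#' @slot compounds Character vector of reachable compound names.
#' @slot terminals Character vector of terminal compound names.
#' @exportClass PredictedProfile
setClass("PredictedProfile",
  representation(
    strain = "character",
    mode = "character",
    states = "list",
    compounds = "character",
    terminals = "character"
  )
)

setValidity("PredictedProfile", function(object) {
  if (!all(object@terminals %in% object@compounds))
    return("terminals must be a subset of reachable compounds")
  if (!"squalene" %in% object@compounds)
    return("squalene must always be reachable")
  TRUE
})

#' DiscrepancyReport: observed lipids vs predicted capability
#'
#' Result of \code{\link{compareProfile}}. Observed compounds (squalene
#' and oxidosqualene excluded from accounting) are split into agreements
#' (reachable under the complement) and orphan modifications (observed
#' but not reachable), each orphan annotated with the smallest set of
#' absent families whose addition would make it reachable, the causing
#' reaction categories, and whether any causing reaction has zero present
#' members of its required family set. Silent capacities are present
#' families lying on no route to any observed compound.
#'
#' @slot strain Strain name.
#' @slot mode Pathway mode used.
#' @slot observed Compounds entering the accounting.
#' @slot agreements Observed compounds within the reachable set.
#' @slot orphans \code{DataFrame}: \code{compound},
#'   \code{missingFamilies} (comma-separated), \code{categories}
#'   (comma-separated reaction names), \code{zeroFamily}.
#' @slot silentCapacities Present-but-unused families.
#' @exportClass DiscrepancyReport
setClass("DiscrepancyReport",
  representation(
    strain = "character",
    mode = "character",
    observed = "character",
    agreements = "character",
    orphans = "DataFrame",
    silentCapacities = "character"
  )
)

setValidity("DiscrepancyReport", function(object) {
  orphanCompounds <- object@orphans$compound
  both <- intersect(object@agreements, orphanCompounds)
  if (length(both))
    return("a compound cannot be both agreement and orphan")
  if (!setequal(object@observed, union(object@agreements, orphanCompounds)))
    return("every accounted compound must be agreement or orphan")
  TRUE
})
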