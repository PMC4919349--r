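#' @rdname AlignmentResult-class
#' @export
setMethod("rawScore", "AlignmentResult", function(x) x@rawScore)

#' @rdname AlignmentResult-class
#' @export
setMethod("percentIdentity", "AlignmentResult",
          function(x) x@percentIdentity)

#' @rdname AlignmentResult-class
#' @export
setMethod("percentSimilarity", "AlignmentResult",
          function(x) x@percentSimilarity)

#' @rdname AlignmentResult-class
#' @export
setMethod("evalue", "AlignmentResult", function(x) x@evalue)

#' @rdname AlignmentResult-class
#' @export
setMethod("alignedPairs", "AlignmentResult", function(x) x@alignedPairs)

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf(
    "AlignmentResult (%s): %s vs %s\n  score %g | identity %.1f%% | similarity %.1f%% | length %d | E %s\n",
    object@type, object@queryId, object@subjectId, object@rawScore,
    object@percentIdentity, object@percentSimilarity,
    object@alignmentLength,
    if (is.na(object@evalue)) "NA" else format(object@evalue, digits = 3)))
})

setMethod("show", "SearchThresholds", function(object) {
  fmt <- function(v) if (is.na(v)) "-" else format(v)
  cat(sprintf(
    "SearchThresholds '%s': E<=%s, identity>=%s, similarity>%s, length%s%s\n",
    object@name, fmt(object@maxEvalue), fmt(object@minIdentity),
    fmt(object@minSimilarity), if (object@strictLength) ">" else ">=",
    fmt(object@minLength)))
})

setMethod("show", "ReferenceAnnotation", function(object) {
  cat(sprintf(
    "ReferenceAnnotation: %s (%d aa, offset %d)\n  diagnostic positions %s | functional positions: %d\n",
    names(object@reference), width(object@reference)[1L],
    object@numberingOffset,
    paste(object@diagnosticPositions, collapse = "/"),
    nrow(object@functionalPositions)))
})

#' @rdname DiagnosticProfile-class
#' @export
setMethod("oscCall", "DiagnosticProfile", function(x) x@call)

#' @rdname DiagnosticProfile-class
#' @export
setMethod("supportingAgreement", "DiagnosticProfile",
          function(x) x@supportingAgreement)

#' @rdname DiagnosticProfile-class
#' @export
setMethod("diagnosticResidues", "DiagnosticProfile",
          function(x) x@residues)

setMethod("show", "DiagnosticProfile", function(object) {
  cat(sprintf(
    "DiagnosticProfile: %s -> %s\n  residues %s | supporting agreement %s\n",
    object@queryId, object@call,
    paste(sprintf("%s=%s", names(object@residues), object@residues),
          collapse = " "),
    ifelse(is.na(object@supportingAgreement), "NA",
           paste0(object@supportingAgreement, "/2"))))
})

setMethod("show", "FunctionalAudit", function(object) {
  cat(sprintf("FunctionalAudit: %s -> %s\n", object@queryId,
              object@verdict))
  if (length(object@divergentPositions))
    cat("  divergent at:",
        paste(object@divergentPositions, collapse = ", "), "\n")
})

setMethod("show", "CompoundState", function(object) {
  cat(sprintf("CompoundState <%s>: %s\n", object@stage,
              compoundName(object)))
})

#' @rdname EnzymeComplement-class
#' @export
setMethod("presentFamilies", "EnzymeComplement", function(x) x@families)

#' @rdname EnzymeComplement-class
#' @export
setMethod("strainName", "EnzymeComplement", function(x) x@strain)

setMethod("show", "EnzymeComplement", function(object) {
  cat(sprintf("EnzymeComplement: %s [%s]\n", object@strain,
              paste(object@families, collapse = ", ")))
})

#' @rdname PredictedProfile-class
#' @export
setMethod("strainName", "PredictedProfile", function(x) x@strain)

#' @rdname PredictedProfile-class
#' @export
setMethod("pathwayMode", "PredictedProfile", function(x) x@mode)

#' @rdname PredictedProfile-class
#' @export
setMethod("reachableNames", "PredictedProfile", function(x) x@compounds)

#' @rdname PredictedProfile-class
#' @export
setMethod("terminalNames", "PredictedProfile", function(x) x@terminals)

setMethod("show", "PredictedProfile", function(object) {
  cat(sprintf("PredictedProfile: %s (%s mode)\n  reachable: %s\n  terminal: %s\n",
              object@strain, object@mode,
              paste(object@compounds, collapse = ", "),
              paste(object@terminals, collapse = ", ")))
})

#' @rdname DiscrepancyReport-class
#' @export
setMethod("strainName", "DiscrepancyReport", function(x) x@strain)

#' @rdname DiscrepancyReport-class
#' @export
setMethod("agreements", "DiscrepancyReport", function(x) x@agreements)

#' @rdname DiscrepancyReport-class
#' @export
setMethod("orphanModifications", "DiscrepancyReport",
          function(x) x@orphans)

#' @rdname DiscrepancyReport-class
#' @export
setMethod("silentCapacities", "DiscrepancyReport",
          function(x) x@silentCapacities)

#' @rdname DiscrepancyReport-class
#' @export
setMethod("zeroFamilyOrphans", "DiscrepancyReport", function(x) {
  x@orphans[x@orphans$zeroFamily, , drop = FALSE]
})

setMethod("show", "DiscrepancyReport", function(object) {
  cat(sprintf("DiscrepancyReport: %s (%s mode)\n", object@strain,
              object@mode))
  cat("  agreements:",
      if (length(object@agreements))
        paste(object@agreements, collapse = ", ") else "(none)", "\n")
  if (nrow(object@orphans)) {
    for (i in seq_len(nrow(object@orphans)))
      cat(sprintf("  orphan: %s [missing %s]%s\n",
                  object@orphans$compound[i],
                  object@orphans$missingFamilies[i],
                  if (object@orphans$zeroFamily[i]) " (zero-family)" else ""))
  } else cat("  orphans: (none)\n")
  cat("  silent capacities:",
      if (length(object@silentCapacities))
        paste(object@silentCapacities, collapse = ", ") else "(none)", "\n")
})
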