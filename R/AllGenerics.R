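#' @rdname AlignmentResult-class
#' @param x,object An object.
#' @export
setGeneric("rawScore", function(x) standardGeneric("rawScore"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("percentIdentity", function(x) standardGeneric("percentIdentity"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("percentSimilarity",
           function(x) standardGeneric("percentSimilarity"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("evalue", function(x) standardGeneric("evalue"))

#' @rdname AlignmentResult-class
#' @export
setGeneric("alignedPairs", function(x) standardGeneric("alignedPairs"))

#' @rdname DiagnosticProfile-class
#' @param x An object.
#' @export
setGeneric("oscCall", function(x) standardGeneric("oscCall"))

#' @rdname DiagnosticProfile-class
#' @export
setGeneric("supportingAgreement",
           function(x) standardGeneric("supportingAgreement"))

#' @rdname DiagnosticProfile-class
#' @export
setGeneric("diagnosticResidues",
           function(x) standardGeneric("diagnosticResidues"))

#' @rdname PredictedProfile-class
#' @param x An object.
#' @export
setGeneric("strainName", function(x) standardGeneric("strainName"))

#' @rdname PredictedProfile-class
#' @export
setGeneric("pathwayMode", function(x) standardGeneric("pathwayMode"))

#' @rdname PredictedProfile-class
#' @export
setGeneric("reachableNames", function(x) standardGeneric("reachableNames"))

#' @rdname PredictedProfile-class
#' @export
setGeneric("terminalNames", function(x) standardGeneric("terminalNames"))

#' @rdname DiscrepancyReport-class
#' @param x An object.
#' @export
setGeneric("agreements", function(x) standardGeneric("agreements"))

#' @rdname DiscrepancyReport-class
#' @export
setGeneric("orphanModifications",
           function(x) standardGeneric("orphanModifications"))

#' @rdname DiscrepancyReport-class
#' @export
setGeneric("silentCapacities",
           function(x) standardGeneric("silentCapacities"))

#' @rdname DiscrepancyReport-class
#' @export
setGeneric("zeroFamilyOrphans",
           function(x) standardGeneric("zeroFamilyOrphans"))

#' @rdname EnzymeComplement-class
#' @param x An object.
#' @export
setGeneric("presentFamilies", function(x) standardGeneric("presentFamilies"))
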