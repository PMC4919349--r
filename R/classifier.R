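#' Build a reference annotation for cyclase classification
#'
#' Pairs an annotated reference cyclase with the residue positions used
#' for classification, in reference numbering (human-Osc style).
#' Defaults encode the diagnostic triple 381/449/453: LAS expects T or C
#' at 381, Q at 449 and V at 453; CAS expects Y/H/I. Position 453 is the
#' discriminator; 381 and 449 only count as supporting evidence. An
#' optional table of functional positions powers
#' \code{\link{auditFunctionalResidues}}; no default list is shipped
#' beyond the diagnostic triple, since the full published residue set is
#' figure-bound — supply your own for real references.
#'
#' @param reference Reference sequence (character, \code{AAString} or
#'   single-sequence \code{AAStringSet}); name used as id.
#' @param diagnosticPositions Integer triple in reference numbering.
#' @param lasStates,casStates Named lists (names = positions) of
#'   acceptable residues per class.
#' @param functionalPositions Data frame with columns \code{position}
#'   and \code{expected} (comma-separated residue set), or \code{NULL}.
#' @param numberingOffset Integer added to 1-based sequence index to get
#'   reference numbering (0 when the reference is numbered from its own
#'   first residue).
#' @param referenceClass Class of the reference itself.
#' @return A \code{\link{ReferenceAnnotation-class}} object.
#' @export
referenceAnnotation <- function(reference,
                                diagnosticPositions = c(381L, 449L, 453L),
                                lasStates = NULL, casStates = NULL,
                                functionalPositions = NULL,
                                numberingOffset = 0L,
                                referenceClass = "LAS") {
  id <- sequenceId(reference, "reference")
  seq <- asSingleSequence(reference, "reference")
  refSet <- AAStringSet(seq)
  names(refSet) <- id
  dp <- as.integer(diagnosticPositions)
  pn <- as.character(dp)
  las <- lasStates %||%
    setNames(list(c("T", "C"), "Q", "V"), pn)
  cas <- casStates %||%
    setNames(list("Y", "H", "I"), pn)
  fp <- if (is.null(functionalPositions)) {
    DataFrame(position = integer(0), expected = character(0))
  } else {
    DataFrame(position = as.integer(functionalPositions$position),
              expected = as.character(functionalPositions$expected))
  }
  new("ReferenceAnnotation", reference = refSet,
      numberingOffset = as.integer(numberingOffset),
      diagnosticPositions = dp, lasStates = las, casStates = cas,
      functionalPositions = fp,
      referenceClass = referenceClass)
}

#' Map reference positions onto a query sequence
#'
#' Globally aligns the query to the annotated reference and returns, for
#' every reference position (in reference numbering), the 1-based query
#' index aligned to it, or \code{NA} where the reference position falls
#' in a gap. The mapping is monotone increasing over mapped positions.
#'
#' @param query Query sequence.
#' @param annot A \code{\link{referenceAnnotation}} object.
#' @param substitution,gapOpening,gapExtension See \code{\link{alignPair}}.
#' @return Named integer vector; names are reference numbering.
#' @export
mapReferencePositions <- function(query, annot,
                                  substitution = "BLOSUM62",
                                  gapOpening = 11, gapExtension = 1) {
  refSeq <- as.character(annot@reference)[[1L]]
  aln <- alignPair(query, refSeq, type = "global",
                   substitution = substitution,
                   gapOpening = gapOpening, gapExtension = gapExtension)
  refLen <- nchar(refSeq)
  mapping <- rep(NA_integer_, refLen)
  ap <- aln@alignedPairs
  if (nrow(ap)) mapping[ap[, "subject"]] <- ap[, "query"]
  names(mapping) <- seq_len(refLen) + annot@numberingOffset
  mapping
}

#' Classify a cyclase as LAS or CAS from diagnostic residues
#'
#' Reads the query residues mapped to the annotated diagnostic positions
#' and calls the class from the discriminator position (453 by default):
#' V means lanosterol synthase, I means cycloartenol synthase, anything
#' else — including an unmapped position, as for fragments that do not
#' cover it — yields an indeterminate call. The supporting-agreement
#' count reports how many of the other two positions match the called
#' class's expected residues.
#'
#' @inheritParams mapReferencePositions
#' @return A \code{\link{DiagnosticProfile-class}} object.
#' @export
classifyOsc <- function(query, annot, substitution = "BLOSUM62",
                        gapOpening = 11, gapExtension = 1) {
  qid <- sequenceId(query, "query")
  qseq <- asSingleSequence(query, "query")
  mapping <- mapReferencePositions(qseq, annot,
                                   substitution = substitution,
                                   gapOpening = gapOpening,
                                   gapExtension = gapExtension)
  qchars <- strsplit(qseq, "")[[1L]]
  dp <- annot@diagnosticPositions
  pn <- as.character(dp)
  idx <- mapping[pn]
  mapped <- !is.na(idx)
  residues <- rep("-", 3L)
  residues[mapped] <- qchars[idx[mapped]]
  names(residues) <- pn
  names(mapped) <- pn

  disc <- pn[3L]
  call <- if (!mapped[disc]) "indeterminate"
  else if (residues[disc] %in% annot@lasStates[[disc]]) "LAS"
  else if (residues[disc] %in% annot@casStates[[disc]]) "CAS"
  else "indeterminate"

  agreement <- NA_integer_
  if (call != "indeterminate") {
    states <- if (call == "LAS") annot@lasStates else annot@casStates
    agreement <- sum(vapply(pn[1:2], function(p)
      mapped[p] && residues[p] %in% states[[p]], logical(1)))
  }
  new("DiagnosticProfile", queryId = qid, residues = residues,
      mapped = mapped, call = call,
      supportingAgreement = as.integer(agreement))
}

#' Audit conservation of functional residues
#'
#' Checks every position of the annotation's functional-position table
#' through the reference mapping: a position is conserved when the
#' observed query residue belongs to its expected residue set. Used to
#' ask whether an unproductive strain's cyclase is nonetheless intact at
#' the positions known to matter for catalysis.
#'
#' @inheritParams mapReferencePositions
#' @return A \code{\link{FunctionalAudit-class}} object.
#' @export
auditFunctionalResidues <- function(query, annot,
                                    substitution = "BLOSUM62",
                                    gapOpening = 11, gapExtension = 1) {
  fp <- annot@functionalPositions
  if (nrow(fp) == 0L)
    stop("annotation carries no functional positions to audit")
  qid <- sequenceId(query, "query")
  qseq <- asSingleSequence(query, "query")
  mapping <- mapReferencePositions(qseq, annot,
                                   substitution = substitution,
                                   gapOpening = gapOpening,
                                   gapExtension = gapExtension)
  qchars <- strsplit(qseq, "")[[1L]]
  observed <- character(nrow(fp))
  conserved <- logical(nrow(fp))
  for (i in seq_len(nrow(fp))) {
    pos <- as.character(fp$position[i])
    expected <- strsplit(fp$expected[i], ",", fixed = TRUE)[[1L]]
    idx <- mapping[pos]
    observed[i] <- if (is.na(idx)) "-" else qchars[idx]
    conserved[i] <- !is.na(idx) && observed[i] %in% expected
  }
  tab <- DataFrame(position = fp$position, expected = fp$expected,
                   observed = observed, conserved = conserved)
  divergent <- fp$position[!conserved]
  new("FunctionalAudit", queryId = qid, table = tab,
      verdict = if (length(divergent)) "divergent" else "all_conserved",
      divergentPositions = as.integer(divergent))
}
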