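## Pairwise and multiple alignment: the screening engine behind the
## homolog survey. Optimal affine-gap local/global alignment is delegated
## to Biostrings::pairwiseAlignment; this layer fixes the conventions the
## survey depends on (identity/similarity over aligned columns, gap costs
## of open + L*extend per gap of length L, Karlin-Altschul e-values).

# resolve a substitution matrix given by name ("BLOSUM62", "BLOSUM50",
# ...) from Biostrings, or pass a full matrix through
resolveSubstitutionMatrix <- function(substitution) {
  if (is.matrix(substitution)) {
    if (!isTRUE(all.equal(substitution, t(substitution))))
      stop("substitution matrix must be symmetric")
    return(substitution)
  }
  e <- new.env()
  data(list = substitution, package = "Biostrings", envir = e)
  get(substitution, envir = e)
}

#' Read a substitution matrix in NCBI format
#'
#' Parses the plain-text format used by NCBI BLAST matrix files: a header
#' row of residue letters, one labeled row per residue, \code{#} comments
#' ignored.
#'
#' @param path Matrix file.
#' @return Symmetric numeric matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  labels <- vapply(rows, `[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                   numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  if (!isTRUE(all.equal(vals, t(vals))))
    stop("matrix file is not symmetric")
  vals
}

asSingleSequence <- function(x, what = "sequence") {
  s <- if (is(x, "AAStringSet")) {
    if (length(x) != 1L) stop(what, " must be a single sequence")
    as.character(x)[1L]
  } else if (is(x, "AAString")) {
    as.character(x)
  } else if (is.character(x) && length(x) == 1L) {
    x
  } else stop(what, " must be a single AA sequence")
  if (!nzchar(s)) stop(what, " must be non-empty")
  toupper(s)
}

sequenceId <- function(x, default) {
  nm <- if (is(x, "AAStringSet") || is.character(x)) names(x) else NULL
  if (is.null(nm) || !nzchar(nm[1L])) default else nm[1L]
}

#' Optimal pairwise alignment with affine gaps
#'
#' Smith-Waterman (\code{type = "local"}) or Needleman-Wunsch
#' (\code{type = "global"}) alignment under a substitution matrix and
#' affine gap penalties. A gap of length L costs
#' \code{gapOpening + L * gapExtension} (both given as positive values
#' and subtracted), the convention of protein BLAST. Identity and
#' similarity are computed over aligned residue-residue columns only;
#' similarity counts columns with a positive substitution score
#' ("positives").
#'
#' @param query,subject Sequences (character, \code{AAString} or
#'   single-sequence \code{AAStringSet}).
#' @param type \code{"local"} or \code{"global"}.
#' @param substitution Matrix name known to Biostrings (default
#'   \code{"BLOSUM62"}) or a full symmetric score matrix.
#' @param gapOpening,gapExtension Positive gap penalties (defaults 11/1,
#'   the protein-BLAST defaults).
#' @param queryId,subjectId Identifiers; taken from names when present.
#' @return An \code{\link{AlignmentResult-class}} object.
#' @examples
#' alignPair("HEAGAWGHEE", "PAWHEAE", type = "local",
#'           substitution = "BLOSUM50", gapOpening = 10)
#' @export
alignPair <- function(query, subject, type = c("local", "global"),
                      substitution = "BLOSUM62",
                      gapOpening = 11, gapExtension = 1,
                      queryId = NULL, subjectId = NULL) {
  type <- match.arg(type)
  qid <- queryId %||% sequenceId(query, "query")
  sid <- subjectId %||% sequenceId(subject, "subject")
  q <- asSingleSequence(query, "query")
  s <- asSingleSequence(subject, "subject")
  mat <- resolveSubstitutionMatrix(substitution)
  aln <- pairwiseAlignment(AAString(q), AAString(s),
                           substitutionMatrix = mat,
                           gapOpening = gapOpening,
                           gapExtension = gapExtension,
                           type = type)
  gq <- strsplit(as.character(pattern(aln)), "")[[1L]]
  gs <- strsplit(as.character(subject(aln)), "")[[1L]]
  qi <- start(pattern(aln)) - 1L
  si <- start(subject(aln)) - 1L
  pairs <- matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("query", "subject")))
  nAligned <- 0L; nMatch <- 0L; nPositive <- 0L
  pairList <- vector("list", length(gq))
  for (k in seq_along(gq)) {
    if (gq[k] != "-") qi <- qi + 1L
    if (gs[k] != "-") si <- si + 1L
    if (gq[k] != "-" && gs[k] != "-") {
      nAligned <- nAligned + 1L
      pairList[[nAligned]] <- c(qi, si)
      if (gq[k] == gs[k]) nMatch <- nMatch + 1L
      if (mat[gq[k], gs[k]] > 0) nPositive <- nPositive + 1L
    }
  }
  if (nAligned > 0L)
    pairs <- matrix(unlist(pairList[seq_len(nAligned)]),
                    ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("query", "subject")))
  # Biostrings clips terminal gaps from the displayed global alignment;
  # count columns from first principles: every column consumes at least
  # one residue, aligned columns consume one of each
  alnLen <- if (type == "global")
    nchar(q) + nchar(s) - nAligned
  else length(gq)
  new("AlignmentResult",
      queryId = qid, subjectId = sid, alignedPairs = pairs,
      rawScore = score(aln),
      percentIdentity = if (nAligned) 100 * nMatch / nAligned else 0,
      percentSimilarity = if (nAligned) 100 * nPositive / nAligned else 0,
      evalue = NA_real_,
      alignmentLength = as.integer(alnLen),
      type = type)
}

#' Karlin-Altschul e-value parameters
#'
#' Parameters of the extreme-value statistic
#' \eqn{E = K \cdot mn \cdot e^{-\lambda S}} used to turn raw alignment
#' scores into expected chance-hit counts. Defaults are the published
#' gapped BLOSUM62 constants (lambda 0.267 nats per score unit,
#' K 0.041); the search space defaults to query length times database
#' length and should be set by the caller for multi-sequence databases.
#'
#' @param lambda,K Positive reals.
#' @param searchSpace Effective search space in residues squared (>= 1).
#' @return An object of class \code{"EvalueParams"}.
#' @export
evalueParams <- function(lambda = 0.267, K = 0.041, searchSpace = 1) {
  stopifnot(lambda > 0, K > 0, searchSpace >= 1)
  structure(list(lambda = lambda, K = K, searchSpace = searchSpace),
            class = "EvalueParams")
}

#' Estimate the e-value of an alignment score
#'
#' Computes \eqn{E = K \cdot searchSpace \cdot e^{-\lambda S}}. Given an
#' \code{AlignmentResult}, returns the result with its \code{evalue} slot
#' filled; given a numeric score, returns the e-value.
#'
#' @param x An \code{AlignmentResult} or numeric raw score.
#' @param params An \code{\link{evalueParams}} object.
#' @return Updated \code{AlignmentResult}, or numeric e-value.
#' @export
estimateEvalue <- function(x, params = evalueParams()) {
  stopifnot(inherits(params, "EvalueParams"))
  ev <- function(s) params$K * params$searchSpace * exp(-params$lambda * s)
  if (is(x, "AlignmentResult")) {
    x@evalue <- ev(x@rawScore)
    validObject(x)
    x
  } else {
    ev(x)
  }
}

#' Center-star progressive multiple alignment
#'
#' A small progressive MSA: the center sequence is the record maximizing
#' its summed pairwise global score against all others; every other
#' record is merged into the growing alignment through its global
#' alignment to the center, with gaps preserved once introduced ("once a
#' gap, always a gap"). Adequate for the conserved cyclase domains this
#' package aligns; it makes no claim to MUSCLE-grade accuracy.
#'
#' @param records An \code{AAStringSet} of at least two sequences.
#' @param substitution,gapOpening,gapExtension As \code{\link{alignPair}}.
#' @return An \code{AAMultipleAlignment}; degapping any row reproduces
#'   its input sequence.
#' @export
progressiveMsa <- function(records, substitution = "BLOSUM62",
                           gapOpening = 11, gapExtension = 1) {
  if (!is(records, "AAStringSet"))
    records <- AAStringSet(records)
  n <- length(records)
  if (n < 2L)
    stop("progressive MSA requires at least two sequences")
  ids <- names(records) %||% paste0("seq", seq_len(n))
  if (is.null(names(records))) names(records) <- ids
  seqs <- as.character(records)
  mat <- resolveSubstitutionMatrix(substitution)

  # center = sequence with maximal summed pairwise global score
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    sc <- rawScore(alignPair(seqs[i], seqs[j], type = "global",
                             substitution = mat,
                             gapOpening = gapOpening,
                             gapExtension = gapExtension))
    scores[i, j] <- sc; scores[j, i] <- sc
  }
  center <- which.max(rowSums(scores))

  masterCenter <- strsplit(seqs[center], "")[[1L]]
  rows <- list(strsplit(seqs[center], "")[[1L]])
  names(rows) <- ids[center]

  for (i in setdiff(seq_len(n), center)) {
    aln <- alignPair(seqs[center], seqs[i], type = "global",
                     substitution = mat, gapOpening = gapOpening,
                     gapExtension = gapExtension)
    cg <- character(aln@alignmentLength)
    rg <- character(aln@alignmentLength)
    # reconstruct gapped strings from the traceback
    cgChars <- strsplit(seqs[center], "")[[1L]]
    rgChars <- strsplit(seqs[i], "")[[1L]]
    ap <- aln@alignedPairs
    ci <- 1L; ri <- 1L; k <- 0L; apRow <- 1L
    while (ci <= length(cgChars) || ri <= length(rgChars)) {
      k <- k + 1L
      inPair <- apRow <= nrow(ap) && ci <= length(cgChars) &&
        ri <= length(rgChars) && ap[apRow, 1L] == ci && ap[apRow, 2L] == ri
      if (inPair) {
        cg[k] <- cgChars[ci]; rg[k] <- rgChars[ri]
        ci <- ci + 1L; ri <- ri + 1L; apRow <- apRow + 1L
      } else if (ci <= length(cgChars) &&
                 (apRow > nrow(ap) || ap[apRow, 1L] > ci)) {
        cg[k] <- cgChars[ci]; rg[k] <- "-"; ci <- ci + 1L
      } else {
        cg[k] <- "-"; rg[k] <- rgChars[ri]; ri <- ri + 1L
      }
    }
    cg <- cg[seq_len(k)]; rg <- rg[seq_len(k)]

    # merge pairwise alignment into the master, once a gap always a gap
    M <- length(masterCenter); P <- length(cg)
    newMaster <- character(M + P)
    newRows <- lapply(rows, function(r) character(M + P))
    newRow <- character(M + P)
    mi <- 1L; pi <- 1L; k <- 0L
    while (mi <= M || pi <= P) {
      k <- k + 1L
      if (mi <= M && masterCenter[mi] == "-") {
        newMaster[k] <- "-"
        for (rn in names(rows)) newRows[[rn]][k] <- rows[[rn]][mi]
        newRow[k] <- "-"
        mi <- mi + 1L
      } else if (pi <= P && cg[pi] == "-") {
        newMaster[k] <- "-"
        for (rn in names(rows)) newRows[[rn]][k] <- "-"
        newRow[k] <- rg[pi]
        pi <- pi + 1L
      } else if (mi <= M && pi <= P) {
        newMaster[k] <- masterCenter[mi]
        for (rn in names(rows)) newRows[[rn]][k] <- rows[[rn]][mi]
        newRow[k] <- rg[pi]
        mi <- mi + 1L; pi <- pi + 1L
      } else stop("internal error: center merge out of sync")
    }
    masterCenter <- newMaster[seq_len(k)]
    rows <- lapply(newRows, function(r) r[seq_len(k)])
    rows[[ids[i]]] <- newRow[seq_len(k)]
  }

  gapped <- vapply(rows, paste, character(1), collapse = "")
  out <- AAStringSet(gapped[ids])  # restore input order
  names(out) <- ids
  AAMultipleAlignment(out)
}

#' Character matrix view of a multiple alignment
#'
#' One row per member, one column per alignment column, gaps as
#' \code{"-"}.
#'
#' @param msa An \code{AAMultipleAlignment} (or a character matrix,
#'   returned unchanged).
#' @return Character matrix with member rownames.
#' @export
msaMatrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  rows <- as.character(unmasked(msa))
  m <- do.call(rbind, strsplit(rows, ""))
  rownames(m) <- names(rows)
  m
}

#' Trim a multiple alignment to conserved blocks
#'
#' Drops alignment columns whose gap fraction exceeds
#' \code{maxGapFraction}, then drops surviving runs of consecutive
#' columns shorter than \code{minBlockLength}. Column order is
#' preserved. If every column is removed the returned alignment has zero
#' width, which callers should treat as an empty-alignment signal rather
#' than an error.
#'
#' @param msa An \code{AAMultipleAlignment}.
#' @param maxGapFraction Gap fraction above which a column is dropped.
#' @param minBlockLength Minimum surviving run length.
#' @return Trimmed \code{AAMultipleAlignment}.
#' @export
trimConservedBlocks <- function(msa, maxGapFraction = 0.5,
                                minBlockLength = 2L) {
  m <- msaMatrix(msa)
  if (ncol(m) == 0L) return(msa)
  gapFrac <- colMeans(m == "-")
  keep <- gapFrac <= maxGapFraction
  runs <- rle(keep)
  runs$values[runs$values & runs$lengths < minBlockLength] <- FALSE
  keep <- inverse.rle(runs)
  kept <- m[, keep, drop = FALSE]
  gapped <- apply(kept, 1L, paste, collapse = "")
  if (ncol(kept) == 0L) gapped <- rep("", nrow(m))
  out <- AAStringSet(gapped)
  names(out) <- rownames(m)
  AAMultipleAlignment(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
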