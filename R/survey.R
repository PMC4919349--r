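#' Screening thresholds, including the survey's named presets
#'
#' Three presets mirror the published screen: \code{"osc_genome"}
#' (e-value <= 1e-100 and similarity strictly > 30\%, the genome-wide Osc
#' screen), \code{"osc_metagenome"} (e-value <= 1e-50 and length >= 400
#' residues, the metagenome screen with its fragment-length filter), and
#' \code{"downstream_erg"} (e-value <= 1e-10 and identity >= 20\%, the
#' screen for downstream sterol-biosynthesis proteins). The length filter
#' is inclusive (>= 400) by default; \code{strictLength = TRUE} switches
#' to a strict comparison.
#'
#' @param preset Preset name, or \code{NULL} for fully custom thresholds.
#' @param maxEvalue,minIdentity,minSimilarity,minLength Criteria
#'   (\code{NA} = unused); override preset values when given.
#' @param strictLength Use strictly-greater length comparison.
#' @return A \code{\link{SearchThresholds-class}} object.
#' @examples
#' searchThresholds("osc_genome")
#' searchThresholds(maxEvalue = 1e-20, minLength = 300)
#' @export
searchThresholds <- function(preset = NULL, maxEvalue = NA_real_,
                             minIdentity = NA_real_,
                             minSimilarity = NA_real_,
                             minLength = NA_real_,
                             strictLength = FALSE) {
  presets <- list(
    osc_genome = list(maxEvalue = 1e-100, minSimilarity = 30),
    osc_metagenome = list(maxEvalue = 1e-50, minLength = 400),
    downstream_erg = list(maxEvalue = 1e-10, minIdentity = 20))
  vals <- list(maxEvalue = maxEvalue, minIdentity = minIdentity,
               minSimilarity = minSimilarity, minLength = minLength)
  name <- "custom"
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    name <- preset
    for (f in names(presets[[preset]]))
      if (is.na(vals[[f]])) vals[[f]] <- presets[[preset]][[f]]
  }
  new("SearchThresholds", name = name,
      maxEvalue = as.numeric(vals$maxEvalue),
      minIdentity = as.numeric(vals$minIdentity),
      minSimilarity = as.numeric(vals$minSimilarity),
      minLength = as.numeric(vals$minLength),
      strictLength = strictLength)
}

#' Screen candidate proteins against a reference homolog
#'
#' Aligns every candidate to the reference (local affine-gap alignment),
#' estimates an e-value for each score, and evaluates every criterion of
#' the thresholds. Candidates are reported in input order with the names
#' of any failed criteria; a hit passes iff no criterion failed.
#'
#' @param candidates \code{AAStringSet} of candidate proteins (may be
#'   empty).
#' @param reference Reference protein (single sequence).
#' @param thresholds A \code{\link{searchThresholds}} object.
#' @param substitution,gapOpening,gapExtension Alignment settings, see
#'   \code{\link{alignPair}}.
#' @param params E-value parameters; when \code{NULL}, defaults with
#'   search space = candidate length x reference length per pair.
#' @return \code{DataFrame} with columns \code{query}, \code{subject},
#'   \code{score}, \code{evalue}, \code{identity}, \code{similarity},
#'   \code{length}, \code{passed}, \code{failed_criteria}
#'   (comma-separated, empty when passed).
#' @export
screenCandidates <- function(candidates, reference, thresholds,
                             substitution = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1,
                             params = NULL) {
  if (!is(candidates, "AAStringSet"))
    candidates <- AAStringSet(candidates)
  refId <- sequenceId(reference, "reference")
  ref <- asSingleSequence(reference, "reference")
  ids <- names(candidates) %||% paste0("candidate", seq_along(candidates))
  n <- length(candidates)
  out <- DataFrame(
    query = ids, subject = rep(refId, n), score = numeric(n),
    evalue = numeric(n), identity = numeric(n), similarity = numeric(n),
    length = width(candidates), passed = logical(n),
    failed_criteria = character(n))
  mat <- resolveSubstitutionMatrix(substitution)
  for (i in seq_len(n)) {
    aln <- alignPair(as.character(candidates[[i]]), ref, type = "local",
                     substitution = mat, gapOpening = gapOpening,
                     gapExtension = gapExtension,
                     queryId = ids[i], subjectId = refId)
    p <- params %||% evalueParams(
      searchSpace = as.numeric(width(candidates)[i]) * nchar(ref))
    aln <- estimateEvalue(aln, p)
    failed <- character(0)
    if (!is.na(thresholds@maxEvalue) && !(evalue(aln) <= thresholds@maxEvalue))
      failed <- c(failed, "max_evalue")
    if (!is.na(thresholds@minIdentity) &&
        !(percentIdentity(aln) >= thresholds@minIdentity))
      failed <- c(failed, "min_identity")
    if (!is.na(thresholds@minSimilarity) &&
        !(percentSimilarity(aln) > thresholds@minSimilarity))
      failed <- c(failed, "min_similarity")
    if (!is.na(thresholds@minLength)) {
      lenOk <- if (thresholds@strictLength)
        width(candidates)[i] > thresholds@minLength
      else width(candidates)[i] >= thresholds@minLength
      if (!lenOk) failed <- c(failed, "min_length")
    }
    out$score[i] <- rawScore(aln)
    out$evalue[i] <- evalue(aln)
    out$identity[i] <- percentIdentity(aln)
    out$similarity[i] <- percentSimilarity(aln)
    out$passed[i] <- length(failed) == 0L
    out$failed_criteria[i] <- paste(failed, collapse = ",")
  }
  metadata(out) <- list(thresholds = thresholds)
  out
}

#' Greedy redundancy reduction of a protein collection
#'
#' Iterates records in input order; a record joins the first existing
#' cluster whose founding representative it matches at or above the
#' identity threshold (global alignment), otherwise it founds a new
#' cluster. Representatives are the founders, making the procedure
#' deterministic in input order.
#'
#' @param records An \code{AAStringSet}.
#' @param identityThreshold Percent identity in (0, 100].
#' @param substitution,gapOpening,gapExtension See \code{\link{alignPair}}.
#' @return List with \code{representatives} (an \code{AAStringSet}) and
#'   \code{clusters} (named character vector: record id -> representative
#'   id).
#' @export
reduceRedundancy <- function(records, identityThreshold = 95,
                             substitution = "BLOSUM62",
                             gapOpening = 11, gapExtension = 1) {
  stopifnot(identityThreshold > 0, identityThreshold <= 100)
  if (!is(records, "AAStringSet"))
    records <- AAStringSet(records)
  if (length(records) == 0L)
    return(list(representatives = records,
                clusters = character(0)))
  ids <- names(records) %||% paste0("seq", seq_along(records))
  mat <- resolveSubstitutionMatrix(substitution)
  repIdx <- integer(0)
  clusters <- setNames(character(length(records)), ids)
  for (i in seq_along(records)) {
    assigned <- NA_integer_
    for (r in repIdx) {
      pid <- percentIdentity(alignPair(
        as.character(records[[i]]), as.character(records[[r]]),
        type = "global", substitution = mat, gapOpening = gapOpening,
        gapExtension = gapExtension))
      if (pid >= identityThreshold) { assigned <- r; break }
    }
    if (is.na(assigned)) {
      repIdx <- c(repIdx, i)
      assigned <- i
    }
    clusters[ids[i]] <- ids[assigned]
  }
  list(representatives = records[repIdx], clusters = clusters)
}

#' Summarize a homolog survey
#'
#' Counts records by phylum, taxon group and environment class (whatever
#' of these columns are present), with keys sorted lexicographically for
#' determinism. Accepts the packaged homolog table or a
#' \code{\link{screenCandidates}} hit table (in which case only passing
#' hits are counted and per-key tables are omitted unless metadata
#' columns exist).
#'
#' @param x Data frame (or \code{DataFrame}) of homolog records.
#' @return List with \code{total} and one named count vector per
#'   available grouping column.
#' @examples
#' surveySummary(loadFixtures()$homologs)$total  # 34
#' @export
surveySummary <- function(x) {
  x <- as.data.frame(x)
  if ("passed" %in% colnames(x)) x <- x[x$passed, , drop = FALSE]
  out <- list(total = nrow(x))
  for (col in c("phylum", "taxon_group", "environment_class")) {
    if (col %in% colnames(x)) {
      counts <- table(x[[col]])
      nms <- names(counts) %||% character(0)
      out[[col]] <- setNames(as.integer(counts), nms)[order(nms)]
    }
  }
  out
}
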