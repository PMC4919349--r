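#' Read protein sequences from FASTA
#'
#' Wraps \code{Biostrings::readAAStringSet} with the validation the survey
#' needs: sequences are uppercased, must be non-empty, and may contain
#' only the 20 standard residues plus X. Record ids (the first whitespace
#' token of each header) must be unique. Source metadata is attached as
#' \code{mcols}.
#'
#' @param path FASTA file.
#' @param sourceClass \code{"genome"} or \code{"metagenome"}; recycled.
#' @param taxonGroup,phylum Optional metadata strings; recycled.
#' @return An \code{AAStringSet} with metadata columns \code{sourceClass},
#'   \code{taxonGroup}, \code{phylum}.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 demo", "MKLVX", ">p2", "ggaws"), fa)
#' readProteins(fa)
#' @export
readProteins <- function(path, sourceClass = "genome",
                         taxonGroup = NA_character_,
                         phylum = NA_character_) {
  if (!file.exists(path))
    stop("FASTA file not found: ", path)
  # parse permissively (BStringSet), then validate the alphabet
  # ourselves so violations are reported per record id
  raw <- tryCatch(readBStringSet(path),
                  error = function(e)
                    stop("FASTA parse error in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(raw))
  desc <- sub("^\\S+\\s*", "", names(raw))
  seqs <- toupper(as.character(raw))
  validateProteinSet(seqs, ids)
  out <- AAStringSet(seqs)
  names(out) <- ids
  mcols(out) <- DataFrame(
    description = desc,
    sourceClass = rep_len(sourceClass, length(out)),
    taxonGroup = rep_len(taxonGroup, length(out)),
    phylum = rep_len(phylum, length(out)))
  out
}

# shared validation for read and simulated protein collections
validateProteinSet <- function(seqs, ids) {
  if (anyDuplicated(ids))
    stop("duplicate record ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "))
  ok <- paste0("^[", paste(aminoAlphabet(), collapse = ""), "]+$")
  bad <- !grepl(ok, seqs)
  if (any(bad))
    stop("illegal residue characters in record(s): ",
         paste(ids[bad], collapse = ", "),
         " (allowed: 20 standard residues plus X)")
  invisible(TRUE)
}

#' Write protein sequences to FASTA
#'
#' @param x An \code{AAStringSet}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeProteins <- function(x, path) {
  writeXStringSet(x, path)
  invisible(path)
}

#' Load the packaged survey fixture tables
#'
#' Reads the four packaged tables transcribed from a published survey of
#' Osc-containing bacteria: tested strains and growth conditions, the Osc
#' homolog inventory across bacterial genomes, observed sterols per
#' strain, and sterol-biosynthesis gene complements per strain. Performs
#' vocabulary and cross-reference checks: compound columns must match
#' \code{\link{compoundVocabulary}}, family columns must match
#' \code{\link{enzymeFamilies}}, and every strain observed in this
#' study's lipid table must carry a complement record and a strain
#' record.
#'
#' @param dir Directory holding the fixture TSVs; defaults to the
#'   packaged copies.
#' @return A list with data frames \code{strains}, \code{homologs},
#'   \code{lipids} (wide, one presence column per compound) and
#'   \code{complements} (one locus-tag column per family, \code{"."} for
#'   absent).
#' @examples
#' fx <- loadFixtures()
#' nrow(fx$homologs)  # 34 Osc homolog records
#' @export
loadFixtures <- function(dir = system.file("extdata",
                                           package = "sterolscan")) {
  paths <- file.path(dir, c("table1_strains.tsv", "table2_osc_homologs.tsv",
                            "table3_sterols.tsv", "table4_complements.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing fixture file(s): ", paste(missing, collapse = ", "))
  rd <- function(p) read.delim(p, check.names = FALSE,
                               stringsAsFactors = FALSE)
  strains <- rd(paths[1L])
  homologs <- rd(paths[2L])
  lipids <- rd(paths[3L])
  complements <- rd(paths[4L])

  if (!all(nzchar(homologs$locus_tag)))
    stop("homolog table contains empty locus tags")

  compoundCols <- setdiff(colnames(lipids),
                          c("strain_name", "study_section", "taxon_group"))
  badCompound <- setdiff(compoundCols, compoundVocabulary())
  if (length(badCompound))
    stop("unknown compound name(s) in lipid table: ",
         paste(badCompound, collapse = ", "))
  badSection <- setdiff(lipids$study_section,
                        c("this_study", "previous_study"))
  if (length(badSection))
    stop("unknown study_section value(s): ",
         paste(badSection, collapse = ", "))

  familyCols <- setdiff(colnames(complements),
                        c("strain_name", "study_section"))
  badFamily <- setdiff(familyCols, enzymeFamilies())
  if (length(badFamily))
    stop("unknown enzyme family name(s) in complement table: ",
         paste(badFamily, collapse = ", "))

  tested <- lipids$strain_name[lipids$study_section == "this_study"]
  noComplement <- setdiff(tested, complements$strain_name)
  if (length(noComplement))
    stop("tested strain(s) lacking a complement record: ",
         paste(noComplement, collapse = ", "))
  noStrain <- setdiff(tested, strains$strain_name)
  if (length(noStrain))
    stop("tested strain(s) lacking a strain record: ",
         paste(noStrain, collapse = ", "))

  list(strains = strains, homologs = homologs, lipids = lipids,
       complements = complements)
}

#' Observed compounds for one strain of the lipid table
#'
#' @param lipids Lipid table from \code{\link{loadFixtures}}.
#' @param strain Strain name.
#' @return Character vector of observed compound names.
#' @export
observedCompounds <- function(lipids, strain) {
  row <- lipids[lipids$strain_name == strain, , drop = FALSE]
  if (nrow(row) == 0L)
    stop("strain not found in lipid table: ", strain)
  if (nrow(row) > 1L) row <- row[1L, , drop = FALSE]
  compoundCols <- intersect(colnames(lipids), compoundVocabulary())
  present <- vapply(compoundCols, function(cc) row[[cc]] == "+", logical(1))
  compoundCols[present]
}

#' Write a record table as TSV
#'
#' Writes a homogeneous data frame as a UTF-8, tab-separated table with a
#' header row, the dialect used by all fixture tables. Round-trips
#' through \code{\link{readRecordTable}}.
#'
#' @param records A data frame.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
writeRecordTable <- function(records, path) {
  if (!is.data.frame(records))
    stop("records must be a data frame")
  if (any(vapply(records, is.list, logical(1))))
    stop("heterogeneous (list) columns cannot be written")
  write.table(records, path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeRecordTable
#' @export
readRecordTable <- function(path) {
  read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
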