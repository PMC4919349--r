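#' Standard amino-acid alphabet accepted by sterolscan
#'
#' The 20 standard residues plus \code{X} for ambiguity. Metagenome-derived
#' fragments routinely contain ambiguous calls; anything beyond \code{X}
#' (B, J, Z, U, O, stops) is rejected at read time so downstream scoring
#' never sees it.
#'
#' @return Character vector of single-letter residue codes.
#' @export
aminoAlphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X")
}

#' Controlled vocabulary of observed sterol compounds
#'
#' The compound names under which lipid observations are recorded: squalene
#' plus the cyclized products routinely reported for Osc-containing
#' bacteria. Lipid fixtures and simulated cohorts are restricted to this
#' set.
#'
#' @return Character vector of compound names.
#' @export
compoundVocabulary <- function() {
  c("squalene",
    "cycloartenol",
    "lanosterol",
    "parkeol",
    "4,4-dimethylcholesta-8,24-dien-3-ol",
    "4,4-dimethylcholesta-8-en-3-ol",
    "4-methylcholesta-8,24-dien-3-ol",
    "4-methylcholesta-8-en-3-ol",
    "zymosterol")
}

#' Enzyme families of the modeled sterol pathway
#'
#' The closed set of enzyme families tracked per strain: squalene
#' epoxidase (SE), the two oxidosqualene cyclase classes (LAS, CAS), and
#' the eukaryotic downstream modification proteins ERG11 (C-14
#' demethylase), ERG24 (C-14 reductase), ERG25/ERG26/ERG27 (the C-4
#' demethylation complex) and ERG4/DHCR24 (C-24(28) reductase).
#'
#' @return Character vector of family identifiers.
#' @export
enzymeFamilies <- function() {
  c("SE", "LAS", "CAS", "ERG11", "ERG24",
    "ERG25", "ERG26", "ERG27", "ERG4_DHCR24")
}

# internal: cyclized members of the observation vocabulary
cyclizedVocabulary <- function() {
  setdiff(compoundVocabulary(), "squalene")
}
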