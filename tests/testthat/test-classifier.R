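# a small synthetic annotated reference used across these tests
makeReference <- function(seed = 31, len = 650) {
  set.seed(seed)
  chars <- sample(setdiff(aminoAlphabet(), "X"), len, replace = TRUE)
  chars[c(381, 449, 453)] <- c("T", "Q", "V")  # LAS states
  refSet <- Biostrings::AAStringSet(setNames(paste(chars, collapse = ""),
                                             "refOsc"))
  referenceAnnotation(refSet)
}

test_that("reference mapping is the identity for the reference itself", {
  annot <- makeReference()
  mapping <- mapReferencePositions(annot@reference, annot)
  expect_equal(unname(mapping), seq_len(650))
})

test_that("reference mapping follows deletions by offset arithmetic", {
  annot <- makeReference()
  refSeq <- as.character(annot@reference)[[1]]
  # first 10 residues deleted: position 381 maps to query index 371
  trimmed <- substr(refSeq, 11, 650)
  mapping <- mapReferencePositions(trimmed, annot)
  expect_equal(unname(mapping["381"]), 371L)
  # residues 440-460 deleted: 449 and 453 map to gaps
  gapped <- paste0(substr(refSeq, 1, 439), substr(refSeq, 461, 650))
  mapping <- mapReferencePositions(gapped, annot)
  expect_true(is.na(mapping["449"]))
  expect_true(is.na(mapping["453"]))
  # mapping is monotone over mapped positions
  mapped <- mapping[!is.na(mapping)]
  expect_true(all(diff(mapped) > 0))
})

test_that("the 453 residue dictates the LAS/CAS call and flips with it", {
  annot <- makeReference()
  refSeq <- as.character(annot@reference)[[1]]
  prof <- classifyOsc(annot@reference, annot)
  expect_equal(oscCall(prof), "LAS")
  expect_equal(supportingAgreement(prof), 2L)

  flipped <- refSeq
  substr(flipped, 453, 453) <- "I"
  profI <- classifyOsc(flipped, annot)
  expect_equal(oscCall(profI), "CAS")
  # 381/449 still carry LAS states, so they do not support the CAS call
  expect_equal(supportingAgreement(profI), 0L)

  # neither V nor I -> indeterminate
  odd <- refSeq
  substr(odd, 453, 453) <- "G"
  expect_equal(oscCall(classifyOsc(odd, annot)), "indeterminate")
})

test_that("fragments missing the discriminator yield indeterminate calls", {
  annot <- makeReference()
  refSeq <- as.character(annot@reference)[[1]]
  frag <- substr(refSeq, 1, 400)  # stops before position 453
  prof <- classifyOsc(frag, annot)
  expect_equal(oscCall(prof), "indeterminate")
  expect_false(prof@mapped["453"])
})

test_that("classification ignores the query id and description", {
  annot <- makeReference()
  fam <- simulateFamily(n = 4, divergence = 0.2, seed = 32)
  s <- as.character(fam$records[[1]])
  a <- classifyOsc(setNames(s, "one name"), annot)
  b <- classifyOsc(setNames(s, "another"), annot)
  expect_equal(oscCall(a), oscCall(b))
  expect_equal(diagnosticResidues(a), diagnosticResidues(b))
})

test_that("class labels are recovered on simulated families", {
  fam <- simulateFamily(n = 20, divergence = c(0.05, 0.2, 0.3),
                        seed = 33)
  calls <- vapply(seq_along(fam$records), function(i)
    oscCall(classifyOsc(fam$records[i], fam$annotation)), character(1))
  expect_equal(calls, fam$truth$class)
})

test_that("functional-residue audits match a direct residue lookup", {
  set.seed(34)
  annotBase <- makeReference()
  refSeq <- as.character(annotBase@reference)[[1]]
  positions <- sort(sample(50:600, 8))
  expected <- substring(refSeq, positions, positions)
  annot <- referenceAnnotation(
    annotBase@reference,
    functionalPositions = data.frame(position = positions,
                                     expected = expected))
  audit <- auditFunctionalResidues(annotBase@reference, annot)
  expect_equal(audit@verdict, "all_conserved")

  # introduce one violation synthetically
  mutSeq <- refSeq
  mutPos <- positions[3]
  substr(mutSeq, mutPos, mutPos) <-
    setdiff(c("A", "G"), substr(refSeq, mutPos, mutPos))[1]
  audit2 <- auditFunctionalResidues(mutSeq, annot)
  expect_equal(audit2@verdict, "divergent")
  expect_equal(audit2@divergentPositions, mutPos)

  # a simulated low-divergence family agrees with a brute-force
  # per-position recheck through the mapping
  fam <- simulateFamily(n = 10, divergence = 0.05, seed = 34)
  annotFam <- referenceAnnotation(
    fam$annotation@reference,
    functionalPositions = data.frame(position = positions,
                                     expected = substring(
                                       as.character(
                                         fam$annotation@reference)[[1]],
                                       positions, positions)))
  for (i in seq_along(fam$records)) {
    qseq <- as.character(fam$records[[i]])
    audit <- auditFunctionalResidues(qseq, annotFam)
    mapping <- mapReferencePositions(qseq, annotFam)
    manual <- vapply(seq_along(positions), function(k) {
      idx <- mapping[as.character(positions[k])]
      !is.na(idx) &&
        substr(qseq, idx, idx) == annotFam@functionalPositions$expected[k]
    }, logical(1))
    expect_equal(audit@table$conserved, manual)
  }
  expect_error(auditFunctionalResidues(refSeq, annotBase),
               "no functional positions")
})
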