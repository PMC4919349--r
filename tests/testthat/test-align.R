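test_that("self-alignment scores the diagonal and reports 100% identity", {
  set.seed(11)
  s <- randomProtein(50)
  m62 <- getMatrix("BLOSUM62")
  for (type in c("local", "global")) {
    a <- alignPair(s, s, type = type)
    expect_equal(percentIdentity(a), 100)
    expect_equal(percentSimilarity(a), 100)
    expect_equal(rawScore(a),
                 sum(m62[cbind(strsplit(s, "")[[1]],
                               strsplit(s, "")[[1]])]))
    expect_equal(nrow(alignedPairs(a)), 50L)
  }
})

test_that("the classic local-alignment example matches the DP oracle", {
  m50 <- getMatrix("BLOSUM50")
  a <- alignPair("HEAGAWGHEE", "PAWHEAE", type = "local",
                 substitution = "BLOSUM50", gapOpening = 10,
                 gapExtension = 1)
  # frozen from the independent full-matrix affine DP oracle
  expect_equal(rawScore(a), 25)
  expect_equal(rawScore(a),
               oracleAlignScore("HEAGAWGHEE", "PAWHEAE", m50, 10, 1,
                                "local"))
})

test_that("local score dominates brute-force short sub-alignments", {
  set.seed(12)
  m62 <- getMatrix("BLOSUM62")
  for (k in 1:10) {
    q <- randomProtein(sample(8:20, 1))
    s <- randomProtein(sample(8:20, 1))
    a <- alignPair(q, s, type = "local")
    expect_gte(rawScore(a), 0)
    expect_gte(rawScore(a), bruteForceSubalignments(q, s, m62, 3))
  }
})

test_that("global alignment handles length differences with gaps", {
  a <- alignPair("AAA", "AA", type = "global")
  expect_equal(a@alignmentLength - nrow(alignedPairs(a)), 1L)
  b <- alignPair("WKLM", "WKLM", type = "global")
  expect_equal(b@alignmentLength, 4L)  # zero gap columns
})

test_that("alignment scores equal the independent DP oracle on random instances", {
  set.seed(2024)
  m62 <- getMatrix("BLOSUM62")
  for (k in 1:40) {
    q <- randomProtein(sample(5:60, 1))
    s <- randomProtein(sample(5:60, 1))
    for (type in c("local", "global")) {
      expect_equal(rawScore(alignPair(q, s, type = type)),
                   oracleAlignScore(q, s, m62, 11, 1, type),
                   info = paste(type, q, s))
    }
  }
})

test_that("identity is symmetric and empty sequences are rejected", {
  set.seed(13)
  q <- randomProtein(30); s <- randomProtein(25)
  expect_equal(percentIdentity(alignPair(q, s, type = "global")),
               percentIdentity(alignPair(s, q, type = "global")))
  expect_error(alignPair("", s), "non-empty")
})

test_that("e-value follows the Karlin-Altschul form", {
  p <- evalueParams(searchSpace = 1000)
  expect_equal(estimateEvalue(0, p), p$K * 1000)  # exponential at zero
  p2 <- evalueParams(searchSpace = 2000)
  expect_equal(estimateEvalue(57, p2), 2 * estimateEvalue(57, p))
  # strictly decreasing in score
  scores <- seq(0, 300, by = 10)
  ev <- vapply(scores, estimateEvalue, numeric(1), params = p)
  expect_true(all(diff(ev) < 0))
  a <- alignPair("MKLVW", "MKLVW", type = "local")
  a <- estimateEvalue(a, p)
  expect_equal(evalue(a), estimateEvalue(rawScore(a), p))
})

test_that("progressive MSA preserves inputs and reduces to pairwise", {
  set.seed(14)
  base <- randomProtein(40)
  variant <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(length(ch), k)
    for (i in idx) ch[i] <- sample(setdiff(aminoAlphabet(),
                                           c("X", ch[i])), 1)
    paste(ch, collapse = "")
  }
  seqs <- AAStringSet(c(a = base, b = variant(base, 3),
                        c = substr(base, 5, 40)))
  msa <- progressiveMsa(seqs)
  m <- msaMatrix(msa)
  # degapping any row reproduces its input
  for (id in names(seqs))
    expect_equal(paste(m[id, m[id, ] != "-"], collapse = ""),
                 as.character(seqs[[id]]))
  # identical sequences -> gap-free alignment
  same <- AAStringSet(c(x = base, y = base, z = base))
  expect_false(any(msaMatrix(progressiveMsa(same)) == "-"))
  # two sequences reduce to the global pairwise traceback
  two <- progressiveMsa(seqs[1:2])
  ref <- alignPair(as.character(seqs[[1]]), as.character(seqs[[2]]),
                   type = "global")
  expect_equal(ncol(msaMatrix(two)), ref@alignmentLength)
  expect_error(progressiveMsa(seqs[1]), "at least two")
})

test_that("conserved-block trimming matches a per-column recount", {
  rows <- c(a = "MK-LVWAA-P",
            b = "MKQLV-AATP",
            c = "MK-LVWAA-P",
            d = "MKQLVWAATP")
  msa <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
  m <- msaMatrix(msa)
  maxGap <- 0.4; minBlock <- 2
  keep <- colMeans(m == "-") <= maxGap
  # drop runs shorter than minBlock, by direct scan
  r <- rle(keep); r$values[r$values & r$lengths < minBlock] <- FALSE
  keepRef <- inverse.rle(r)
  trimmed <- trimConservedBlocks(msa, maxGapFraction = maxGap,
                                 minBlockLength = minBlock)
  expect_equal(msaMatrix(trimmed),
               m[, keepRef, drop = FALSE], ignore_attr = TRUE)
  # gap-free alignment is unchanged
  clean <- Biostrings::AAMultipleAlignment(
    Biostrings::AAStringSet(c(x = "MKLV", y = "MKLV")))
  expect_equal(msaMatrix(trimConservedBlocks(clean, 0.5, 1)),
               msaMatrix(clean))
  # a 50%-gapped column survives threshold 0.5; a 60% one does not
  half <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(
    c(p = "M-KL", q = "MAKL", r = "M-KL", s = "MAKL", t = "M-KL")))
  trimmedHalf <- trimConservedBlocks(half, 0.5, 1)
  expect_equal(ncol(msaMatrix(trimmedHalf)), 3L)
  # trimming everything yields the zero-width empty-alignment signal
  allGap <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(
    c(x = "M-", y = "-A")))
  expect_equal(ncol(msaMatrix(trimConservedBlocks(allGap, 0.4, 1))), 0L)
})

test_that("NCBI-format substitution matrices can be read back", {
  m <- getMatrix("BLOSUM62")
  tmp <- tempfile()
  lines <- c("# comment",
             paste(" ", paste(colnames(m), collapse = " ")),
             vapply(rownames(m), function(r)
               paste(r, paste(m[r, ], collapse = " ")), character(1)))
  writeLines(lines, tmp)
  m2 <- readSubstitutionMatrix(tmp)
  expect_equal(m2, m, ignore_attr = FALSE)
})
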