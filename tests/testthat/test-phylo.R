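test_that("p-distances match a direct column scan", {
  rows <- c(a = "MKLV", b = "MKLA", c = "M-LV")
  msa <- Biostrings::AAMultipleAlignment(Biostrings::AAStringSet(rows))
  d <- pairwiseDistances(msa, "p_distance")
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.25)  # 1 of 4 ungapped columns differs
  expect_equal(d["a", "c"], 0)     # gap column excluded
  expect_equal(d["b", "c"], 1 / 3)
  expect_equal(d, t(d))

  # random alignment vs an independent per-pair recount
  set.seed(61)
  m <- matrix(sample(c("A", "C", "D", "-"), 60, replace = TRUE), nrow = 5,
              dimnames = list(paste0("t", 1:5), NULL))
  m[, 1] <- "A"  # guarantee comparability
  dm <- pairwiseDistances(m, "p_distance")
  for (i in 1:4) for (j in (i + 1):5) {
    comp <- m[i, ] != "-" & m[j, ] != "-"
    expect_equal(dm[i, j], mean(m[i, comp] != m[j, comp]))
  }
  # poisson correction is -ln(1 - p)
  dp <- pairwiseDistances(m, "poisson_corrected")
  expect_equal(dp[1, 2], -log(1 - dm[1, 2]))
  # incomparable pairs are named in the error
  bad <- matrix(c("A", "-", "A",
                  "-", "C", "C",
                  "A", "C", "C"), nrow = 3, byrow = TRUE,
                dimnames = list(c("x", "y", "z"), NULL))
  bad <- bad[, 1:2]
  expect_error(pairwiseDistances(bad), "x / y")
})

test_that("neighbor joining exactly recovers additive trees", {
  set.seed(62)
  for (k in 1:5) {
    tr <- ape::rtree(sample(4:10, 1))
    dm <- ape::cophenetic.phylo(tr)
    ord <- sort(rownames(dm))
    nj <- neighborJoining(dm[ord, ord])
    back <- ape::cophenetic.phylo(nj)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(back - dm)), 1e-9)           # path lengths
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj)), 0)  # topology
  }
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(63)
  n <- 8
  dm <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dm[i, j] <- dm[j, i] <- runif(1, 0.1, 2)
  }
  # a random matrix is not additive, so clamping warnings are expected
  mine <- suppressWarnings(neighborJoining(dm))
  reference <- ape::nj(dm)
  expect_equal(as.numeric(ape::dist.topo(mine, reference)), 0)
})

test_that("three taxa give the closed-form star lengths", {
  dm <- matrix(c(0, 3, 4,
                 3, 0, 5,
                 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(dm)
  back <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(back, dm)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
})

test_that("negative branch lengths are clamped with a warning", {
  # violates additivity: the three-point formulas give a negative length
  dm <- matrix(c(0, 3, 4,
                 3, 0, 10,
                 4, 10, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- neighborJoining(dm), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("newick serialization round-trips topology and lengths", {
  set.seed(64)
  tr <- ape::rtree(12)
  tmp <- tempfile(fileext = ".nwk")
  writeNewick(tr, tmp)
  back <- readNewick(tmp)
  expect_equal(as.numeric(suppressWarnings(ape::dist.topo(tr, back))), 0)
  d1 <- ape::cophenetic.phylo(tr)
  expect_lt(max(abs(ape::cophenetic.phylo(back)[rownames(d1),
                                                colnames(d1)] - d1)),
            1e-9)
})

test_that("outgroup rooting splits the tree and keeps path lengths", {
  set.seed(65)
  tr <- ape::rtree(6)
  out <- tr$tip.label[1]
  rooted <- rootWithOutgroup(ape::unroot(tr), out)
  expect_true(ape::is.rooted(rooted))
  d0 <- ape::cophenetic.phylo(tr)
  d1 <- ape::cophenetic.phylo(rooted)[rownames(d0), colnames(d0)]
  expect_lt(max(abs(d1 - d0)), 1e-9)
  expect_error(rootWithOutgroup(tr, "no_such_tip"), "absent")
})

test_that("a deep two-family split roots cleanly; scattered outgroups fail", {
  # two clean clades joined by a long branch, like Osc vs Shc
  txt <- "((o1:1,(o2:1,o3:1):1):5,((i1:1,i2:1):1,(i3:1,i4:1):1):5);"
  tr <- ape::unroot(ape::read.tree(text = txt))
  rooted <- rootWithOutgroup(tr, c("o1", "o2", "o3"))
  kids <- rooted$edge[rooted$edge[, 1] == ape::Ntip(rooted) + 1, 2]
  sides <- lapply(kids, function(k)
    if (k <= ape::Ntip(rooted)) rooted$tip.label[k]
    else ape::extract.clade(rooted, k)$tip.label)
  expect_true(any(vapply(sides, setequal, logical(1),
                         c("o1", "o2", "o3"))))
  # outgroup scattered across the ingroup is rejected by name
  expect_error(rootWithOutgroup(tr, c("o1", "i3")),
               "not monophyletic")
})

test_that("clade membership reports monophyly and assigns queries", {
  txt <- "(((a1:1,a2:1):1,(q1:1,a3:1):1):2,((b1:1,b2:1):1,q2:3):2);"
  tr <- ape::read.tree(text = txt)
  groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B")
  res <- cladeMembership(tr, groups)
  expect_true(res$monophyly[["A"]])  # q1 inside A does not break it
  expect_true(res$monophyly[["B"]])
  expect_equal(res$assignments[["q1"]], "A")
  expect_equal(res$assignments[["q2"]], "B")
  # grafting a B taxon into clade A breaks A's monophyly
  txt2 <- "(((a1:1,b3:1):1,a2:1):2,(b1:1,b2:1):2);"
  groups2 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", b3 = "B")
  res2 <- cladeMembership(ape::read.tree(text = txt2), groups2)
  expect_false(res2$monophyly[["A"]])
  expect_error(cladeMembership(ape::read.tree(text = txt2),
                               c(zz = "Z")), "no labeled taxa")
})

test_that("simulated fragments are assigned to their true group", {
  # two deeply split families (independent ancestors), low divergence
  # within each; fragments of family members must join their family
  famA <- simulateFamily(n = 4, divergence = 0.08, classes = "LAS",
                         ancestorLength = 300,
                         diagnosticPositions = c(100L, 110L, 120L),
                         seed = 66)
  famB <- simulateFamily(n = 4, divergence = 0.08, classes = "CAS",
                         ancestorLength = 300,
                         diagnosticPositions = c(100L, 110L, 120L),
                         seed = 67)
  recsA <- famA$records; names(recsA) <- paste0("A_", 1:4)
  recsB <- famB$records; names(recsB) <- paste0("B_", 1:4)
  frags <- fragmentRecords(c(recsA[1], recsB[1]), lengths = 250L,
                           seed = 66)
  all <- c(recsA, recsB, frags$records)
  # distances from pairwise global alignments (the two families are too
  # divergent for a single joint MSA to be meaningful)
  n <- length(all)
  dm <- matrix(0, n, n, dimnames = list(names(all), names(all)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    pid <- percentIdentity(alignPair(as.character(all[[i]]),
                                     as.character(all[[j]]),
                                     type = "global"))
    dm[i, j] <- dm[j, i] <- 1 - pid / 100
  }
  tr <- suppressWarnings(neighborJoining(dm))  # non-additive distances
  groups <- setNames(rep(c("A", "B"), each = 4),
                     c(names(recsA), names(recsB)))
  rooted <- rootWithOutgroup(tr, "B_2")
  res <- cladeMembership(rooted, groups)
  expect_equal(res$assignments[["A_1_frag"]], "A")
  expect_equal(res$assignments[["B_1_frag"]], "B")
})
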