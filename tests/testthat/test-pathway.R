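test_that("compound naming is correct and bijective over the named set", {
  expect_equal(compoundName(compoundState("cyclized", c4Methyl = 2,
                                          c14Methyl = TRUE,
                                          delta8 = TRUE)),
               "lanosterol")
  expect_equal(compoundName(compoundState("cyclized", c4Methyl = 2,
                                          c14Methyl = TRUE,
                                          cyclopropane = TRUE)),
               "cycloartenol")
  expect_equal(compoundName(compoundState("cyclized", c4Methyl = 0,
                                          c14Methyl = FALSE,
                                          delta8 = TRUE)),
               "zymosterol")
  expect_equal(compoundName(compoundState("linear")), "squalene")
  states <- namedCompoundStates()
  names_ <- vapply(states, compoundName, character(1))
  expect_equal(unname(names_), names(states))  # naming inverts the table
  expect_false(anyDuplicated(names_) > 0)
  # invariant-violating state is rejected
  expect_error(compoundState("cyclized", c14Methyl = TRUE,
                             delta14 = TRUE), "demethylation")
})

test_that("required families match the eukaryotic pathway", {
  c4 <- requiredFamilies("C-4 demethylation", "canonical")
  expect_setequal(c4, c("ERG25", "ERG26", "ERG27"))
  expect_length(c4, 3L)
  expect_false(attr(c4, "anyOne"))
  c4r <- requiredFamilies("C-4 demethylation", "relaxed")
  expect_true(attr(c4r, "anyOne"))
  expect_equal(c(requiredFamilies("C-14 demethylation")), "ERG11")
  expect_equal(c(requiredFamilies("squalene oxygenation")), "SE")
  expect_error(requiredFamilies("no such reaction"), "unknown reaction")
})

test_that("reachability reproduces the worked strain examples", {
  # SE + CAS: only cycloartenol beyond the precursors
  p <- reachableCompounds(c("SE", "CAS"))
  expect_setequal(reachableNames(p),
                  c("squalene", "oxidosqualene", "cycloartenol"))
  expect_equal(terminalNames(p), "cycloartenol")
  # empty complement: squalene only
  expect_equal(reachableNames(reachableCompounds(character(0))),
               "squalene")
  # the full LAS route reaches zymosterol
  full <- reachableCompounds(c("SE", "LAS", "ERG11", "ERG24", "ERG25",
                               "ERG26", "ERG27"))
  expect_true("zymosterol" %in% reachableNames(full))
  # with the side-chain reductase, saturated variants appear
  withErg4 <- reachableCompounds(c("SE", "LAS", "ERG11", "ERG24",
                                   "ERG25", "ERG26", "ERG27",
                                   "ERG4_DHCR24"))
  expect_true(all(c("4,4-dimethylcholesta-8-en-3-ol",
                    "4-methylcholesta-8-en-3-ol") %in%
                    reachableNames(withErg4)))
})

test_that("pathway modes and options behave as documented", {
  # relaxed mode lets a single C-4 family demethylate
  erg25only <- c("SE", "LAS", "ERG11", "ERG24", "ERG25")
  expect_false("zymosterol" %in%
                 reachableNames(reachableCompounds(erg25only,
                                                   "canonical")))
  expect_true("zymosterol" %in%
                reachableNames(reachableCompounds(erg25only, "relaxed")))
  # parkeol requires the product-spectrum option
  las <- c("SE", "LAS")
  expect_false("parkeol" %in% reachableNames(reachableCompounds(las)))
  expect_true("parkeol" %in%
                reachableNames(reachableCompounds(las,
                                                  parkeolSpectrum = TRUE)))
})

test_that("minimal missing sets match exhaustive subset enumeration", {
  # independent oracle: scan every subset of the absent families and
  # take the smallest (lexicographically first) that reaches the target
  oracleMissing <- function(fams, target, mode = "canonical") {
    absent <- sort(setdiff(enzymeFamilies(), fams))
    best <- NULL
    for (k in 0:length(absent)) {
      for (sub in if (k == 0) list(character(0))
           else combn(absent, k, simplify = FALSE)) {
        if (target %in% reachableNames(
          reachableCompounds(c(fams, sub), mode = mode))) {
          best <- sub
          break
        }
      }
      if (!is.null(best)) break
    }
    best
  }
  cases <- list(
    list(fams = c("SE", "LAS"), target = "zymosterol"),
    list(fams = c("SE", "LAS", "ERG11", "ERG24"),
         target = "4-methylcholesta-8,24-dien-3-ol"),
    list(fams = character(0), target = "cycloartenol"),
    list(fams = c("SE", "CAS"), target = "zymosterol"))
  for (cs in cases) {
    expect_equal(minimalMissingFamilies(cs$fams, cs$target),
                 oracleMissing(cs$fams, cs$target), info = cs$target)
  }
  expect_equal(minimalMissingFamilies(c("SE", "LAS"), "zymosterol"),
               c("ERG11", "ERG24", "ERG25", "ERG26", "ERG27"))
  # full complement: nothing missing
  expect_equal(minimalMissingFamilies(enzymeFamilies(), "zymosterol"),
               character(0))
  # infeasible targets are signaled, not crashed
  expect_identical(minimalMissingFamilies(c("SE", "CAS"), "parkeol"), NA)
})

test_that("reachability is monotone and mode-consistent", {
  set.seed(41)
  fams <- enzymeFamilies()
  for (k in 1:25) {
    a <- sample(fams, sample.int(length(fams), 1))
    extra <- setdiff(fams, a)
    b <- union(a, if (length(extra)) sample(extra,
                                            sample.int(length(extra), 1))
               else character(0))
    for (mode in c("canonical", "relaxed")) {
      ra <- reachableNames(reachableCompounds(a, mode))
      rb <- reachableNames(reachableCompounds(b, mode))
      expect_true(all(ra %in% rb))  # complement growth
    }
    # canonical reachable set is contained in relaxed
    expect_true(all(reachableNames(reachableCompounds(a, "canonical"))
                    %in% reachableNames(reachableCompounds(a,
                                                           "relaxed"))))
  }
})

test_that("the closure is deterministic and idempotent", {
  fams <- c("SE", "LAS", "ERG11", "ERG24", "ERG4_DHCR24")
  r1 <- reachableNames(reachableCompounds(fams))
  r2 <- reachableNames(reachableCompounds(rev(fams)))
  expect_identical(r1, r2)
  expect_identical(r1, reachableNames(reachableCompounds(fams)))
})
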