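# Independent oracles used across the suite. These deliberately share no
# code with the package: the aligner is a plain full-matrix affine-gap
# dynamic program (three matrices, no shortcuts), and the small helpers
# recount things by direct scanning.

# score-only affine-gap DP; a gap of length L costs open + L * ext
oracleAlignScore <- function(q, s, mat, open, ext,
                             type = c("local", "global")) {
  type <- match.arg(type)
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in subject (consumes query)
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in query (consumes subject)
  local <- type == "local"
  M[1, 1] <- 0
  if (!local) {
    for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  } else {
    M[, 1] <- 0
    M[1, ] <- 0
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- mat[qc[i], sc[j]]
      best <- max(M[i, j], Ix[i, j], Iy[i, j])
      if (local) best <- max(best, 0)
      M[i + 1, j + 1] <- sub + best
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext)
    }
  }
  if (local) max(0, max(M)) else max(M[n + 1, m + 1],
                                     Ix[n + 1, m + 1],
                                     Iy[n + 1, m + 1])
}

getMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

randomProtein <- function(len, alphabet = setdiff(aminoAlphabet(), "X")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# all ungapped sub-alignment scores up to a given length
bruteForceSubalignments <- function(q, s, mat, maxLen = 3) {
  qc <- strsplit(q, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  best <- 0
  for (L in seq_len(maxLen)) {
    for (i in seq_len(length(qc) - L + 1)) {
      for (j in seq_len(length(sc) - L + 1)) {
        sco <- sum(mat[cbind(qc[i:(i + L - 1)], sc[j:(j + L - 1)])])
        if (sco > best) best <- sco
      }
    }
  }
  best
}
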