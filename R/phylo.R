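## Distance-based phylogenetics over trimmed alignments: p-distances,
## canonical neighbor-joining with deterministic tie-breaking, outgroup
## rooting and clade-membership queries. Trees are ape "phylo" objects
## so the usual newick tooling applies.

#' Pairwise distances from a multiple alignment
#'
#' For each taxon pair, columns where both rows carry a residue are
#' compared: \code{p_distance} is the mismatch fraction;
#' \code{poisson_corrected} is \eqn{-\ln(1 - p)}, capped at
#' \code{maxDistance} as p approaches 1.
#'
#' @param msa An \code{AAMultipleAlignment} (or character matrix) of at
#'   least 3 rows.
#' @param method \code{"p_distance"} or \code{"poisson_corrected"}.
#' @param maxDistance Cap for the corrected distance (default 10).
#' @return Symmetric numeric matrix with taxon dimnames.
#' @export
pairwiseDistances <- function(msa,
                              method = c("p_distance",
                                         "poisson_corrected"),
                              maxDistance = 10) {
  method <- match.arg(method)
  m <- msaMatrix(msa)
  n <- nrow(m)
  if (n < 3L) stop("at least 3 taxa are required")
  if (ncol(m) < 1L) stop("alignment has no columns")
  taxa <- rownames(m) %||% paste0("t", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    comparable <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(comparable))
      stop("no comparable columns for pair ", taxa[i], " / ", taxa[j])
    p <- mean(m[i, comparable] != m[j, comparable])
    v <- if (method == "p_distance") p
    else if (p >= 1 - exp(-maxDistance)) maxDistance
    else -log(1 - p)
    d[i, j] <- v; d[j, i] <- v
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (Saitou-Nei Q criterion with the standard
#' branch-length formulas), implemented with a deterministic tie-break:
#' among pairs minimizing Q, the pair whose subtree labels (each
#' represented by its lexicographically smallest tip) sort first is
#' joined. Negative branch lengths are clamped to zero with a warning.
#' Exactly recovers additive matrices, topology and path lengths.
#'
#' @param dm Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(dm) {
  if (!isSymmetric(unname(dm)) || any(dm < 0) || any(diag(dm) != 0))
    stop("dm must be symmetric and non-negative with a zero diagonal")
  taxa <- rownames(dm)
  n <- length(taxa)
  if (n < 3L) stop("at least 3 taxa are required")

  clampWarned <- FALSE
  clamp <- function(x) {
    if (x < 0) {
      if (!clampWarned)
        warning("negative branch length(s) clamped to zero")
      clampWarned <<- TRUE
      0
    } else x
  }

  # active nodes: provisional ids (tips 1..n, internals n+1, n+2, ...)
  nodeId <- seq_len(n)
  keys <- taxa  # lexicographic tie-break keys
  D <- dm
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  nextInternal <- n + 1L

  while (length(nodeId) > 3L) {
    r <- length(nodeId)
    R <- rowSums(D)
    best <- NULL; bestQ <- Inf; bestKey <- NULL
    for (i in seq_len(r - 1L)) for (j in seq(i + 1L, r)) {
      q <- (r - 2) * D[i, j] - R[i] - R[j]
      key <- sort(c(keys[i], keys[j]))
      better <- q < bestQ - 1e-12 ||
        (abs(q - bestQ) <= 1e-12 && !is.null(bestKey) &&
           (key[1L] < bestKey[1L] ||
              (key[1L] == bestKey[1L] && key[2L] < bestKey[2L])))
      if (is.null(best) || better) {
        best <- c(i, j); bestQ <- q; bestKey <- key
      }
    }
    i <- best[1L]; j <- best[2L]
    vi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2)))
    vj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (r - 2))))
    u <- nextInternal; nextInternal <- nextInternal + 1L
    edges <- rbind(edges, c(u, nodeId[i]), c(u, nodeId[j]))
    lens <- c(lens, vi, vj)
    newD <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D2 <- matrix(0, length(keep) + 1L, length(keep) + 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep, drop = FALSE]
    D2[length(keep) + 1L, seq_along(keep)] <- newD[keep]
    D2[seq_along(keep), length(keep) + 1L] <- newD[keep]
    D <- D2
    keys <- c(keys[keep], min(keys[c(i, j)]))
    nodeId <- c(nodeId[keep], u)
  }

  # final three-point join
  u <- nextInternal
  v1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  v2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  v3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  edges <- rbind(edges, c(u, nodeId[1L]), c(u, nodeId[2L]),
                 c(u, nodeId[3L]))
  lens <- c(lens, v1, v2, v3)
  nInternal <- u - n

  # renumber internal nodes: ape expects the root (never a child) first
  children <- edges[, 2L]
  rootProv <- u
  internalProv <- seq(n + 1L, u)
  ordering <- c(rootProv, setdiff(rev(internalProv), rootProv))
  remap <- integer(u)
  remap[seq_len(n)] <- seq_len(n)
  remap[ordering] <- n + seq_len(nInternal)
  edge <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
  storage.mode(edge) <- "integer"
  tree <- list(edge = edge, edge.length = lens, tip.label = taxa,
               Nnode = nInternal)
  class(tree) <- "phylo"
  attr(tree, "order") <- NULL
  stats::reorder(tree, "cladewise")
}

#' Root a tree on the branch separating an outgroup
#'
#' Checks that the outgroup tips are monophyletic on the unrooted tree
#' (they sit on one side of some branch) and roots the tree on that
#' branch. A non-monophyletic outgroup is an error naming the intruding
#' ingroup taxa found inside the smallest clade containing the outgroup.
#'
#' @param tree An unrooted \code{phylo} tree.
#' @param outgroup Character vector of outgroup tip labels.
#' @return A rooted \code{phylo} tree.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup taxa absent from tree: ",
         paste(missing, collapse = ", "))
  ingroup <- setdiff(tree$tip.label, outgroup)
  if (length(ingroup) == 0L)
    stop("outgroup covers every tip")

  # monophyly on the unrooted tree: some split separates outgroup from
  # ingroup exactly
  if (length(outgroup) > 1L) {
    anchored <- root(tree, outgroup = ingroup[1L], resolve.root = TRUE)
    mrca <- getMRCA(anchored, outgroup)
    cladeTips <- tipsBelow(anchored, mrca)
    intruders <- setdiff(cladeTips, outgroup)
    if (length(intruders))
      stop("outgroup is not monophyletic; intruding taxa: ",
           paste(sort(intruders), collapse = ", "))
  }
  root(tree, outgroup = outgroup, resolve.root = TRUE)
}

# tips descending from a node (the node itself if a tip)
tipsBelow <- function(tree, node) {
  n <- Ntip(tree)
  if (node <= n) return(tree$tip.label[node])
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    tips <- kids[kids <= n]
    acc <- c(acc, tips)
    stack <- c(stack, kids[kids > n])
  }
  tree$tip.label[acc]
}

#' Group monophyly and nearest-group assignment on a rooted tree
#'
#' For each labeled group, reports whether its taxa form exactly one
#' maximal clade (judged among labeled tips, so unlabeled queries nested
#' inside a group do not break its monophyly). Each unlabeled tip is
#' assigned the group of its smallest enclosing clade whose labeled tips
#' all belong to one group, or \code{"unassigned"} if none exists below
#' the root.
#'
#' @param tree A rooted \code{phylo} tree.
#' @param groups Named character vector: tip label -> group.
#' @return List with \code{monophyly} (named logical per group) and
#'   \code{assignments} (named character per unlabeled tip).
#' @export
cladeMembership <- function(tree, groups) {
  if (!is.rooted(tree)) stop("tree must be rooted")
  labeled <- intersect(names(groups), tree$tip.label)
  if (length(labeled) == 0L)
    stop("no labeled taxa present in the tree")
  groups <- groups[labeled]

  monophyly <- vapply(sort(unique(groups)), function(g) {
    tips <- names(groups)[groups == g]
    if (length(tips) == 1L) return(TRUE)
    mrca <- getMRCA(tree, tips)
    below <- intersect(tipsBelow(tree, mrca), labeled)
    setequal(below, tips)
  }, logical(1))

  n <- Ntip(tree)
  parent <- integer(n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  queries <- setdiff(tree$tip.label, labeled)
  assignments <- vapply(queries, function(q) {
    node <- which(tree$tip.label == q)
    repeat {
      node <- parent[node]
      if (node == 0L) return("unassigned")
      below <- intersect(tipsBelow(tree, node), labeled)
      if (length(below)) {
        gg <- unique(groups[below])
        return(if (length(gg) == 1L) unname(gg) else "unassigned")
      }
      if (node == n + 1L) return("unassigned")
    }
  }, character(1))

  list(monophyly = monophyly, assignments = assignments)
}

#' Read and write trees in newick format
#'
#' Thin wrappers over \code{ape::read.tree} / \code{ape::write.tree}
#' with enough digits to round-trip branch lengths.
#'
#' @param tree A \code{phylo} tree.
#' @param path File path.
#' @return \code{readNewick} returns a \code{phylo}; \code{writeNewick}
#'   returns \code{path} invisibly.
#' @export
writeNewick <- function(tree, path) {
  txt <- write.tree(tree, digits = 15)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) {
  read.tree(path)
}
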