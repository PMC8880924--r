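# Tree building and topology utilities.

#' Neighbor-joining tree from a distance matrix
#'
#' Builds the unrooted NJ tree. Negative intermediate branch lengths are
#' clamped to zero. The two-taxon case returns the single edge split evenly
#' across the root so that the patristic distance equals the input distance.
#'
#' @param dm A [DistanceMatrix-class] or a symmetric numeric matrix with
#'   dimnames.
#' @return An `ape::phylo` tree.
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- neighborJoining(d)
#' @export
neighborJoining <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else dm
  if (!isSymmetric(unname(d), tol = 1e-9)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2) stop("at least 2 taxa are required")
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2),
               edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- "cladewise"
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Patristic tree diameter
#'
#' The maximum path length (sum of branch lengths) between any pair of
#' leaves; the quantity the gene-QC rule compares to its threshold.
#'
#' @param tree An `ape::phylo` with branch lengths.
#' @return The diameter as a single number.
#' @examples
#' treeDiameter(parseNewick("((A:0.1,B:0.2):0.3,C:0.4);"))  # 0.9
#' @export
treeDiameter <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  if (length(tree$tip.label) < 2) return(0)
  max(ape::cophenetic.phylo(tree))
}

# Leaf sets on the child side of every edge (list parallel to tree$edge rows).
.edgeLeafSets <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sets[[tree$edge[e, 2]]])
}

# Canonical string key of the unordered split induced by a leaf subset.
.splitKey <- function(side, all_tips) {
  a <- paste(sort(side), collapse = "\r")
  b <- paste(sort(setdiff(all_tips, side)), collapse = "\r")
  if (a < b) paste(a, b, sep = "\n") else paste(b, a, sep = "\n")
}

# All non-trivial splits of a tree as canonical keys.
.treeSplits <- function(tree) {
  tips <- tree$tip.label
  sets <- .edgeLeafSets(tree)
  keep <- vapply(sets, function(s) {
    k <- length(s); k >= 2 && k <= length(tips) - 2
  }, logical(1))
  unique(vapply(sets[keep], .splitKey, character(1), all_tips = tips))
}

# Does some edge of the (unrooted) tree separate exactly `group` from the
# rest? Reciprocal monophyly of group vs complement.
.hasSeparatingEdge <- function(tree, group) {
  tips <- tree$tip.label
  group <- intersect(group, tips)
  if (length(group) %in% c(0L, length(tips))) return(TRUE)
  if (length(group) == 1L || length(group) == length(tips) - 1L) return(TRUE)
  key <- .splitKey(group, tips)
  key %in% vapply(.edgeLeafSets(tree), .splitKey, character(1), all_tips = tips)
}
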