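# Nonparametric bootstrap support for NJ trees.

#' Bootstrap support on the NJ point-estimate tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate, and annotates every internal edge of the point-estimate
#' tree with the percentage of replicates containing the same bipartition.
#' Supports are stored as internal node labels (the Newick convention), so
#' they survive writing and re-reading.
#'
#' @param aln A [SeqAlignment-class].
#' @param model Distance model passed to [pairwiseDistances()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param params [GTRParams-class] for `GTR_ML` distances.
#' @return The NJ tree with `node.label` carrying supports in [0, 100]
#'   (empty label on the root).
#' @export
bootstrapSupport <- function(aln, model = "JC69", n_reps = 100, seed = 1,
                             params = gtrParams()) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  point <- neighborJoining(pairwiseDistances(aln, model, params))
  tips <- point$tip.label
  L <- alignmentLength(aln)
  counts <- new.env(parent = emptyenv())
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    m <- .alnCharMatrix(aln)[, cols, drop = FALSE]
    res <- seqAlignment(setNames(apply(m, 1, paste, collapse = ""), rownames(m)),
                        taxonLabels(aln), aln@mode)
    rt <- neighborJoining(pairwiseDistances(res, model, params))
    for (key in .treeSplits(rt)) {
      cur <- if (is.null(counts[[key]])) 0L else counts[[key]]
      assign(key, cur + 1L, envir = counts)
    }
  }
  ntip <- length(tips)
  sets <- .edgeLeafSets(point)
  node_lab <- rep("", point$Nnode)
  for (e in seq_len(nrow(point$edge))) {
    chd <- point$edge[e, 2]
    if (chd <= ntip) next
    side <- sets[[e]]
    if (length(side) < 2 || length(side) > ntip - 2) next
    key <- .splitKey(side, tips)
    k <- if (is.null(counts[[key]])) 0L else counts[[key]]
    node_lab[chd - ntip] <- format(k / n_reps * 100)
  }
  point$node.label <- node_lab
  point
}
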