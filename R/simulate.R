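# Sequence simulation along a tree under GTR(+Gamma).

# Evolve integer state vector (1..4) along one branch of length t at
# relative rate `rate` (transition matrix from the eigensystem).
.evolveStates <- function(states, t, eig, rate = 1) {
  if (t <= 0) return(states)
  P <- .gtrTransition(eig, t * rate)
  out <- states
  for (s in 1:4) {
    idx <- which(states == s)
    if (length(idx))
      out[idx] <- sample.int(4, length(idx), replace = TRUE, prob = P[s, ])
  }
  out
}

#' Simulate an alignment along a tree under GTR(+Gamma)
#'
#' The root state of each site is drawn from the stationary base
#' frequencies; states then evolve along each branch with transition matrix
#' \eqn{\exp(Qt)}. With Gamma rate variation, each site is assigned one of
#' the discrete rate categories for the whole tree, as sequence simulators
#' conventionally do.
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param params A [GTRParams-class].
#' @param length Number of sites (>= 1).
#' @param seed Integer seed; the simulation is a pure function of
#'   (tree, params, length, seed).
#' @return A nucleotide [SeqAlignment-class] with one row per leaf.
#' @export
simulateGTRAlignment <- function(tree, params, length, seed) {
  if (length < 1) stop("length must be >= 1")
  validObject(params)
  set.seed(seed)
  eig <- .gtrEigen(params)
  rates <- .gammaRates(params)
  site_rate <- if (length(rates) == 1) rep(1, length) else
    rates[sample.int(length(rates), length, replace = TRUE)]
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(pre$edge)))  # preorder traversal
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1]] <- sample.int(4, length, replace = TRUE, prob = params@freqs)
  for (e in edge_order) {
    par <- pre$edge[e, 1]; chd <- pre$edge[e, 2]
    t <- pre$edge.length[e]
    x <- states[[par]]
    # evolve each rate class separately
    out <- x
    for (r in unique(site_rate)) {
      idx <- which(site_rate == r)
      out[idx] <- .evolveStates(x[idx], t, eig, r)
    }
    states[[chd]] <- out
  }
  seqs <- vapply(seq_len(ntip), function(i)
    paste(DNA_STATES[states[[i]]], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  seqAlignment(seqs, taxon = tree$tip.label, mode = "nucleotide")
}
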