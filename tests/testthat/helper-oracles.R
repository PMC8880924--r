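# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: rate matrices are built from the model
# definition and exponentiated with Matrix::expm, likelihoods are summed by
# explicit enumeration over ancestral states, and the local-alignment
# oracle is a plain quadratic Gotoh dynamic program.

oracle_rate_matrix <- function(params) {
  st <- c("A", "C", "G", "T")
  r <- params@rates; pi <- params@freqs
  s <- matrix(0, 4, 4, dimnames = list(st, st))
  s["A", "C"] <- s["C", "A"] <- r[1]; s["A", "G"] <- s["G", "A"] <- r[2]
  s["A", "T"] <- s["T", "A"] <- r[3]; s["C", "G"] <- s["G", "C"] <- r[4]
  s["C", "T"] <- s["T", "C"] <- r[5]; s["G", "T"] <- s["T", "G"] <- r[6]
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  Q / (-sum(pi * diag(Q)))
}

oracle_gamma_rates <- function(params) {
  if (is.na(params@gammaShape) || params@nCategories == 1L) return(1)
  k <- params@nCategories; a <- params@gammaShape
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = a, rate = a)
  r / mean(r)
}

# Log-likelihood by explicit summation over all ancestral state
# assignments (feasible for <= 5 taxa, <= 4 sites).
oracle_loglik <- function(tree, aln, params) {
  Q <- oracle_rate_matrix(params)
  rates <- oracle_gamma_rates(params)
  st <- c("A", "C", "G", "T")
  tips <- tree$tip.label
  ntip <- length(tips)
  m <- do.call(rbind, strsplit(alignedSeqs(aln)[tips], ""))
  total <- 0
  for (site in seq_len(ncol(m))) {
    lik_cat <- numeric(length(rates))
    for (ci in seq_along(rates)) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        as.matrix(Matrix::expm(Q * tree$edge.length[e] * rates[ci])))
      combos <- as.matrix(expand.grid(rep(list(1:4), tree$Nnode)))
      lik <- 0
      for (rr in seq_len(nrow(combos))) {
        stateOf <- function(node) {
          if (node <= ntip) match(m[node, site], st)  # NA = missing
          else combos[rr, node - ntip]
        }
        pr <- params@freqs[combos[rr, 1]]
        for (e in seq_len(nrow(tree$edge))) {
          b <- stateOf(tree$edge[e, 2])
          if (is.na(b)) next
          pr <- pr * P[[e]][stateOf(tree$edge[e, 1]), b]
        }
        lik <- lik + pr
      }
      lik_cat[ci] <- lik
    }
    total <- total + log(mean(lik_cat))
  }
  total
}

# Smith-Waterman local alignment score with affine gaps (Gotoh), matching
# the convention that a gap of length k costs open + k * extend.
oracle_sw_score <- function(a, b, match, mismatch, gap_open, gap_extend) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)   # gap in x (horizontal)
  F <- matrix(NEG, n + 1, m + 1)   # gap in y (vertical)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1] + gap_extend, H[i, j - 1] + gap_open + gap_extend)
      F[i, j] <- max(F[i - 1, j] + gap_extend, H[i - 1, j] + gap_open + gap_extend)
      sub <- H[i - 1, j - 1] + if (x[i - 1] == y[j - 1]) match else mismatch
      H[i, j] <- max(0, sub, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# All maximal single-copy clades of an unrooted tree, by brute force over
# every bipartition side (plus singletons), for checking the paralog
# partition.
oracle_paralog_groups <- function(tree, taxa) {
  ids <- tree$tip.label
  sides <- list()
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", length(ids) + tree$Nnode)
  for (i in seq_along(ids)) sets[[i]] <- ids[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
    sides[[length(sides) + 1]] <- sets[[chd]]
  }
  cands <- c(sides, lapply(sides, function(s) setdiff(ids, s)), list(ids))
  cands <- unique(lapply(cands, sort))
  ok <- vapply(cands, function(s) !anyDuplicated(taxa[s]), logical(1))
  cands <- cands[ok]
  maximal <- cands[vapply(seq_along(cands), function(i)
    !any(vapply(seq_along(cands), function(j)
      j != i && all(cands[[i]] %in% cands[[j]]), logical(1))), logical(1))]
  maximal
}

random_jc_pair <- function(L, p_target, seed) {
  set.seed(seed)
  s1 <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  s2 <- s1
  flip <- which(runif(L) < p_target)
  for (i in flip) s2[i] <- sample(setdiff(c("A", "C", "G", "T"), s1[i]), 1)
  seqAlignment(c(a = paste(s1, collapse = ""), b = paste(s2, collapse = "")))
}

random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.5)
  ape::unroot(tr)
}

default_bench_params <- function() {
  gtrParams(rates = c(1.2, 3, 0.8, 1.1, 3.2, 1),
            freqs = c(0.28, 0.22, 0.24, 0.26))
}
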