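# GTR rate-matrix machinery shared by distances, likelihood and simulation.

# Normalized GTR rate matrix: off-diagonal Q[i,j] = s_ij * pi_j, diagonal
# makes rows sum to zero, scaled so the mean rate at stationarity is 1.
.gtrRateMatrix <- function(params) {
  s <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  s["A", "C"] <- s["C", "A"] <- params@rates[1]
  s["A", "G"] <- s["G", "A"] <- params@rates[2]
  s["A", "T"] <- s["T", "A"] <- params@rates[3]
  s["C", "G"] <- s["G", "C"] <- params@rates[4]
  s["C", "T"] <- s["T", "C"] <- params@rates[5]
  s["G", "T"] <- s["T", "G"] <- params@rates[6]
  pi <- params@freqs
  Q <- s * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q / mu
}

# Eigendecomposition of Q via symmetrization (Q is reversible):
# B = D^(1/2) Q D^(-1/2) is symmetric, so Q = V L Vinv with real L.
.gtrEigen <- function(params) {
  Q <- .gtrRateMatrix(params)
  pi <- params@freqs
  sq <- sqrt(pi)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- diag(1 / sq) %*% eig$vectors
  Vinv <- t(eig$vectors) %*% diag(sq)
  list(V = V, Vinv = Vinv, lambda = eig$values, freqs = pi, Q = Q)
}

# Transition probability matrix P(t) = exp(Qt).
.gtrTransition <- function(eig, t) {
  P <- eig$V %*% (exp(eig$lambda * t) * eig$Vinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Discrete-Gamma relative rates: quantile midpoints of Gamma(shape, shape)
# (mean 1), renormalized to mean exactly 1. Returns 1 for homogeneity.
.gammaRates <- function(params) {
  if (is.na(params@gammaShape) || params@nCategories == 1L) return(1)
  k <- params@nCategories
  a <- params@gammaShape
  r <- qgamma((2 * seq_len(k) - 1) / (2 * k), shape = a, rate = a)
  r / mean(r)
}

# Character matrix (rows = sequences) from a SeqAlignment.
.alnCharMatrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln@seqs, "", fixed = TRUE))
  rownames(m) <- names(aln@seqs)
  m
}

# Site-pattern compression for the nucleotide likelihood. Any character
# outside A/C/G/T is treated as missing data. Rows ordered as `order`.
.alnPatterns <- function(aln, order = names(aln@seqs)) {
  m <- .alnCharMatrix(aln)[order, , drop = FALSE]
  idx <- matrix(match(m, DNA_STATES), nrow = nrow(m))
  idx[is.na(idx)] <- 0L
  key <- apply(idx, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  states <- idx[, first, drop = FALSE] - 1L  # 0..3, -1 missing
  storage.mode(states) <- "integer"
  list(states = states, weights = as.numeric(w))
}
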