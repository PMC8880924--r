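# Pairwise evolutionary distances.

SATURATION_CAP <- 5.0

#' Pairwise distances from an alignment
#'
#' Computes all pairwise distances using only columns where both sequences
#' carry an unambiguous residue (pairwise deletion). Available models:
#' \describe{
#'   \item{p}{Raw proportion of differing shared columns.}
#'   \item{JC69}{Jukes-Cantor, \eqn{d = -\frac{3}{4}\ln(1 - 4p/3)}.}
#'   \item{protein_corrected}{Kimura's correction
#'     \eqn{d = -\ln(1 - p - 0.2p^2)}, the standard surrogate for
#'     Dayhoff/JTT maximum-likelihood protein distances; rank-consistent with
#'     them at the divergences the curation rules operate on.}
#'   \item{GTR_ML}{Maximum-likelihood distance under the GTR model in
#'     `params`, optimizing the two-sequence likelihood over the
#'     divergence time.}
#' }
#' Pairs at or beyond a model's singularity are capped at 5.0 and flagged
#' as saturated rather than returned as infinite, so that downstream means
#' stay finite while the cell is marked unreliable.
#'
#' @param aln A [SeqAlignment-class].
#' @param model One of "p", "JC69", "GTR_ML", "protein_corrected".
#' @param params A [GTRParams-class], used by `GTR_ML` (its Gamma settings
#'   are ignored for pairwise estimation).
#' @return A [DistanceMatrix-class].
#' @examples
#' aln <- seqAlignment(c(a = "AAAAAAATTT", b = "AAAAAAAAAA"))
#' distances(pairwiseDistances(aln, "JC69"))["a", "b"]  # -0.75 * log(0.6)
#' @export
pairwiseDistances <- function(aln, model = c("JC69", "p", "GTR_ML", "protein_corrected"),
                              params = gtrParams()) {
  model <- match.arg(model)
  m <- .alnCharMatrix(aln)
  n <- nrow(m)
  if (n < 2) stop("at least 2 sequences are required")
  ids <- rownames(m)
  valid <- if (aln@mode == "nucleotide") {
    matrix(m %in% DNA_STATES, nrow = n)
  } else {
    matrix(m %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], nrow = n)
  }
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  eig <- if (model == "GTR_ML") .gtrEigen(params) else NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- valid[i, ] & valid[j, ]
      ns <- sum(shared)
      if (ns == 0)
        stop(sprintf("sequences '%s' and '%s' share no comparable columns",
                     ids[i], ids[j]))
      p <- sum(m[i, shared] != m[j, shared]) / ns
      res <- switch(model,
        p = list(d = p, sat = FALSE),
        JC69 = if (p >= 0.75) list(d = SATURATION_CAP, sat = TRUE)
               else list(d = -0.75 * log(1 - 4 * p / 3), sat = FALSE),
        protein_corrected = {
          arg <- 1 - p - 0.2 * p^2
          if (arg <= 0) list(d = SATURATION_CAP, sat = TRUE)
          else list(d = -log(arg), sat = FALSE)
        },
        GTR_ML = .gtrPairML(m[i, shared], m[j, shared], eig))
      d[i, j] <- d[j, i] <- res$d
      sat[i, j] <- sat[j, i] <- res$sat
    }
  }
  new("DistanceMatrix", d = d, saturated = sat)
}

# ML divergence time for one pair under GTR: maximize
# sum_ab N_ab log(pi_a P_ab(t)) over t.
.gtrPairML <- function(x, y, eig) {
  a <- factor(x, levels = DNA_STATES)
  b <- factor(y, levels = DNA_STATES)
  N <- table(a, b)
  if (all(x == y)) return(list(d = 0, sat = FALSE))
  nll <- function(t) {
    P <- .gtrTransition(eig, t)
    lp <- log(pmax(eig$freqs * P, 1e-300))
    -sum(N * lp)
  }
  opt <- optimize(nll, c(1e-9, SATURATION_CAP * 4))
  t <- opt$minimum
  if (t >= SATURATION_CAP) list(d = SATURATION_CAP, sat = TRUE)
  else list(d = t, sat = FALSE)
}

#' Export a distance matrix as TSV
#'
#' Writes a taxa-by-taxa tab-separated table with row and column labels.
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeDistanceTSV <- function(dm, path) {
  write.table(dm@d, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
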