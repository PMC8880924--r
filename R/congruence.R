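# Parametric-bootstrap assessment of per-gene phylogenetic signal against
# the concatenated tree.

#' Parametric bootstrap of one gene against the concatenated tree
#'
#' Re-fits the concatenated topology's branch lengths on the gene
#' alignment, simulates `n_reps` pseudo-replicate alignments of the gene's
#' length on that fitted tree, and records each replicate's optimized
#' log-likelihood. Two observed values are placed on that distribution:
#' the likelihood of the gene alignment on its own inferred tree
#' (`loglikOwn`) and on the concatenated topology (`loglikConcat`);
#' percentiles are the fraction of replicates at or below the observed
#' value.
#'
#' Each replicate's likelihood is obtained the same way as `loglikOwn`
#' (tree inferred from the replicate, branch lengths optimized), so the
#' observed and replicate statistics are exchangeable when the gene really
#' evolved on the concatenated topology; set `refit_topology = FALSE` to
#' instead re-optimize branch lengths on the fixed simulating topology.
#'
#' @param gene_aln The gene [SeqAlignment-class].
#' @param concat_tree `ape::phylo`: the concatenated-analysis topology.
#' @param params [GTRParams-class] used for fitting and simulation.
#' @param n_reps Number of pseudo-replicates (>= 1).
#' @param seed Integer seed; identical seeds give identical reports.
#' @param gene_tree Optional `phylo` for the gene's own tree; inferred by
#'   NJ + branch-length optimization when NULL.
#' @param refit_topology Re-infer each replicate's topology (default TRUE).
#' @param gene_id Label carried into the report.
#' @return A [CongruenceReport-class].
#' @export
parametricBootstrapGene <- function(gene_aln, concat_tree, params,
                                    n_reps = 100, seed = 1,
                                    gene_tree = NULL, refit_topology = TRUE,
                                    gene_id = "gene") {
  if (n_reps < 1) stop("n_reps must be >= 1")
  ids <- names(gene_aln@seqs)
  shared <- intersect(ids, concat_tree$tip.label)
  if (length(shared) < 3)
    stop("gene and concatenated tree share fewer than 3 taxa")
  if (length(shared) < length(ids) ||
      length(shared) < length(concat_tree$tip.label)) {
    message(sprintf("restricting to %d shared taxa", length(shared)))
    gene_aln <- seqAlignment(gene_aln@seqs[shared],
                             taxonLabels(gene_aln)[shared], gene_aln@mode)
    concat_tree <- ape::drop.tip(concat_tree,
                                 setdiff(concat_tree$tip.label, shared))
    if (!is.null(gene_tree))
      gene_tree <- ape::drop.tip(gene_tree,
                                 setdiff(gene_tree$tip.label, shared))
  }
  L <- alignmentLength(gene_aln)
  # (1) concatenated topology, branch lengths re-fit on this gene
  fitted_concat <- optimizeBranchLengths(concat_tree, gene_aln, params)
  loglik_concat <- attr(fitted_concat, "loglik")
  # observed own-tree likelihood
  if (is.null(gene_tree)) {
    own <- .njFit(gene_aln, params)
    loglik_own <- own$loglik
  } else {
    fit_own <- optimizeBranchLengths(gene_tree, gene_aln, params)
    loglik_own <- attr(fit_own, "loglik")
  }
  # (2)-(3) simulate and score replicates
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1, n_reps)
  rep_ll <- vapply(rep_seeds, function(s) {
    sim <- simulateGTRAlignment(fitted_concat, params, L, s)
    if (refit_topology) {
      .njFit(sim, params)$loglik
    } else {
      attr(optimizeBranchLengths(fitted_concat, sim, params), "loglik")
    }
  }, numeric(1))
  new("CongruenceReport", geneId = gene_id, L = as.integer(L),
      replicateLoglik = rep_ll, loglikOwn = loglik_own,
      loglikConcat = loglik_concat,
      percentileOwn = mean(rep_ll <= loglik_own),
      percentileConcat = mean(rep_ll <= loglik_concat),
      nReps = as.integer(n_reps))
}

#' Summarize congruence reports
#'
#' One row per gene with the observed likelihoods and percentiles; a gene
#' is flagged "discordant" when its own-tree percentile falls outside the
#' central interval implied by the two-sided `level` (default 0.02, i.e.
#' outside [0.01, 0.99]).
#'
#' @param reports List of [CongruenceReport-class] objects (order
#'   preserved).
#' @param level Two-sided flag level (default 0.02).
#' @return Data frame: gene, L, loglik_own, loglik_concat, percentile_own,
#'   percentile_concat, discordant.
#' @export
summarizeCongruence <- function(reports, level = 0.02) {
  if (length(reports) == 0) stop("no reports to summarize")
  do.call(rbind, lapply(reports, function(r) {
    data.frame(gene = r@geneId, L = r@L,
               loglik_own = r@loglikOwn, loglik_concat = r@loglikConcat,
               percentile_own = r@percentileOwn,
               percentile_concat = r@percentileConcat,
               discordant = r@percentileOwn < level / 2 |
                 r@percentileOwn > 1 - level / 2)
  }))
}
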