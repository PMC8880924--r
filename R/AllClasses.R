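#' @import methods
#' @importFrom stats optimize qgamma runif rbinom setNames ave as.dist
#' @importFrom utils read.delim write.table head
#' @useDynLib dinoResolve, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

DNA_STATES <- c("A", "C", "G", "T")
RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")
CALL_TOKENS <- c("Y", "YP", "YA", "N", "NA")
SURVEY_REGIONS <- c("SSU", "ITS", "LSU5prime")

#' GTR substitution model parameters
#'
#' Holds the parameters of the general time-reversible (GTR) nucleotide
#' substitution model, optionally with discrete-Gamma rate variation across
#' sites. The rate matrix built from these parameters is always rescaled so
#' that the expected substitution rate at stationarity is 1, i.e. branch
#' lengths are in expected substitutions per site.
#'
#' @slot rates Numeric(6), non-negative exchangeabilities in the order
#'   AC, AG, AT, CG, CT, GT.
#' @slot freqs Numeric(4), strictly positive stationary base frequencies
#'   (A, C, G, T) summing to 1.
#' @slot gammaShape Positive shape of the Gamma rate distribution, or
#'   `NA_real_` for rate homogeneity across sites.
#' @slot nCategories Integer >= 1, number of discrete Gamma categories
#'   (ignored when `gammaShape` is `NA`).
#' @export
setClass("GTRParams",
  representation(rates = "numeric", freqs = "numeric",
                 gammaShape = "numeric", nCategories = "integer"),
  prototype(rates = rep(1, 6), freqs = rep(0.25, 4),
            gammaShape = NA_real_, nCategories = 1L))

setValidity("GTRParams", function(object) {
  msg <- character()
  if (length(object@rates) != 6 || any(object@rates < 0) || all(object@rates == 0))
    msg <- c(msg, "rates must be 6 non-negative values, not all zero")
  if (length(object@freqs) != 4 || any(object@freqs <= 0) ||
      abs(sum(object@freqs) - 1) > 1e-8)
    msg <- c(msg, "freqs must be 4 strictly positive values summing to 1")
  if (!is.na(object@gammaShape) && object@gammaShape <= 0)
    msg <- c(msg, "gammaShape must be positive or NA")
  if (object@nCategories < 1L)
    msg <- c(msg, "nCategories must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct GTR model parameters
#'
#' @param rates Exchangeabilities (AC, AG, AT, CG, CT, GT). Default all 1
#'   (Jukes-Cantor when frequencies are equal).
#' @param freqs Stationary base frequencies (A, C, G, T).
#' @param gammaShape Gamma shape for among-site rate variation, or `NA` for
#'   a single rate.
#' @param nCategories Number of discrete Gamma categories (default 4, the
#'   usual GTRGAMMA setting).
#' @return A [GTRParams-class] object.
#' @examples
#' jc <- gtrParams()
#' gtr <- gtrParams(rates = c(1.2, 3, 0.8, 1.1, 3.2, 1),
#'                  freqs = c(0.28, 0.22, 0.24, 0.26), gammaShape = 0.5)
#' @export
gtrParams <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                      gammaShape = NA_real_, nCategories = 4L) {
  if (is.na(gammaShape)) nCategories <- 1L
  new("GTRParams", rates = as.numeric(rates), freqs = as.numeric(freqs),
      gammaShape = as.numeric(gammaShape), nCategories = as.integer(nCategories))
}

setMethod("show", "GTRParams", function(object) {
  cat("GTRParams\n")
  cat("  exchangeabilities:",
      paste(sprintf("%s=%.4g", RATE_NAMES, object@rates), collapse = " "), "\n")
  cat("  base frequencies :",
      paste(sprintf("%s=%.4g", DNA_STATES, object@freqs), collapse = " "), "\n")
  if (is.na(object@gammaShape)) {
    cat("  rate variation   : none\n")
  } else {
    cat(sprintf("  rate variation   : discrete Gamma, shape=%.4g, %d categories\n",
                object@gammaShape, object@nCategories))
  }
})

#' Multiple sequence alignment
#'
#' A set of equal-length aligned sequences with taxon labels. Columns are
#' 0-based internally and reported 1-based in all user-facing output.
#'
#' @slot seqs Named character vector of aligned sequence strings (names are
#'   sequence ids, unique).
#' @slot taxon Character vector of taxon labels, parallel to `seqs`.
#' @slot mode Either "nucleotide" or "protein".
#' @export
setClass("SeqAlignment",
  representation(seqs = "character", taxon = "character", mode = "character"))

setValidity("SeqAlignment", function(object) {
  msg <- character()
  if (length(object@seqs) < 2) msg <- c(msg, "an alignment needs at least 2 sequences")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "sequence ids must be present and unique")
  if (length(unique(nchar(object@seqs))) > 1)
    msg <- c(msg, "all sequences must have the same aligned length")
  if (length(object@taxon) != length(object@seqs))
    msg <- c(msg, "taxon labels must be parallel to sequences")
  if (!object@mode %in% c("nucleotide", "protein"))
    msg <- c(msg, "mode must be 'nucleotide' or 'protein'")
  if (length(msg)) msg else TRUE
})

#' Construct a sequence alignment
#'
#' @param seqs Named character vector of aligned strings, or an
#'   `XStringSet` (names used as ids).
#' @param taxon Taxon labels, one per sequence. Defaults to the sequence ids.
#' @param mode "nucleotide" (default) or "protein".
#' @return A [SeqAlignment-class] object.
#' @examples
#' aln <- seqAlignment(c(s1 = "ACGT", s2 = "ACGA"), taxon = c("A", "B"))
#' alignmentLength(aln)
#' @export
seqAlignment <- function(seqs, taxon = NULL, mode = "nucleotide") {
  if (!is.character(seqs)) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  seqs <- toupper(seqs)
  if (is.null(taxon)) taxon <- names(seqs)
  new("SeqAlignment", seqs = seqs, taxon = as.character(taxon), mode = mode)
}

#' @describeIn seqAlignment Number of alignment columns.
#' @param x A `SeqAlignment`.
#' @export
alignmentLength <- function(x) nchar(x@seqs[[1]])

#' @describeIn seqAlignment Named character vector of aligned strings.
#' @export
alignedSeqs <- function(x) x@seqs

#' @describeIn seqAlignment Taxon labels (named by sequence id).
#' @export
taxonLabels <- function(x) setNames(x@taxon, names(x@seqs))

setMethod("show", "SeqAlignment", function(object) {
  cat(sprintf("SeqAlignment: %d sequences x %d columns (%s)\n",
              length(object@seqs), alignmentLength(object), object@mode))
  shown <- head(seq_along(object@seqs), 5)
  for (i in shown) {
    s <- object@seqs[[i]]
    cat(sprintf("  %-15s %s%s\n", names(object@seqs)[i],
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(object@seqs) > 5) cat(sprintf("  ... %d more\n", length(object@seqs) - 5))
})

#' Pairwise distance matrix with saturation flags
#'
#' Symmetric matrix of pairwise evolutionary distances, with a parallel
#' logical matrix flagging pairs whose observed divergence sits at or beyond
#' the distance model's singularity; such cells carry the cap value (5.0).
#'
#' @slot d Symmetric numeric matrix, zero diagonal, dimnames = taxa/ids.
#' @slot saturated Logical matrix, TRUE where the distance was capped.
#' @export
setClass("DistanceMatrix",
  representation(d = "matrix", saturated = "matrix"))

setValidity("DistanceMatrix", function(object) {
  msg <- character()
  d <- object@d
  if (!isSymmetric(unname(d), tol = 1e-9)) msg <- c(msg, "matrix must be symmetric")
  if (any(diag(d) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(d < 0)) msg <- c(msg, "distances must be non-negative")
  if (!identical(dim(object@saturated), dim(d)))
    msg <- c(msg, "saturation flags must match the matrix dimensions")
  if (length(msg)) msg else TRUE
})

#' @describeIn pairwiseDistances Extract the plain numeric matrix.
#' @export
distances <- function(x) x@d

#' @describeIn pairwiseDistances Logical matrix of saturation flags.
#' @export
saturatedCells <- function(x) x@saturated

setMethod("show", "DistanceMatrix", function(object) {
  n <- nrow(object@d)
  cat(sprintf("DistanceMatrix: %d taxa, %d saturated cell(s)\n",
              n, sum(object@saturated[upper.tri(object@saturated)])))
  print(round(object@d[seq_len(min(n, 6)), seq_len(min(n, 6)), drop = FALSE], 4))
  if (n > 6) cat("  ...\n")
})

#' Candidate gene family
#'
#' The per-gene set of candidate homologous sequences (possibly more than
#' one per taxon) passed through the ortholog-curation filters, optionally
#' carrying the family alignment and gene tree covering exactly the current
#' member set.
#'
#' @slot geneId Gene identifier.
#' @slot seqs Named character vector of member sequences (ids unique).
#' @slot taxon Taxon label per member.
#' @slot alignment A [SeqAlignment-class] over the members, or NULL.
#' @slot tree An `ape::phylo` over the members, or NULL.
#' @export
setClass("GeneFamily",
  representation(geneId = "character", seqs = "character",
                 taxon = "character", alignment = "ANY", tree = "ANY"))

setValidity("GeneFamily", function(object) {
  msg <- character()
  if (length(object@seqs) == 0) msg <- c(msg, "members must be non-empty")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "member ids must be present and unique")
  if (length(object@taxon) != length(object@seqs))
    msg <- c(msg, "taxon labels must be parallel to members")
  if (!is.null(object@alignment)) {
    if (!setequal(names(object@alignment@seqs), names(object@seqs)))
      msg <- c(msg, "alignment must cover exactly the current members")
  }
  if (!is.null(object@tree)) {
    if (!setequal(object@tree$tip.label, names(object@seqs)))
      msg <- c(msg, "tree must cover exactly the current members")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a gene family
#'
#' @param geneId Gene identifier.
#' @param seqs Named character vector of member sequences.
#' @param taxon Taxon label for each member.
#' @param alignment Optional [SeqAlignment-class] over the members.
#' @param tree Optional `ape::phylo` whose tip labels are the member ids.
#' @return A [GeneFamily-class] object.
#' @export
geneFamily <- function(geneId, seqs, taxon, alignment = NULL, tree = NULL) {
  new("GeneFamily", geneId = geneId, seqs = seqs, taxon = as.character(taxon),
      alignment = alignment, tree = tree)
}

#' @describeIn geneFamily Member ids.
#' @param x A `GeneFamily`.
#' @export
familyMembers <- function(x) names(x@seqs)

#' @describeIn geneFamily Taxon label per member (named by member id).
#' @export
familyTaxa <- function(x) setNames(x@taxon, names(x@seqs))

setMethod("show", "GeneFamily", function(object) {
  cat(sprintf("GeneFamily '%s': %d members, %d taxa%s%s\n",
              object@geneId, length(object@seqs), length(unique(object@taxon)),
              if (!is.null(object@alignment)) ", aligned" else "",
              if (!is.null(object@tree)) ", with tree" else ""))
})

# Subset a family to a set of member ids, dropping stale alignment/tree rows.
.familySubset <- function(family, keep) {
  aln <- family@alignment
  if (!is.null(aln)) {
    if (length(keep) >= 2) {
      aln <- seqAlignment(aln@seqs[keep], taxonLabels(aln)[keep], aln@mode)
    } else aln <- NULL
  }
  tree <- family@tree
  if (!is.null(tree)) {
    drop <- setdiff(tree$tip.label, keep)
    tree <- if (length(keep) >= 2 && length(drop) < length(tree$tip.label) - 1)
      ape::drop.tip(tree, drop) else NULL
  }
  geneFamily(family@geneId, family@seqs[keep], familyTaxa(family)[keep],
             alignment = aln, tree = tree)
}

#' End-to-end ortholog curation report
#'
#' Produced by [runCuration()]: the gene counts surviving each pipeline
#' stage, every per-gene decision, every individual elimination with its
#' numeric evidence, and the final supermatrix, partition table and tree.
#'
#' @slot stageCounts Named integer vector: candidates, hit_rule,
#'   group_selection, tree_qc.
#' @slot decisions Data frame, one row per gene: gene, stage reached, status,
#'   reason.
#' @slot eliminations Data frame of member-level removals: gene, member, rule,
#'   value, threshold.
#' @slot supermatrix Final concatenated [SeqAlignment-class], or NULL when no
#'   gene survives.
#' @slot partitions Data frame of 1-based inclusive gene block coordinates.
#' @slot members Data frame of the retained members of surviving genes:
#'   gene, member, taxon.
#' @slot tree Final `phylo` with bootstrap node labels, or NULL.
#' @slot status "ok" or "empty".
#' @export
setClass("CurationReport",
  representation(stageCounts = "integer", decisions = "data.frame",
                 eliminations = "data.frame", supermatrix = "ANY",
                 partitions = "data.frame", members = "data.frame",
                 tree = "ANY", status = "character"))

setValidity("CurationReport", function(object) {
  sc <- object@stageCounts
  need <- c("candidates", "hit_rule", "group_selection", "tree_qc")
  if (!identical(names(sc), need))
    return("stageCounts must be named candidates/hit_rule/group_selection/tree_qc")
  if (any(diff(sc) > 0)) return("stage counts must be monotone non-increasing")
  TRUE
})

#' @describeIn runCuration Stage counters of a report.
#' @param report A `CurationReport`.
#' @export
stageCounts <- function(report) report@stageCounts

setMethod("show", "CurationReport", function(object) {
  cat("CurationReport\n")
  sc <- object@stageCounts
  cat(sprintf("  candidates %d -> hit rule %d -> group selection %d -> tree QC %d\n",
              sc[1], sc[2], sc[3], sc[4]))
  if (object@status == "ok") {
    cat(sprintf("  supermatrix: %d taxa x %d columns, %d partitions\n",
                length(object@supermatrix@seqs),
                alignmentLength(object@supermatrix), nrow(object@partitions)))
  } else {
    cat("  no gene survived curation (empty supermatrix)\n")
  }
  if (nrow(object@eliminations))
    cat(sprintf("  %d member-level eliminations logged\n", nrow(object@eliminations)))
})

#' Per-gene parametric-bootstrap congruence report
#'
#' @slot geneId Gene identifier.
#' @slot L Gene alignment length.
#' @slot replicateLoglik Optimized log-likelihoods of the simulated
#'   pseudo-replicates.
#' @slot loglikOwn Optimized log-likelihood of the observed gene alignment on
#'   its own inferred tree.
#' @slot loglikConcat Optimized log-likelihood of the observed gene alignment
#'   on the concatenated-tree topology.
#' @slot percentileOwn,percentileConcat Fraction of replicates with
#'   log-likelihood <= the observed value.
#' @slot nReps Number of replicates.
#' @export
setClass("CongruenceReport",
  representation(geneId = "character", L = "integer",
                 replicateLoglik = "numeric", loglikOwn = "numeric",
                 loglikConcat = "numeric", percentileOwn = "numeric",
                 percentileConcat = "numeric", nReps = "integer"))

setValidity("CongruenceReport", function(object) {
  if (length(object@replicateLoglik) != object@nReps)
    return("replicateLoglik must have nReps entries")
  ok <- function(p) p >= 0 && p <= 1
  if (!ok(object@percentileOwn) || !ok(object@percentileConcat))
    return("percentiles must lie in [0, 1]")
  TRUE
})

setMethod("show", "CongruenceReport", function(object) {
  cat(sprintf("CongruenceReport '%s' (L=%d, %d replicates)\n",
              object@geneId, object@L, object@nReps))
  cat(sprintf("  logL own=%.3f (percentile %.3f)  logL concat=%.3f (percentile %.3f)\n",
              object@loglikOwn, object@percentileOwn,
              object@loglikConcat, object@percentileConcat))
})
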