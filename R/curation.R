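# Paralog pruning and gene-QC rules: mean-distance outlier elimination,
# paralog-group partitioning and selection, tree-diameter and
# reciprocal-monophyly rejection, identity-gap filtering, longest-sequence
# duplicate resolution, and the end-to-end curation pipeline.

#' Curation configuration
#'
#' @slot distanceFactor Multiplier of the grand-mean pairwise distance above
#'   which a member is eliminated (default 2).
#' @slot diameterMax Maximum acceptable gene-tree diameter in
#'   substitutions/site (default 1).
#' @slot identityGap Percentage-point identity gap triggering elimination of
#'   the most divergent member (default 20).
#' @slot ingroup,outgroup Taxon sets used by the reciprocal-monophyly check.
#' @slot coverageFloor Fraction of ingroup taxa a paralog group must cover
#'   to be adequate (default 0.8, the operational reading of "all or nearly
#'   all taxa").
#' @slot meanBasis "grand" (default) compares each member's mean distance to
#'   the grand mean of all off-diagonal entries; "leaveout" compares it to
#'   the grand mean computed without the member's own row/column. The
#'   wording of the elimination rule admits either reading; "grand" is the
#'   package's choice.
#' @export
setClass("CurationConfig",
  representation(distanceFactor = "numeric", diameterMax = "numeric",
                 identityGap = "numeric", ingroup = "character",
                 outgroup = "character", coverageFloor = "numeric",
                 meanBasis = "character"))

setValidity("CurationConfig", function(object) {
  if (object@distanceFactor <= 1) return("distanceFactor must be > 1")
  if (object@diameterMax <= 0) return("diameterMax must be > 0")
  if (length(intersect(object@ingroup, object@outgroup)))
    return("ingroup and outgroup must be disjoint")
  if (!object@meanBasis %in% c("grand", "leaveout"))
    return("meanBasis must be 'grand' or 'leaveout'")
  TRUE
})

#' Construct a curation configuration
#'
#' @param distance_factor,diameter_max,identity_gap,coverage_floor Filter
#'   thresholds (see class slots).
#' @param ingroup,outgroup Taxon labels of the in- and outgroup.
#' @param mean_basis "grand" or "leaveout" (see class slots).
#' @return A [CurationConfig-class].
#' @export
curationConfig <- function(distance_factor = 2, diameter_max = 1,
                           identity_gap = 20, ingroup = character(),
                           outgroup = character(), coverage_floor = 0.8,
                           mean_basis = "grand") {
  new("CurationConfig", distanceFactor = distance_factor,
      diameterMax = diameter_max, identityGap = identity_gap,
      ingroup = ingroup, outgroup = outgroup,
      coverageFloor = coverage_floor, meanBasis = mean_basis)
}

setMethod("show", "CurationConfig", function(object) {
  cat(sprintf(
    "CurationConfig: %gx mean-distance, diameter <= %g, identity gap %g pts\n",
    object@distanceFactor, object@diameterMax, object@identityGap))
  cat(sprintf("  ingroup: %d taxa, outgroup: %d taxa\n",
              length(object@ingroup), length(object@outgroup)))
})

# Attach an elimination log (data frame) to a family.
.withLog <- function(family, log) { attr(family, "eliminated") <- log; family }
.emptyLog <- function() data.frame(member = character(), rule = character(),
                                   value = numeric(), threshold = numeric())

#' Eliminate divergent members by the mean-distance rule
#'
#' A member is eliminated iff its mean distance to all other members
#' exceeds `distanceFactor` times the grand mean of all off-diagonal
#' distances. Applied once, not iterated (iteration could cascade a family
#' to empty). Eliminated members are logged with both values in
#' `attr(, "eliminated")`.
#'
#' @param family A [GeneFamily-class] with >= 3 members (smaller families
#'   are returned unchanged with a warning).
#' @param dm A [DistanceMatrix-class] covering the members.
#' @param config A [CurationConfig-class].
#' @return The filtered family; `attr(, "eliminated")` logs removals.
#' @export
meanDistanceOutlierFilter <- function(family, dm, config = curationConfig()) {
  ids <- familyMembers(family)
  if (length(ids) < 3) {
    warning("fewer than 3 members: mean-distance filter not applied")
    return(.withLog(family, .emptyLog()))
  }
  d <- dm@d[ids, ids]
  n <- length(ids)
  member_mean <- rowSums(d) / (n - 1)
  if (config@meanBasis == "grand") {
    thr <- config@distanceFactor * mean(d[upper.tri(d)])
    drop <- member_mean > thr
    thrs <- rep(thr, n)
  } else {
    thrs <- vapply(seq_len(n), function(i) {
      sub <- d[-i, -i, drop = FALSE]
      config@distanceFactor * mean(sub[upper.tri(sub)])
    }, numeric(1))
    drop <- member_mean > thrs
  }
  log <- data.frame(member = ids[drop], rule = rep("mean_distance", sum(drop)),
                    value = member_mean[drop], threshold = thrs[drop])
  keep <- ids[!drop]
  if (length(keep) == length(ids)) return(.withLog(family, log))
  .withLog(.familySubset(family, keep), log)
}

#' Partition a family into paralog groups
#'
#' Finds the maximal clades of the (unrooted) gene tree -- considering both
#' sides of every edge -- that contain at most one member per taxon, and
#' partitions the members into such groups ("separated clades containing
#' duplicate copies for each taxon"). A family already holding at most one
#' member per taxon comes back as a single group.
#'
#' @param family A [GeneFamily-class] with a tree.
#' @return List of character vectors of member ids (disjoint, jointly
#'   covering all members).
#' @export
partitionParalogGroups <- function(family) {
  tree <- family@tree
  if (is.null(tree)) stop("family has no tree")
  taxa <- familyTaxa(family)
  ids <- familyMembers(family)
  if (!anyDuplicated(taxa)) return(list(ids))
  singleCopy <- function(members) !anyDuplicated(taxa[members])
  sides <- .edgeLeafSets(tree)
  cands <- c(sides, lapply(sides, function(s) setdiff(ids, s)),
             list(ids), as.list(ids))
  cands <- unique(lapply(cands[vapply(cands, singleCopy, logical(1))], sort))
  # greedy maximal cover: largest clades first, deterministic tie-break
  ord <- order(-lengths(cands),
               vapply(cands, function(s) s[1], character(1)))
  cands <- cands[ord]
  groups <- list()
  taken <- character(0)
  for (g in cands) {
    if (!length(intersect(g, taken))) {
      groups <- c(groups, list(g))
      taken <- c(taken, g)
    }
  }
  left <- setdiff(ids, taken)
  c(groups, as.list(left))
}

#' Select the ortholog group among paralog groups
#'
#' Groups are ranked by taxon coverage (descending) and then mean
#' within-group distance (ascending): the most complete group wins, and
#' between equally complete groups the tighter one wins. When no group
#' covers at least `coverageFloor` of the ingroup taxa the gene has no
#' adequate group and `NULL` is returned (the gene is then dropped).
#'
#' @param family The [GeneFamily-class] the groups belong to.
#' @param groups List of member-id vectors from [partitionParalogGroups()].
#' @param dm A [DistanceMatrix-class] covering the members.
#' @param config A [CurationConfig-class]; its `ingroup` (when non-empty)
#'   defines the taxon universe for coverage.
#' @return The selected member-id vector, or NULL when no group is adequate.
#' @export
selectOrthologGroup <- function(family, groups, dm, config = curationConfig()) {
  if (length(groups) == 0) stop("empty group list")
  taxa <- familyTaxa(family)
  universe <- if (length(config@ingroup)) config@ingroup else unique(taxa)
  coverage <- vapply(groups, function(g)
    length(intersect(unique(taxa[g]), universe)), numeric(1))
  within <- vapply(groups, function(g) {
    if (length(g) < 2) return(0)
    sub <- dm@d[g, g]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  ord <- order(-coverage, within,
               -lengths(groups),
               vapply(groups, function(g) sort(g)[1], character(1)))
  best <- ord[1]
  if (coverage[best] < config@coverageFloor * length(universe)) return(NULL)
  groups[[best]]
}

#' Gene-tree quality control
#'
#' Rejects a gene when the tree diameter exceeds `diameterMax` and/or when
#' the outgroup and ingroup members are not reciprocally monophyletic on
#' the unrooted tree (no edge separates exactly the outgroup members from
#' the ingroup members). Both reasons are reported when both fail.
#'
#' @param family A [GeneFamily-class] with a tree carrying branch lengths.
#' @param config A [CurationConfig-class] with non-empty ingroup/outgroup.
#' @return List with elements `accept` (logical) and `reasons` (character
#'   vector among "diameter", "monophyly"; empty when accepted).
#' @export
qcGeneTree <- function(family, config) {
  tree <- family@tree
  if (is.null(tree)) stop("family has no tree")
  taxa <- familyTaxa(family)
  out_tips <- names(taxa)[taxa %in% config@outgroup]
  in_tips <- names(taxa)[taxa %in% config@ingroup]
  if (length(out_tips) == 0 || length(in_tips) == 0)
    stop("ingroup or outgroup absent from the tree")
  reasons <- character(0)
  if (treeDiameter(tree) > config@diameterMax) reasons <- c(reasons, "diameter")
  if (!.hasSeparatingEdge(tree, out_tips)) reasons <- c(reasons, "monophyly")
  list(accept = length(reasons) == 0, reasons = reasons)
}

# Mean percent identity of each member to all others (pairwise-shared,
# non-gap columns).
.memberIdentity <- function(aln) {
  m <- .alnCharMatrix(aln)
  n <- nrow(m)
  valid <- matrix(m != "-" & m != "N", nrow = n)
  pid <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- valid[i, ] & valid[j, ]
    pid[i, j] <- pid[j, i] <-
      if (any(shared)) 100 * sum(m[i, shared] == m[j, shared]) / sum(shared)
      else 0
  }
  rowMeans(pid, na.rm = TRUE)
}

#' Identity-gap elimination
#'
#' Computes each member's mean percent identity to all others, sorts the
#' averages, and eliminates the lowest member(s) iff the gap between the
#' lowest and next-lowest average is at least `identityGap` percentage
#' points. Applied once. This operationalizes a garbled elimination rule in
#' its source description as "at least a 20-point gap below the
#' next-lowest average".
#'
#' @param family A [GeneFamily-class] with >= 3 members (smaller families
#'   come back unchanged with a warning).
#' @param aln A [SeqAlignment-class] covering the members (defaults to the
#'   family's own alignment).
#' @param config A [CurationConfig-class].
#' @return The filtered family; `attr(, "eliminated")` logs removals.
#' @export
identityGapFilter <- function(family, aln = family@alignment,
                              config = curationConfig()) {
  ids <- familyMembers(family)
  if (length(ids) < 3) {
    warning("fewer than 3 members: identity-gap filter not applied")
    return(.withLog(family, .emptyLog()))
  }
  if (is.null(aln)) stop("no alignment available")
  avg <- .memberIdentity(aln)[ids]
  o <- order(avg)
  lowest <- avg[o[1]]
  next_vals <- avg[avg > lowest + 1e-9]
  if (!length(next_vals)) return(.withLog(family, .emptyLog()))
  gap <- min(next_vals) - lowest
  if (gap < config@identityGap) return(.withLog(family, .emptyLog()))
  drop <- names(avg)[abs(avg - lowest) <= 1e-9]
  log <- data.frame(member = drop, rule = "identity_gap",
                    value = avg[drop], threshold = lowest + gap)
  .withLog(.familySubset(family, setdiff(ids, drop)), log)
}

#' Resolve monophyletic within-taxon duplicates by length
#'
#' For each taxon represented by more than one member whose members form an
#' exclusive clade on the gene tree, keeps the member with the greatest
#' non-gap length (ties: id ascending). Duplicates that are not
#' monophyletic are left alone for paralog-group partitioning.
#'
#' @param family A [GeneFamily-class] with a tree.
#' @return The filtered family; `attr(, "eliminated")` logs removals.
#' @export
resolveMonophyleticDuplicates <- function(family) {
  tree <- family@tree
  if (is.null(tree)) stop("family has no tree")
  taxa <- familyTaxa(family)
  log <- .emptyLog()
  keep <- familyMembers(family)
  for (tx in unique(taxa[duplicated(taxa)])) {
    tips <- names(taxa)[taxa == tx]
    if (!.hasSeparatingEdge(tree, tips)) next
    lens <- nchar(gsub("-", "", family@seqs[tips], fixed = TRUE))
    best <- tips[order(-lens, tips)][1]
    drop <- setdiff(tips, best)
    keep <- setdiff(keep, drop)
    log <- rbind(log, data.frame(member = drop, rule = "duplicate_length",
                                 value = lens[drop], threshold = lens[best]))
  }
  if (length(keep) == length(familyMembers(family)))
    return(.withLog(family, log))
  .withLog(.familySubset(family, keep), log)
}

# Anchor a contig onto reference-gene coordinates via local alignment:
# returns a string of the reference's length (gaps outside the aligned
# range). Used to obtain per-gene comparable member sequences when the
# input contigs carry flanking untranslated sequence.
.anchorToReference <- function(contig, ref, config) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(
    match = config@match, mismatch = config@mismatch, baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(contig), Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = sm,
    gapOpening = -config@gapOpen, gapExtension = -config@gapExtend)
  sub_start <- Biostrings::start(Biostrings::subject(al))
  pat <- as.character(Biostrings::alignedPattern(al))
  subj <- as.character(Biostrings::alignedSubject(al))
  # project the aligned pattern onto ungapped subject coordinates
  pch <- strsplit(pat, "")[[1]]
  sch <- strsplit(subj, "")[[1]]
  out <- rep("-", nchar(ref))
  pos <- sub_start - 1
  for (i in seq_along(sch)) {
    if (sch[i] != "-") {
      pos <- pos + 1
      out[pos] <- pch[i]
    }
  }
  paste(out, collapse = "")
}

#' Run the full ortholog-curation pipeline
#'
#' Screen contig libraries against the reference panel, apply the hit-count
#' gene-selection rule, then per gene: anchor members to reference
#' coordinates, eliminate mean-distance outliers, resolve monophyletic
#' duplicates, apply the identity-gap rule, partition paralog groups and
#' select the ortholog group, and reject genes failing tree QC (diameter /
#' reciprocal monophyly). Survivors are concatenated into a supermatrix
#' with a partition table and a final NJ tree with bootstrap supports and
#' optimized branch lengths.
#'
#' @param libraries Named list (taxon -> contigs) as for
#'   [reciprocalBestHits()].
#' @param reference Named reference gene panel.
#' @param screen_config A [ScreenConfig-class].
#' @param curation_config A [CurationConfig-class] (ingroup/outgroup
#'   required for tree QC).
#' @param params [GTRParams-class] for distances and the final tree.
#' @param dist_model Distance model for per-gene trees (default "JC69";
#'   "GTR_ML" matches the engine's likelihood model at higher cost).
#' @param n_boot Bootstrap replicates on the final tree (default 100).
#' @param seed Seed for the bootstrap.
#' @return A [CurationReport-class].
#' @export
runCuration <- function(libraries, reference,
                        screen_config = screenConfig(),
                        curation_config = curationConfig(),
                        params = gtrParams(), dist_model = "JC69",
                        n_boot = 100, seed = 1) {
  reference <- .asCharSeqs(reference)
  hits <- reciprocalBestHits(libraries, reference, screen_config)
  all_taxa <- names(libraries)
  selected <- selectCandidateGenes(hits, screen_config, all_taxa)
  decisions <- data.frame(gene = sort(names(reference)), stage = "hit_rule",
                          status = "eliminated", reason = "hit_count_rule")
  rownames(decisions) <- decisions$gene
  decisions[selected, c("status", "reason")] <- c("retained", "")
  elims <- .emptyLog(); elims$gene <- character(0)
  contig_seqs <- do.call(c, lapply(names(libraries), function(tx)
    .asCharSeqs(libraries[[tx]])))
  survivors <- list()
  retained <- data.frame(gene = character(), member = character(),
                         taxon = character())
  n_group <- 0L
  for (g in selected) {
    h <- hits[hits$gene == g, , drop = FALSE]
    members <- setNames(contig_seqs[h$contig], h$contig)
    anchored <- vapply(members, .anchorToReference, character(1),
                       ref = reference[[g]], config = screen_config)
    fam <- geneFamily(g, anchored, h$taxon,
                      alignment = if (length(anchored) >= 2)
                        seqAlignment(anchored, h$taxon) else NULL)
    logGene <- function(log) {
      if (nrow(log)) {
        log$gene <- g
        elims <<- rbind(elims, log)
      }
    }
    refreshTree <- function(fam) {
      if (length(fam@seqs) < 3) return(fam)
      dm <- pairwiseDistances(fam@alignment, dist_model, params)
      fam@tree <- neighborJoining(dm)
      attr(fam, "dm") <- dm
      fam
    }
    fam <- refreshTree(fam)
    if (length(fam@seqs) >= 3) {
      fam2 <- meanDistanceOutlierFilter(fam, attr(fam, "dm"), curation_config)
      logGene(attr(fam2, "eliminated"))
      fam <- refreshTree(fam2)
    }
    if (length(fam@seqs) >= 3 && !is.null(fam@tree)) {
      fam2 <- resolveMonophyleticDuplicates(fam)
      logGene(attr(fam2, "eliminated"))
      fam <- refreshTree(fam2)
    }
    if (length(fam@seqs) >= 3) {
      fam2 <- identityGapFilter(fam, config = curation_config)
      logGene(attr(fam2, "eliminated"))
      fam <- refreshTree(fam2)
    }
    # paralog-group partitioning and selection
    taxa <- familyTaxa(fam)
    if (length(fam@seqs) < 3) {
      decisions[g, c("stage", "status", "reason")] <-
        c("group_selection", "eliminated", "too_few_members")
      next
    }
    groups <- partitionParalogGroups(fam)
    pick <- selectOrthologGroup(fam, groups, attr(fam, "dm"), curation_config)
    if (is.null(pick)) {
      decisions[g, c("stage", "status", "reason")] <-
        c("group_selection", "eliminated", "no_adequate_group")
      next
    }
    if (length(pick) < length(fam@seqs)) {
      dropped <- setdiff(familyMembers(fam), pick)
      logGene(data.frame(member = dropped, rule = "paralog_group",
                         value = NA_real_, threshold = NA_real_))
      fam <- refreshTree(.familySubset(fam, pick))
    }
    if (length(fam@seqs) < 3 || is.null(fam@tree)) {
      decisions[g, c("stage", "status", "reason")] <-
        c("group_selection", "eliminated", "too_few_members")
      next
    }
    decisions[g, "stage"] <- "group_selection"
    qc <- qcGeneTree(fam, curation_config)
    if (!qc$accept) {
      decisions[g, c("stage", "status", "reason")] <-
        c("tree_qc", "eliminated", paste(qc$reasons, collapse = "+"))
      next
    }
    decisions[g, c("stage", "status", "reason")] <- c("tree_qc", "retained", "")
    retained <- rbind(retained, data.frame(
      gene = g, member = familyMembers(fam), taxon = unname(familyTaxa(fam))))
    # one member per taxon by construction of the selected group
    aln <- seqAlignment(setNames(fam@seqs, unname(familyTaxa(fam))),
                        unname(familyTaxa(fam)))
    survivors[[g]] <- aln
  }
  n_candidates <- length(reference)
  n_hit <- length(selected)
  n_group <- sum(decisions$stage %in% c("group_selection", "tree_qc") &
                   !(decisions$stage == "group_selection" &
                       decisions$status == "eliminated"))
  n_qc <- length(survivors)
  stage_counts <- c(candidates = n_candidates, hit_rule = n_hit,
                    group_selection = n_group, tree_qc = n_qc)
  if (length(survivors) == 0) {
    return(new("CurationReport",
               stageCounts = setNames(as.integer(stage_counts), names(stage_counts)),
               decisions = decisions, eliminations = elims,
               supermatrix = NULL,
               partitions = data.frame(gene = character(), start = integer(),
                                       end = integer()),
               members = retained, tree = NULL, status = "empty"))
  }
  cc <- concatenateAlignments(survivors)
  final <- bootstrapSupport(cc$alignment, model = dist_model, n_reps = n_boot,
                            seed = seed, params = params)
  final <- optimizeBranchLengths(final, cc$alignment, params, tol = 1e-3)
  new("CurationReport",
      stageCounts = setNames(as.integer(stage_counts), names(stage_counts)),
      decisions = decisions, eliminations = elims,
      supermatrix = cc$alignment, partitions = cc$partitions,
      members = retained, tree = final, status = "ok")
}

#' Write a curation report to JSON
#'
#' Serializes the stage counters, per-gene decisions and member
#' eliminations.
#'
#' @param report A [CurationReport-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCurationJSON <- function(report, path) {
  jsonlite::write_json(list(
    stage_counts = as.list(stageCounts(report)),
    status = report@status,
    decisions = report@decisions,
    eliminations = report@eliminations,
    partitions = report@partitions), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
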