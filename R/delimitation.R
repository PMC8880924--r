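# The Y/YP/YA/N/NA species-resolution classifier, compound-call handling,
# the three-category mapping, survey summarization, region agreement, and
# the species-description decision tree.

# Root a tree on a declared outgroup, or approximately at the midpoint of
# the longest leaf-to-leaf path when no outgroup is given (rooted at the
# node of the midpoint edge nearest the midpoint; minimal-clade containment
# only depends on which component the root lies in).
.rootForClades <- function(tree, outgroup = NULL) {
  if (!is.null(outgroup) && length(outgroup)) {
    out_tips <- intersect(outgroup, tree$tip.label)
    if (length(out_tips) == 0) stop("declared outgroup not found among leaves")
    if (ape::is.monophyletic(tree, out_tips) ||
        length(out_tips) == 1)
      return(ape::root(tree, outgroup = out_tips, resolve.root = TRUE))
  }
  pat <- ape::cophenetic.phylo(tree)
  ij <- which(pat == max(pat), arr.ind = TRUE)[1, ]
  a <- rownames(pat)[ij[1]]; b <- rownames(pat)[ij[2]]
  ntip <- length(tree$tip.label)
  an <- which(tree$tip.label == a)
  bn <- which(tree$tip.label == b)
  nd <- ape::dist.nodes(tree)
  # walk from a towards b, find the node closest to the path midpoint
  path_len <- nd[an, bn]
  nodes <- seq_len(ntip + tree$Nnode)
  on_path <- nodes[abs(nd[an, nodes] + nd[nodes, bn] - path_len) < 1e-10]
  mid <- on_path[which.min(abs(nd[an, on_path] - path_len / 2))]
  if (mid <= ntip || mid == ntip + 1) return(ape::root(tree, outgroup = a,
                                                       resolve.root = TRUE))
  ape::root(tree, node = mid, resolve.root = TRUE)
}

# Tip labels descending from each node of a rooted tree.
.descTips <- function(tree) {
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    sets[[par]] <- c(sets[[par]], sets[[chd]])
  }
  sets
}

#' Classify species resolution on a phylogeny (Y/YP/YA/N/NA)
#'
#' For each species S, let C be the smallest clade containing all S-leaves
#' on the rooted tree (rooted on `outgroup` when given, else near the
#' midpoint).
#' \itemize{
#'   \item Y: C contains only S-leaves, S has >= 2 leaves, and C's support
#'     (internal-node label) is at least `support_threshold` when supports
#'     are present -- multiple conspecific sequences forming a distinct
#'     cluster.
#'   \item YP: S is a singleton whose leaf lies inside no other species'
#'     minimal clade -- a single sequence on its own distinct branch.
#'   \item YA: C contains foreign leaves, but all of them are flagged as
#'     suspected misidentifications.
#'   \item NA: C contains foreign leaves carrying evidence-of-distinctness
#'     flags (with any remaining foreign leaves at most misidentified).
#'   \item N: otherwise -- sequences of morphologically distinct species
#'     fall into the same clade.
#' }
#' YA and NA require explicit leaf flags because in the underlying survey
#' they derive from reading original species descriptions, not from
#' topology.
#'
#' @param tree `ape::phylo`; internal node labels, when present and
#'   numeric, are interpreted as supports in [0, 100].
#' @param species_map Named character vector: leaf label -> species.
#' @param flags Optional named character vector: leaf label ->
#'   "misidentified" or "distinct".
#' @param support_threshold Minimal support for an exclusive clade to count
#'   as resolved (default 80, the conventional bootstrap cutoff below which
#'   branches are drawn as unsupported).
#' @param outgroup Optional leaf labels to root on.
#' @return Data frame: species, call, n_leaves, support, evidence.
#' @export
classifySpeciesCalls <- function(tree, species_map, flags = NULL,
                                 support_threshold = 80, outgroup = NULL) {
  unmapped <- setdiff(tree$tip.label, names(species_map))
  if (length(unmapped))
    stop(sprintf("unmapped leaf label(s): %s", paste(unmapped, collapse = ", ")))
  rooted <- .rootForClades(tree, outgroup)
  ntip <- length(rooted$tip.label)
  sets <- .descTips(rooted)
  species <- unique(species_map[rooted$tip.label])
  sp_tips <- split(names(species_map), species_map)
  # minimal clade (node) of a tip set
  mrcaNode <- function(tips) {
    if (length(tips) == 1) which(rooted$tip.label == tips)
    else ape::getMRCA(rooted, tips)
  }
  nodes <- lapply(species, function(s)
    mrcaNode(intersect(sp_tips[[s]], rooted$tip.label)))
  names(nodes) <- species
  supp <- function(node) {
    if (node <= ntip || is.null(rooted$node.label)) return(NA_real_)
    v <- suppressWarnings(as.numeric(rooted$node.label[node - ntip]))
    v
  }
  out <- lapply(species, function(s) {
    tips <- intersect(sp_tips[[s]], rooted$tip.label)
    node <- nodes[[s]]
    clade <- sets[[node]]
    foreign <- setdiff(clade, tips)
    sup <- supp(node)
    if (length(tips) >= 2 && length(foreign) == 0) {
      ok <- is.na(sup) || sup >= support_threshold
      return(data.frame(species = s, call = if (ok) "Y" else "N",
                        n_leaves = length(tips), support = sup,
                        evidence = if (ok)
                          "exclusive supported clade of >=2 sequences"
                        else "exclusive clade below the support threshold"))
    }
    if (length(tips) == 1) {
      inside_other <- any(vapply(species[species != s], function(o)
        tips %in% sets[[nodes[[o]]]], logical(1)))
      if (!inside_other)
        return(data.frame(species = s, call = "YP", n_leaves = 1L,
                          support = sup,
                          evidence = "single sequence on a distinct branch"))
      return(data.frame(species = s, call = "N", n_leaves = 1L, support = sup,
                        evidence = "single sequence inside another species' clade"))
    }
    fflags <- if (is.null(flags)) rep(NA_character_, length(foreign))
              else unname(flags[foreign])
    if (length(foreign) && all(!is.na(fflags)) &&
        all(fflags == "misidentified"))
      return(data.frame(species = s, call = "YA", n_leaves = length(tips),
                        support = sup,
                        evidence = "foreign sequences all flagged as misidentified"))
    if (length(foreign) && all(!is.na(fflags)) && any(fflags == "distinct"))
      return(data.frame(species = s, call = "NA", n_leaves = length(tips),
                        support = sup,
                        evidence = "foreign sequences carry evidence of distinctness"))
    data.frame(species = s, call = "N", n_leaves = length(tips), support = sup,
               evidence = "clade mixes sequences of distinct species")
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Combine per-phylogeny calls into a compound call
#'
#' Distinct tokens joined by "/" in the fixed order Y, YP, YA, N, NA.
#'
#' @param calls Character vector of call tokens from one or more
#'   phylogenies.
#' @return A single compound call string.
#' @examples
#' combineCalls(c("Y", "Y"))   # "Y"
#' combineCalls(c("N", "Y"))   # "Y/N"
#' @export
combineCalls <- function(calls) {
  bad <- setdiff(calls, CALL_TOKENS)
  if (length(bad)) stop(sprintf("unknown call token(s): %s",
                                paste(bad, collapse = ", ")))
  toks <- CALL_TOKENS[CALL_TOKENS %in% calls]
  paste(toks, collapse = "/")
}

#' Map a compound call to the three-category classification
#'
#' Closed-world mapping: not_resolved for N, NA, N/NA, N/YA and Y/N;
#' ambiguous for YA, Y/YA and YP/YA; resolved for Y and YP. Token order in
#' the compound string does not matter; any other combination is an error.
#'
#' @param compound_call Compound call string (tokens joined by "/").
#' @return One of "resolved", "ambiguous", "not_resolved".
#' @examples
#' mapToCategory("Y/N")   # not_resolved
#' mapToCategory("YP/YA") # ambiguous
#' @export
mapToCategory <- function(compound_call) {
  toks <- sort(strsplit(compound_call, "/", fixed = TRUE)[[1]])
  keyOf <- function(x) paste(sort(x), collapse = "/")
  key <- keyOf(toks)
  not_res <- vapply(list("N", "NA", c("N", "NA"), c("N", "YA"), c("Y", "N")),
                    keyOf, character(1))
  ambig <- vapply(list("YA", c("Y", "YA"), c("YP", "YA")), keyOf, character(1))
  resol <- vapply(list("Y", "YP"), keyOf, character(1))
  if (key %in% not_res) return("not_resolved")
  if (key %in% ambig) return("ambiguous")
  if (key %in% resol) return("resolved")
  stop(sprintf("call combination '%s' is outside the three closed lists",
               compound_call))
}

.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summarize a survey table into the three-category table
#'
#' Restricted to described species; per region, counts each compound call's
#' category and the percentage of species per category (half-up, one
#' decimal). Regions with no entries get zero counts and NA percentages.
#'
#' @param table A survey data frame (see [validateSurveyTable()]).
#' @return Data frame with one row per region: counts and percentages for
#'   not_resolved / ambiguous / resolved.
#' @export
summarizeSurvey <- function(table) {
  validateSurveyTable(table)
  table <- table[as.logical(table$is_described), , drop = FALSE]
  out <- lapply(SURVEY_REGIONS, function(rg) {
    sub <- table[table$region == rg, , drop = FALSE]
    cats <- if (nrow(sub)) vapply(sub$call, mapToCategory, character(1))
            else character(0)
    n <- c(not_resolved = sum(cats == "not_resolved"),
           ambiguous = sum(cats == "ambiguous"),
           resolved = sum(cats == "resolved"))
    tot <- sum(n)
    pct <- if (tot > 0) .roundHalfUp(100 * n / tot) else rep(NA_real_, 3)
    data.frame(region = rg, n_not_resolved = n[1], n_ambiguous = n[2],
               n_resolved = n[3], pct_not_resolved = pct[1],
               pct_ambiguous = pct[2], pct_resolved = pct[3])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Agreement between two rDNA regions
#'
#' Among entries (described species and ribotypes) with calls in both
#' regions, counts how often the two regions give the same
#' resolved-vs-not-resolved outcome. Ambiguous entries side with resolved
#' by default (`ambiguous_with`).
#'
#' @param table A survey data frame.
#' @param region_a,region_b Two distinct region names.
#' @param ambiguous_with "resolved" (default) or "not_resolved".
#' @return List: n_both, n_agree, n_disagree, disagreements (data frame
#'   with species and both calls).
#' @export
regionAgreement <- function(table, region_a, region_b,
                            ambiguous_with = c("resolved", "not_resolved")) {
  ambiguous_with <- match.arg(ambiguous_with)
  if (region_a == region_b) stop("region_a and region_b must differ")
  validateSurveyTable(table)
  a <- table[table$region == region_a, c("species", "call")]
  b <- table[table$region == region_b, c("species", "call")]
  m <- merge(a, b, by = "species", suffixes = c("_a", "_b"))
  if (nrow(m) == 0)
    return(list(n_both = 0L, n_agree = 0L, n_disagree = 0L,
                disagreements = data.frame(species = character(),
                                           call_a = character(),
                                           call_b = character())))
  resolvedOutcome <- function(call) {
    cat <- mapToCategory(call)
    if (cat == "ambiguous") cat <- ambiguous_with
    cat == "resolved"
  }
  oa <- vapply(m$call_a, resolvedOutcome, logical(1))
  ob <- vapply(m$call_b, resolvedOutcome, logical(1))
  dis <- m[oa != ob, , drop = FALSE]
  names(dis) <- c("species", "call_a", "call_b")
  rownames(dis) <- NULL
  list(n_both = nrow(m), n_agree = sum(oa == ob), n_disagree = nrow(dis),
       disagreements = dis)
}

.CASE_ACTIONS <- c(
  "1a" = paste("Morphology alone could justify the description, but both",
               "ITS/5.8S and D1-D3 phylogenies should still be included to",
               "anchor the name and future identifications."),
  "1b" = paste("Describe on morphology and rDNA phylogeny jointly, giving",
               "the molecular data more weight and stating the degree of",
               "morphological overlap with similar species."),
  "2"  = paste("rDNA cannot separate the taxa: seek a multigene phylogeny",
               "or other corroborating evidence (habitat, mating,",
               "toxicity); describe on morphology plus that evidence, or",
               "note the shared rDNA explicitly if describing on",
               "morphology alone."),
  "3a" = paste("Use the distinct species-specific rDNA clades as the",
               "primary character, with a full morphological description",
               "and its known overlaps; deposit type sequences."),
  "3b" = paste("Cryptic species: description can rest on the molecular",
               "phylogenies alone, though a ribotype designation is the",
               "prudent course until a functional difference is known."),
  "4"  = paste("Morphological and molecular evidence conflict: collect",
               "more isolates and additional data (multigene phylogenies,",
               "mating studies, ecology) before describing anything."),
  "5"  = paste("No evidence of separate species from either data type: do",
               "not describe a new species."))

#' Species-description decision tree
#'
#' Maps the degree of morphological differentiation and the rDNA phylogeny
#' outcome onto the five-case scheme for weighting morphology against
#' ITS/5.8S and D1-D3 evidence when describing a dinoflagellate species.
#'
#' @param morphology One of "highly_divergent", "distinct_with_overlap",
#'   "largely_overlapping", "indistinguishable", "conflicting".
#' @param rdna One of "distinct", "identical", "conflicting".
#' @param multigene_distinct,ecological_evidence Optional auxiliary flags,
#'   echoed into the advice for Case 2.
#' @return List with elements `case` (one of 1a, 1b, 2, 3a, 3b, 4, 5) and
#'   `action` (the prescribed course of action).
#' @examples
#' recommendDescriptionCase("distinct_with_overlap", "identical")$case  # "2"
#' recommendDescriptionCase("indistinguishable", "distinct")$case       # "3b"
#' @export
recommendDescriptionCase <- function(morphology = c("highly_divergent",
                                                    "distinct_with_overlap",
                                                    "largely_overlapping",
                                                    "indistinguishable",
                                                    "conflicting"),
                                     rdna = c("distinct", "identical",
                                              "conflicting"),
                                     multigene_distinct = NA,
                                     ecological_evidence = NA) {
  morphology <- match.arg(morphology)
  rdna <- match.arg(rdna)
  case <- if (morphology == "conflicting" || rdna == "conflicting") "4"
  else if (rdna == "distinct") switch(morphology,
    highly_divergent = "1a", distinct_with_overlap = "1b",
    largely_overlapping = "3a", indistinguishable = "3b")
  else switch(morphology,  # rdna identical
    highly_divergent = "2", distinct_with_overlap = "2",
    largely_overlapping = "5", indistinguishable = "5")
  action <- .CASE_ACTIONS[[case]]
  if (case == "2" && isTRUE(multigene_distinct))
    action <- paste(action, "A multigene phylogeny already separates the",
                    "morphotypes: describe on morphology first, multigene",
                    "results second.")
  if (case == "2" && isTRUE(ecological_evidence))
    action <- paste(action, "Corroborating ecological evidence supports",
                    "separation despite identical rDNA.")
  list(case = case, action = action)
}
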