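# Seeded generators for every input the pipeline consumes: species trees,
# gene families with paralogs, transcriptome-like contig libraries, rDNA
# allele arrays under concerted evolution with pseudogenes, and survey
# fixtures -- each with machine-readable ground truth.

# Sequence states along a tree using the current RNG state; returns tip
# sequences and the root sequence (integer states 1..4).
.simAlongTree <- function(tree, params, length) {
  eig <- .gtrEigen(params)
  rates <- .gammaRates(params)
  site_rate <- if (length(rates) == 1) rep(1, length) else
    rates[sample.int(length(rates), length, replace = TRUE)]
  ntip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  states <- vector("list", ntip + tree$Nnode)
  root_states <- sample.int(4, length, replace = TRUE, prob = params@freqs)
  states[[ntip + 1]] <- root_states
  for (e in rev(seq_len(nrow(post$edge)))) {
    par <- post$edge[e, 1]; chd <- post$edge[e, 2]
    t <- post$edge.length[e]
    x <- states[[par]]
    out <- x
    for (r in unique(site_rate)) {
      idx <- which(site_rate == r)
      out[idx] <- .evolveStates(x[idx], t, eig, r)
    }
    states[[chd]] <- out
  }
  tips <- lapply(seq_len(ntip), function(i) states[[i]])
  names(tips) <- tree$tip.label
  list(tips = tips, root = root_states, eig = eig)
}

.statesToSeq <- function(states) paste(DNA_STATES[states], collapse = "")

.stripSemicolon <- function(nwk) sub(";$", "", nwk)

#' Simulate an ultrametric species tree with an outgroup
#'
#' An ultrametric (coalescent-shaped) ingroup clade and, when
#' `n_outgroup > 0`, an outgroup clade attached at the root, with every
#' root-to-tip path equal to `depth` (substitutions/site). Ingroup tips are
#' labelled `in01`, `in02`, ...; outgroup tips `out01`, ....
#'
#' @param n_species Number of ingroup species (>= 2).
#' @param n_outgroup Number of outgroup taxa (0 for none).
#' @param depth Root-to-tip depth.
#' @param seed Integer seed.
#' @param spacing "even" (default) respaces the split depths uniformly
#'   between the crown and the present, giving well-differentiated species
#'   (the situation of described species with distinct markers);
#'   "coalescent" keeps the raw coalescent depths, which concentrate
#'   splits near the present and yield barely differentiated sister
#'   species.
#' @return An `ape::phylo`.
#' @export
simulateSpeciesTree <- function(n_species, n_outgroup = 0, depth = 0.15,
                                seed = 1, spacing = c("even", "coalescent")) {
  if (n_species < 2) stop("n_species must be >= 2")
  spacing <- match.arg(spacing)
  set.seed(seed)
  scaleTo <- function(tr, target) {
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length * target / h
    tr
  }
  respace <- function(tr, crown) {
    # keep the topology, space internal-node depths evenly to the crown
    bt <- ape::branching.times(tr)
    ntip <- length(tr$tip.label)
    newbt <- stats::setNames(rank(bt, ties.method = "first") /
                               length(bt) * crown, names(bt))
    timeOf <- function(node) if (node <= ntip) 0 else
      newbt[[as.character(node)]]
    tr$edge.length <- vapply(seq_len(nrow(tr$edge)), function(e)
      timeOf(tr$edge[e, 1]) - timeOf(tr$edge[e, 2]), numeric(1))
    tr
  }
  subNewick <- function(n, labels, crown) {
    if (n == 1) return(list(nwk = labels[1], h = 0))
    tr <- scaleTo(ape::rcoal(n, tip.label = labels), crown)
    if (spacing == "even") tr <- respace(tr, crown)
    list(nwk = .stripSemicolon(ape::write.tree(tr, digits = 10)), h = crown)
  }
  ing <- subNewick(n_species, sprintf("in%02d", seq_len(n_species)),
                   0.6 * depth)
  if (n_outgroup == 0) {
    tr <- ape::read.tree(text = paste0(ing$nwk, ";"))
    return(scaleTo(tr, depth))
  }
  outg <- subNewick(n_outgroup, sprintf("out%02d", seq_len(n_outgroup)),
                    0.5 * depth)
  nwk <- sprintf("(%s:%.10f,%s:%.10f);", ing$nwk, depth - ing$h,
                 outg$nwk, depth - outg$h)
  ape::read.tree(text = nwk)
}

#' Simulate a gene family with planted paralogs
#'
#' Starts from the species tree (one copy per species), optionally
#' duplicates whole clades: with probability `dup_prob` a duplication is
#' planted at the root (producing two separated clades that each mirror
#' the species tree -- the signature the paralog-partitioning rule must
#' detect) and, independently, on each internal edge at its midpoint.
#' Duplicate-copy branches evolve `paralog_rate` times faster (duplicated
#' copies experience relaxed constraint), and each non-original copy is
#' lost per species with probability `loss_prob`. Sequences are evolved
#' under `params`; the returned truth labels every member as in-paralog
#' (copy 1) or out-paralog.
#'
#' @param species_tree `ape::phylo` from [simulateSpeciesTree()].
#' @param dup_prob Duplication probability (root and each internal edge).
#' @param loss_prob Per-species loss probability of duplicate copies.
#' @param params [GTRParams-class].
#' @param length Sequence length.
#' @param seed Integer seed.
#' @param gene_id Gene identifier used in member ids.
#' @param paralog_rate Rate multiplier of duplicate-copy branches (>= 1).
#' @param edge_dup_prob Duplication probability on internal edges
#'   (defaults to `dup_prob`; set to 0 for root-only duplication).
#' @return List: `family` (a [GeneFamily-class] with alignment and true
#'   gene tree), `truth` (data frame: id, taxon, copy, is_paralog),
#'   `root_seq` (the ancestral sequence, usable as a reference-panel
#'   entry).
#' @export
simulateGeneFamily <- function(species_tree, dup_prob = 0, loss_prob = 0,
                               params = gtrParams(), length = 300, seed = 1,
                               gene_id = "g1", paralog_rate = 2,
                               edge_dup_prob = dup_prob) {
  set.seed(seed)
  depth <- max(ape::node.depth.edgelength(species_tree))
  base <- species_tree
  base$tip.label <- paste0(base$tip.label, ".c1")
  ntip <- length(species_tree$tip.label)
  copy_counter <- stats::setNames(rep(1L, ntip), species_tree$tip.label)
  gene_tree <- base
  dupCopy <- function(clade_tips) {
    # next copy index per species in the clade
    taxa <- sub("\\.c[0-9]+$", "", clade_tips)
    copy_counter[taxa] <<- copy_counter[taxa] + 1L
    paste0(taxa, ".c", copy_counter[taxa])
  }
  # root duplication: both copies mirror the species tree
  if (runif(1) < dup_prob) {
    copyA <- species_tree
    copyA$tip.label <- paste0(copyA$tip.label, ".c1")
    copyB <- species_tree
    copyB$tip.label <- dupCopy(copyA$tip.label)
    copyB$edge.length <- copyB$edge.length * paralog_rate
    stem <- 0.25 * depth
    nwk <- sprintf("(%s:%.10f,%s:%.10f);",
                   .stripSemicolon(ape::write.tree(copyA, digits = 10)), stem,
                   .stripSemicolon(ape::write.tree(copyB, digits = 10)),
                   stem * paralog_rate)
    gene_tree <- ape::read.tree(text = nwk)
  }
  # midpoint duplications on internal edges of the original species tree
  internal_edges <- which(species_tree$edge[, 2] > ntip)
  for (e in internal_edges) {
    if (runif(1) >= edge_dup_prob) next
    node <- species_tree$edge[e, 2]
    clade <- ape::extract.clade(species_tree, node)
    pos <- species_tree$edge.length[e] / 2
    clade$tip.label <- dupCopy(paste0(clade$tip.label, ".c1"))
    clade$edge.length <- clade$edge.length * paralog_rate
    clade$root.edge <- pos * paralog_rate
    where <- ape::getMRCA(gene_tree,
                          intersect(gene_tree$tip.label,
                                    paste0(ape::extract.clade(species_tree,
                                                              node)$tip.label,
                                           ".c1")))
    gene_tree <- ape::bind.tree(gene_tree, clade, where = where,
                                position = pos)
  }
  # losses among duplicate copies
  dup_tips <- grep("\\.c([2-9]|[0-9]{2,})$", gene_tree$tip.label, value = TRUE)
  lost <- dup_tips[runif(length(dup_tips)) < loss_prob]
  if (length(lost) && length(lost) < length(gene_tree$tip.label) - 2)
    gene_tree <- ape::drop.tip(gene_tree, lost)
  sim <- .simAlongTree(gene_tree, params, length)
  seqs <- vapply(sim$tips, .statesToSeq, character(1))
  ids <- paste0(gene_id, "|", names(seqs))
  taxa <- sub("\\.c[0-9]+$", "", names(seqs))
  copies <- as.integer(sub("^.*\\.c", "", names(seqs)))
  names(seqs) <- ids
  fam <- geneFamily(gene_id, seqs, taxa,
                    alignment = if (length(seqs) >= 2)
                      seqAlignment(seqs, taxa) else NULL,
                    tree = { gt <- gene_tree
                             gt$tip.label <- paste0(gene_id, "|", gt$tip.label)
                             gt })
  list(family = fam,
       truth = data.frame(id = ids, taxon = taxa, copy = copies,
                          is_paralog = copies > 1L),
       root_seq = .statesToSeq(sim$root))
}

# Fit a first-order Markov chain to sequences and simulate from it.
.markovFit <- function(seqs) {
  ch <- unlist(strsplit(seqs, ""), use.names = FALSE)
  trans <- matrix(1, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  idx <- match(ch, DNA_STATES)
  from <- idx[-length(idx)]; to <- idx[-1]
  ok <- !is.na(from) & !is.na(to)
  for (k in seq_along(from)[ok]) trans[from[k], to[k]] <- trans[from[k], to[k]] + 1
  trans / rowSums(trans)
}

.markovSim <- function(trans, n) {
  out <- integer(n)
  out[1] <- sample.int(4, 1)
  for (i in 2:n) out[i] <- sample.int(4, 1, prob = trans[out[i - 1], ])
  paste(DNA_STATES[out], collapse = "")
}

#' Simulate transcriptome-like contig libraries with ground truth
#'
#' Generates, per taxon, contigs for `n_genes` reference genes plus
#' `n_noise` noise contigs, together with the reference panel (each gene's
#' ancestral sequence) and a truth table. Genes come in three planted
#' types: clean single-copy orthologs; paralog families with a root
#' duplication (both copies present per taxon); and genes evolved on a
#' species tree whose outgroup was scrambled into the ingroup, which the
#' tree-QC reciprocal-monophyly rule must reject. Ortholog/paralog contigs
#' carry random flanking sequence (untranslated ends); noise contigs are
#' drawn from a first-order Markov chain fitted to the ortholog base
#' composition -- a harder negative control than uniform random sequence.
#'
#' @param species_tree `ape::phylo` with `in*`/`out*` tip labels.
#' @param n_genes Number of reference genes (>= 1).
#' @param n_noise Noise contigs per taxon.
#' @param params [GTRParams-class].
#' @param seed Integer seed.
#' @param frac_paralog,frac_bad Fractions of genes planted as paralog
#'   families and as scrambled-outgroup genes.
#' @param gene_length Gene length (nt).
#' @param utr_range Min/max length of each random flank.
#' @return List: `libraries` (named list taxon -> named character contigs),
#'   `reference` (named character), `truth` (list with `genes` and
#'   `contigs` data frames), `species_tree`.
#' @export
simulateTranscriptomeLibrary <- function(species_tree, n_genes = 30,
                                         n_noise = 5, params = gtrParams(),
                                         seed = 1, frac_paralog = 0.2,
                                         frac_bad = 0.1, gene_length = 300,
                                         utr_range = c(20, 60)) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  taxa <- species_tree$tip.label
  n_par <- round(frac_paralog * n_genes)
  n_bad <- round(frac_bad * n_genes)
  types <- c(rep("paralog", n_par), rep("bad_outgroup", n_bad),
             rep("clean", n_genes - n_par - n_bad))
  types <- sample(types)   # shuffle gene order
  # scrambled tree: swap one ingroup label with one outgroup label, which
  # breaks ingroup/outgroup reciprocal monophyly on the generating tree
  scrambled <- species_tree
  ing <- grep("^in", taxa); outg <- grep("^out", taxa)
  if (length(outg)) {
    i <- ing[1]; o <- outg[1]
    scrambled$tip.label[c(i, o)] <- scrambled$tip.label[c(o, i)]
  }
  libraries <- setNames(lapply(taxa, function(x) character(0)), taxa)
  reference <- character(0)
  gene_rows <- list(); contig_rows <- list()
  utr <- function(trans) .markovSim(trans, sample(utr_range[1]:utr_range[2], 1))
  plain_trans <- matrix(0.25, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  for (gi in seq_len(n_genes)) {
    g <- sprintf("gene%03d", gi)
    type <- types[gi]
    tr <- if (type == "bad_outgroup") scrambled else species_tree
    fam <- simulateGeneFamily(tr,
                              dup_prob = if (type == "paralog") 1 else 0,
                              edge_dup_prob = 0,
                              loss_prob = 0, params = params,
                              length = gene_length,
                              seed = sample.int(.Machine$integer.max - 1, 1),
                              gene_id = g)
    reference[g] <- fam$root_seq
    for (k in seq_len(nrow(fam$truth))) {
      tx <- fam$truth$taxon[k]
      cid <- fam$truth$id[k]
      seq_core <- fam$family@seqs[[cid]]
      contig <- paste0(utr(plain_trans), seq_core, utr(plain_trans))
      libraries[[tx]][cid] <- contig
      cls <- if (type == "bad_outgroup") "bad_gene"
             else if (fam$truth$is_paralog[k]) "paralog" else "ortholog"
      contig_rows[[cid]] <- data.frame(id = cid, taxon = tx, gene = g,
                                       copy = fam$truth$copy[k], class = cls)
    }
    gene_rows[[g]] <- data.frame(gene = g, type = type)
  }
  # noise contigs from a Markov chain fitted to the ortholog composition
  trans <- .markovFit(unname(reference))
  for (tx in taxa) {
    for (j in seq_len(n_noise)) {
      cid <- sprintf("noise|%s|n%02d", tx, j)
      libraries[[tx]][cid] <- .markovSim(trans, gene_length)
      contig_rows[[cid]] <- data.frame(id = cid, taxon = tx, gene = NA,
                                       copy = NA_integer_, class = "noise")
    }
  }
  truth <- list(genes = do.call(rbind, gene_rows),
                contigs = do.call(rbind, contig_rows))
  rownames(truth$genes) <- rownames(truth$contigs) <- NULL
  list(libraries = libraries, reference = reference, truth = truth,
       species_tree = species_tree)
}

#' rDNA concerted-evolution simulation settings
#'
#' @slot nAlleles Allele copies carried per species lineage.
#' @slot h Per-copy homogenization (gene-conversion) probability at each
#'   event boundary.
#' @slot pseudoProb Probability that a sampled copy is a pseudogene that
#'   arose within the terminal lineage.
#' @slot rho Rate multiplier of pseudogene evolution (>= 1).
#' @slot params Base [GTRParams-class].
#' @slot length Locus length (nt).
#' @export
setClass("RdnaSimConfig",
  representation(nAlleles = "integer", h = "numeric", pseudoProb = "numeric",
                 rho = "numeric", params = "GTRParams", length = "integer"))

setValidity("RdnaSimConfig", function(object) {
  if (object@h < 0 || object@h > 1) return("h must lie in [0, 1]")
  if (object@pseudoProb < 0 || object@pseudoProb > 1)
    return("pseudoProb must lie in [0, 1]")
  if (object@rho < 1) return("rho must be >= 1")
  if (object@nAlleles < 1) return("nAlleles must be >= 1")
  TRUE
})

#' Construct rDNA simulation settings
#'
#' @param n_alleles Copies per species (default 4).
#' @param h Homogenization probability per copy per event boundary
#'   (default 0.9).
#' @param pseudo_prob Pseudogene escape probability per copy (default 0.2).
#' @param rho Pseudogene rate multiplier (default 5).
#' @param params Base [GTRParams-class].
#' @param length Locus length (default 800 nt, the scale of a D1-D3
#'   fragment).
#' @return An [RdnaSimConfig-class].
#' @export
rdnaSimConfig <- function(n_alleles = 4L, h = 0.9, pseudo_prob = 0.2,
                          rho = 5, params = gtrParams(), length = 800L) {
  new("RdnaSimConfig", nAlleles = as.integer(n_alleles), h = h,
      pseudoProb = pseudo_prob, rho = rho, params = params,
      length = as.integer(length))
}

#' Simulate rDNA allele arrays under concerted evolution
#'
#' Each species lineage carries `nAlleles` copies of the locus. Copies
#' evolve independently along branches; concerted evolution is modelled as
#' homogenization rounds in which each functional copy is replaced by the
#' lineage consensus with probability `h`. Gene conversion recurs over the
#' many generations a lineage spans, so rounds fire repeatedly: in the
#' parent array immediately before each speciation, in each daughter array
#' immediately after it, at two interior points of every branch, and at
#' sampling; a copy escapes its species' history only by missing every
#' round since the species originated. Pseudogenes
#' arise on terminal branches (surviving pseudogene copies in extant
#' genomes are young): with probability `pseudoProb` a copy escapes at a
#' uniform time on the terminal branch and thereafter evolves at `rho`
#' times the base rate, never homogenized again -- producing the divergent
#' within-species subclusters seen in real rDNA arrays while remaining
#' species-specific. With `h = 1` and no pseudogenes, within-species
#' allele distances are all zero; with `h = 0` copies coalesce far above
#' the species level and species monophyly breaks down.
#'
#' @param species_tree Rooted `ape::phylo` (species tips).
#' @param config An [RdnaSimConfig-class].
#' @param seed Integer seed.
#' @return List: `alignment` (all alleles, ids `species_aK`),
#'   `species_map` (named character: allele id -> species), `truth` (data
#'   frame: id, species, type functional/pseudogene), `tree` (the input
#'   species tree).
#' @export
simulateRdnaAlleles <- function(species_tree, config = rdnaSimConfig(),
                                seed = 1) {
  validObject(config)
  set.seed(seed)
  eig <- .gtrEigen(config@params)
  L <- config@length
  ntip <- length(species_tree$tip.label)
  children <- split(species_tree$edge[, 2], species_tree$edge[, 1])
  edge_len <- stats::setNames(species_tree$edge.length,
                              paste(species_tree$edge[, 1],
                                    species_tree$edge[, 2]))
  homogenize <- function(alleles, germ) {
    for (k in seq_along(alleles)) {
      if (!alleles[[k]]$pseudo && runif(1) < config@h)
        alleles[[k]]$seq <- germ
    }
    alleles
  }
  # Evolve the lineage (germ + allele array) along one branch of length t.
  # Conversion eras fire at two interior points of the branch (concerted
  # evolution recurs within a lineage, not only at nodes); on terminal
  # branches functional copies may escape as pseudogenes at a uniform
  # depth, after which they evolve at rho times the base rate and are
  # never converted again.
  evolveBranch <- function(germ, alleles, t, terminal) {
    events <- data.frame(depth = c(2 * t / 3, t / 3), kind = "era",
                         k = NA_integer_)
    if (terminal) {
      for (k in seq_along(alleles)) {
        # escape depth drawn on the younger half of the branch: pseudogene
        # copies as old as the species itself decay beyond recognition and
        # are not sampled as rDNA
        if (!alleles[[k]]$pseudo && runif(1) < config@pseudoProb)
          events <- rbind(events,
                          data.frame(depth = runif(1, 0, t / 2),
                                     kind = "escape", k = k))
      }
    }
    events <- events[order(-events$depth), , drop = FALSE]
    cur <- t
    step <- function(dt) {
      if (dt <= 0) return()
      germ <<- .evolveStates(germ, dt, eig, 1)
      for (k in seq_along(alleles))
        alleles[[k]]$seq <<- .evolveStates(alleles[[k]]$seq, dt, eig,
                                           if (alleles[[k]]$pseudo)
                                             config@rho else 1)
    }
    for (i in seq_len(nrow(events))) {
      step(cur - events$depth[i])
      cur <- events$depth[i]
      if (events$kind[i] == "era") {
        alleles <- homogenize(alleles, germ)
      } else {
        k <- events$k[i]
        if (!alleles[[k]]$pseudo)
          alleles[[k]] <- list(seq = germ, pseudo = TRUE)
      }
    }
    step(cur)
    list(germ = germ, alleles = alleles)
  }
  out <- new.env(parent = emptyenv())
  descend <- function(node, germ, alleles) {
    # conversion era in the parent array at the coming speciation
    alleles <- homogenize(alleles, germ)
    for (chd in children[[as.character(node)]]) {
      t <- edge_len[[paste(node, chd)]]
      a <- homogenize(alleles, germ)          # daughter-side era
      ev <- evolveBranch(germ, a, t, terminal = chd <= ntip)
      if (chd <= ntip) {
        sp <- species_tree$tip.label[chd]
        assign(sp, homogenize(ev$alleles, ev$germ), envir = out)  # sampling era
      } else {
        descend(chd, ev$germ, ev$alleles)
      }
    }
  }
  germ0 <- sample.int(4, L, replace = TRUE, prob = config@params@freqs)
  alleles0 <- replicate(config@nAlleles, list(seq = germ0, pseudo = FALSE),
                        simplify = FALSE)
  descend(ntip + 1, germ0, alleles0)
  seqs <- character(0); sp_map <- character(0); type <- character(0)
  for (sp in species_tree$tip.label) {
    a <- get(sp, envir = out)
    for (k in seq_along(a)) {
      id <- sprintf("%s_a%d", sp, k)
      seqs[id] <- .statesToSeq(a[[k]]$seq)
      sp_map[id] <- sp
      type[id] <- if (a[[k]]$pseudo) "pseudogene" else "functional"
    }
  }
  list(alignment = seqAlignment(seqs, taxon = unname(sp_map)),
       species_map = sp_map,
       truth = data.frame(id = names(seqs), species = unname(sp_map),
                          type = unname(type)),
       tree = species_tree)
}

.CATEGORY_CALLS <- list(
  resolved = c("Y", "YP"),
  ambiguous = c("YA", "Y/YA", "YP/YA"),
  not_resolved = c("N", "NA", "N/NA", "N/YA", "Y/N"))

#' Generate a synthetic literature-survey table with known truth
#'
#' Samples, per (species, region), a resolution category with the given
#' probabilities and a compound call uniformly from the category's closed
#' call list, so that [mapToCategory()] recovers the drawn category by
#' construction. A fraction of entries appear in only a subset of regions,
#' and a fraction of rows are undescribed ribotypes (excluded from the
#' three-category summary, like their real counterparts).
#'
#' @param n_genera Number of genera to spread species over.
#' @param n_species Number of described species.
#' @param category_probs Probabilities of (not_resolved, ambiguous,
#'   resolved); must sum to 1.
#' @param regions Regions to generate (default all three).
#' @param seed Integer seed.
#' @param region_presence Probability an entry exists for a region
#'   (at least one region is always present).
#' @param ribotype_frac Ribotype rows added as a fraction of n_species.
#' @return List: `table` (survey data frame), `truth` (data frame:
#'   species, region, category).
#' @export
generateSurveyFixture <- function(n_genera = 30, n_species = 200,
                                  category_probs = c(0.05, 0.02, 0.93),
                                  regions = SURVEY_REGIONS, seed = 1,
                                  region_presence = 0.8,
                                  ribotype_frac = 0.2) {
  if (abs(sum(category_probs) - 1) > 1e-8)
    stop("category_probs must sum to 1")
  set.seed(seed)
  cats <- c("not_resolved", "ambiguous", "resolved")
  rows <- list(); truth <- list()
  makeEntries <- function(name, genus, described) {
    present <- runif(length(regions)) < region_presence
    if (!any(present)) present[sample.int(length(regions), 1)] <- TRUE
    for (rg in regions[present]) {
      cat_i <- sample(cats, 1, prob = category_probs)
      call <- sample(.CATEGORY_CALLS[[cat_i]], 1)
      rows[[length(rows) + 1]] <<- data.frame(
        genus = genus, species = name, is_described = described,
        region = rg, call = call)
      truth[[length(truth) + 1]] <<- data.frame(
        species = name, region = rg, category = cat_i)
    }
  }
  for (i in seq_len(n_species)) {
    g <- sprintf("Genus%02d", sample.int(n_genera, 1))
    makeEntries(sprintf("%s species%04d", g, i), g, TRUE)
  }
  n_ribo <- round(ribotype_frac * n_species)
  for (i in seq_len(n_ribo)) {
    g <- sprintf("Genus%02d", sample.int(n_genera, 1))
    makeEntries(sprintf("%s sp. ribotype%03d", g, i), g, FALSE)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  validateSurveyTable(table)
  list(table = table, truth = do.call(rbind, truth))
}

#' Synthetic survey archive with prescribed marginals
#'
#' Builds a synthetic stand-in for a full literature-survey archive whose
#' aggregate properties are supplied as arguments: a chosen number of
#' described species, of dual-region (ITS + 5' LSU) instances, and of
#' dual-region discordances (ITS resolved, LSU not), with a chosen number
#' of the discordances concentrated in one genus. Useful for exercising
#' [regionAgreement()] and [summarizeSurvey()] against known tallies when
#' the real archive is not at hand. Entirely synthetic: rows are generated,
#' not transcribed from any source.
#'
#' @param n_described Total described species.
#' @param n_dual Entries carrying both ITS and LSU5prime calls.
#' @param n_discordant Dual entries where ITS resolves and LSU does not.
#' @param n_discordant_one_genus How many discordances sit in a single
#'   genus.
#' @param n_ribotypes Undescribed ribotype rows (single-region).
#' @param seed Integer seed.
#' @return A survey data frame.
#' @export
syntheticSurveyArchive <- function(n_described = 863, n_dual = 439,
                                   n_discordant = 6,
                                   n_discordant_one_genus = 5,
                                   n_ribotypes = 315, seed = 1) {
  set.seed(seed)
  stopifnot(n_dual <= n_described, n_discordant <= n_dual)
  rows <- list()
  addRow <- function(genus, species, described, region, call)
    rows[[length(rows) + 1]] <<- data.frame(
      genus = genus, species = species, is_described = described,
      region = region, call = call)
  hot_genus <- "GenusA"
  for (i in seq_len(n_described)) {
    sp <- sprintf("species%04d", i)
    genus <- if (i <= n_discordant_one_genus) hot_genus
             else sprintf("Genus%02d", 1 + (i %% 40))
    if (i <= n_dual) {
      if (i <= n_discordant) {
        addRow(genus, sp, TRUE, "ITS", "Y")
        addRow(genus, sp, TRUE, "LSU5prime", "N")
      } else {
        call <- sample(c("Y", "YP"), 1, prob = c(0.85, 0.15))
        addRow(genus, sp, TRUE, "ITS", call)
        addRow(genus, sp, TRUE, "LSU5prime", call)
      }
    } else {
      region <- sample(SURVEY_REGIONS, 1)
      addRow(genus, sp, TRUE, region, sample(c("Y", "YP", "N"), 1,
                                             prob = c(0.8, 0.13, 0.07)))
    }
  }
  for (i in seq_len(n_ribotypes)) {
    addRow(sprintf("Genus%02d", 1 + (i %% 40)),
           sprintf("sp. ribotype%04d", i), FALSE,
           sample(c("ITS", "LSU5prime"), 1), "YP")
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validateSurveyTable(tab)
  tab
}
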