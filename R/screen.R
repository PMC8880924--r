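# Reciprocal-best-hit screening of contig libraries against a reference
# gene panel, and the 1-4 top-hit gene-selection rule.

#' Screening configuration
#'
#' @slot minHits,maxHits Per-taxon hit-count bounds for gene selection
#'   (default 1 and 4: the "one to four top hits" rule).
#' @slot scoreFloor Minimum local alignment score for a hit to be kept
#'   (default 50, which excludes chance matches between unrelated 30-mers
#'   under the default scoring; verified by simulation in the test suite).
#' @slot match,mismatch,gapOpen,gapExtend Nucleotide scoring (defaults
#'   2/-3/-5/-2, the classic megablast-style scheme).
#' @slot matrixName Substitution matrix name (e.g. "BLOSUM62") for protein
#'   scoring, or NA for nucleotide match/mismatch scoring.
#' @slot coverageFloor Minimum fraction of library taxa a gene must be
#'   represented in to be selected (default 0.8).
#' @slot seedK Word size of the exact-match prefilter used to avoid scoring
#'   unrelated pairs (default 11); 0 disables the prefilter.
#' @slot minSeedHits Minimum shared words required to score a pair.
#' @export
setClass("ScreenConfig",
  representation(minHits = "integer", maxHits = "integer",
                 scoreFloor = "numeric", match = "numeric",
                 mismatch = "numeric", gapOpen = "numeric",
                 gapExtend = "numeric", matrixName = "character",
                 coverageFloor = "numeric", seedK = "integer",
                 minSeedHits = "integer"))

setValidity("ScreenConfig", function(object) {
  if (object@minHits < 1L || object@minHits > object@maxHits)
    return("need 1 <= minHits <= maxHits")
  if (object@scoreFloor < 0) return("scoreFloor must be non-negative")
  if (object@coverageFloor < 0 || object@coverageFloor > 1)
    return("coverageFloor must be in [0, 1]")
  TRUE
})

#' Construct a screening configuration
#'
#' @param min_hits,max_hits Hit-count bounds per (gene, taxon).
#' @param score_floor Minimum retained alignment score.
#' @param match,mismatch,gap_open,gap_extend Nucleotide scoring parameters.
#' @param matrix_name Protein substitution matrix name, or NA.
#' @param coverage_floor Minimum fraction of taxa a gene must cover.
#' @param seed_k,min_seed_hits Exact-word prefilter settings (seed_k = 0
#'   scores every pair exhaustively).
#' @return A [ScreenConfig-class].
#' @export
screenConfig <- function(min_hits = 1L, max_hits = 4L, score_floor = 50,
                         match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2, matrix_name = NA_character_,
                         coverage_floor = 0.8, seed_k = 11L,
                         min_seed_hits = 2L) {
  new("ScreenConfig", minHits = as.integer(min_hits),
      maxHits = as.integer(max_hits), scoreFloor = score_floor,
      match = match, mismatch = mismatch, gapOpen = gap_open,
      gapExtend = gap_extend, matrixName = matrix_name,
      coverageFloor = coverage_floor, seedK = as.integer(seed_k),
      minSeedHits = as.integer(min_seed_hits))
}

setMethod("show", "ScreenConfig", function(object) {
  cat(sprintf(
    "ScreenConfig: %d-%d hits/taxon, score floor %g, coverage floor %.2f\n",
    object@minHits, object@maxHits, object@scoreFloor, object@coverageFloor))
})

.isNucleotide <- function(s) {
  ch <- unique(strsplit(s, "")[[1]])
  all(ch %in% c(DNA_STATES, "N", "-"))
}

#' Smith-Waterman local alignment score
#'
#' Affine-gap local alignment score between two sequences, the internal
#' scoring step of reciprocal-best-hit screening (raw score, not a
#' bitscore: only the ranking matters downstream). Symmetric in its
#' arguments.
#'
#' @param a,b Sequences (character strings) over the same alphabet.
#' @param config A [ScreenConfig-class] carrying the scoring scheme.
#' @return The local alignment score (0 when no positive-scoring local
#'   alignment exists).
#' @examples
#' cfg <- screenConfig(match = 1, mismatch = -1, gap_open = -2, gap_extend = -2)
#' localAlignScore("ACGTACGT", "ACGTACGT", cfg)  # 8
#' localAlignScore("AAAA", "CCCC", cfg)          # 0
#' @export
localAlignScore <- function(a, b, config = screenConfig()) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("sequences must be non-empty")
  protein <- !is.na(config@matrixName)
  if (!protein && (!.isNucleotide(a) || !.isNucleotide(b))) {
    if (.isNucleotide(a) != .isNucleotide(b))
      stop("alphabet mismatch between the two sequences")
    stop("non-nucleotide input: set a protein substitution matrix")
  }
  .alignScoreSet(a, b, config)[1]
}

# Vectorized scores of many patterns against one subject.
.alignScoreSet <- function(patterns, subject, config) {
  protein <- !is.na(config@matrixName)
  if (protein) {
    Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
      type = "local", substitutionMatrix = config@matrixName,
      gapOpening = -config@gapOpen, gapExtension = -config@gapExtend,
      scoreOnly = TRUE)
  } else {
    sm <- Biostrings::nucleotideSubstitutionMatrix(
      match = config@match, mismatch = config@mismatch, baseOnly = TRUE)
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = sm,
      gapOpening = -config@gapOpen, gapExtension = -config@gapExtend,
      scoreOnly = TRUE)
  }
}

# All overlapping k-words of a sequence.
.kwords <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1), k:n))
}

# For each contig, the reference genes sharing >= min_hits exact k-words.
.seedCandidates <- function(contigs, genes, k, min_hits) {
  gene_words <- lapply(genes, .kwords, k = k)
  word2gene <- split(rep(names(genes), lengths(gene_words)),
                     unlist(gene_words))
  lapply(contigs, function(ct) {
    hits <- unlist(word2gene[.kwords(ct, k)], use.names = FALSE)
    if (is.null(hits)) return(character(0))
    tab <- table(hits)
    names(tab)[tab >= min_hits]
  })
}

.asCharSeqs <- function(x) {
  if (is.character(x)) return(toupper(x))
  setNames(toupper(as.character(x)), names(x))
}

#' Reciprocal-best-hit screening
#'
#' Scores each contig against the reference gene panel with local alignment
#' (an exact-word prefilter restricts scoring to plausibly homologous
#' pairs, as seeded search tools do). A (gene, taxon, contig) hit is
#' retained only if the contig's best-scoring reference gene is that gene
#' and the contig sits within the gene's top `maxHits` scoring contigs for
#' that taxon; hits below the score floor are dropped. Retained hits are
#' ranked by score within (gene, taxon); ties broken by longer contig, then
#' id.
#'
#' @param libraries Named list (one element per taxon) of named character
#'   vectors or `XStringSet`s of contigs.
#' @param reference Named character vector or `XStringSet` of reference
#'   genes.
#' @param config A [ScreenConfig-class].
#' @return A hit table: data frame with columns gene, taxon, contig, score,
#'   rank, length.
#' @export
reciprocalBestHits <- function(libraries, reference, config = screenConfig()) {
  reference <- .asCharSeqs(reference)
  if (length(reference) == 0) stop("empty reference gene panel")
  if (length(libraries) == 0 || all(lengths(libraries) == 0))
    stop("empty contig libraries")
  out <- list()
  for (taxon in names(libraries)) {
    contigs <- .asCharSeqs(libraries[[taxon]])
    if (length(contigs) == 0) next
    cand <- if (config@seedK > 0)
      .seedCandidates(contigs, reference, config@seedK, config@minSeedHits)
    else lapply(contigs, function(x) names(reference))
    # score candidate pairs, grouped by gene for vectorized alignment
    pairs <- data.frame(
      contig = rep(names(contigs), lengths(cand)),
      gene = unlist(cand, use.names = FALSE))
    if (nrow(pairs) == 0) next
    pairs$score <- NA_real_
    for (g in unique(pairs$gene)) {
      idx <- which(pairs$gene == g)
      pairs$score[idx] <- .alignScoreSet(contigs[pairs$contig[idx]],
                                         reference[[g]], config)
    }
    pairs <- pairs[pairs$score >= config@scoreFloor, , drop = FALSE]
    if (nrow(pairs) == 0) next
    # best gene per contig (ties: lexicographically first gene id)
    pairs <- pairs[order(pairs$contig, -pairs$score, pairs$gene), ]
    best_gene <- pairs[!duplicated(pairs$contig), c("contig", "gene")]
    best_of <- setNames(best_gene$gene, best_gene$contig)
    # rank of each contig within each gene's scored list
    pairs$len <- nchar(contigs[pairs$contig])
    pairs <- pairs[order(pairs$gene, -pairs$score, -pairs$len, pairs$contig), ]
    pairs$generank <- ave(pairs$score, pairs$gene,
                          FUN = function(x) seq_along(x))
    keep <- best_of[pairs$contig] == pairs$gene &
      pairs$generank <= config@maxHits
    ret <- pairs[keep, , drop = FALSE]
    if (nrow(ret) == 0) next
    ret$rank <- ave(ret$score, ret$gene, FUN = function(x) seq_along(x))
    out[[taxon]] <- data.frame(gene = ret$gene, taxon = taxon,
                               contig = ret$contig, score = ret$score,
                               rank = as.integer(ret$rank),
                               length = ret$len)
  }
  if (length(out) == 0)
    return(data.frame(gene = character(), taxon = character(),
                      contig = character(), score = numeric(),
                      rank = integer(), length = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select candidate genes by the hit-count rule
#'
#' A gene is retained iff every taxon with at least one retained hit
#' contributes between `minHits` and `maxHits` hits, and the number of
#' represented taxa is at least `coverageFloor` of the taxa present in the
#' hit table.
#'
#' @param hit_table A hit table from [reciprocalBestHits()].
#' @param config A [ScreenConfig-class].
#' @param all_taxa Optional character vector of the full taxon universe
#'   (defaults to the taxa appearing in the hit table).
#' @return Character vector of retained gene ids (possibly empty).
#' @export
selectCandidateGenes <- function(hit_table, config = screenConfig(),
                                 all_taxa = NULL) {
  if (nrow(hit_table) == 0) return(character(0))
  if (is.null(all_taxa)) all_taxa <- unique(hit_table$taxon)
  floor_n <- ceiling(config@coverageFloor * length(all_taxa))
  keep <- vapply(split(hit_table, hit_table$gene), function(h) {
    counts <- table(h$taxon)
    all(counts >= config@minHits & counts <= config@maxHits) &&
      length(counts) >= floor_n
  }, logical(1))
  sort(names(keep)[keep])
}
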