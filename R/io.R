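# Readers and writers: FASTA, Newick, survey TSV, partition files;
# alignment concatenation.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX*-", "")[[1]]
.NT_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Read sequences from FASTA
#'
#' Reads a FASTA file into a `Biostrings` string set. The record id is the
#' first whitespace-delimited token of the header; the taxon label is parsed
#' from a configurable field of the id (so headers like
#' `>g1|taxA description` yield id `g1|taxA` and taxon `taxA`). The taxon is
#' stored in `mcols(x)$taxon`.
#'
#' @param path FASTA file path.
#' @param mode "nucleotide" (alphabet A/C/G/T/-/N) or "protein".
#' @param taxon_delim Field delimiter inside the id (default "|").
#' @param taxon_field Which delimited field carries the taxon (default 2);
#'   ids without that field fall back to the whole id.
#' @return A `DNAStringSet` (nucleotide) or `AAStringSet` (protein) with
#'   `mcols()$taxon`.
#' @export
readFasta <- function(path, mode = c("nucleotide", "protein"),
                      taxon_delim = "|", taxon_field = 2L) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stop(sprintf("empty FASTA file: %s", path))
  ids <- vapply(strsplit(names(raw), "[ \t]"), `[[`, character(1), 1)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate sequence id(s): %s", paste(unique(dup), collapse = ", ")))
  seqs <- toupper(as.character(raw))
  alphabet <- if (mode == "nucleotide") .NT_ALPHABET else .AA_ALPHABET
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[[i]], "")[[1]]
    if (length(ch) == 0) stop(sprintf("record '%s' has an empty sequence", ids[i]))
    bad <- which(!ch %in% alphabet)
    if (length(bad))
      stop(sprintf("record '%s': invalid %s residue '%s' at offset %d",
                   ids[i], mode, ch[bad[1]], bad[1]))
  }
  taxon <- vapply(strsplit(ids, taxon_delim, fixed = TRUE), function(f) {
    if (length(f) >= taxon_field) f[[taxon_field]] else paste(f, collapse = taxon_delim)
  }, character(1))
  out <- if (mode == "nucleotide") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$taxon <- taxon
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector, `XStringSet`, or [SeqAlignment-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(x, path) {
  if (is(x, "SeqAlignment")) x <- x@seqs
  if (!is.character(x)) {
    nm <- names(x); x <- as.character(x); names(x) <- nm
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x))
    writeLines(c(paste0(">", names(x)[i]), x[[i]]), con)
  invisible(path)
}

#' Parse and write Newick trees
#'
#' `parseNewick` validates the string (balanced parentheses, non-negative
#' branch lengths, reporting the character position of the first problem)
#' and returns an `ape::phylo`; internal-node support labels are kept in
#' `node.label`. `writeNewick` writes branch lengths to 10 significant
#' digits so that write/parse round-trips preserve topology, lengths and
#' supports.
#'
#' @param text A Newick string.
#' @return `parseNewick`: an `ape::phylo`; `writeNewick`: a Newick string.
#' @examples
#' tr <- parseNewick("((A:0.1,B:0.2)95:0.3,C:0.4);")
#' tr$node.label
#' writeNewick(tr)
#' @export
parseNewick <- function(text) {
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0) stop(sprintf("unbalanced ')' at character %d", i))
    }
  }
  if (depth != 0) stop(sprintf("unbalanced '(' (%d unclosed) in Newick string", depth))
  neg <- regexpr(":\\s*-", text)
  if (neg > 0) stop(sprintf("negative branch length at character %d", as.integer(neg)))
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse Newick string")
  tr
}

#' @rdname parseNewick
#' @param tree An `ape::phylo`.
#' @export
writeNewick <- function(tree) {
  ape::write.tree(tree, digits = 10)
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Rows are taxa; each gene contributes one column block. Taxa absent from
#' a gene are filled with gaps ("-", treated as missing data by the
#' likelihood engine) for that block. Block coordinates are recorded for
#' partition output (1-based inclusive).
#'
#' @param alignments Named list of [SeqAlignment-class] objects (each taxon
#'   at most once per alignment); names are used as gene names.
#' @return A list with elements `alignment` (the supermatrix, rows named by
#'   taxon) and `partitions` (data frame: gene, start, end).
#' @examples
#' a1 <- seqAlignment(c(x = "ACGT", y = "ACGA"), taxon = c("t1", "t2"))
#' a2 <- seqAlignment(c(x = "GG", z = "GC"), taxon = c("t1", "t3"))
#' concatenateAlignments(list(g1 = a1, g2 = a2))$partitions
#' @export
concatenateAlignments <- function(alignments) {
  if (length(alignments) == 0) stop("no alignments to concatenate")
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    names(alignments) <- paste0("gene", seq_along(alignments))
  for (g in names(alignments)) {
    tx <- alignments[[g]]@taxon
    if (anyDuplicated(tx))
      stop(sprintf("gene '%s' has duplicate taxon '%s'",
                   g, tx[duplicated(tx)][1]))
  }
  taxa <- sort(unique(unlist(lapply(alignments, function(a) a@taxon))))
  blocks <- list()
  parts <- data.frame(gene = character(), start = integer(), end = integer())
  pos <- 0L
  for (g in names(alignments)) {
    a <- alignments[[g]]
    L <- alignmentLength(a)
    block <- setNames(rep(strrep("-", L), length(taxa)), taxa)
    block[a@taxon] <- unname(a@seqs)
    blocks[[g]] <- block
    parts <- rbind(parts, data.frame(gene = g, start = pos + 1L, end = pos + L))
    pos <- pos + L
  }
  seqs <- do.call(paste0, blocks)
  names(seqs) <- taxa
  mode <- alignments[[1]]@mode
  aln <- if (length(taxa) >= 2) seqAlignment(seqs, taxon = taxa, mode = mode) else NULL
  list(alignment = aln, partitions = parts)
}

#' Write a partition file
#'
#' One line per gene block, `gene_name = start-end`, 1-based inclusive.
#'
#' @param partitions Data frame with columns gene, start, end (as produced
#'   by [concatenateAlignments()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePartitionFile <- function(partitions, path) {
  writeLines(sprintf("%s = %d-%d", partitions$gene,
                     partitions$start, partitions$end), path)
  invisible(path)
}

# ---- survey tables -------------------------------------------------------

.validCompoundCall <- function(call) {
  toks <- strsplit(call, "/", fixed = TRUE)
  vapply(toks, function(t) length(t) > 0 && all(t %in% CALL_TOKENS), logical(1))
}

#' Validate a species-resolution survey table
#'
#' Checks the table against the survey contract: columns genus, species,
#' is_described, region, call; regions drawn from SSU/ITS/LSU5prime
#' (the 5' LSU divergent-domain results, D1-D2/D1-D3/D1-D6, are treated as
#' one region); calls are "/"-joined combinations of Y, YP, YA, N, NA; one
#' call per (species, region).
#'
#' @param table A data frame.
#' @return The table, invisibly, or an error describing the violation.
#' @export
validateSurveyTable <- function(table) {
  need <- c("genus", "species", "is_described", "region", "call")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols))
    stop(sprintf("survey table lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  bad_region <- setdiff(unique(table$region), SURVEY_REGIONS)
  if (length(bad_region))
    stop(sprintf("unknown region(s): %s", paste(bad_region, collapse = ", ")))
  bad <- !.validCompoundCall(table$call)
  if (any(bad))
    stop(sprintf("invalid call token(s) in: %s",
                 paste(unique(table$call[bad]), collapse = ", ")))
  key <- paste(table$species, table$region)
  if (anyDuplicated(key))
    stop(sprintf("duplicate (species, region) pair: %s", key[duplicated(key)][1]))
  invisible(table)
}

#' Read / write a survey table (TSV)
#'
#' UTF-8 tab-separated with a header row; compound calls are joined by "/".
#'
#' @param path TSV file path.
#' @return `readSurveyTable`: a validated data frame.
#' @export
readSurveyTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  tab$is_described <- as.logical(tab$is_described)
  validateSurveyTable(tab)
  tab
}

#' @rdname readSurveyTable
#' @param table A survey data frame.
#' @export
writeSurveyTable <- function(table, path) {
  validateSurveyTable(table)
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
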