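test_that("FASTA reading preserves order, parses taxa, validates input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1|taxA some description", "ACGTAC",
               ">g2|taxB", "ACGT-N"), f)
  x <- readFasta(f)
  expect_equal(names(x), c("g1|taxA", "g2|taxB"))
  expect_equal(S4Vectors::mcols(x)$taxon, c("taxA", "taxB"))
  expect_equal(as.character(x[["g1|taxA"]]), "ACGTAC")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1", "ACJT"), bad)
  expect_error(readFasta(bad), "r1.*'J' at offset 3")

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), dup)
  expect_error(readFasta(dup), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(readFasta(empty), "empty")
})

test_that("FASTA write/read round-trips random sequence sets", {
  set.seed(42)
  for (i in 1:5) {
    n <- sample(2:8, 1)
    seqs <- setNames(vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), sample(10:50, 1), replace = TRUE),
            collapse = ""), character(1)), paste0("s", seq_len(n)))
    f <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(seqs, f)
    back <- readFasta(f)
    expect_equal(setNames(as.character(back), names(back)), seqs)
  }
})

test_that("Newick parsing, supports, and lossless round trips", {
  tr <- parseNewick("((A:0.1,B:0.2):0.3,C:0.4);")
  expect_equal(length(tr$tip.label), 3)
  expect_equal(nrow(tr$edge), 4)

  trs <- parseNewick("((A,B)95:0.3,C);")
  expect_true("95" %in% trs$node.label)

  expect_error(parseNewick("((A,B):0.3,C));"), "unbalanced.*character 14")
  expect_error(parseNewick("((A:-0.1,B):0.3,C);"), "negative.*character 4")

  set.seed(7)
  for (i in 1:5) {
    tr <- ape::rtree(sample(4:10, 1))
    tr$edge.length <- round(runif(nrow(tr$edge), 0.001, 2), 6)
    back <- parseNewick(writeNewick(tr))
    expect_equal(sort(back$tip.label), sort(tr$tip.label))
    # identical bipartition sets and branch lengths via patristic matrices
    expect_equal(ape::cophenetic.phylo(back)[tr$tip.label, tr$tip.label],
                 ape::cophenetic.phylo(tr), tolerance = 1e-9)
    again <- parseNewick(writeNewick(back))
    expect_equal(writeNewick(again), writeNewick(back))
  }
})

test_that("concatenation is length-additive, gap-fills, and records blocks", {
  a1 <- seqAlignment(c(x1 = strrep("A", 100), x2 = strrep("C", 100),
                       x3 = strrep("G", 100), x4 = strrep("T", 100)),
                     taxon = c("t1", "t2", "t3", "t4"))
  a2 <- seqAlignment(c(y1 = strrep("A", 50), y2 = strrep("C", 50),
                       y3 = strrep("G", 50), y4 = strrep("T", 50)),
                     taxon = c("t1", "t2", "t3", "t4"))
  cc <- concatenateAlignments(list(g1 = a1, g2 = a2))
  expect_equal(alignmentLength(cc$alignment), 150)
  expect_equal(length(alignedSeqs(cc$alignment)), 4)
  expect_equal(cc$partitions$start, c(1L, 101L))
  expect_equal(cc$partitions$end, c(100L, 150L))

  # a taxon missing from one gene gets a gap block there
  a3 <- seqAlignment(c(z1 = "ACGT", z5 = "AGGT"), taxon = c("t1", "t5"))
  cc2 <- concatenateAlignments(list(g1 = a1, g3 = a3))
  s5 <- alignedSeqs(cc2$alignment)[["t5"]]
  expect_equal(substr(s5, 1, 100), strrep("-", 100))
  expect_equal(substr(s5, 101, 104), "AGGT")

  expect_error(concatenateAlignments(list()), "no alignments")
  dup <- seqAlignment(c(d1 = "AC", d2 = "AC"), taxon = c("t1", "t1"))
  expect_error(concatenateAlignments(list(g = dup)), "duplicate taxon 't1'")
})

test_that("a 28-block concatenation of the published total length checks out", {
  lens <- c(rep(1637L, 27), 1629L)
  expect_equal(sum(lens), 45828L)
  taxa <- paste0("t", 1:4)
  blocks <- lapply(seq_along(lens), function(i) {
    seqAlignment(setNames(rep(strrep("A", lens[i]), 4), paste0("s", 1:4, "_", i)),
                 taxon = taxa)
  })
  names(blocks) <- sprintf("g%02d", seq_along(blocks))
  cc <- concatenateAlignments(blocks)
  expect_equal(alignmentLength(cc$alignment), 45828L)
  expect_equal(nrow(cc$partitions), 28L)
  f <- withr::local_tempfile(fileext = ".txt")
  writePartitionFile(cc$partitions, f)
  lines <- readLines(f)
  expect_equal(lines[1], "g01 = 1-1637")
  expect_equal(lines[28], sprintf("g28 = %d-45828", 45828 - 1629 + 1))
})

test_that("concatenation is invariant to gene order up to block permutation", {
  set.seed(3)
  alns <- lapply(1:4, function(i) {
    taxa <- sample(paste0("t", 1:6), sample(3:6, 1))
    L <- sample(10:30, 1)
    seqAlignment(setNames(vapply(taxa, function(tx)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1)), paste0("s", seq_along(taxa), "_", i)), taxon = taxa)
  })
  names(alns) <- paste0("g", 1:4)
  cc1 <- concatenateAlignments(alns)
  cc2 <- concatenateAlignments(rev(alns))
  expect_setequal(names(alignedSeqs(cc1$alignment)),
                  names(alignedSeqs(cc2$alignment)))
  # per-gene blocks agree regardless of input order
  for (g in names(alns)) {
    p1 <- cc1$partitions[cc1$partitions$gene == g, ]
    p2 <- cc2$partitions[cc2$partitions$gene == g, ]
    for (tx in names(alignedSeqs(cc1$alignment))) {
      expect_equal(substr(alignedSeqs(cc1$alignment)[[tx]], p1$start, p1$end),
                   substr(alignedSeqs(cc2$alignment)[[tx]], p2$start, p2$end))
    }
  }
  tax_union <- sort(unique(unlist(lapply(alns, function(a) a@taxon))))
  expect_equal(sort(names(alignedSeqs(cc1$alignment))), tax_union)
})

test_that("survey TSV round-trips and rejects malformed tables", {
  tab <- data.frame(genus = "Gambierdiscus", species = c("sp1", "sp1", "sp2"),
                    is_described = c(TRUE, TRUE, FALSE),
                    region = c("ITS", "SSU", "ITS"),
                    call = c("Y/N", "Y", "YP"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeSurveyTable(tab, f)
  back <- readSurveyTable(f)
  expect_equal(back$call, tab$call)
  expect_equal(back$is_described, tab$is_described)

  bad <- tab; bad$call[1] <- "Q"
  expect_error(validateSurveyTable(bad), "invalid call")
  bad2 <- tab; bad2$region[2] <- "ITS"
  expect_error(validateSurveyTable(bad2), "duplicate")
  bad3 <- tab; bad3$region[2] <- "LSU"
  expect_error(validateSurveyTable(bad3), "unknown region")
})
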