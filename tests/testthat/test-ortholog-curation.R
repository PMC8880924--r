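fake_family <- function(ids, taxa, tree = NULL, seqs = NULL) {
  if (is.null(seqs)) seqs <- setNames(rep("ACGT", length(ids)), ids)
  else names(seqs) <- ids
  geneFamily("g", seqs, taxa, tree = tree)
}

dm_from <- function(d) new("DistanceMatrix", d = d,
                           saturated = matrix(FALSE, nrow(d), ncol(d)))

test_that("mean-distance rule eliminates the divergent member once", {
  ids <- paste0("s", 1:10)
  d <- matrix(0.05, 10, 10, dimnames = list(ids, ids))
  d[10, ] <- d[, 10] <- 0.6
  diag(d) <- 0
  fam <- fake_family(ids, paste0("t", 1:10))
  grand <- mean(d[upper.tri(d)])
  expect_equal(grand, (36 * 0.05 + 9 * 0.6) / 45)
  out <- meanDistanceOutlierFilter(fam, dm_from(d), curationConfig())
  expect_equal(familyMembers(out), ids[1:9])
  log <- attr(out, "eliminated")
  expect_equal(log$member, "s10")
  expect_equal(log$value, 0.6)
  expect_equal(log$threshold, 2 * grand)
  # idempotent on its own output
  d9 <- d[1:9, 1:9]
  out2 <- meanDistanceOutlierFilter(out, dm_from(d9), curationConfig())
  expect_equal(familyMembers(out2), familyMembers(out))

  # all-equal distances: nothing to eliminate
  dEq <- matrix(0.1, 10, 10, dimnames = list(ids, ids)); diag(dEq) <- 0
  outEq <- meanDistanceOutlierFilter(fam, dm_from(dEq), curationConfig())
  expect_equal(familyMembers(outEq), ids)

  # degenerate input: unchanged with a warning
  fam2 <- fake_family(c("a", "b"), c("t1", "t2"))
  d2 <- matrix(c(0, .1, .1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(out2 <- meanDistanceOutlierFilter(fam2, dm_from(d2)),
                 "fewer than 3")
  expect_equal(familyMembers(out2), c("a", "b"))
})

test_that("paralog groups are the maximal single-copy clades", {
  tr <- parseNewick("((A1:1,B1:1):1,(A2:1,B2:1):1);")
  fam <- fake_family(c("A1", "B1", "A2", "B2"), c("A", "B", "A", "B"), tree = tr)
  groups <- partitionParalogGroups(fam)
  expect_equal(length(groups), 2)
  expect_setequal(vapply(groups, paste, character(1), collapse = ","),
                  c("A1,B1", "A2,B2"))

  single <- fake_family(c("A1", "B1", "C1"), c("A", "B", "C"),
                        tree = parseNewick("((A1:1,B1:1):1,C1:1);"))
  expect_equal(partitionParalogGroups(single), list(c("A1", "B1", "C1")))

  expect_error(partitionParalogGroups(fake_family("A1", "A")), "no tree")

  # brute-force check on duplicated 3-taxon families
  tr3 <- parseNewick("(((A1:1,B1:1):1,C1:1):2,((A2:1,B2:1):1,C2:1):2);")
  taxa <- setNames(c("A", "B", "C", "A", "B", "C"),
                   c("A1", "B1", "C1", "A2", "B2", "C2"))
  fam3 <- fake_family(names(taxa), unname(taxa), tree = tr3)
  groups3 <- partitionParalogGroups(fam3)
  expect_equal(length(groups3), 2)
  oracle <- oracle_paralog_groups(tr3, taxa)
  for (g in groups3)
    expect_true(any(vapply(oracle, function(o) setequal(o, g), logical(1))))
  expect_setequal(unlist(groups3), names(taxa))
})

test_that("ortholog-group selection ranks by coverage then tightness", {
  ids <- c("A1", "B1", "C1", "A2", "B2", "C2")
  taxa <- c("A", "B", "C", "A", "B", "C")
  fam <- fake_family(ids, taxa)
  d <- matrix(0.5, 6, 6, dimnames = list(ids, ids)); diag(d) <- 0
  d[1:3, 1:3] <- 0.10; d[4:6, 4:6] <- 0.30; diag(d) <- 0
  cfg <- curationConfig(ingroup = c("A", "B", "C"))
  pick <- selectOrthologGroup(fam, list(ids[1:3], ids[4:6]), dm_from(d), cfg)
  expect_equal(pick, ids[1:3])   # equal coverage, lower within-distance

  pick2 <- selectOrthologGroup(fam, list(ids[c(1, 2)], ids[4:6]), dm_from(d), cfg)
  expect_equal(pick2, ids[4:6])  # more complete wins despite higher distance

  # no group reaches the coverage floor
  none <- selectOrthologGroup(fam, list(ids[1], ids[4]), dm_from(d),
                              curationConfig(ingroup = c("A", "B", "C", "D", "E")))
  expect_null(none)
  expect_error(selectOrthologGroup(fam, list(), dm_from(d), cfg), "empty")
})

test_that("gene-tree QC rejects by diameter and by broken monophyly", {
  cfg <- curationConfig(ingroup = "A", outgroup = "B")
  good <- parseNewick("((A1:0.1,A2:0.1):0.2,(B1:0.1,B2:0.1):0.2);")
  famG <- fake_family(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"),
                      tree = good)
  expect_true(qcGeneTree(famG, cfg)$accept)

  wide <- parseNewick("((A1:0.65,A2:0.65):0.2,(B1:0.1,B2:0.1):0.2);")
  famW <- fake_family(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"),
                      tree = wide)
  res <- qcGeneTree(famW, cfg)
  expect_false(res$accept)
  expect_equal(res$reasons, "diameter")

  mixed <- parseNewick("((A1:0.1,B1:0.1):0.2,(A2:0.1,B2:0.1):0.2);")
  famM <- fake_family(c("A1", "B1", "A2", "B2"), c("A", "B", "A", "B"),
                      tree = mixed)
  res2 <- qcGeneTree(famM, cfg)
  expect_false(res2$accept)
  expect_equal(res2$reasons, "monophyly")

  both <- parseNewick("((A1:0.7,B1:0.7):0.2,(A2:0.1,B2:0.1):0.2);")
  famB <- fake_family(c("A1", "B1", "A2", "B2"), c("A", "B", "A", "B"),
                      tree = both)
  expect_setequal(qcGeneTree(famB, cfg)$reasons, c("diameter", "monophyly"))

  expect_error(qcGeneTree(famG, curationConfig(ingroup = "A", outgroup = "Z")),
               "absent")
})

test_that("identity-gap rule eliminates a clearly divergent member only", {
  mk <- function(p_diff, base, seed) {
    set.seed(seed)
    ch <- strsplit(base, "")[[1]]
    idx <- sample(length(ch), round(p_diff * length(ch)))
    for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste(ch, collapse = "")
  }
  set.seed(2)
  base <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  seqs <- c(s1 = base, s2 = mk(0.04, base, 3), s3 = mk(0.05, base, 4),
            s4 = mk(0.55, base, 5))
  fam <- geneFamily("g", seqs, paste0("t", 1:4),
                    alignment = seqAlignment(seqs, paste0("t", 1:4)))
  # independent arithmetic oracle for the member averages
  pid <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    100 * mean(x == y)
  }
  avg <- vapply(names(seqs), function(i)
    mean(vapply(setdiff(names(seqs), i), function(j)
      pid(seqs[[i]], seqs[[j]]), numeric(1))), numeric(1))
  o <- sort(avg)
  expect_gte(o[2] - o[1], 20)    # the divergent member sits >= 20 pts below
  out <- identityGapFilter(fam, config = curationConfig())
  expect_equal(familyMembers(out), c("s1", "s2", "s3"))
  expect_equal(attr(out, "eliminated")$member, "s4")

  # small gap: nothing eliminated
  seqs2 <- c(s1 = base, s2 = mk(0.04, base, 6), s3 = mk(0.15, base, 7))
  fam2 <- geneFamily("g", seqs2, paste0("t", 1:3),
                     alignment = seqAlignment(seqs2, paste0("t", 1:3)))
  out2 <- identityGapFilter(fam2, config = curationConfig())
  expect_equal(familyMembers(out2), names(seqs2))

  # identical sequences: nothing eliminated
  same <- setNames(rep(base, 3), c("a", "b", "c"))
  fam3 <- geneFamily("g", same, paste0("t", 1:3),
                     alignment = seqAlignment(same, paste0("t", 1:3)))
  expect_equal(familyMembers(identityGapFilter(fam3, config = curationConfig())),
               c("a", "b", "c"))
})

test_that("monophyletic duplicates resolve to the longest sequence", {
  tr <- parseNewick("((A1:0.01,A2:0.01):0.2,(B1:0.1,C1:0.1):0.05);")
  seqs <- c(A1 = strrep("A", 900), A2 = strrep("A", 700),
            B1 = strrep("C", 500), C1 = strrep("G", 500))
  fam <- geneFamily("g", seqs, c("A", "A", "B", "C"), tree = tr)
  out <- resolveMonophyleticDuplicates(fam)
  expect_setequal(familyMembers(out), c("A1", "B1", "C1"))
  expect_equal(attr(out, "eliminated")$member, "A2")

  # non-monophyletic duplicates are left for group partitioning
  tr2 <- parseNewick("((A1:0.1,B1:0.1):0.2,(A2:0.1,C1:0.1):0.05);")
  fam2 <- geneFamily("g", seqs[c(1, 3, 2, 4)] , c("A", "B", "A", "C"),
                     tree = tr2)
  names(fam2@seqs) <- c("A1", "B1", "A2", "C1")
  out2 <- resolveMonophyleticDuplicates(fam2)
  expect_setequal(familyMembers(out2), c("A1", "B1", "A2", "C1"))

  # equal lengths: lexicographically first id kept
  tr3 <- parseNewick("((A1:0.01,A2:0.01):0.2,B1:0.2);")
  seqs3 <- c(A1 = strrep("A", 500), A2 = strrep("A", 500), B1 = strrep("C", 500))
  fam3 <- geneFamily("g", seqs3, c("A", "A", "B"), tree = tr3)
  expect_setequal(familyMembers(resolveMonophyleticDuplicates(fam3)),
                  c("A1", "B1"))
})

test_that("the curation pipeline logs eliminations and keeps counters monotone", {
  p <- default_bench_params()
  tr <- simulateSpeciesTree(5, 2, depth = 0.15, seed = 2)
  bench <- simulateTranscriptomeLibrary(tr, n_genes = 6, n_noise = 2,
                                        params = p, seed = 5)
  cc <- curationConfig(ingroup = grep("^in", tr$tip.label, value = TRUE),
                       outgroup = grep("^out", tr$tip.label, value = TRUE))
  rep <- runCuration(bench$libraries, bench$reference, screenConfig(), cc,
                     params = p, n_boot = 10, seed = 1)
  sc <- stageCounts(rep)
  expect_equal(names(sc), c("candidates", "hit_rule", "group_selection",
                            "tree_qc"))
  expect_true(all(diff(sc) <= 0))
  expect_equal(unname(sc["candidates"]), 6L)
  if (rep@status == "ok") {
    expect_s4_class(rep@supermatrix, "SeqAlignment")
    expect_equal(nrow(rep@partitions), unname(sc["tree_qc"]))
    expect_false(is.null(rep@tree))
    # every elimination carries its rule and evidence
    if (nrow(rep@eliminations))
      expect_true(all(rep@eliminations$rule %in%
                        c("mean_distance", "identity_gap", "duplicate_length",
                          "paralog_group")))
  }
  expect_error(runCuration(list(), bench$reference), "empty contig")
})
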