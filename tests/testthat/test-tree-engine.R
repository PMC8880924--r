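test_that("pairwise distances match closed forms and flag saturation", {
  ident <- seqAlignment(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  for (m in c("p", "JC69", "GTR_ML")) {
    expect_equal(distances(pairwiseDistances(ident, m))["a", "b"], 0,
                 tolerance = 1e-8)
  }
  aln <- seqAlignment(c(a = "AAAAAAATTT", b = "AAAAAAAAAA"))
  expect_equal(distances(pairwiseDistances(aln, "p"))["a", "b"], 0.3)
  expect_equal(distances(pairwiseDistances(aln, "JC69"))["a", "b"],
               -0.75 * log(1 - 4 * 0.3 / 3), tolerance = 1e-9)
  prot <- seqAlignment(c(a = "AAAAAAAKKK", b = "AAAAAAAAAA"), mode = "protein")
  expect_equal(distances(pairwiseDistances(prot, "protein_corrected"))["a", "b"],
               -log(1 - 0.3 - 0.2 * 0.09), tolerance = 1e-9)

  sat <- seqAlignment(c(a = "AAAAACCCCC", b = "CCCCCGGGGG"))  # p = 1
  dm <- pairwiseDistances(sat, "JC69")
  expect_equal(distances(dm)["a", "b"], 5)
  expect_true(saturatedCells(dm)["a", "b"])

  gap <- seqAlignment(c(a = "AC--", b = "--GT", c = "ACGT"))
  expect_error(pairwiseDistances(gap, "JC69"), "'a' and 'b'.*no comparable")
})

test_that("GTR_ML pairwise distance recovers the generating divergence", {
  p <- default_bench_params()
  tr <- parseNewick("(A:0.15,B:0.15);")
  aln <- simulateGTRAlignment(tr, p, 20000, 11)
  d <- distances(pairwiseDistances(aln, "GTR_ML", p))["A", "B"]
  expect_equal(d, 0.3, tolerance = 0.05)
})

test_that("GTR_ML estimates converge to the true path length as L grows", {
  p <- default_bench_params()
  truths <- c(0.05, 0.15, 0.4, 0.8)
  for (L in c(500, 5000, 50000)) {
    est <- vapply(seq_along(truths), function(i) {
      tr <- parseNewick(sprintf("(A:%f,B:%f);", truths[i] / 2, truths[i] / 2))
      aln <- simulateGTRAlignment(tr, p, L, 100 + i)
      distances(pairwiseDistances(aln, "GTR_ML", p))["A", "B"]
    }, numeric(1))
    slope <- coef(lm(log(est) ~ log(truths)))[2]
    if (L == 50000) {
      expect_equal(unname(slope), 1, tolerance = 0.05)
      expect_equal(est, truths, tolerance = 0.05)
    }
  }
})

test_that("neighbor joining handles degenerate and additive inputs exactly", {
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  tr2 <- neighborJoining(d2)
  expect_equal(sum(tr2$edge.length), 0.4)

  d3 <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr3 <- neighborJoining(d3)
  pend <- setNames(tr3$edge.length[tr3$edge[, 2] <= 3],
                   tr3$tip.label[tr3$edge[tr3$edge[, 2] <= 3, 2]])
  expect_equal(pend[c("A", "B", "C")], c(A = 0.05, B = 0.15, C = 0.25))

  asym <- d3; asym[1, 2] <- 0.9
  expect_error(neighborJoining(asym), "symmetric")

  # additive matrices are inverted exactly: path metric of output = input
  for (s in 1:10) {
    tr <- random_additive_tree(6, s)
    D <- ape::cophenetic.phylo(tr)
    out <- neighborJoining(D)
    expect_equal(ape::cophenetic.phylo(out)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("JC distances behave like a metric on simulated data", {
  p <- gtrParams()
  tr <- random_additive_tree(5, 77)
  tr$edge.length <- tr$edge.length / 3
  aln <- simulateGTRAlignment(tr, p, 3000, 8)
  d <- distances(pairwiseDistances(aln, "JC69"))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
})

test_that("pruning log-likelihood matches closed forms", {
  jc <- gtrParams()
  aln <- seqAlignment(c(A = "A", B = "A"))
  d0 <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(felsensteinLoglik(neighborJoining(d0), aln, jc), log(0.25),
               tolerance = 1e-12)
  t <- -0.75 * log(0.6)
  dt <- matrix(c(0, t, t, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(felsensteinLoglik(neighborJoining(dt),
                                 seqAlignment(c(A = "A", B = "C")), jc),
               log(0.25 * 0.25 * (1 - exp(-4 * t / 3))), tolerance = 1e-10)
  expect_error(
    felsensteinLoglik(neighborJoining(dt), seqAlignment(c(A = "A", X = "C")), jc),
    "mismatch.*X")
})

test_that("pruning log-likelihood matches brute-force enumeration", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(3:5, 1)
    tr <- ape::rtree(n, tip.label = paste0("t", seq_len(n)))
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.7)
    f <- runif(4, 0.1, 0.4); f <- f / sum(f)
    p <- gtrParams(rates = runif(6, 0.3, 3), freqs = f,
                   gammaShape = if (i %% 2) NA else runif(1, 0.3, 2))
    aln <- simulateGTRAlignment(tr, p, sample(2:4, 1), 100 + i)
    expect_equal(felsensteinLoglik(tr, aln, p), oracle_loglik(tr, aln, p),
                 tolerance = 1e-10)
  }
})

test_that("pruning log-likelihood agrees with an independent implementation", {
  skip_if_not_installed("phangorn")
  p <- default_bench_params()
  tr <- random_additive_tree(7, 13)
  aln <- simulateGTRAlignment(tr, p, 400, 21)
  dat <- phangorn::phyDat(do.call(rbind, strsplit(alignedSeqs(aln), "")))
  fit <- phangorn::pml(tr, dat, bf = p@freqs, Q = p@rates / p@rates[6])
  expect_equal(felsensteinLoglik(tr, aln, p), fit$logLik, tolerance = 1e-6)
})

test_that("branch-length optimization reaches closed-form optima monotonely", {
  jc <- gtrParams()
  aln <- random_jc_pair(2000, 0.3, 31)
  p_obs <- distances(pairwiseDistances(aln, "p"))[1, 2]
  start <- neighborJoining(matrix(c(0, .05, .05, 0), 2,
                                  dimnames = list(c("a", "b"), c("a", "b"))))
  fit <- optimizeBranchLengths(start, aln, jc)
  expect_equal(sum(fit$edge.length), -0.75 * log(1 - 4 * p_obs / 3),
               tolerance = 1e-4)

  ident <- seqAlignment(c(a = strrep("ACGT", 25), b = strrep("ACGT", 25)))
  fit0 <- optimizeBranchLengths(start, ident, jc)
  expect_lt(sum(fit0$edge.length), 1e-5)

  # fixed point: re-optimizing from the optimum changes logL by < tol
  p <- default_bench_params()
  tr <- random_additive_tree(5, 3)
  sim <- simulateGTRAlignment(tr, p, 300, 5)
  f1 <- optimizeBranchLengths(tr, sim, p, tol = 1e-4)
  expect_gte(attr(f1, "loglik"), felsensteinLoglik(tr, sim, p))
  f2 <- optimizeBranchLengths(f1, sim, p, tol = 1e-4)
  expect_lt(abs(attr(f2, "loglik") - attr(f1, "loglik")), 1e-3)
})

test_that("bootstrap supports are reproducible percentages of replicates", {
  p <- gtrParams()
  tr <- random_additive_tree(6, 9)
  aln <- simulateGTRAlignment(tr, p, 800, 17)
  b1 <- bootstrapSupport(aln, "JC69", n_reps = 50, seed = 4)
  b2 <- bootstrapSupport(aln, "JC69", n_reps = 50, seed = 4)
  expect_identical(writeNewick(b1), writeNewick(b2))
  sup <- suppressWarnings(as.numeric(b1$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(all(abs(sup / 100 * 50 - round(sup / 100 * 50)) < 1e-9))

  # an alignment with overwhelming signal: every resample gives the tree
  strong <- simulateGTRAlignment(tr, p, 5000, 23)
  bs <- bootstrapSupport(strong, "JC69", n_reps = 500, seed = 6)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup == 100))
  expect_true(all(abs(sup / 100 * 500 - round(sup / 100 * 500)) < 1e-9))
})

test_that("GTR simulation honours its contracts", {
  p <- default_bench_params()
  star0 <- parseNewick("(A:0,B:0,C:0);")
  sim0 <- simulateGTRAlignment(star0, p, 50, 2)
  expect_equal(length(unique(alignedSeqs(sim0))), 1L)
  expect_equal(alignmentLength(sim0), 50L)

  # stationarity: leaf composition within 3 binomial SEs of base_freqs
  star <- parseNewick("(A:2,B:2,C:2,D:2);")
  L <- 50000
  sim <- simulateGTRAlignment(star, p, L, 3)
  for (s in alignedSeqs(sim)) {
    comp <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    for (k in 1:4) {
      se <- sqrt(p@freqs[k] * (1 - p@freqs[k]) / L)
      expect_lt(abs(comp[k] / L - p@freqs[k]), 3 * se + 1e-9)
    }
  }
  expect_identical(alignedSeqs(simulateGTRAlignment(star0, p, 30, 9)),
                   alignedSeqs(simulateGTRAlignment(star0, p, 30, 9)))
})

test_that("tree diameter is the maximal patristic leaf distance", {
  expect_equal(treeDiameter(parseNewick("((A:0.1,B:0.2):0.3,C:0.4);")), 0.9)
  expect_equal(treeDiameter(parseNewick("(A:0.25,B:0.15);")), 0.4)
  z <- parseNewick("((A:0,B:0):0,C:0);")
  expect_equal(treeDiameter(z), 0)
  bad <- parseNewick("((A,B):0.3,C);")
  expect_error(treeDiameter(bad), "missing branch length")
})
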