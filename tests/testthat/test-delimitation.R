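test_that("species-resolution calls follow the five-way definitions", {
  # species X: two leaves in a supported exclusive clade -> Y
  tr <- parseNewick("(((x1:0.01,x2:0.01)95:0.2,y1:0.2)90:0.1,(z1:0.05,z2:0.05)99:0.1);")
  spmap <- c(x1 = "X", x2 = "X", y1 = "Y_sp", z1 = "Z", z2 = "Z")
  calls <- classifySpeciesCalls(tr, spmap)
  bysp <- setNames(calls$call, calls$species)
  expect_equal(bysp[["X"]], "Y")
  expect_equal(bysp[["Z"]], "Y")
  expect_equal(bysp[["Y_sp"]], "YP")   # singleton on its own branch

  # exclusive but unsupported clade fails the support threshold
  tr2 <- parseNewick("(((x1:0.01,x2:0.01)55:0.2,y1:0.2)90:0.1,(z1:0.05,z2:0.05)99:0.1);")
  calls2 <- classifySpeciesCalls(tr2, spmap, support_threshold = 80)
  expect_equal(setNames(calls2$call, calls2$species)[["X"]], "N")

  # interleaved species -> both N
  tr3 <- parseNewick("(((a1:0.1,b1:0.1):0.1,(a2:0.1,b2:0.1):0.1):0.1,o1:0.3);")
  sp3 <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", o1 = "O")
  calls3 <- classifySpeciesCalls(tr3, sp3, outgroup = "o1")
  bysp3 <- setNames(calls3$call, calls3$species)
  expect_equal(bysp3[["A"]], "N")
  expect_equal(bysp3[["B"]], "N")

  # flags turn foreign leaves into YA / NA
  callsYA <- classifySpeciesCalls(tr3, sp3, flags = c(b1 = "misidentified",
                                                      b2 = "misidentified"),
                                  outgroup = "o1")
  expect_equal(setNames(callsYA$call, callsYA$species)[["A"]], "YA")
  callsNA <- classifySpeciesCalls(tr3, sp3, flags = c(b1 = "distinct",
                                                      b2 = "distinct"),
                                  outgroup = "o1")
  expect_equal(setNames(callsNA$call, callsNA$species)[["A"]], "NA")

  expect_error(classifySpeciesCalls(tr3, sp3[-1]), "unmapped leaf.*a1")
})

test_that("species with homogenized alleles always resolve on random trees", {
  p <- default_bench_params()
  for (s in 1:5) {
    tr <- simulateSpeciesTree(5, 1, depth = 0.15, seed = 100 + s)
    sim <- simulateRdnaAlleles(tr, rdnaSimConfig(3, 1, 0, 1, p, 500L),
                               seed = s)
    nj <- neighborJoining(pairwiseDistances(sim$alignment, "JC69"))
    calls <- classifySpeciesCalls(nj, sim$species_map,
                                  outgroup = grep("^out",
                                                  names(sim$species_map),
                                                  value = TRUE))
    expect_true(all(calls$call %in% c("Y", "YP")), info = paste("seed", s))
  }
})

test_that("compound calls combine, order and map to categories exactly", {
  expect_equal(combineCalls(c("Y", "Y")), "Y")
  expect_equal(combineCalls(c("N", "Y")), "Y/N")
  expect_equal(combineCalls(c("YA", "YP")), "YP/YA")
  expect_error(combineCalls(c("Y", "Q")), "unknown call")

  not_res <- c("N", "NA", "N/NA", "N/YA", "Y/N")
  for (x in not_res) expect_equal(mapToCategory(x), "not_resolved")
  for (x in c("YA", "Y/YA", "YP/YA")) expect_equal(mapToCategory(x), "ambiguous")
  for (x in c("Y", "YP")) expect_equal(mapToCategory(x), "resolved")
  # token order within the compound string does not matter
  expect_equal(mapToCategory("YA/N"), "not_resolved")
  expect_error(mapToCategory("YP/N"), "outside")
  expect_error(mapToCategory("Y/NA"), "outside")
})

test_that("survey summaries count by category with half-up percentages", {
  tab <- data.frame(genus = "G", species = "sp1", is_described = TRUE,
                    region = "ITS", call = "Y")
  s <- summarizeSurvey(tab)
  its <- s[s$region == "ITS", ]
  expect_equal(its$n_resolved, 1)
  expect_equal(its$pct_resolved, 100.0)
  ssu <- s[s$region == "SSU", ]
  expect_equal(ssu$n_resolved + ssu$n_ambiguous + ssu$n_not_resolved, 0)
  expect_true(is.na(ssu$pct_resolved))

  # percentages always total 100 after rounding (within one rounding step)
  set.seed(31)
  for (i in 1:5) {
    fx <- generateSurveyFixture(n_species = 150,
                                category_probs = c(0.2, 0.2, 0.6),
                                seed = 300 + i)
    s <- summarizeSurvey(fx$table)
    tot <- s$pct_not_resolved + s$pct_ambiguous + s$pct_resolved
    expect_true(all(abs(tot[!is.na(tot)] - 100) <= 0.1))
  }
})

test_that("region agreement counts dual-region outcomes and lists conflicts", {
  tab <- data.frame(
    genus = "G",
    species = c("s1", "s1", "s2", "s2", "s3"),
    is_described = TRUE,
    region = c("ITS", "LSU5prime", "ITS", "LSU5prime", "ITS"),
    call = c("Y", "Y", "Y", "N", "YP"))
  ag <- regionAgreement(tab, "ITS", "LSU5prime")
  expect_equal(ag$n_both, 2L)
  expect_equal(ag$n_agree, 1L)
  expect_equal(ag$n_disagree, 1L)
  expect_equal(ag$disagreements$species, "s2")
  expect_equal(ag$disagreements$call_b, "N")

  none <- regionAgreement(tab[tab$region == "ITS", ], "ITS", "LSU5prime")
  expect_equal(none$n_both, 0L)
  expect_error(regionAgreement(tab, "ITS", "ITS"), "must differ")
})

test_that("the species-description decision tree is total and correct", {
  expect_equal(recommendDescriptionCase("highly_divergent", "distinct")$case, "1a")
  expect_equal(recommendDescriptionCase("distinct_with_overlap", "distinct")$case, "1b")
  expect_equal(recommendDescriptionCase("highly_divergent", "identical")$case, "2")
  expect_equal(recommendDescriptionCase("distinct_with_overlap", "identical")$case, "2")
  expect_equal(recommendDescriptionCase("largely_overlapping", "distinct")$case, "3a")
  expect_equal(recommendDescriptionCase("indistinguishable", "distinct")$case, "3b")
  expect_equal(recommendDescriptionCase("conflicting", "distinct")$case, "4")
  expect_equal(recommendDescriptionCase("largely_overlapping", "conflicting")$case, "4")
  expect_equal(recommendDescriptionCase("indistinguishable", "identical")$case, "5")
  expect_equal(recommendDescriptionCase("largely_overlapping", "identical")$case, "5")
  # every combination yields a case with an action
  for (m in c("highly_divergent", "distinct_with_overlap", "largely_overlapping",
              "indistinguishable", "conflicting"))
    for (r in c("distinct", "identical", "conflicting")) {
      res <- recommendDescriptionCase(m, r)
      expect_true(res$case %in% c("1a", "1b", "2", "3a", "3b", "4", "5"))
      expect_gt(nchar(res$action), 20)
    }
})
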