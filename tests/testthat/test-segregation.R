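test_that("member_compatible encodes the recessive and de novo rules", {
  # recessive: parents heterozygous, index homozygous
  expect_true(member_compatible("HET", "parent", "recessive"))
  expect_false(member_compatible("HOM_ALT", "parent", "recessive"))
  expect_true(member_compatible("HOM_ALT", "index", "recessive"))
  # unaffected relatives may be carriers but not homozygous (nonshared rule)
  expect_true(member_compatible("HET", "unaffected_relative", "recessive"))
  expect_false(member_compatible("HOM_ALT", "unaffected_relative", "recessive"))
  # de novo: index carries, parents reference
  expect_true(member_compatible("HET", "index", "denovo"))
  expect_false(member_compatible("HET", "parent", "denovo"))
  expect_true(member_compatible("HET", "parent", "denovo", inherited_het = TRUE))
  # MISSING: non-informative for relatives, never for the index, strict kills
  expect_true(member_compatible("MISSING", "parent", "recessive"))
  expect_false(member_compatible("MISSING", "parent", "recessive", "strict"))
  expect_false(member_compatible("MISSING", "index", "recessive"))
})

test_that("exhaustive trio enumeration retains exactly the Mendelian patterns", {
  ped <- fix_ped()
  dos <- fix_enumeration(c("index", "father", "mother"))   # 27 assignments
  vt <- fix_vt(dos)
  rec <- segregation_filter(vt, ped, colnames(dos), model = "recessive")
  expect_equal(sum(rec$counts[, "total"]), 1L)
  expect_equal(dos[rec$retained, ], c(index = 2L, father = 1L, mother = 1L))
  dnv <- segregation_filter(vt, ped, colnames(dos), model = "denovo")
  expect_equal(sum(dnv$counts[, "total"]), 2L)
  expect_true(all(dos[dnv$retained, c("father", "mother")] == 0L))
  expect_setequal(dos[dnv$retained, "index"], c(1L, 2L))
  # agreement with the independent brute-force oracle
  expect_equal(rec$retained, oracle_filter(vt, ped, colnames(dos), "recessive"))
  expect_equal(dnv$retained, oracle_filter(vt, ped, colnames(dos), "denovo"))
})

test_that("exhaustive sibship enumeration (3 affected, 2 unaffected) retains 4 of 243", {
  ped <- fix_ped(c("affected", "affected", "unaffected", "unaffected"))
  sibs <- c("index", paste0("sib", 1:4))
  dos <- fix_enumeration(sibs)                             # 243 assignments
  vt <- fix_vt(dos)
  rec <- segregation_filter(vt, ped, sibs, model = "recessive")
  expect_equal(length(rec$retained), 4L)
  kept <- dos[rec$retained, , drop = FALSE]
  expect_true(all(kept[, c("index", "sib1", "sib2")] == 2L))
  expect_true(all(kept[, c("sib3", "sib4")] %in% 0:1))
  # agrees with the independent oracle; sibship_filter unites the de novo
  # (shared-het) stratum on top of the recessive one
  expect_equal(rec$retained, oracle_filter(vt, ped, sibs, "recessive"))
  cs <- sibship_filter(vt, ped)
  expect_true(all(rec$retained %in% cs$retained))
  # all five homozygous -> excluded by the nonshared constraint
  all_hom <- which(apply(dos == 2L, 1, all))
  expect_false(all_hom %in% rec$retained)
})

test_that("index-only testing keeps every pass-filter site with a determinate carrier genotype", {
  ped <- fix_ped()
  dos <- cbind(index = c(0L, 1L, 2L, NA), father = 0L, mother = 0L)
  vt <- fix_vt(dos)
  rec <- segregation_filter(vt, ped, "index", model = "recessive")
  expect_equal(rec$retained, 3L)
  both <- segregation_filter(vt, ped, "index", model = "both")
  expect_equal(both$retained, c(2L, 3L))
})

test_that("segregation_filter matches the brute-force oracle on random small cohorts", {
  for (seed in 1:3) {
    sim <- simulate_cohort(sim_config(template = "quintet", seed = seed,
                                      n_population_sites = 500L,
                                      n_family_sites = 100L))
    tested <- sim$tested
    for (model in c("recessive", "denovo", "both")) {
      cs <- segregation_filter(sim$vt, sim$ped, tested, model = model)
      expect_equal(cs$retained,
                   oracle_filter(sim$vt, sim$ped, tested, model),
                   info = paste("seed", seed, model))
    }
  }
})

test_that("the both model is the union of recessive and de novo candidates", {
  sim <- simulate_cohort(sim_config(template = "quintet", seed = 4,
                                    n_population_sites = 800L,
                                    n_family_sites = 100L))
  args <- list(sim$vt, sim$ped, sim$tested)
  rec <- do.call(segregation_filter, c(args, model = "recessive"))
  dnv <- do.call(segregation_filter, c(args, model = "denovo"))
  both <- do.call(segregation_filter, c(args, model = "both"))
  expect_setequal(both$retained, union(rec$retained, dnv$retained))
  # on complete genotypes the two sets are disjoint strata
  ped <- fix_ped()
  dos <- fix_enumeration(c("index", "father", "mother"))
  vt <- fix_vt(dos)
  r <- segregation_filter(vt, ped, colnames(dos), model = "recessive")$retained
  d <- segregation_filter(vt, ped, colnames(dos), model = "denovo")$retained
  expect_length(intersect(r, d), 0)
})

test_that("trio_filter applies the parental-carrier rule and needs both parents", {
  ped <- fix_ped()
  dos <- rbind(c(2L, 1L, 1L),   # the classic pattern: retained, hom stratum
               c(2L, 2L, 1L),   # father homozygous: rejected
               c(1L, 0L, 0L))   # de novo: retained, het stratum
  colnames(dos) <- c("index", "father", "mother")
  vt <- fix_vt(dos, af = 0.001, dp = 30L)
  cs <- trio_filter(vt, ped)
  expect_setequal(cs$retained, c(1L, 3L))
  expect_equal(cs$keys$index_zygosity[cs$keys$pos == 100], "HOM_ALT")
  expect_equal(cs$keys$index_zygosity[cs$keys$pos == 300], "HET")
  # missing parent
  m <- ped$members; m$father[m$id == "index"] <- NA
  ped2 <- pedigree("F1", m, "index")
  expect_error(trio_filter(vt, ped2), "both parents")
})

test_that("sibship_filter ignores parents and requires a sibling", {
  ped <- fix_ped(c("affected", "unaffected"))
  # parents homozygous-alt would fail the trio rule; sibship must not care
  dos <- cbind(index = 2L, father = 2L, mother = 2L, sib1 = 2L, sib2 = 0L)
  vt <- fix_vt(dos)
  cs <- sibship_filter(vt, ped)
  expect_equal(cs$retained, 1L)
  expect_error(sibship_filter(vt, fix_ped()), "sibling")
})

test_that("MISSING relatives drop constraints under the permissive policy only", {
  ped <- fix_ped(c("affected"))
  dos <- cbind(index = 2L, father = 1L, mother = 1L, sib1 = NA_integer_)
  vt <- fix_vt(dos)
  tested <- colnames(dos)
  perm <- segregation_filter(vt, ped, tested, model = "recessive")
  expect_equal(perm$retained, 1L)
  strict <- segregation_filter(vt, ped, tested, model = "recessive",
                               missing_policy = "strict")
  expect_length(strict$retained, 0)
  # depth failure downgrades a call to MISSING with the same behaviour
  dos2 <- cbind(index = 2L, father = 1L, mother = 1L, sib1 = 0L)
  vt2 <- fix_vt(dos2, dp = matrix(c(30L, 30L, 30L, 5L), 1))
  expect_equal(segregation_filter(vt2, ped, tested, model = "recessive")$retained, 1L)
  expect_length(segregation_filter(vt2, ped, tested, model = "recessive",
                                   missing_policy = "strict")$retained, 0)
})

test_that("incremental reduction is nested and matches per-variant evaluation", {
  ped <- fix_ped(c("affected", "unaffected", "unaffected", "affected",
                   "unaffected"))
  # 12 hand-built variants over the octet
  dos <- rbind(
    c(2, 1, 1, 2, 1, 0, 2, 1),   # causal-like: survives everything
    c(2, 1, 1, 2, 1, 0, 2, 2),   # unaffected sib5 homozygous: dies at step 8
    c(2, 1, 1, 0, 0, 0, 0, 0),   # affected sib1 not hom: dies at step 4
    c(2, 2, 1, 2, 0, 0, 2, 0),   # father hom: dies at trio
    c(2, 1, 1, 2, 2, 2, 2, 2),   # unaffected sibs hom: dies at step 5
    c(1, 0, 0, 1, 0, 0, 1, 0),   # de novo shared by affecteds: survives
    c(1, 0, 0, 0, 0, 0, 0, 0),   # de novo not in affected sib1: dies at 4
    c(1, 1, 0, 1, 0, 0, 1, 0),   # father carries: no de novo, no recessive
    c(0, 1, 1, 2, 1, 0, 2, 1),   # index hom-ref: never a candidate
    c(2, 1, 1, 2, 1, 1, 2, 1),   # like 1 with carrier sibs: survives
    c(1, 0, 0, 1, 0, 0, 2, 0),   # affected sib4 hom, index het: survives (denovo needs carrier)
    c(2, 1, 1, 2, 0, 0, 2, 1))   # survives: unaffecteds clear
  storage.mode(dos) <- "integer"
  colnames(dos) <- c("index", "father", "mother", paste0("sib", 1:5))
  vt <- fix_vt(dos, csq = rep(c("missense_variant", "intron_variant"), 6))
  plan <- addition_order(ped)
  curve <- incremental_reduction(vt, ped, plan)
  # per-step counts equal the brute-force truth table
  for (k in seq_len(nrow(plan))) {
    keep <- oracle_filter(vt, ped, plan$id[seq_len(k)], "both")
    expect_equal(curve$total[k], length(keep), info = paste("step", k))
  }
  # monotone in every stratum
  for (cc in c("coding_hom", "coding_het", "noncoding_hom", "noncoding_het",
               "total"))
    expect_true(all(diff(curve[[cc]]) <= 0), info = cc)
  # nested key sets
  keys <- attr(curve, "keys")
  for (k in 2:length(keys))
    expect_true(all(keys[[k]]$pos %in% keys[[k - 1]]$pos))
})

test_that("a single-step curve has no drops and percentages follow the definition", {
  ped <- fix_ped()
  dos <- cbind(index = c(2L, 1L), father = c(1L, 0L), mother = c(1L, 0L))
  vt <- fix_vt(dos)
  plan <- addition_order(ped, "index")
  curve <- incremental_reduction(vt, ped, plan)
  expect_equal(nrow(curve), 1L)
  expect_equal(curve$pct_drop, 0)
  expect_error(reduction_percentages(curve), "2 steps")

  fake <- data.frame(total = c(100, 40, 30))
  expect_equal(reduction_percentages(fake), c(60, 25))
  expect_equal(reduction_percentages(data.frame(total = c(5, 5))), 0)
  expect_equal(reduction_percentages(data.frame(total = c(7, 0, 0))), c(100, 0))
})

test_that("trio vs sibship comparison reflects the constructed asymmetry", {
  ped <- fix_ped(c("unaffected", "unaffected"))
  # index hom, parents het, but one unaffected sib is also hom:
  # the trio rule keeps it, the sibship rule excludes it
  dos <- cbind(index = 2L, father = 1L, mother = 1L, sib1 = 2L, sib2 = 1L)
  vt <- fix_vt(dos)
  cmp <- compare_trio_vs_sibship(vt, ped)
  expect_equal(cmp$trio_candidate_count, 1L)
  expect_equal(cmp$sibship_candidate_count, 0L)
  expect_equal(cmp$shared_among_affected_sibs, 1L)   # the index alone
  expect_equal(cmp$shared_among_unaffected_sibs, 0L)
  # empty records give all-zero counts
  vt0 <- fix_vt(matrix(0L, 0, 5,
                       dimnames = list(NULL, colnames(dos))))
  cmp0 <- compare_trio_vs_sibship(vt0, ped)
  expect_equal(cmp0$trio_candidate_count, 0L)
  expect_equal(cmp0$sibship_candidate_count, 0L)
  # structure requirements
  expect_error(compare_trio_vs_sibship(vt, fix_ped("affected")),
               "two siblings")
})

test_that("comparison counts equal brute-force evaluation on a simulated quintet", {
  sim <- simulate_cohort(sim_config(template = "quintet", seed = 5,
                                    n_population_sites = 600L,
                                    n_family_sites = 150L))
  cmp <- compare_trio_vs_sibship(sim$vt, sim$ped)
  coding <- classify_region(sim$vt$sites$csq)
  trio_keep <- oracle_filter(sim$vt, sim$ped,
                             c("index", "father", "mother"), "recessive")
  sib_keep <- oracle_filter(sim$vt, sim$ped,
                            c("index", "sib1", "sib2"), "recessive")
  expect_equal(cmp$trio_candidate_count, sum(coding[trio_keep] == "coding"))
  expect_equal(cmp$sibship_candidate_count, sum(coding[sib_keep] == "coding"))
})

test_that("mitochondrial records are excluded from segregation", {
  ped <- fix_ped()
  dos <- cbind(index = c(2L, 2L), father = 1L, mother = 1L)
  vt <- fix_vt(dos, chrom = c("chrM", "chr1"))
  cs <- segregation_filter(vt, ped, colnames(dos), model = "recessive")
  expect_equal(cs$retained, 2L)
})
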