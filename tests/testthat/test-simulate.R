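small_cfg <- function(...) {
  sim_config(n_population_sites = 400L, n_family_sites = 80L, ...)
}

test_that("templates have the expected tested and ancestor structure", {
  ped <- build_template(sim_config())
  expect_equal(length(attr(ped, "tested")), 8L)
  expect_equal(nrow(ped$members), 14L)               # 8 tested + 6 ancestors
  ped5 <- build_template(sim_config(template = "quintet"))
  expect_setequal(attr(ped5, "tested"),
                  c("index", "father", "mother", "sib1", "sib2"))
  # father and mother are first cousins: they share great-grandparents
  m <- ped$members
  pgf <- m[m$id == m$father[m$id == "father"], ]
  mgm <- m[m$id == m$mother[m$id == "mother"], ]
  expect_equal(pgf$father, mgm$father)
  expect_equal(pgf$mother, mgm$mother)
  expect_error(build_template(sim_config(n_affected_sibs = 4,
                                         n_unaffected_sibs = 4)),
               "capacity")
  # octet sibling affections follow the fixed addition pattern
  sibs <- m[grepl("^sib", m$id), ]
  expect_equal(sibs$affection,
               c("affected", "unaffected", "unaffected", "affected",
                 "unaffected"))
})

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_cohort(small_cfg(seed = 3))
  b <- simulate_cohort(small_cfg(seed = 3))
  expect_identical(a$vt, b$vt)
  fa <- tmp_file(""); fb <- tmp_file("")
  emit(a, fa); emit(b, fb)
  expect_identical(readLines(paste0(fa, ".vcf")), readLines(paste0(fb, ".vcf")))
  expect_identical(readLines(paste0(fa, ".ped")), readLines(paste0(fb, ".ped")))
  c2 <- simulate_cohort(small_cfg(seed = 4))
  expect_false(identical(a$vt$gt, c2$vt$gt))
})

test_that("transmission is Mendelian when error and de novo are disabled", {
  sim <- simulate_genotypes(small_cfg(seed = 5, genotype_error_rate = 0,
                                      de_novo_count_mean = 0, causal = FALSE))
  expect_equal(mendelian_violations(sim$vt, sim$ped), 0L)
  # with genotyping error the same check reports violations
  sim_err <- simulate_genotypes(small_cfg(seed = 5, genotype_error_rate = 0.05,
                                          de_novo_count_mean = 0,
                                          causal = FALSE))
  expect_gt(mendelian_violations(sim_err$vt, sim_err$ped), 0L)
})

test_that("founder genotypes follow Hardy-Weinberg at the configured spectrum", {
  sim <- simulate_genotypes(sim_config(seed = 11, genotype_error_rate = 0,
                                       de_novo_count_mean = 0, causal = FALSE))
  popA <- !sim$is_x & !sim$is_family
  af <- sim$vt$sites$af[popA]
  hom <- mean(sim$vt$gt[popA, sim$founders] == 2L)
  expected <- mean(af^2)
  ndraw <- 4 * sum(popA)
  se <- sqrt(sum(af^2 * (1 - af^2)) * 4) / ndraw
  expect_lt(abs(hom - expected), 3 * se)
  # founder alt-allele frequency matches the spectrum mean
  carrier <- sim$vt$gt[popA, sim$founders]
  afreq <- mean(carrier) / 2
  se_a <- sqrt(sum(2 * af * (1 - af)) * 4) / (2 * ndraw)
  expect_lt(abs(afreq - mean(af)), 3 * se_a)
})

test_that("offspring autozygosity is near 1/16, as for first-cousin matings", {
  sim <- simulate_genotypes(sim_config(seed = 12, genotype_error_rate = 0,
                                       de_novo_count_mean = 0, causal = FALSE))
  n_auto <- sum(!sim$is_x)
  se <- sqrt((1 / 16) * (15 / 16) / n_auto)
  for (id in c("index", "sib1"))
    expect_lt(abs(sim$autozygosity[[id]] - 1 / 16), 3 * se)
})

test_that("the planted causal variant has the exact segregating pattern", {
  sim <- simulate_cohort(small_cfg(seed = 6))
  row <- sim$causal$row
  expect_equal(sim$vt$sites$csq[row], "missense_variant")
  expect_lt(sim$vt$sites$af[row], 0.015)
  expect_true(all(sim$vt$dp[row, ] >= 20L))
  g <- sim$vt$gt[row, ]
  expect_equal(unname(g[c("index", "sib1", "sib4")]), c(2L, 2L, 2L))
  expect_equal(unname(g[c("father", "mother")]), c(1L, 1L))
  expect_true(all(g[c("sib2", "sib3", "sib5")] < 2L))
  # carrier chain through one great-grandparent
  expect_equal(unname(g["ggf"]), 1L)
  expect_equal(unname(g["ggm"]), 0L)
})

test_that("x_fraction 0 yields no X records; males are hemizygous on X", {
  sim <- simulate_cohort(small_cfg(seed = 7, x_fraction = 0))
  expect_false(any(sim$vt$sites$chrom == "chrX"))
  sim_x <- simulate_genotypes(small_cfg(seed = 8, x_fraction = 0.5,
                                        causal = FALSE))
  xr <- sim_x$vt$sites$chrom == "chrX"
  expect_true(any(xr))
  expect_true(all(sim_x$vt$ploidy[xr, "father"] == 1L))
  expect_true(all(sim_x$vt$ploidy[xr, "mother"] == 2L))
  expect_true(all(sim_x$vt$gt[xr, "father"] <= 1L))
})

test_that("emit writes tested-only files that read back consistently", {
  sim <- simulate_cohort(small_cfg(seed = 9))
  prefix <- tmp_file("")
  paths <- emit(sim, prefix)
  vt <- read_vcf(paths[["vcf"]])
  expect_equal(vt_samples(vt), sim$tested)
  ped <- read_ped(paths[["ped"]])
  expect_equal(ped$index_id, "index")
  expect_setequal(ped$members$id, sim$tested)
  # parents of the parents are blanked since ancestors are not written
  expect_true(all(is.na(ped$members$father[ped$members$id == "father"])))
  # ancestors included on request
  paths2 <- emit(sim, tmp_file(""), include_ancestors = TRUE)
  vt2 <- read_vcf(paths2[["vcf"]])
  expect_equal(ncol(vt2$gt), 14L)
})
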