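#' Simulation configuration
#'
#' Parameters of the synthetic consanguineous-cohort generator. Defaults
#' emulate a clinical WES cohort: 100,000 rare population sites with allele
#' frequencies log-uniform on [1e-4, 0.015), 1,000 family-enriched sites
#' whose founder-pool frequency is 0.3 (their INFO AF is still drawn from
#' the population spectrum — locally common alleles invisible to population
#' databases), 2\% coding sites, 5\% of sites on chrX, a first-cousin
#' parental mating loop (offspring inbreeding coefficient F = 1/16),
#' genotyping error 0.5\% per call, about one de novo alt per offspring,
#' mean depth 90x (WES; the WGS profile uses 30x) with 1\% of calls drawn at
#' mean depth 10 to exercise the 20x rule, and a planted homozygous
#' recessive causal variant segregating with affection status.
#'
#' @param template `"octet"` (index, both parents, 5 siblings) or
#'   `"quintet"` (index, both parents, 2 siblings).
#' @param n_affected_sibs,n_unaffected_sibs Sibling counts; defaults 2/3 for
#'   the octet (in the order affected, unaffected, unaffected, affected,
#'   unaffected) and 0/2 for the quintet.
#' @param n_population_sites,n_family_sites Site counts.
#' @param af_low,af_high Bounds of the log-uniform population AF spectrum.
#' @param family_pool_af Founder allele frequency at family-enriched sites.
#' @param coding_fraction Fraction of sites annotated as coding
#'   (missense); the rest are intronic.
#' @param x_fraction Fraction of sites on chrX.
#' @param genotype_error_rate Per-call probability of flipping the emitted
#'   genotype to a uniformly chosen different code.
#' @param de_novo_count_mean Mean number of de novo alt alleles per
#'   offspring (Poisson).
#' @param mean_depth Mean per-call sequencing depth (Poisson).
#' @param low_depth_fraction,low_depth_mean Fraction of calls drawn at a
#'   reduced mean depth.
#' @param profile `"wes"` (depth 90) or `"wgs"` (depth 30); overrides
#'   `mean_depth` when given.
#' @param causal Plant a recessive causal variant (see [plant_causal()]).
#' @param seed Integer seed; the whole generator is reproducible under it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(template = c("octet", "quintet"),
                       n_affected_sibs = NULL, n_unaffected_sibs = NULL,
                       n_population_sites = 100000L, n_family_sites = 1000L,
                       af_low = 1e-4, af_high = 0.015,
                       family_pool_af = 0.3, coding_fraction = 0.02,
                       x_fraction = 0.05, genotype_error_rate = 0.005,
                       de_novo_count_mean = 1, mean_depth = 90,
                       low_depth_fraction = 0.01, low_depth_mean = 10,
                       profile = NULL, causal = TRUE, seed = 1L) {
  template <- match.arg(template)
  if (!is.null(profile)) {
    profile <- match.arg(profile, c("wes", "wgs"))
    mean_depth <- if (profile == "wes") 90 else 30
  }
  if (is.null(n_affected_sibs))
    n_affected_sibs <- if (template == "octet") 2L else 0L
  if (is.null(n_unaffected_sibs))
    n_unaffected_sibs <- if (template == "octet") 3L else 2L
  stopifnot(af_low < af_high, af_high <= 1,
            family_pool_af >= 0, family_pool_af <= 1,
            coding_fraction >= 0, coding_fraction <= 1,
            x_fraction >= 0, x_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            n_affected_sibs >= 0, n_unaffected_sibs >= 0)
  structure(list(template = template,
                 n_affected_sibs = as.integer(n_affected_sibs),
                 n_unaffected_sibs = as.integer(n_unaffected_sibs),
                 n_population_sites = as.integer(n_population_sites),
                 n_family_sites = as.integer(n_family_sites),
                 af_low = af_low, af_high = af_high,
                 family_pool_af = family_pool_af,
                 coding_fraction = coding_fraction,
                 x_fraction = x_fraction,
                 genotype_error_rate = genotype_error_rate,
                 de_novo_count_mean = de_novo_count_mean,
                 mean_depth = mean_depth,
                 low_depth_fraction = low_depth_fraction,
                 low_depth_mean = low_depth_mean,
                 causal = isTRUE(causal), seed = as.integer(seed)),
            class = "sim_config")
}

# sibling affection order within the template; the octet interleaves
# affected and unaffected additions (A,U,U,A,U)
sib_pattern <- function(n_aff, n_unaff) {
  if (n_aff == 2L && n_unaff == 3L) return(c(TRUE, FALSE, FALSE, TRUE, FALSE))
  pat <- logical(0)
  a <- n_aff; u <- n_unaff; turn_aff <- TRUE
  while (a + u > 0) {
    if ((turn_aff && a > 0) || u == 0) { pat <- c(pat, TRUE); a <- a - 1 }
    else { pat <- c(pat, FALSE); u <- u - 1 }
    turn_aff <- !turn_aff
  }
  pat
}

#' Build the consanguineous pedigree template
#'
#' The template embeds the nuclear family in a first-cousin mating loop: one
#' great-grandparental couple has two children who, with married-in
#' founders, produce the father and the mother; father and mother are thus
#' first cousins and their offspring have expected inbreeding coefficient
#' F = 1/16. The tested members are the index, both parents and the
#' siblings; the six ancestors are generated but excluded from testing
#' (pedigree attribute `"tested"`).
#'
#' @param cfg A `sim_config`.
#' @return A `pedigree` with a `tested` attribute.
#' @export
build_template <- function(cfg = sim_config()) {
  k <- cfg$n_affected_sibs + cfg$n_unaffected_sibs
  cap <- if (cfg$template == "octet") 5L else 2L
  if (k > cap)
    stop("sibling count ", k, " exceeds the ", cfg$template,
         " template capacity of ", cap)
  pat <- sib_pattern(cfg$n_affected_sibs, cfg$n_unaffected_sibs)
  sib_ids <- if (k > 0) paste0("sib", seq_len(k)) else character(0)
  sib_sex <- rep(c("male", "female"), length.out = k)
  members <- data.frame(
    id = c("index", "father", "mother", sib_ids,
           "pgf", "pgm", "mgf", "mgm", "ggf", "ggm"),
    father = c("father", "pgf", "mgf", rep("father", k),
               "ggf", NA, NA, "ggf", NA, NA),
    mother = c("mother", "pgm", "mgm", rep("mother", k),
               "ggm", NA, NA, "ggm", NA, NA),
    sex = c("male", "male", "female", sib_sex,
            "male", "female", "male", "female", "male", "female"),
    affection = c("affected", "unaffected", "unaffected",
                  ifelse(pat, "affected", "unaffected"),
                  rep("unaffected", 6)),
    proband = c(TRUE, rep(FALSE, 2 + k + 6)),
    stringsAsFactors = FALSE)
  ped <- pedigree("FAM1", members, index_id = "index")
  attr(ped, "tested") <- c("index", "father", "mother", sib_ids)
  ped
}

sim_founder <- function(q, sex, is_x, hap_base) {
  n <- length(q)
  v <- cbind(stats::rbinom(n, 1L, q), stats::rbinom(n, 1L, q))
  o <- cbind(rep.int(hap_base, n), rep.int(hap_base + 1L, n))
  if (sex == "male") { v[is_x, 2] <- NA_integer_; o[is_x, 2] <- NA_integer_ }
  list(v = v, o = o, sex = sex)
}

sim_child <- function(father, mother, sex, is_x) {
  n <- nrow(father$v)
  pickm <- stats::runif(n) < 0.5
  mat_v <- ifelse(pickm, mother$v[, 1], mother$v[, 2])
  mat_o <- ifelse(pickm, mother$o[, 1], mother$o[, 2])
  pickp <- stats::runif(n) < 0.5
  pickp[is_x] <- TRUE                       # father's X is haplotype 1
  pat_v <- ifelse(pickp, father$v[, 1], father$v[, 2])
  pat_o <- ifelse(pickp, father$o[, 1], father$o[, 2])
  if (sex == "male") {
    # a male's X allele is maternal and kept in haplotype 1
    pat_v[is_x] <- mat_v[is_x]; pat_o[is_x] <- mat_o[is_x]
    mat_v[is_x] <- NA_integer_; mat_o[is_x] <- NA_integer_
  }
  list(v = cbind(pat_v, mat_v), o = cbind(pat_o, mat_o), sex = sex)
}

#' Simulate cohort genotypes
#'
#' Draws founder genotypes under Hardy-Weinberg equilibrium at each site's
#' allele frequency (the family-enriched founder-pool frequency at family
#' sites), transmits alleles by fair Mendelian sampling through the
#' first-cousin pedigree with founder-allele tracking (so autozygosity is
#' emergent, not asserted), adds Poisson de novo alt alleles per offspring,
#' applies per-call genotype error and draws per-call Poisson depths. Sites
#' are independent (no linkage). Males are truly hemizygous at chrX sites.
#' Fully reproducible under `cfg$seed`.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_cohort` list: `vt` (`variant_table` over all members,
#'   ancestors included), `ped`, `tested`, `founders`, `is_family`, `is_x`
#'   (site flags), `autozygosity` (per-offspring fraction of autosomal sites
#'   with both alleles tracing to one founder allele) and `config`.
#' @export
simulate_genotypes <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- build_template(cfg)
  tested <- attr(ped, "tested")
  npop <- cfg$n_population_sites
  nfam <- cfg$n_family_sites
  n <- npop + nfam
  is_family <- c(rep(FALSE, npop), rep(TRUE, nfam))

  is_x <- stats::runif(n) < cfg$x_fraction
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  chrom[is_x] <- "chrX"
  pos <- seq_len(n) * 10L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- bases[(match(ref, bases) + sample(1:3, n, replace = TRUE) - 1L) %% 4L + 1L]
  af <- signif(exp(stats::runif(n, log(cfg$af_low), log(cfg$af_high))), 6)
  coding <- stats::runif(n) < cfg$coding_fraction
  csq <- ifelse(coding, "missense_variant", "intron_variant")

  q <- ifelse(is_family, cfg$family_pool_af, af)
  founders <- c(pgm = "female", mgf = "male", ggf = "male", ggm = "female")
  hap <- list()
  hap$pgm <- sim_founder(q, "female", is_x, 1L)
  hap$mgf <- sim_founder(q, "male", is_x, 3L)
  hap$ggf <- sim_founder(q, "male", is_x, 5L)
  hap$ggm <- sim_founder(q, "female", is_x, 7L)
  hap$pgf <- sim_child(hap$ggf, hap$ggm, "male", is_x)
  hap$mgm <- sim_child(hap$ggf, hap$ggm, "female", is_x)
  hap$father <- sim_child(hap$pgf, hap$pgm, "male", is_x)
  hap$mother <- sim_child(hap$mgf, hap$mgm, "female", is_x)
  sib_ids <- setdiff(tested, c("index", "father", "mother"))
  kids <- c("index", sib_ids)
  for (id in kids) {
    sx <- ped$members$sex[ped$members$id == id]
    hap[[id]] <- sim_child(hap$father, hap$mother, sx, is_x)
  }

  # de novo alt alleles in offspring, each with a fresh founder-allele label
  offspring <- c("pgf", "mgm", "father", "mother", kids)
  new_origin <- 9L
  for (id in offspring) {
    cnt <- stats::rpois(1, cfg$de_novo_count_mean)
    if (cnt == 0) next
    at <- sample.int(n, min(cnt, n))
    for (s in at) {
      j <- if (is.na(hap[[id]]$v[s, 2])) 1L else sample(1:2, 1)
      hap[[id]]$v[s, j] <- 1L
      hap[[id]]$o[s, j] <- new_origin
      new_origin <- new_origin + 1L
    }
  }

  all_ids <- ped$members$id
  m <- length(all_ids)
  D <- matrix(0L, n, m, dimnames = list(NULL, all_ids))
  P <- matrix(2L, n, m, dimnames = list(NULL, all_ids))
  for (id in all_ids) {
    D[, id] <- as.integer(rowSums(hap[[id]]$v, na.rm = TRUE))
    if (hap[[id]]$sex == "male") P[is_x, id] <- 1L
  }

  if (cfg$genotype_error_rate > 0) {
    err <- matrix(stats::runif(n * m) < cfg$genotype_error_rate, n, m)
    e2 <- err & P == 2L
    D[e2] <- (D[e2] + sample(1:2, sum(e2), replace = TRUE)) %% 3L
    e1 <- err & P == 1L
    D[e1] <- 1L - D[e1]
  }

  dp <- matrix(stats::rpois(n * m, cfg$mean_depth), n, m,
               dimnames = list(NULL, all_ids))
  if (cfg$low_depth_fraction > 0) {
    low <- matrix(stats::runif(n * m) < cfg$low_depth_fraction, n, m)
    dp[low] <- stats::rpois(sum(low), cfg$low_depth_mean)
  }

  auto <- vapply(kids, function(id) {
    o <- hap[[id]]$o[!is_x, , drop = FALSE]
    mean(o[, 1] == o[, 2])
  }, 1)

  sites <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                      filter = "pass", af = af, csq = csq,
                      stringsAsFactors = FALSE)
  vt <- variant_table(sites, D, P, dp)
  structure(list(vt = vt, ped = ped, tested = tested,
                 founders = names(founders), is_family = is_family,
                 is_x = is_x, autozygosity = auto, causal = NULL,
                 config = cfg),
            class = "sim_cohort")
}

#' Plant the recessive causal variant
#'
#' Overwrites one autosomal coding population site so that the causal
#' genotype pattern holds exactly and error-free: the alt allele enters
#' through one great-grandparent, both parents are heterozygous carriers,
#' the index and every affected sibling are homozygous-alt, and unaffected
#' siblings are carriers or reference (never homozygous). Depth at the site
#' is forced to at least 20 for every member and its population AF is below
#' the 1.5\% filter bound, so the site passes the default filters by
#' construction.
#'
#' @param sim A `sim_cohort`.
#' @return The `sim_cohort` with element `causal` set to a one-row key
#'   data.frame.
#' @export
plant_causal <- function(sim) {
  cfg <- sim$config
  cand <- which(!sim$is_x & !sim$is_family &
                  sim$vt$sites$csq == "missense_variant" &
                  sim$vt$sites$af < 0.015)
  if (!length(cand))
    stop("no autosomal coding population site available to plant the ",
         "causal variant; increase n_population_sites or coding_fraction")
  s <- cand[sample.int(length(cand), 1)]
  ped <- sim$ped
  sibs <- setdiff(sim$tested, c("index", "father", "mother"))
  aff <- ped$members$affection[match(sibs, ped$members$id)] == "affected"
  d <- c(index = 2L, father = 1L, mother = 1L,
         pgf = 1L, pgm = 0L, mgf = 0L, mgm = 1L, ggf = 1L, ggm = 0L)
  sib_d <- ifelse(aff, 2L, sample(c(1L, 0L), length(sibs), replace = TRUE,
                                  prob = c(2, 1) / 3))
  names(sib_d) <- sibs
  d <- c(d, sib_d)
  ids <- colnames(sim$vt$gt)
  sim$vt$gt[s, ids] <- d[ids]
  sim$vt$ploidy[s, ids] <- 2L
  sim$vt$dp[s, ] <- pmax(sim$vt$dp[s, ], 20L)
  sim$causal <- cbind(sim$vt$sites[s, c("chrom", "pos", "ref", "alt")],
                      row = s)
  sim
}

#' Simulate a complete cohort
#'
#' [simulate_genotypes()] followed by [plant_causal()] when the
#' configuration asks for a causal variant.
#'
#' @param cfg A `sim_config`.
#' @return A `sim_cohort`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  sim <- simulate_genotypes(cfg)
  if (cfg$causal) sim <- plant_causal(sim)
  sim
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("sim_cohort:", x$config$template, "template,",
      n_variants(x$vt), "sites,", length(x$tested), "tested members",
      "( seed", x$config$seed, ")\n")
  if (!is.null(x$causal))
    cat("  causal variant at", x$causal$chrom, x$causal$pos, "\n")
  invisible(x)
}

#' Write a simulated cohort as VCF + PED
#'
#' The VCF carries only the tested members' sample columns by default
#' (ancestors can be included); AF and consequence terms go to INFO so the
#' downstream annotation works without a gene model. The PED file lists the
#' tested members as rows (the index flagged in the proband column) and the
#' ancestors as comment lines.
#'
#' @param sim A `sim_cohort`.
#' @param out_prefix Output path prefix; writes `<prefix>.vcf` and
#'   `<prefix>.ped`.
#' @param include_ancestors Also write the ancestor sample columns / rows.
#' @return Invisibly, a named character vector of the two paths.
#' @export
emit <- function(sim, out_prefix, include_ancestors = FALSE) {
  ids <- if (include_ancestors) ped_ids(sim$ped) else sim$tested
  vcf <- paste0(out_prefix, ".vcf")
  pedf <- paste0(out_prefix, ".ped")
  write_vcf(sim$vt, vcf, samples = ids)
  write_ped(sim$ped, pedf, tested = ids)
  invisible(c(vcf = vcf, ped = pedf))
}

#' Count Mendelian inconsistencies in a cohort
#'
#' For every member whose parents have genotype columns, counts genotype
#' calls impossible under Mendelian transmission (e.g. a homozygous-alt
#' child of a homozygous-ref parent), with hemizygous X logic for males.
#' Missing calls and half-calls are skipped. With genotype error and de novo
#' mutation disabled the simulator produces zero violations.
#'
#' @param vt A `variant_table`.
#' @param ped A `pedigree`.
#' @return Integer count of violating (site, member) calls.
#' @export
mendelian_violations <- function(vt, ped) {
  sm <- vt_samples(vt)
  x <- chrom_is_x(vt$sites$chrom)
  n <- n_variants(vt)
  total <- 0L
  # min/max alt alleles a parent can contribute; unknown calls contribute 0..1
  contrib <- function(pid) {
    if (is.na(pid) || !(pid %in% sm))
      return(list(lo = integer(n), hi = rep(1L, n)))
    dd <- vt$gt[, pid]; pp <- vt$ploidy[, pid]
    usable <- !is.na(dd) & pp > 0L & (pp == 2L | x)
    lo <- ifelse(usable & dd == pp, 1L, 0L)
    hi <- ifelse(usable, as.integer(dd > 0L), 1L)
    list(lo = lo, hi = hi)
  }
  for (id in intersect(ped_ids(ped), sm)) {
    m <- ped_member(ped, id)
    if (is.na(m$father) && is.na(m$mother)) next
    d <- vt$gt[, id]; p <- vt$ploidy[, id]
    valid <- !is.na(d) & (p == 2L | (p == 1L & x))
    fa <- contrib(m$father)
    mo <- contrib(m$mother)
    if (m$sex == "male") { fa$lo[x] <- 0L; fa$hi[x] <- 0L }  # no paternal X
    lo <- fa$lo + mo$lo
    hi <- fa$hi + mo$hi
    total <- total + sum(valid & (d < lo | d > hi))
  }
  total
}
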