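#' Site- and call-level filter configuration
#'
#' The basic quality filters applied before any segregation logic: caller
#' FILTER status must be PASS, population allele frequency must be strictly
#' below `max_af` (default 1.5\%), and a genotype call is only trusted when
#' its depth is at least `min_depth` (default 20x, inclusive); an
#' under-covered call is downgraded to MISSING rather than discarding the
#' site. AF semantics are strict less-than and depth is inclusive, following
#' the usual clinical phrasing ("allele frequency < 1.5\%", "minimum coverage
#' ... is 20x").
#'
#' @param min_depth Minimum per-call read depth (inclusive).
#' @param max_af Population allele frequency upper bound (exclusive).
#' @param require_pass Drop sites whose FILTER is not PASS.
#' @param af_missing_policy What to do when a site has no AF annotation:
#'   `"retain"` (default) or `"drop"`.
#' @param depth_scope `"call"` (default): the depth rule downgrades
#'   individual calls; `"site"`: a site is dropped outright unless every
#'   tested member meets `min_depth`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_depth = 20L, max_af = 0.015,
                          require_pass = TRUE,
                          af_missing_policy = c("retain", "drop"),
                          depth_scope = c("call", "site")) {
  stopifnot(min_depth >= 0, max_af >= 0, max_af <= 1)
  structure(list(min_depth = as.integer(min_depth), max_af = max_af,
                 require_pass = isTRUE(require_pass),
                 af_missing_policy = match.arg(af_missing_policy),
                 depth_scope = match.arg(depth_scope)),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("filter_config: DP >=", x$min_depth, "(", x$depth_scope, "scope ), AF <",
      x$max_af, ", require PASS:", x$require_pass,
      ", missing AF:", x$af_missing_policy, "\n")
  invisible(x)
}

#' Site-level filter decision
#'
#' A site passes when its FILTER status is pass (unless `require_pass` is
#' off) and its population allele frequency is strictly below `max_af`
#' (a missing AF is retained or dropped per `af_missing_policy`).
#'
#' @param vt A `variant_table`.
#' @param cfg A `filter_config`.
#' @return Logical vector, one decision per site.
#' @export
site_passes <- function(vt, cfg = filter_config()) {
  s <- vt$sites
  ok <- if (cfg$require_pass) s$filter == "pass" else rep(TRUE, nrow(s))
  af_ok <- ifelse(is.na(s$af), cfg$af_missing_policy == "retain",
                  s$af < cfg$max_af)
  ok & af_ok
}

#' Call-level depth decision
#'
#' A genotype call is certified only when its depth is present and at least
#' `min_depth`; failing calls are treated as MISSING for segregation.
#'
#' @param vt A `variant_table`.
#' @param cfg A `filter_config`.
#' @return Logical matrix matching `vt$dp`.
#' @export
call_passes <- function(vt, cfg = filter_config()) {
  !is.na(vt$dp) & vt$dp >= cfg$min_depth
}

chrom_is_x <- function(chrom) chrom %in% c("X", "chrX", "x", "23")
chrom_is_y <- function(chrom) chrom %in% c("Y", "chrY", "y", "24")
chrom_is_mt <- function(chrom) chrom %in% c("MT", "chrM", "chrMT", "M", "m")

#' Zygosity of genotype calls
#'
#' Classifies calls as HOM_ALT / HET / HOM_REF / MISSING given the chromosome
#' and the sample's sex. On autosomes a diploid call maps by alt dosage. On
#' chrX (and chrY) a male is hemizygous, and any alt-carrying call — a single
#' `"1"`, `"1/1"`, or a diploid-coded `"0/1"` — counts as HOM_ALT, the
#' convention under which male X variants are treated as homozygous; alt-free
#' male X calls are HOM_REF. Females on X follow the autosomal rule. A
#' single-allele call on an autosome (a half-call left by multi-allelic
#' splitting) maps HET when it carries the alt, HOM_REF otherwise. Samples of
#' unknown sex follow the diploid rule.
#'
#' @param dosage Integer vector of observed alt-allele copies.
#' @param ploidy Integer vector of observed allele counts (0 = missing).
#' @param chrom Chromosome name(s), recycled.
#' @param sex `"male"`, `"female"` or `"unknown"`, recycled.
#' @return Character vector of zygosity codes.
#' @export
zygosity <- function(dosage, ploidy, chrom, sex) {
  n <- max(length(dosage), length(ploidy), length(chrom), length(sex))
  dosage <- rep_len(dosage, n); ploidy <- rep_len(ploidy, n)
  chrom <- rep_len(chrom, n); sex <- rep_len(sex, n)
  z <- rep("MISSING", n)
  obs <- !is.na(dosage) & !is.na(ploidy) & ploidy > 0L
  hemi <- obs & (chrom_is_x(chrom) | chrom_is_y(chrom)) & sex == "male"
  z[hemi & dosage >= 1L] <- "HOM_ALT"
  z[hemi & dosage == 0L] <- "HOM_REF"
  dip <- obs & !hemi
  z[dip & ploidy == 2L & dosage == 0L] <- "HOM_REF"
  z[dip & ploidy == 2L & dosage == 1L] <- "HET"
  z[dip & ploidy == 2L & dosage == 2L] <- "HOM_ALT"
  # half-calls outside the male X: known allele decides carrier status only
  z[dip & ploidy == 1L & dosage == 1L] <- "HET"
  z[dip & ploidy == 1L & dosage == 0L] <- "HOM_REF"
  z
}

#' Zygosity matrix for a cohort
#'
#' Applies [zygosity()] column-wise, taking each sample's sex from the
#' pedigree.
#'
#' @param vt A `variant_table`.
#' @param ped A `pedigree` covering the samples of `vt`.
#' @return Character matrix of zygosity codes, sites x samples.
#' @export
zygosity_matrix <- function(vt, ped) {
  sm <- vt_samples(vt)
  sex <- ped$members$sex[match(sm, ped$members$id)]
  sex[is.na(sex)] <- "unknown"
  out <- matrix("MISSING", n_variants(vt), length(sm),
                dimnames = list(NULL, sm))
  for (j in seq_along(sm))
    out[, j] <- zygosity(vt$gt[, j], vt$ploidy[, j], vt$sites$chrom, sex[j])
  out
}
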