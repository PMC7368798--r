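#' Construct a variant table
#'
#' Columnar container for a set of normalized biallelic sites with per-sample
#' genotype calls. Genotypes are stored as two integer matrices: `gt`, the
#' number of alternate-allele copies observed in the call, and `ploidy`, the
#' number of alleles observed (2 = diploid, 1 = hemizygous or half-call,
#' 0 = missing). Depths live in `dp` (`NA` = absent).
#'
#' @param sites data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `filter` (`"pass"` or `"fail"`), `af` (population allele frequency,
#'   `NA` when absent) and `csq` (comma-joined consequence terms, `""` when
#'   absent).
#' @param gt,ploidy,dp Integer matrices, one row per site, one column per
#'   sample (column names are the sample ids).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(sites, gt, ploidy, dp) {
  stopifnot(is.data.frame(sites),
            all(c("chrom", "pos", "ref", "alt", "filter", "af", "csq") %in% names(sites)),
            nrow(gt) == nrow(sites), all(dim(gt) == dim(ploidy)),
            all(dim(gt) == dim(dp)), !is.null(colnames(gt)))
  bad_af <- !is.na(sites$af) & (sites$af < 0 | sites$af > 1)
  if (any(bad_af)) stop("pop_af outside [0,1] at row ", which(bad_af)[1])
  rownames(sites) <- NULL
  structure(list(sites = sites, gt = gt, ploidy = ploidy, dp = dp),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "sites x", ncol(x$gt), "samples (",
      paste(utils::head(colnames(x$gt), 8), collapse = ", "),
      if (ncol(x$gt) > 8) ", ..." else "", ")\n", sep = " ")
  invisible(x)
}

#' @export
`[.variant_table` <- function(x, i, ...) {
  variant_table(x$sites[i, , drop = FALSE],
                x$gt[i, , drop = FALSE],
                x$ploidy[i, , drop = FALSE],
                x$dp[i, , drop = FALSE])
}

#' Number of sites in a variant table
#' @param vt A `variant_table`.
#' @return Integer count of sites.
#' @export
n_variants <- function(vt) nrow(vt$sites)

#' Sample ids of a variant table
#' @param vt A `variant_table`.
#' @return Character vector of sample ids.
#' @export
vt_samples <- function(vt) colnames(vt$gt)

variant_keys <- function(vt) {
  paste(vt$sites$chrom, vt$sites$pos, vt$sites$ref, vt$sites$alt, sep = ":")
}

# parse one GT token list against a retained alt index; alleles equal to a
# different alt are dropped (half-call), so the retained-alt dosage survives
parse_gt_token <- function(gt_str, alt_idx) {
  toks <- strsplit(gt_str, "[/|]")[[1]]
  toks <- toks[toks != "."]
  keep <- toks == "0" | toks == as.character(alt_idx)
  toks <- toks[keep]
  c(dosage = sum(toks != "0"), ploidy = length(toks))
}

#' Split a raw multi-allelic record into biallelic records
#'
#' Takes one parsed VCF record (possibly multi-allelic) and returns one
#' record per alternate allele. Per-sample genotypes are recoded so the
#' retained alt is allele index 1; an allele matching a *different* alt is
#' dropped from the call (leaving a half-call), so no carrier of the retained
#' alt is ever lost. A vector-valued AF annotation is mapped positionally.
#'
#' @param rec A list with elements `chrom`, `pos`, `ref`, `alt` (character
#'   vector of alternate alleles), `filter` (`"pass"`/`"fail"`), `af`
#'   (numeric vector of length `length(alt)` or `NULL`), `csq` (character
#'   scalar), `gt` (named character vector of GT strings) and `dp` (named
#'   integer vector, `NA` allowed).
#' @return A list of biallelic records, each with scalar `alt` and `af` and
#'   integer `dosage`/`ploidy` vectors in place of `gt`.
#' @export
split_multiallelic <- function(rec) {
  k <- length(rec$alt)
  stopifnot(k >= 1L)
  if (!is.null(rec$af) && length(rec$af) != k)
    stop("AF vector length ", length(rec$af), " does not match ", k,
         " alt allele(s) at ", rec$chrom, ":", rec$pos)
  lapply(seq_len(k), function(j) {
    parsed <- vapply(rec$gt, parse_gt_token, c(dosage = 0, ploidy = 0),
                     alt_idx = j)
    list(chrom = rec$chrom, pos = rec$pos, ref = rec$ref, alt = rec$alt[j],
         filter = rec$filter,
         af = if (is.null(rec$af)) NA_real_ else rec$af[j],
         csq = rec$csq, dp = rec$dp,
         dosage = as.integer(parsed["dosage", ]),
         ploidy = as.integer(parsed["ploidy", ]))
  })
}

info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  if (!length(m)) return(NA_character_)
  sub(paste0("^;?", key, "="), "", m)
}

#' Read a multi-sample VCF into a variant table
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}), splits multi-allelic sites into
#' biallelic records in file order, and extracts the fields the analysis
#' consumes: per-sample GT and DP, the site FILTER status (`"."` or `"PASS"`
#' map to pass, anything else to fail), a population allele frequency INFO
#' field and a consequence INFO field.
#'
#' @param path Path to the VCF file.
#' @param af_key INFO key holding the population allele frequency
#'   (comma-separated per alt for multi-allelic sites). Default `"AF"`.
#' @param csq_key INFO key holding consequence terms. Default `"CSQ"`.
#' @return A `variant_table`.
#' @export
read_vcf <- function(path, af_key = "AF", csq_key = "CSQ") {
  if (!file.exists(path)) stop("cannot read VCF file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  samples <- character(0)
  gt_mat <- NULL
  if (!is.null(v@gt) && ncol(v@gt) >= 2L) {
    samples <- colnames(v@gt)[-1]
    gt_mat <- v@gt
  }
  n <- nrow(fix)
  if (n > 0L) {
    if (is.null(gt_mat)) stop("VCF has no sample genotype columns: ", path)
    if (any(!grepl("(^|:)GT(:|$)", gt_mat[, 1])))
      stop("GT missing from FORMAT in ", path)
  }
  out <- vector("list", n)
  for (i in seq_len(n)) {
    fmt <- strsplit(gt_mat[i, 1], ":", fixed = TRUE)[[1]]
    gi <- match("GT", fmt)
    di <- match("DP", fmt)
    cells <- strsplit(gt_mat[i, -1], ":", fixed = TRUE)
    gts <- vapply(cells, function(x) if (length(x) >= gi) x[gi] else ".", "")
    dps <- if (is.na(di)) rep(NA_integer_, length(cells)) else
      vapply(cells, function(x) {
        d <- if (length(x) >= di) x[di] else "."
        if (d %in% c(".", "")) NA_integer_ else suppressWarnings(as.integer(d))
      }, 1L)
    names(gts) <- names(dps) <- samples
    info <- fix[i, "INFO"]
    af_raw <- info_field(info, af_key)
    csq_raw <- info_field(info, csq_key)
    filt <- fix[i, "FILTER"]
    rec <- list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
                ref = fix[i, "REF"],
                alt = strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]],
                filter = if (is.na(filt) || filt %in% c(".", "PASS")) "pass" else "fail",
                af = if (is.na(af_raw)) NULL else
                  suppressWarnings(as.numeric(strsplit(af_raw, ",", fixed = TRUE)[[1]])),
                csq = if (is.na(csq_raw)) "" else csq_raw,
                gt = gts, dp = dps)
    out[[i]] <- split_multiallelic(rec)
  }
  recs <- unlist(out, recursive = FALSE)
  m <- length(recs)
  sites <- data.frame(
    chrom = vapply(recs, `[[`, "", "chrom"),
    pos = vapply(recs, `[[`, 1L, "pos"),
    ref = vapply(recs, `[[`, "", "ref"),
    alt = vapply(recs, `[[`, "", "alt"),
    filter = vapply(recs, `[[`, "", "filter"),
    af = vapply(recs, `[[`, 1, "af"),
    csq = vapply(recs, `[[`, "", "csq"),
    stringsAsFactors = FALSE)
  ns <- length(samples)
  mk <- function(fld) {
    mat <- matrix(NA_integer_, nrow = m, ncol = ns,
                  dimnames = list(NULL, samples))
    if (m > 0)
      mat[] <- t(vapply(recs, `[[`, integer(ns), fld))
    mat
  }
  if (m == 0L) {
    sites <- sites[0, ]
    empty <- matrix(integer(0), 0, ns, dimnames = list(NULL, samples))
    return(variant_table(sites, empty, empty, empty))
  }
  dp <- matrix(NA_integer_, m, ns, dimnames = list(NULL, samples))
  dp[] <- t(vapply(recs, function(r) as.integer(r$dp), integer(ns)))
  variant_table(sites, mk("dosage"), mk("ploidy"), dp)
}

gt_string <- function(dosage, ploidy) {
  out <- rep("./.", length(dosage))
  d2 <- ploidy == 2L & !is.na(dosage)
  out[d2] <- c("0/0", "0/1", "1/1")[dosage[d2] + 1L]
  d1 <- ploidy == 1L & !is.na(dosage)
  out[d1] <- c("0", "1")[dosage[d1] + 1L]
  out
}

#' Write a variant table to a VCF file
#'
#' Emits plain-text VCF v4.2 with GT:DP sample fields and AF/CSQ INFO fields.
#' The writer round-trips with [read_vcf()]: chrom, pos, ref, alt, GT, DP and
#' AF are preserved field-for-field. Hemizygous calls are written as
#' single-allele GTs (`"0"`/`"1"`).
#'
#' @param vt A `variant_table`.
#' @param path Output path.
#' @param samples Optional subset (and ordering) of sample columns to write.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(vt, path, samples = NULL) {
  if (is.null(samples)) samples <- vt_samples(vt)
  missing_s <- setdiff(samples, vt_samples(vt))
  if (length(missing_s))
    stop("samples not present in variant table: ",
         paste(missing_s, collapse = ", "))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency\">",
    "##INFO=<ID=CSQ,Number=.,Type=String,Description=\"Consequence terms\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FILTER=<ID=FAIL,Description=\"Failed caller quality filters\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  n <- n_variants(vt)
  if (n == 0L) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  s <- vt$sites
  info <- ifelse(is.na(s$af), "", paste0("AF=", format(s$af, scientific = FALSE, trim = TRUE, digits = 10)))
  has_csq <- nzchar(s$csq)
  info <- paste0(info, ifelse(has_csq & nzchar(info), ";", ""),
                 ifelse(has_csq, paste0("CSQ=", s$csq), ""))
  info[!nzchar(info)] <- "."
  cells <- vapply(samples, function(sm) {
    g <- gt_string(vt$gt[, sm], vt$ploidy[, sm])
    d <- ifelse(is.na(vt$dp[, sm]), ".", as.character(vt$dp[, sm]))
    paste0(g, ":", d)
  }, character(n))
  if (n == 1L) cells <- matrix(cells, nrow = 1)
  body <- paste(s$chrom, s$pos, ".", s$ref, s$alt, ".",
                ifelse(s$filter == "pass", "PASS", "FAIL"),
                info, "GT:DP",
                apply(cells, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
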