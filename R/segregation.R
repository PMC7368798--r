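#' Per-member genotype compatibility under an inheritance model
#'
#' The elementary rule behind every filtering strategy. Under the
#' recessive-homozygous model the index and every affected relative must be
#' HOM_ALT, a (unaffected) parent of the index must be HET — the classic
#' parental-carrier rule — and an unaffected relative must not be HOM_ALT
#' (carriers are allowed). Under the de novo model the index and affected
#' relatives must carry the alt (HET or HOM_ALT) while parents and unaffected
#' relatives must be HOM_REF; `inherited_het = TRUE` relaxes the parental
#' constraint to "not HOM_ALT" for sensitivity analysis. A MISSING genotype
#' is non-informative under the default permissive policy — the constraint is
#' skipped — except for the index, whose carrier genotype defines the
#' candidate and must be observed; the strict policy treats MISSING as
#' incompatible everywhere.
#'
#' @param z Character vector of zygosity codes (see [zygosity()]).
#' @param role One of `"index"`, `"parent"`, `"affected_relative"`,
#'   `"unaffected_relative"`.
#' @param model `"recessive"` or `"denovo"`.
#' @param missing_policy `"permissive"` (default) or `"strict"`.
#' @param inherited_het Relax the de novo parental HOM_REF constraint to
#'   allow HET parents.
#' @return Logical vector of compatibility decisions.
#' @export
member_compatible <- function(z,
                              role = c("index", "parent", "affected_relative",
                                       "unaffected_relative"),
                              model = c("recessive", "denovo"),
                              missing_policy = c("permissive", "strict"),
                              inherited_het = FALSE) {
  role <- match.arg(role)
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  ok <- switch(model,
    recessive = switch(role,
      index = z == "HOM_ALT",
      parent = z == "HET",
      affected_relative = z == "HOM_ALT",
      unaffected_relative = z != "HOM_ALT"),
    denovo = switch(role,
      index = z %in% c("HET", "HOM_ALT"),
      parent = if (inherited_het) z != "HOM_ALT" else z == "HOM_REF",
      affected_relative = z %in% c("HET", "HOM_ALT"),
      unaffected_relative = z == "HOM_REF"))
  miss <- z == "MISSING"
  ok[miss] <- missing_policy == "permissive" && role != "index"
  ok
}

# role of each tested member relative to the index; unknown affection -> NA
# (no constraint). Unaffected parents of the index take the parent role;
# affected parents are treated as affected relatives.
member_roles <- function(ped, tested) {
  idx <- ped$index_id
  im <- ped_member(ped, idx)
  vapply(tested, function(id) {
    if (id == idx) return("index")
    m <- ped_member(ped, id)
    is_parent <- (!is.na(im$father) && id == im$father) ||
                 (!is.na(im$mother) && id == im$mother)
    if (is_parent && m$affection == "unaffected") return("parent")
    switch(m$affection,
           affected = "affected_relative",
           unaffected = "unaffected_relative",
           NA_character_)
  }, "")
}

# shared preprocessing for repeated filtering over the same table
seg_prep <- function(vt, ped, cfg, ranking, gene_model) {
  Z <- zygosity_matrix(vt, ped)
  cp <- call_passes(vt, cfg)
  Z[!cp] <- "MISSING"
  site_ok <- site_passes(vt, cfg) & !chrom_is_mt(vt$sites$chrom)
  region <- classify_variants(vt, ranking, gene_model)
  list(Z = Z, site_ok = site_ok, region = region, cp = cp)
}

new_candidate_set <- function(vt, prep, retained, model, tested) {
  region <- prep$region[retained]
  zi <- prep$Z[retained, 1L]
  counts <- matrix(0L, 2, 3, dimnames = list(c("coding", "noncoding"),
                                             c("hom", "het", "total")))
  if (length(retained)) {
    tab <- table(factor(region, c("coding", "noncoding")),
                 factor(ifelse(zi == "HOM_ALT", "hom", "het"), c("hom", "het")))
    counts[, c("hom", "het")] <- as.integer(tab)
    counts[, "total"] <- counts[, "hom"] + counts[, "het"]
  }
  keys <- vt$sites[retained, c("chrom", "pos", "ref", "alt")]
  keys$region <- region
  keys$index_zygosity <- zi
  rownames(keys) <- NULL
  structure(list(keys = keys, counts = counts, model = model,
                 tested = tested, retained = retained,
                 n_input = n_variants(vt), n_site_pass = sum(prep$site_ok)),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set (", x$model, " model, ", length(x$tested),
      " tested member(s)): ", sum(x$counts[, "total"]), " candidates of ",
      x$n_input, " input sites\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Stratified counts of a candidate set
#' @param cs A `candidate_set`.
#' @return Integer matrix: rows coding/noncoding, columns hom/het/total.
#' @export
candidate_counts <- function(cs) cs$counts

#' Family segregation filter
#'
#' The core computation: retains the sites that pass the site-level filters
#' and whose genotypes are compatible, member by member, with the requested
#' inheritance model across all tested individuals. Compatibility per member
#' is [member_compatible()] with the role derived from the pedigree: index;
#' unaffected parents of the index as parents; other members as affected or
#' unaffected relatives by affection status (unknown-affection members
#' impose no constraint). Under `model = "both"` the recessive and de novo
#' candidate sets are united; they are disjoint strata by the index's
#' zygosity. Counts are stratified coding/noncoding (by consequence
#' severity, with optional gene-model fallback) and by index zygosity
#' (homozygous/heterozygous).
#'
#' @param vt A `variant_table`.
#' @param ped A `pedigree`.
#' @param tested Character vector of tested member ids; must contain the
#'   index.
#' @param model `"both"` (default), `"recessive"` or `"denovo"`.
#' @param cfg A `filter_config`.
#' @param ranking Severity ranking for region classification.
#' @param gene_model Optional `gene_model` fallback.
#' @param missing_policy `"permissive"` or `"strict"` handling of MISSING
#'   genotypes in non-index members.
#' @param inherited_het Passed to [member_compatible()].
#' @param prep Precomputed internals (used by [incremental_reduction()]).
#' @return A `candidate_set`.
#' @export
segregation_filter <- function(vt, ped, tested,
                               model = c("both", "recessive", "denovo"),
                               cfg = filter_config(),
                               ranking = default_ranking(),
                               gene_model = NULL,
                               missing_policy = c("permissive", "strict"),
                               inherited_het = FALSE,
                               prep = NULL) {
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  tested <- as.character(tested)
  if (!length(tested)) stop("tested member set is empty")
  if (!all(tested %in% ped_ids(ped)))
    stop("tested ids not in pedigree: ",
         paste(setdiff(tested, ped_ids(ped)), collapse = ", "))
  if (!(ped$index_id %in% tested))
    stop("the index (", ped$index_id, ") must be among the tested members")
  if (!all(tested %in% vt_samples(vt)))
    stop("tested ids lack genotype columns: ",
         paste(setdiff(tested, vt_samples(vt)), collapse = ", "))
  if (is.null(prep)) prep <- seg_prep(vt, ped, cfg, ranking, gene_model)

  ok <- prep$site_ok
  if (cfg$depth_scope == "site" && length(tested))
    ok <- ok & rowSums(!prep$cp[, tested, drop = FALSE]) == 0L

  roles <- member_roles(ped, tested)
  # index first so counts stratify on its zygosity
  ord <- order(roles != "index")
  tested <- tested[ord]; roles <- roles[ord]

  model_mask <- function(mod) {
    m <- rep(TRUE, n_variants(vt))
    for (j in seq_along(tested)) {
      if (is.na(roles[j])) next
      m <- m & member_compatible(prep$Z[, tested[j]], roles[j], mod,
                                 missing_policy, inherited_het)
    }
    m
  }
  mask <- switch(model,
                 recessive = model_mask("recessive"),
                 denovo = model_mask("denovo"),
                 both = model_mask("recessive") | model_mask("denovo"))
  retained <- unname(which(ok & mask))
  prep$Z <- prep$Z[, tested, drop = FALSE]
  new_candidate_set(vt, prep, retained, model, tested)
}

#' Trio filter: index plus both parents
#'
#' Candidate selection over the index and both parents. The recessive
#' (homozygous) stratum implements the classic rule — variant heterozygous in
#' both parents and homozygous in the index; the heterozygous stratum is the
#' de novo model (index carries, parents reference).
#'
#' @inheritParams segregation_filter
#' @return A `candidate_set` (model `"both"`).
#' @export
trio_filter <- function(vt, ped, cfg = filter_config(), ...) {
  im <- ped_member(ped, ped$index_id)
  if (is.na(im$father) || is.na(im$mother))
    stop("trio analysis requires both parents of the index in the pedigree")
  segregation_filter(vt, ped, c(ped$index_id, im$father, im$mother),
                     model = "both", cfg = cfg, ...)
}

#' Sibship filter: index plus siblings, no parents
#'
#' Candidate selection over the index and its siblings only; parental
#' genotypes are never consulted even when present. The homozygous stratum
#' requires HOM_ALT in the index and every affected sibling and excludes
#' sites HOM_ALT in any unaffected sibling; the heterozygous stratum requires
#' every affected sibling to carry the alt and every unaffected sibling to be
#' alt-free.
#'
#' @inheritParams segregation_filter
#' @return A `candidate_set` (model `"both"`).
#' @export
sibship_filter <- function(vt, ped, cfg = filter_config(), ...) {
  sibs <- role_sets(ped)$siblings_of_index
  if (!length(sibs))
    stop("sibship analysis requires at least one sibling of the index")
  segregation_filter(vt, ped, c(ped$index_id, sibs),
                     model = "both", cfg = cfg, ...)
}

#' Incremental family-member reduction curve
#'
#' Recomputes the candidate set as family members are added one at a time in
#' the order of a member-addition plan (index first, then typically father,
#' mother, and the remaining members). Because each added member only
#' contributes constraints, the candidate sets are nested and every stratum
#' count is non-increasing along the curve.
#'
#' @inheritParams segregation_filter
#' @param plan A `member_plan` from [addition_order()]; default order when
#'   `NULL`.
#' @return A `reduction_curve` data.frame with one row per step: `step`,
#'   `label`, `member`, stratified counts, `total` and `pct_drop` (percent
#'   drop from the previous step, 0 for the first step and when the previous
#'   total is 0). The per-step candidate key tables are attached as
#'   attribute `"keys"`.
#' @export
incremental_reduction <- function(vt, ped, plan = NULL,
                                  model = c("both", "recessive", "denovo"),
                                  cfg = filter_config(),
                                  ranking = default_ranking(),
                                  gene_model = NULL,
                                  missing_policy = c("permissive", "strict"),
                                  inherited_het = FALSE) {
  model <- match.arg(model)
  missing_policy <- match.arg(missing_policy)
  if (is.null(plan)) plan <- addition_order(ped)
  prep <- seg_prep(vt, ped, cfg, ranking, gene_model)
  steps <- nrow(plan)
  sets <- vector("list", steps)
  rows <- vector("list", steps)
  for (k in seq_len(steps)) {
    cs <- segregation_filter(vt, ped, plan$id[seq_len(k)], model = model,
                             cfg = cfg, ranking = ranking,
                             gene_model = gene_model,
                             missing_policy = missing_policy,
                             inherited_het = inherited_het, prep = prep)
    sets[[k]] <- cs$keys
    cn <- cs$counts
    rows[[k]] <- data.frame(
      step = k, label = plan$label[k], member = plan$id[k],
      coding_hom = cn["coding", "hom"], coding_het = cn["coding", "het"],
      coding_total = cn["coding", "total"],
      noncoding_hom = cn["noncoding", "hom"],
      noncoding_het = cn["noncoding", "het"],
      noncoding_total = cn["noncoding", "total"],
      total = sum(cn[, "total"]), stringsAsFactors = FALSE)
  }
  curve <- do.call(rbind, rows)
  prev <- c(NA, curve$total[-steps])
  curve$pct_drop <- ifelse(is.na(prev) | prev == 0, 0,
                           100 * (1 - curve$total / prev))
  attr(curve, "keys") <- sets
  class(curve) <- c("reduction_curve", "data.frame")
  curve
}

#' Per-step percent drops of a reduction curve
#'
#' `drop_k = 100 * (1 - total_k / total_(k-1))` over the combined
#' (coding + noncoding, hom + het) totals; a zero previous total gives a
#' drop of 0.
#'
#' @param curve A `reduction_curve` with at least 2 steps.
#' @return Numeric vector of length `nrow(curve) - 1`.
#' @export
reduction_percentages <- function(curve) {
  if (nrow(curve) < 2L) stop("reduction curve needs at least 2 steps")
  tot <- curve$total
  prev <- tot[-length(tot)]
  ifelse(prev == 0, 0, 100 * (1 - tot[-1] / prev))
}

#' @export
print.reduction_curve <- function(x, ...) {
  cat("reduction_curve over", nrow(x), "steps\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.reduction_curve <- function(x, log = "y", ...) {
  tot <- pmax(x$total, if (grepl("y", log)) 0.5 else 0)
  graphics::plot(x$step, tot, type = "b", log = log, xaxt = "n",
                 xlab = "tested individuals", ylab = "candidate variants", ...)
  graphics::axis(1, at = x$step, labels = x$label)
  invisible(x)
}

#' Compare the trio and sibship strategies on one family
#'
#' For a family with both parents and at least two siblings of the index,
#' reports the coding homozygous-recessive candidate count under the trio
#' strategy versus the sibship strategy, together with the counts of sites
#' homozygous-alt in every affected and in every unaffected member of the
#' sibship (NA when the corresponding set is empty).
#'
#' @inheritParams segregation_filter
#' @return A `strategy_comparison` list with elements
#'   `trio_candidate_count`, `sibship_candidate_count`,
#'   `shared_among_affected_sibs`, `shared_among_unaffected_sibs`.
#' @export
compare_trio_vs_sibship <- function(vt, ped, cfg = filter_config(), ...) {
  rs <- role_sets(ped)
  im <- ped_member(ped, ped$index_id)
  if (is.na(im$father) || is.na(im$mother))
    stop("strategy comparison requires both parents of the index")
  if (length(rs$siblings_of_index) < 2L)
    stop("strategy comparison requires at least two siblings of the index")
  trio <- segregation_filter(vt, ped,
                             c(ped$index_id, im$father, im$mother),
                             model = "recessive", cfg = cfg, ...)
  sib <- segregation_filter(vt, ped,
                            c(ped$index_id, rs$siblings_of_index),
                            model = "recessive", cfg = cfg, ...)

  prep <- seg_prep(vt, ped, cfg, default_ranking(), NULL)
  sibship_members <- c(ped$index_id, rs$siblings_of_index)
  aff <- intersect(sibship_members, rs$affected)
  unaff <- intersect(sibship_members, rs$unaffected)
  shared_hom <- function(ids) {
    if (!length(ids)) return(NA_integer_)
    sum(prep$site_ok &
          rowSums(prep$Z[, ids, drop = FALSE] == "HOM_ALT") == length(ids))
  }
  structure(list(
    trio_candidate_count = unname(trio$counts["coding", "hom"]),
    sibship_candidate_count = unname(sib$counts["coding", "hom"]),
    shared_among_affected_sibs = shared_hom(aff),
    shared_among_unaffected_sibs = shared_hom(unaff)),
    class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("strategy comparison (coding homozygous-recessive candidates)\n")
  cat("  trio:   ", x$trio_candidate_count, "\n")
  cat("  sibship:", x$sibship_candidate_count, "\n")
  cat("  shared HOM_ALT, all-affected sibship members:  ",
      x$shared_among_affected_sibs, "\n")
  cat("  shared HOM_ALT, all-unaffected sibship members:",
      x$shared_among_unaffected_sibs, "\n")
  invisible(x)
}

#' Export candidates as a TSV table
#'
#' Writes one row per retained variant: key, region class, index zygosity and
#' the per-member genotype strings of the tested individuals.
#'
#' @param cs A `candidate_set`.
#' @param vt The `variant_table` the set was computed from.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_candidates <- function(cs, vt, path) {
  df <- cs$keys
  for (id in cs$tested)
    df[[id]] <- gt_string(vt$gt[cs$retained, id], vt$ploidy[cs$retained, id])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
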