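#' Render a reduction curve as TSV or JSON
#'
#' One row per member-addition step with the coding and non-coding column
#' groups (total / homozygous / heterozygous) and the percent drop from the
#' previous step. Numbers are the exact per-family counts; the TSV and JSON
#' renderings carry identical values, and the JSON parses back to the
#' curve's counts losslessly.
#'
#' @param curve A `reduction_curve`.
#' @param format `"tsv"` or `"json"`.
#' @param path Optional output path; when given the document is written
#'   there as well.
#' @return The rendered document as a character scalar.
#' @export
render_reduction <- function(curve, format = c("tsv", "json"), path = NULL) {
  format <- match.arg(format)
  df <- data.frame(
    Step = curve$label,
    Member.Added = curve$member,
    Coding.Total.Variants = curve$coding_total,
    Coding.Homozygous.Variants = curve$coding_hom,
    Coding.Heterozygous.Variants = curve$coding_het,
    NonCoding.Total.Variants = curve$noncoding_total,
    NonCoding.Homozygous.Variants = curve$noncoding_hom,
    NonCoding.Heterozygous.Variants = curve$noncoding_het,
    Percent.Drop = curve$pct_drop,
    stringsAsFactors = FALSE, check.names = FALSE)
  doc <- if (format == "tsv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    paste0(paste(out, collapse = "\n"), "\n")
  } else {
    jsonlite::toJSON(df, dataframe = "rows", digits = NA, auto_unbox = TRUE,
                     pretty = TRUE)
  }
  if (!is.null(path)) writeLines(doc, path, sep = "")
  as.character(doc)
}

#' Aggregate replicate reduction curves
#'
#' Averages stratified counts across replicate curves sharing the same step
#' structure (exact fractional means, with a display column rounded half-up
#' to the integer, mirroring how such tables are usually printed) and
#' summarizes the per-step percent-drop distribution across replicates by
#' median, min and max.
#'
#' @param curves A list of `reduction_curve` objects with identical step
#'   labels.
#' @return A list with `mean_table` (data.frame of exact mean counts plus
#'   `total_display`) and `drop_summary` (per step: median/min/max percent
#'   drop across replicates).
#' @export
aggregate_replicates <- function(curves) {
  stopifnot(length(curves) >= 1)
  labs <- curves[[1]]$label
  for (cv in curves)
    if (!identical(cv$label, labs) || nrow(cv) != length(labs))
      stop("replicate curves have mismatched step structure")
  num_cols <- c("coding_hom", "coding_het", "coding_total",
                "noncoding_hom", "noncoding_het", "noncoding_total", "total")
  mean_table <- data.frame(step = curves[[1]]$step, label = labs,
                           stringsAsFactors = FALSE)
  for (cc in num_cols)
    mean_table[[cc]] <- rowMeans(vapply(curves, `[[`, numeric(length(labs)), cc))
  mean_table$total_display <- floor(mean_table$total + 0.5)   # round half-up
  drops <- vapply(curves, function(cv) cv$pct_drop, numeric(length(labs)))
  drops <- matrix(drops, nrow = length(labs))
  drop_summary <- data.frame(
    step = curves[[1]]$step, label = labs,
    median_drop = apply(drops, 1, stats::median),
    min_drop = apply(drops, 1, min),
    max_drop = apply(drops, 1, max))
  list(mean_table = mean_table, drop_summary = drop_summary)
}
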