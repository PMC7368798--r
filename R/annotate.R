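#' Default consequence-severity ranking
#'
#' A fixed ordering of sequence-ontology consequence terms from most to least
#' severe, each mapped to a coding/noncoding region class. Protein-changing
#' and splice-site terms are coding; splice-region, UTR, intronic and
#' intergenic terms are noncoding (the working dichotomy is exonic versus
#' intronic); synonymous changes still mark a coding position and map coding.
#' Terms not in the ranking sort least severe and map noncoding.
#'
#' @return A `severity_ranking` data.frame with columns `term` (in severity
#'   order) and `class` (`"coding"` or `"noncoding"`).
#' @export
default_ranking <- function() {
  df <- data.frame(
    term = c("transcript_ablation", "frameshift_variant", "stop_gained",
             "stop_lost", "start_lost", "splice_acceptor_variant",
             "splice_donor_variant", "missense_variant", "inframe_insertion",
             "inframe_deletion", "protein_altering_variant",
             "splice_region_variant", "synonymous_variant",
             "stop_retained_variant", "5_prime_UTR_variant",
             "3_prime_UTR_variant", "non_coding_transcript_exon_variant",
             "intron_variant", "upstream_gene_variant",
             "downstream_gene_variant", "intergenic_variant"),
    class = c(rep("coding", 11), "noncoding", "coding", "coding",
              rep("noncoding", 7)),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(df$term))
  class(df) <- c("severity_ranking", "data.frame")
  df
}

#' Read a gene model from a BED-like TSV
#'
#' Four tab- or whitespace-separated columns: chrom, start, end, region class
#' (`coding_exon` or `noncoding`). Coordinates are 1-based inclusive by
#' default to match VCF positions; set `zero_based = TRUE` for true BED
#' half-open 0-based input.
#'
#' @param path Path to the interval file.
#' @param zero_based Interpret starts as 0-based half-open (BED) coordinates.
#' @return A `gene_model` data.frame with columns `chrom`, `start`, `end`,
#'   `class`.
#' @export
read_gene_model <- function(path, zero_based = FALSE) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "class"))
  if (zero_based) df$start <- df$start + 1L
  if (any(df$start > df$end)) stop("gene model interval with start > end")
  class(df) <- c("gene_model", "data.frame")
  df
}

in_coding_exon <- function(model, chrom, pos) {
  hit <- logical(length(pos))
  cod <- model[model$class == "coding_exon", , drop = FALSE]
  for (i in seq_len(nrow(cod)))
    hit <- hit | (chrom == cod$chrom[i] & pos >= cod$start[i] & pos <= cod$end[i])
  hit
}

#' Classify variants as coding or noncoding
#'
#' Each site is classified by the most severe of its annotated consequence
#' terms under a severity ranking. Sites with no usable terms fall back to a
#' gene model (coding iff the position lies in a `coding_exon` interval), and
#' to noncoding when no model is given — the function is total by design.
#' Classification is independent of the order of terms in the annotation.
#'
#' @param csq Character vector of consequence annotations, one per site;
#'   terms separated by `,`, `|` or `&`. `NA` or `""` means unannotated.
#' @param ranking A `severity_ranking`; defaults to [default_ranking()].
#' @param model Optional `gene_model` fallback.
#' @param chrom,pos Site coordinates, required when `model` is given.
#' @return Character vector of `"coding"`/`"noncoding"`.
#' @export
classify_region <- function(csq, ranking = default_ranking(), model = NULL,
                            chrom = NULL, pos = NULL) {
  csq <- as.character(csq)
  csq[is.na(csq)] <- ""
  terms <- strsplit(csq, "[,|&]")
  nterm <- length(ranking$term)
  cls <- vapply(terms, function(tt) {
    tt <- tt[nzchar(tt)]
    if (!length(tt)) return(NA_character_)
    r <- match(tt, ranking$term)
    if (all(is.na(r))) return("noncoding")   # only unknown terms
    ranking$class[min(r, na.rm = TRUE)]
  }, "")
  need <- is.na(cls)
  if (any(need)) {
    if (!is.null(model)) {
      stopifnot(!is.null(chrom), !is.null(pos))
      chrom <- rep_len(chrom, length(cls))
      pos <- rep_len(pos, length(cls))
      cls[need] <- ifelse(in_coding_exon(model, chrom[need], pos[need]),
                          "coding", "noncoding")
    } else {
      cls[need] <- "noncoding"
    }
  }
  cls
}

classify_variants <- function(vt, ranking = default_ranking(), model = NULL) {
  classify_region(vt$sites$csq, ranking, model, vt$sites$chrom, vt$sites$pos)
}
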