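# in-code fixture builders shared by the test files

# nuclear-family pedigree: index + parents + siblings with given affections
fix_ped <- function(sib_aff = character(0), parents_typed = TRUE) {
  k <- length(sib_aff)
  sib_ids <- if (k) paste0("sib", seq_len(k)) else character(0)
  members <- data.frame(
    id = c("index", "father", "mother", sib_ids),
    father = c("father", NA, NA, rep("father", k)),
    mother = c("mother", NA, NA, rep("mother", k)),
    sex = c("male", "male", "female", rep(c("female", "male"), length.out = k)),
    affection = c("affected", "unaffected", "unaffected", sib_aff),
    stringsAsFactors = FALSE)
  pedigree("F1", members, index_id = "index")
}

# variant table from a dosage matrix (rows = sites, cols = samples)
fix_vt <- function(dos, chrom = "chr1", af = 0.001, csq = "missense_variant",
                   dp = 100L, ploidy = 2L, filter = "pass", pos = NULL) {
  dos <- as.matrix(dos)
  n <- nrow(dos)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(chrom = rep_len(chrom, n), pos = pos,
                      ref = rep_len("A", n), alt = rep_len("G", n),
                      filter = rep_len(filter, n),
                      af = rep_len(af, n), csq = rep_len(csq, n),
                      stringsAsFactors = FALSE)
  pl <- matrix(rep_len(ploidy, length(dos)), n, ncol(dos))
  pl[is.na(dos)] <- 0L
  dimnames(pl) <- dimnames(dos)
  dpm <- matrix(as.integer(rep_len(dp, length(dos))), n, ncol(dos),
                dimnames = dimnames(dos))
  variant_table(sites, dos, pl, dpm)
}

# all genotype assignments (0/1/2 dosage) for the given samples, one per row
fix_enumeration <- function(samples) {
  g <- do.call(expand.grid, rep(list(0:2), length(samples)))
  m <- as.matrix(g)
  colnames(m) <- samples
  m
}

tmp_file <- function(ext) tempfile(fileext = ext)
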