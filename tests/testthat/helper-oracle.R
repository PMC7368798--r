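# independent brute-force reference implementation: per-variant, per-member
# scalar logic with no shared machinery with the package internals

oracle_zyg <- function(d, p, chrom, sex) {
  if (is.na(d) || is.na(p) || p == 0) return("MISSING")
  on_xy <- chrom %in% c("chrX", "X", "chrY", "Y")
  if (on_xy && sex == "male") {
    if (d >= 1) return("HOM_ALT") else return("HOM_REF")
  }
  if (p == 2) {
    if (d == 0) return("HOM_REF")
    if (d == 1) return("HET")
    return("HOM_ALT")
  }
  if (d == 1) "HET" else "HOM_REF"
}

oracle_role <- function(ped, id) {
  if (id == ped$index_id) return("index")
  row <- ped$members[ped$members$id == id, ]
  irow <- ped$members[ped$members$id == ped$index_id, ]
  parent <- (!is.na(irow$father) && id == irow$father) ||
            (!is.na(irow$mother) && id == irow$mother)
  if (parent && row$affection == "unaffected") return("parent")
  if (row$affection == "affected") return("affected_relative")
  if (row$affection == "unaffected") return("unaffected_relative")
  "none"
}

oracle_compat <- function(z, role, model, permissive = TRUE) {
  if (role == "none") return(TRUE)
  if (z == "MISSING") return(permissive && role != "index")
  if (model == "recessive") {
    if (role %in% c("index", "affected_relative")) return(z == "HOM_ALT")
    if (role == "parent") return(z == "HET")
    return(z != "HOM_ALT")
  }
  # de novo
  if (role %in% c("index", "affected_relative")) return(z %in% c("HET", "HOM_ALT"))
  return(z == "HOM_REF")
}

# returns the row indices of retained variants
oracle_filter <- function(vt, ped, tested, model, min_depth = 20,
                          max_af = 0.015, permissive = TRUE) {
  sex <- setNames(ped$members$sex, ped$members$id)
  keep <- integer(0)
  for (i in seq_len(nrow(vt$sites))) {
    chrom <- vt$sites$chrom[i]
    if (chrom %in% c("chrM", "MT", "M")) next
    if (vt$sites$filter[i] != "pass") next
    af <- vt$sites$af[i]
    if (!is.na(af) && af >= max_af) next
    ok <- TRUE
    for (mod in if (model == "both") c("recessive", "denovo") else model) {
      ok <- TRUE
      for (id in tested) {
        d <- vt$gt[i, id]; p <- vt$ploidy[i, id]; dp <- vt$dp[i, id]
        if (is.na(dp) || dp < min_depth) { d <- NA; p <- 0 }
        z <- oracle_zyg(d, p, chrom, sex[[id]])
        if (!oracle_compat(z, oracle_role(ped, id), mod, permissive)) {
          ok <- FALSE; break
        }
      }
      if (ok) break
    }
    if (ok) keep <- c(keep, i)
  }
  keep
}
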