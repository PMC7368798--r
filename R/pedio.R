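#' Construct a pedigree object
#'
#' A pedigree is the family graph driving all segregation logic: an ordered
#' set of members with sex, affection status and parent links, plus a
#' designated index (proband) through whom the family is ascertained.
#'
#' @param family_id Family identifier.
#' @param members A data.frame with columns `id`, `father`, `mother`
#'   (`NA` for a missing parent), `sex` (`"male"`, `"female"` or
#'   `"unknown"`), `affection` (`"affected"`, `"unaffected"` or `"unknown"`)
#'   and optionally a logical `proband` column.
#' @param index_id Identifier of the index case. When `NULL`, the member
#'   flagged in `proband` is used, else the first affected member in row
#'   order.
#'
#' @return An object of class `pedigree`.
#' @export
pedigree <- function(family_id, members, index_id = NULL) {
  stopifnot(is.data.frame(members))
  need <- c("id", "father", "mother", "sex", "affection")
  miss <- setdiff(need, names(members))
  if (length(miss)) stop("members lacks columns: ", paste(miss, collapse = ", "))
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  if (is.null(members$proband)) members$proband <- FALSE

  if (anyDuplicated(members$id))
    stop("duplicate individual id in family ", family_id, ": ",
         members$id[duplicated(members$id)][1])
  for (side in c("father", "mother")) {
    ref <- members[[side]]
    bad <- !is.na(ref) & !(ref %in% members$id)
    if (any(bad))
      stop("unresolved ", side, " id in family ", family_id, ": ", ref[bad][1])
  }
  fa_sex <- members$sex[match(members$father, members$id)]
  if (any(!is.na(fa_sex) & !(fa_sex %in% c("male", "unknown"))))
    stop("individual referenced as father is not male in family ", family_id)
  mo_sex <- members$sex[match(members$mother, members$id)]
  if (any(!is.na(mo_sex) & !(mo_sex %in% c("female", "unknown"))))
    stop("individual referenced as mother is not female in family ", family_id)

  # acyclicity: peel members whose (remaining) parents are already resolved
  done <- logical(nrow(members))
  repeat {
    fok <- is.na(members$father) | done[match(members$father, members$id)]
    mok <- is.na(members$mother) | done[match(members$mother, members$id)]
    can <- !done & fok & mok
    if (!any(can)) break
    done[can] <- TRUE
  }
  if (!all(done))
    stop("parent graph contains a cycle in family ", family_id,
         " (involving ", members$id[!done][1], ")")

  if (is.null(index_id)) {
    if (any(members$proband)) {
      index_id <- members$id[members$proband][1]
    } else if (any(members$affection == "affected")) {
      index_id <- members$id[members$affection == "affected"][1]
    } else {
      stop("family ", family_id,
           ": no proband flag and no affected member; cannot determine index")
    }
  }
  if (!index_id %in% members$id)
    stop("index_id ", index_id, " is not a member of family ", family_id)

  structure(list(family_id = as.character(family_id),
                 members = members,
                 index_id = as.character(index_id)),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree", x$family_id, "-", nrow(x$members), "members, index",
      x$index_id, "\n")
  cat("  affected:", sum(x$members$affection == "affected"),
      " unaffected:", sum(x$members$affection == "unaffected"), "\n")
  tested <- attr(x, "tested")
  if (!is.null(tested)) cat("  tested:", paste(tested, collapse = ", "), "\n")
  invisible(x)
}

ped_ids <- function(ped) ped$members$id

ped_member <- function(ped, id) ped$members[match(id, ped$members$id), ]

#' Read a PED pedigree file
#'
#' Standard 6-column whitespace-delimited PED dialect: family, individual,
#' father, mother, sex (1 = male, 2 = female, other = unknown), phenotype
#' (2 = affected, 1 = unaffected, other = unknown). `"0"` denotes a missing
#' parent. An optional 7th column flags the proband with `1`; without it the
#' index is the first affected member in file order. Lines starting with `#`
#' are comments.
#'
#' @param path Path to the PED file.
#' @return A `pedigree` if the file holds one family, else a named list of
#'   `pedigree` objects (one per family id, in order of first appearance).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("cannot read PED file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop("PED file has no data lines: ", path)
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  nfld <- lengths(fields)
  if (any(nfld < 6L))
    stop("malformed PED line ", lineno[which(nfld < 6L)[1]],
         ": fewer than 6 columns")
  col <- function(k) vapply(fields, function(f) if (length(f) >= k) f[k] else NA_character_, "")
  df <- data.frame(
    fam = col(1), id = col(2), father = col(3), mother = col(4),
    sex = unname(c("1" = "male", "2" = "female")[col(5)]),
    affection = unname(c("2" = "affected", "1" = "unaffected")[col(6)]),
    proband = !is.na(col(7)) & col(7) == "1",
    stringsAsFactors = FALSE)
  df$sex[is.na(df$sex)] <- "unknown"
  df$affection[is.na(df$affection)] <- "unknown"
  df$father[df$father == "0"] <- NA_character_
  df$mother[df$mother == "0"] <- NA_character_

  fams <- unique(df$fam)
  peds <- lapply(fams, function(f) {
    m <- df[df$fam == f, c("id", "father", "mother", "sex", "affection", "proband")]
    rownames(m) <- NULL
    pedigree(f, m)
  })
  names(peds) <- fams
  if (length(peds) == 1L) peds[[1]] else peds
}

#' Write a pedigree to a PED file
#'
#' Emits the 6 core columns plus the proband flag as a 7th column. When
#' `tested` is given, only those members are written as data rows; the
#' remaining members (e.g. simulated ancestors) appear as `#ancestor` comment
#' lines and parent references pointing outside the written set are blanked
#' to `"0"` so the file stays self-contained.
#'
#' @param ped A `pedigree`.
#' @param path Output path.
#' @param tested Optional character vector of member ids to write as rows;
#'   defaults to the pedigree's `tested` attribute, else all members.
#' @return Invisibly, `path`.
#' @export
write_ped <- function(ped, path, tested = NULL) {
  if (is.null(tested)) tested <- attr(ped, "tested")
  m <- ped$members
  if (is.null(tested)) tested <- m$id
  stopifnot(all(tested %in% m$id))
  fmt_row <- function(r, blank_outside) {
    fa <- r$father; mo <- r$mother
    if (blank_outside) {
      if (!is.na(fa) && !(fa %in% tested)) fa <- NA
      if (!is.na(mo) && !(mo %in% tested)) mo <- NA
    }
    paste(ped$family_id, r$id,
          ifelse(is.na(fa), "0", fa), ifelse(is.na(mo), "0", mo),
          c(male = "1", female = "2", unknown = "0")[r$sex],
          c(affected = "2", unaffected = "1", unknown = "0")[r$affection],
          if (r$id == ped$index_id) "1" else "0")
  }
  rows <- vapply(which(m$id %in% tested), function(i) fmt_row(m[i, ], TRUE), "")
  anc <- vapply(which(!(m$id %in% tested)), function(i)
    paste("#ancestor:", fmt_row(m[i, ], FALSE)), "")
  writeLines(c(rows, anc), path)
  invisible(path)
}

step_label <- function(k) {
  lab <- c("Index", "2", "Trio", "Quartet", "Quintet", "Sextet", "Septet", "Octet")
  ifelse(k <= 8L, lab[pmax(k, 1L)], as.character(k))
}

#' Member-addition plan for the incremental analysis
#'
#' Orders family members for the extended-family analysis in which candidate
#' counts are recomputed as each member is added, starting from the index.
#' The default order is index, father, mother, then the remaining members in
#' file order. Step labels follow the count of tested individuals (Index,
#' Trio, Quartet, ..., Octet); when the second and third steps are exactly
#' the two parents, the second step is labelled Trio as well, since the trio
#' constraint only binds once both parents are present.
#'
#' @param ped A `pedigree`.
#' @param requested Optional character vector giving the order explicitly;
#'   must start with the index and contain only members of `ped` (restricted
#'   to the `tested` attribute when present).
#' @return A `member_plan` data.frame with columns `step`, `id`, `label`.
#' @export
addition_order <- function(ped, requested = NULL) {
  scope <- attr(ped, "tested")
  if (is.null(scope)) scope <- ped$members$id
  idx <- ped$index_id
  if (is.null(requested)) {
    im <- ped_member(ped, idx)
    parents <- c(im$father, im$mother)
    parents <- parents[!is.na(parents) & parents %in% scope]
    rest <- setdiff(scope, c(idx, parents))
    requested <- c(idx, parents, rest)
  } else {
    requested <- as.character(requested)
    if (!all(requested %in% scope))
      stop("requested order contains non-members: ",
           paste(setdiff(requested, scope), collapse = ", "))
    if (requested[1] != idx)
      stop("member-addition order must start with the index (", idx, ")")
    if (anyDuplicated(requested)) stop("requested order has duplicates")
  }
  k <- seq_along(requested)
  label <- step_label(k)
  im <- ped_member(ped, idx)
  if (length(requested) >= 3L && !is.na(im$father) && !is.na(im$mother) &&
      setequal(requested[2:3], c(im$father, im$mother)))
    label[2] <- "Trio"
  plan <- data.frame(step = k, id = requested, label = label,
                     stringsAsFactors = FALSE)
  class(plan) <- c("member_plan", "data.frame")
  plan
}

#' Affection-based role sets of a pedigree
#'
#' Partitions members into affected and unaffected sets (members with unknown
#' affection fall in neither) and reports the index's parents and siblings.
#' Siblings are members sharing at least one resolved parent with the index
#' (half-siblings included).
#'
#' @param ped A `pedigree`.
#' @return A list with elements `affected`, `unaffected`, `parents_of_index`
#'   (length 0-2 character vector) and `siblings_of_index`.
#' @export
role_sets <- function(ped) {
  m <- ped$members
  idx <- ped$index_id
  im <- ped_member(ped, idx)
  parents <- c(im$father, im$mother)
  parents <- parents[!is.na(parents)]
  sib <- m$id != idx &
    ((!is.na(m$father) & !is.na(im$father) & m$father == im$father) |
     (!is.na(m$mother) & !is.na(im$mother) & m$mother == im$mother))
  list(affected = m$id[m$affection == "affected"],
       unaffected = m$id[m$affection == "unaffected"],
       parents_of_index = parents,
       siblings_of_index = m$id[sib])
}
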