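#' Construct and validate a pedigree table
#'
#' A pedigree is a tibble with one row per individual and columns
#' `family_id`, `individual_id`, `father_id`, `mother_id` (`NA` when absent),
#' `sex` (`"male"`, `"female"`, `"unknown"`), `affection` (`"brain_tumor"`,
#' `"unaffected"`, `"unknown"`), the diagnosis fields `histology`, `grade`,
#' `age_band` (printed bands such as `"20-24"`, never exact ages), `sampled`
#' (genotype data available) and `side_label`. `side_label` records, for
#' founders only, which founder lineage the reported family history of brain
#' or other tumors points at: `"tumor_side"`, `"married_in"` (joined the
#' family from outside the tumor-history lineage) or `"none"` (no
#' information). Non-founders always carry `"none"`; their lineage side is a
#' derived quantity (see [side_of()]).
#'
#' @param x A data frame with at least the first six columns above.
#' @return A validated pedigree tibble.
#' @details Structural invariants enforced: parent references resolve within
#'   the same family; parents are recorded both-or-neither; no individual is
#'   its own ancestor; fathers are male and mothers female where sex is known;
#'   `side_label` is `"none"` for non-founders; every family has at least one
#'   founder.
#' @export
pedigree <- function(x) {
  x <- as_tibble(x)
  required <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  defaults <- list(
    histology = NA_character_, grade = NA_character_, age_band = NA_character_,
    sampled = TRUE, side_label = "none"
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(x)) x[[nm]] <- defaults[[nm]]
  }
  x <- x |>
    mutate(
      across(c("family_id", "individual_id", "father_id", "mother_id"), as.character),
      father_id = if_else(.data$father_id %in% c("0", ""), NA_character_, .data$father_id),
      mother_id = if_else(.data$mother_id %in% c("0", ""), NA_character_, .data$mother_id),
      side_label = if_else(is.na(.data$side_label), "none", .data$side_label),
      sampled = if_else(is.na(.data$sampled), TRUE, as.logical(.data$sampled))
    ) |>
    select(
      "family_id", "individual_id", "father_id", "mother_id", "sex", "affection",
      "histology", "grade", "age_band", "sampled", "side_label"
    )
  validate_pedigree(x)
  x
}

validate_pedigree <- function(ped) {
  if (nrow(ped) == 0) {
    return(invisible(ped))
  }
  bad_sex <- setdiff(unique(ped$sex), c("male", "female", "unknown"))
  if (length(bad_sex) > 0) {
    abort(paste0("invalid sex value(s): ", paste(bad_sex, collapse = ", ")))
  }
  bad_aff <- setdiff(unique(ped$affection), c("brain_tumor", "unaffected", "unknown"))
  if (length(bad_aff) > 0) {
    abort(paste0("invalid affection value(s): ", paste(bad_aff, collapse = ", ")))
  }
  bad_side <- setdiff(unique(ped$side_label), c("tumor_side", "married_in", "none"))
  if (length(bad_side) > 0) {
    abort(paste0("invalid side_label value(s): ", paste(bad_side, collapse = ", ")))
  }
  dup <- ped |>
    dplyr::count(.data$family_id, .data$individual_id) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated individual id(s): ", paste(dup$individual_id, collapse = ", ")))
  }
  one_parent <- is.na(ped$father_id) != is.na(ped$mother_id)
  if (any(one_parent)) {
    abort(paste0(
      "individual(s) with exactly one recorded parent: ",
      paste(ped$individual_id[one_parent], collapse = ", ")
    ))
  }
  for (fam in unique(ped$family_id)) {
    p <- ped[ped$family_id == fam, ]
    ids <- p$individual_id
    for (col in c("father_id", "mother_id")) {
      ref <- p[[col]]
      dangling <- !is.na(ref) & !ref %in% ids
      if (any(dangling)) {
        abort(paste0(
          "family ", fam, ": parent id(s) not in pedigree: ",
          paste(unique(ref[dangling]), collapse = ", ")
        ))
      }
    }
    self_par <- !is.na(p$father_id) & (p$father_id == ids) |
      !is.na(p$mother_id) & (p$mother_id == ids)
    if (any(self_par)) {
      abort(paste0(
        "family ", fam, ": individual(s) listed as own parent: ",
        paste(ids[self_par], collapse = ", ")
      ))
    }
    sex_of <- setNames(p$sex, ids)
    f_bad <- !is.na(p$father_id) & sex_of[p$father_id] == "female"
    m_bad <- !is.na(p$mother_id) & sex_of[p$mother_id] == "male"
    if (any(f_bad, na.rm = TRUE) || any(m_bad, na.rm = TRUE)) {
      abort(paste0("family ", fam, ": parent sex/role conflict"))
    }
    # acyclicity by iterated founder stripping (topological order must exist)
    remaining <- ids
    repeat {
      fa <- setNames(p$father_id, ids)[remaining]
      mo <- setNames(p$mother_id, ids)[remaining]
      strip <- (is.na(fa) | !fa %in% remaining) & (is.na(mo) | !mo %in% remaining)
      if (all(strip)) break
      if (!any(strip)) {
        abort(paste0("family ", fam, ": pedigree contains a cycle"))
      }
      remaining <- remaining[!strip]
    }
    is_f <- is.na(p$father_id) & is.na(p$mother_id)
    if (!any(is_f)) {
      abort(paste0("family ", fam, ": no founder present"))
    }
    if (any(!is_f & p$side_label != "none")) {
      abort(paste0("family ", fam, ": side_label must be \"none\" for non-founders"))
    }
  }
  invisible(ped)
}

#' Read a PED file (with optional extension sidecar)
#'
#' Reads the standard whitespace-delimited 6-column PED format
#' (`family_id individual_id father_id mother_id sex affection`), where a
#' missing parent is encoded `0`, sex is `1` = male / `2` = female /
#' `0` = unknown, and affection is `2` = affected (brain tumor),
#' `1` = unaffected, `0` = unknown. An optional tab-separated sidecar keyed by
#' `family_id` + `individual_id` supplies the extension columns `histology`,
#' `grade`, `age_band`, `sampled` and `side_label`.
#'
#' @param path Path to the PED file.
#' @param sidecar Optional path to the extension TSV.
#' @return A validated pedigree tibble (zero rows for an empty file).
#' @export
read_ped <- function(path, sidecar = NULL) {
  if (!file.exists(path)) abort(paste0("PED file not found: ", path))
  empty <- pedigree_template()
  if (file.info(path)$size == 0) {
    return(empty)
  }
  raw <- utils::read.table(
    path,
    header = FALSE, colClasses = "character", comment.char = "#",
    col.names = c("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  )
  if (nrow(raw) == 0) {
    return(empty)
  }
  ped <- as_tibble(raw) |>
    mutate(
      sex = unname(c(`1` = "male", `2` = "female", `0` = "unknown")[.data$sex]),
      affection = unname(c(`2` = "brain_tumor", `1` = "unaffected", `0` = "unknown")[.data$affection])
    )
  if (any(is.na(ped$sex)) || any(is.na(ped$affection))) {
    abort("PED sex must be 0/1/2 and affection 0/1/2")
  }
  if (!is.null(sidecar)) {
    side <- readr::read_tsv(sidecar, show_col_types = FALSE, progress = FALSE) |>
      mutate(across(c("family_id", "individual_id"), as.character))
    ped <- left_join(ped, side, by = c("family_id", "individual_id"))
  }
  pedigree(ped)
}

pedigree_template <- function() {
  tibble(
    family_id = character(), individual_id = character(),
    father_id = character(), mother_id = character(),
    sex = character(), affection = character(),
    histology = character(), grade = character(), age_band = character(),
    sampled = logical(), side_label = character()
  )
}

#' Write a pedigree to PED + sidecar files
#'
#' Inverse of [read_ped()]; genotype-independent round trip.
#'
#' @param ped Pedigree tibble.
#' @param path Output PED path.
#' @param sidecar Optional output path for the extension TSV.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path, sidecar = NULL) {
  core <- ped |>
    mutate(
      father_id = if_else(is.na(.data$father_id), "0", .data$father_id),
      mother_id = if_else(is.na(.data$mother_id), "0", .data$mother_id),
      sex = c(male = "1", female = "2", unknown = "0")[.data$sex],
      affection = c(brain_tumor = "2", unaffected = "1", unknown = "0")[.data$affection]
    ) |>
    select("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  utils::write.table(core, path,
    quote = FALSE, sep = "\t",
    row.names = FALSE, col.names = FALSE
  )
  if (!is.null(sidecar)) {
    ped |>
      select(
        "family_id", "individual_id", "histology", "grade", "age_band",
        "sampled", "side_label"
      ) |>
      readr::write_tsv(sidecar, progress = FALSE)
  }
  invisible(path)
}

#' Founders of a pedigree
#'
#' Founders are the members with no recorded parents.
#'
#' @param ped Pedigree tibble (one or more families).
#' @param family Optional family id to restrict to.
#' @return Tibble of founder rows.
#' @export
founders <- function(ped, family = NULL) {
  if (!is.null(family)) ped <- filter(ped, .data$family_id %in% !!family)
  filter(ped, is.na(.data$father_id) & is.na(.data$mother_id))
}

single_family <- function(ped, family = NULL) {
  if (!is.null(family)) ped <- ped[ped$family_id == family, , drop = FALSE]
  fams <- unique(ped$family_id)
  if (length(fams) != 1) {
    abort("expected exactly one family; pass `family =` to select one")
  }
  ped
}

map_founder_side <- function(label) {
  c(tumor_side = "tumor_side", married_in = "non_tumor_side", none = "undetermined")[label]
}

#' Founder-lineage side of an individual
#'
#' Founders report their own label (`married_in` mapping to
#' `non_tumor_side`). A non-founder is `tumor_side` if every ancestral path
#' reaches only tumor-side founders, `non_tumor_side` if only married-in
#' founders, `mixed` if founders of both labels are among its ancestors, and
#' `undetermined` when labels are missing.
#'
#' @param ped Pedigree tibble for a single family (or pass `family`).
#' @param individual_id Individual id(s); vectorized.
#' @param family Optional family id.
#' @return Character vector in
#'   `{"tumor_side", "non_tumor_side", "mixed", "undetermined"}`.
#' @export
side_of <- function(ped, individual_id, family = NULL) {
  p <- single_family(ped, family)
  unknown <- setdiff(individual_id, p$individual_id)
  if (length(unknown) > 0) {
    abort(paste0("individual(s) not in pedigree: ", paste(unknown, collapse = ", ")))
  }
  fa <- setNames(p$father_id, p$individual_id)
  mo <- setNames(p$mother_id, p$individual_id)
  lab <- setNames(p$side_label, p$individual_id)
  founder_labels <- function(id) {
    if (is.na(fa[[id]])) {
      return(lab[[id]])
    }
    unique(c(founder_labels(fa[[id]]), founder_labels(mo[[id]])))
  }
  vapply(individual_id, function(id) {
    labs <- founder_labels(id)
    has_t <- "tumor_side" %in% labs
    has_m <- "married_in" %in% labs
    if (has_t && has_m) {
      "mixed"
    } else if ("none" %in% labs) {
      "undetermined"
    } else if (has_t) {
      "tumor_side"
    } else {
      "non_tumor_side"
    }
  }, character(1))
}

# Allele sets transmissible by a parent genotype code (autosomal / X female).
transmissible <- function(code) {
  if (is.na(code)) {
    return(c(0L, 1L))
  }
  switch(as.character(code),
    `0` = 0L, `1` = c(0L, 1L), `2` = 1L, `3` = 0L, `4` = 1L
  )
}

#' List Mendelian violations for one variant
#'
#' Checks every (child, father, mother) trio of the pedigree against Mendelian
#' transmission for the given chromosome. X-chromosome (non-PAR) rules apply to
#' males: genotypes are hemizygous, sons inherit from the mother only and a
#' heterozygous male call is itself a violation. Missing genotypes skip the
#' check for that trio.
#'
#' @param ped Pedigree tibble for one family (or pass `family`).
#' @param genotypes Named character vector of genotype labels
#'   (`"hom_ref"`, `"het"`, `"hom_alt"`, `"hemi_ref"`, `"hemi_alt"`,
#'   `"missing"`) keyed by individual id; absent individuals are treated as
#'   missing.
#' @param chrom Chromosome of the variant.
#' @param family Optional family id.
#' @return Tibble of violation records with a `reason` column (zero rows when
#'   consistent).
#' @export
mendelian_violations <- function(ped, genotypes, chrom, family = NULL) {
  p <- single_family(ped, family)
  chrom <- normalize_chrom(chrom)
  g <- setNames(rep(NA_integer_, nrow(p)), p$individual_id)
  got <- intersect(names(genotypes), p$individual_id)
  g[got] <- gt_to_code(genotypes[got])
  sex <- setNames(p$sex, p$individual_id)
  out <- list()
  add <- function(id, reason) {
    out[[length(out) + 1L]] <<- tibble(
      family_id = p$family_id[[1]], individual_id = id,
      father_id = p$father_id[match(id, p$individual_id)],
      mother_id = p$mother_id[match(id, p$individual_id)],
      genotype = code_to_gt(g[[id]]), reason = reason
    )
  }
  on_x <- chrom == "X"
  on_y <- chrom == "Y"
  if (on_x || on_y) {
    for (id in p$individual_id) {
      if (!is.na(g[[id]]) && sex[[id]] == "male" && g[[id]] == 1L) {
        add(id, paste0("heterozygous male genotype on chr", chrom))
      }
    }
  }
  # treat diploid male codes on X as their hemizygous equivalents for the
  # transmission check (read_vcf already coerces with a warning)
  eff <- g
  if (on_x) {
    male <- names(eff)[sex[names(eff)] == "male"]
    eff[male] <- ifelse(!is.na(eff[male]) & eff[male] == 0L, 3L, eff[male])
    eff[male] <- ifelse(!is.na(eff[male]) & eff[male] == 2L, 4L, eff[male])
  }
  kids <- p[!is.na(p$father_id), , drop = FALSE]
  for (i in seq_len(nrow(kids))) {
    id <- kids$individual_id[[i]]
    cg <- eff[[id]]
    if (is.na(cg) || (on_x && sex[[id]] == "male" && cg == 1L)) next
    fg <- eff[[kids$father_id[[i]]]]
    mg <- eff[[kids$mother_id[[i]]]]
    ok <- if (on_y) {
      if (sex[[id]] != "male") TRUE else is.na(fg) || code_dosage(cg) == code_dosage(fg)
    } else if (on_x && sex[[id]] == "male") {
      # son: one allele, from the mother
      code_dosage(cg) %in% transmissible(mg)
    } else if (on_x) {
      # daughter: father's single X allele + one maternal allele
      pat <- if (is.na(fg)) c(0L, 1L) else code_dosage(fg)
      any(outer(pat, transmissible(mg), `+`) == code_dosage(cg))
    } else {
      any(outer(transmissible(fg), transmissible(mg), `+`) == code_dosage(cg))
    }
    if (!ok) add(id, "genotype impossible under Mendelian transmission")
  }
  if (length(out) == 0) {
    tibble(
      family_id = character(), individual_id = character(),
      father_id = character(), mother_id = character(),
      genotype = character(), reason = character()
    )
  } else {
    bind_rows(out)
  }
}

#' Infer the founder-lineage side a variant was inherited from
#'
#' For each affected carrier the transmitting parent is traced recursively:
#' a genotyped carrier parent transmits; when one parent is genotyped
#' homozygous- (or hemizygous-) reference, the other parent is the obligate
#' transmitter; X-linked hemizygous males receive the allele from the mother.
#' Tracing continues through ungenotyped obligate carriers until a founder or
#' an uninformative point is reached; at an uninformative point the lineage
#' side of the last established carrier ([side_of()]) is used when it is
#' unambiguous. The inference assumes a single founder entry point for the
#' allele (rare-variant parsimony) and never invokes de novo mutation. If all
#' affected carriers resolve to one side that side is returned; disagreement
#' or lack of information yields `"undetermined"`.
#'
#' @inheritParams mendelian_violations
#' @return One of `"tumor_side"`, `"non_tumor_side"`, `"undetermined"`.
#' @export
infer_inheritance_side <- function(ped, genotypes, chrom, family = NULL) {
  p <- single_family(ped, family)
  chrom <- normalize_chrom(chrom)
  g <- setNames(rep(NA_integer_, nrow(p)), p$individual_id)
  got <- intersect(names(genotypes), p$individual_id)
  g[got] <- gt_to_code(genotypes[got])
  sex <- setNames(p$sex, p$individual_id)
  fa <- setNames(p$father_id, p$individual_id)
  mo <- setNames(p$mother_id, p$individual_id)
  lab <- setNames(p$side_label, p$individual_id)
  aff <- setNames(p$affection, p$individual_id)
  on_x <- chrom == "X"

  affected_carriers <- names(g)[aff[names(g)] == "brain_tumor" & code_is_carrier(g)]
  if (length(affected_carriers) == 0) {
    abort("no affected carrier in family; inheritance side undefined")
  }

  if (on_x) {
    # a father transmits his single X to every daughter, so genotyped
    # daughters pin an ungenotyped father's X: any homozygous-reference
    # daughter forces hemi_ref, any homozygous-alternate daughter hemi_alt
    for (id in p$individual_id[sex[p$individual_id] == "male"]) {
      if (!is.na(g[[id]])) next
      daughters <- p$individual_id[!is.na(fa[p$individual_id]) &
        fa[p$individual_id] == id & sex[p$individual_id] == "female"]
      dg <- g[daughters]
      forces_ref <- any(!is.na(dg) & dg == 0L)
      forces_alt <- any(!is.na(dg) & dg == 2L)
      if (forces_ref && !forces_alt) g[[id]] <- 3L
      if (forces_alt && !forces_ref) g[[id]] <- 4L
    }
  }

  status_of <- function(id) {
    code <- g[[id]]
    if (is.na(code)) {
      "unknown"
    } else if (code_is_carrier(code)) {
      "carrier"
    } else {
      "noncarrier"
    }
  }

  # set of founders through which the carrier's allele can have entered under
  # single-entry parsimony: a genotyped carrier parent is the transmitter; a
  # genotyped reference parent blocks its branch (making the other parent the
  # obligate transmitter); X-linked hemizygous males receive from the mother;
  # homozygotes received from both parents; de novo is never invoked
  entries <- function(id) {
    if (is.na(fa[[id]])) {
      return(id)
    }
    f <- fa[[id]]
    m <- mo[[id]]
    code <- g[[id]]
    if (on_x && sex[[id]] == "male") {
      if (status_of(m) == "noncarrier") {
        return(character()) # inconsistent data
      }
      return(entries(m))
    }
    hom_child <- !is.na(code) && code == 2L
    if (hom_child) {
      if (status_of(f) == "noncarrier" || status_of(m) == "noncarrier") {
        return(character())
      }
      return(union(entries(f), entries(m)))
    }
    st <- c(status_of(f), status_of(m))
    candidates <- if (any(st == "carrier")) {
      c(f, m)[st == "carrier"] # parsimony: a known carrier is the source
    } else {
      c(f, m)[st == "unknown"]
    }
    if (length(candidates) == 0) {
      return(character()) # both parents reference: would require de novo
    }
    unique(unlist(lapply(candidates, entries)))
  }

  # joint parsimony: the possible entry founders of every observed carrier
  # (affected or not) constrain each other -- the allele entered through a
  # minimum-size founder set hitting all of them (single origin for a rare
  # allele). Each affected carrier is then restricted to the entries that
  # appear in some minimal hitting set.
  all_carriers <- names(g)[code_is_carrier(g)]
  entry_sets <- lapply(all_carriers, entries)
  names(entry_sets) <- all_carriers
  if (any(lengths(entry_sets) == 0)) {
    return("undetermined") # observed genotypes admit no non-de-novo origin
  }
  universe <- unique(unlist(entry_sets))
  minimal_hits <- NULL
  for (k in seq_along(universe)) {
    combos <- utils::combn(universe, k, simplify = FALSE)
    hits <- Filter(
      function(s) all(vapply(entry_sets, function(e) any(e %in% s), logical(1))),
      combos
    )
    if (length(hits) > 0) {
      minimal_hits <- hits
      break
    }
  }
  side_from <- function(id) {
    ent <- unique(unlist(lapply(minimal_hits, function(s) intersect(entry_sets[[id]], s))))
    if (length(ent) == 0) {
      return("undetermined")
    }
    labs <- unique(unname(map_founder_side(lab[ent])))
    if (length(labs) == 1 && labs != "undetermined") labs else "undetermined"
  }

  sides <- vapply(affected_carriers, side_from, character(1))
  det <- unique(sides[sides %in% c("tumor_side", "non_tumor_side")])
  # all carriers share the single entry point, so agreement among the
  # determinate carriers decides; conflict or no information yields
  # undetermined
  if (length(det) == 1) det else "undetermined"
}
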