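# Shared fixtures and independent oracles used by the property-style tests.

fixture <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- example_glioma_cohort()
    coh
  }
})

vkey <- list(
  r185c = "2:155099285:C:T",
  l405q = "2:155252560:T:A",
  n1483s = "5:16680150:A:G",
  a504v = "5:16762730:C:T",
  ar = "X:66937326:G:T",
  rs = "8:130645692:A:G",
  chek2 = "22:29091856:AC:A",
  tp53_rare = c("17:7573997:T:C", "17:7578560:T:C", "17:7579538:G:A")
)

family_genotypes <- function(coh, variant, family) {
  p <- coh$ped[coh$ped$family_id == family, ]
  ids <- intersect(p$individual_id, colnames(coh$geno))
  setNames(famseg:::code_to_gt(coh$geno[variant, ids]), ids)
}

# ---- independent Mendelian trio checker (allele-set logic, used only by the
# ---- enumeration oracle below)

oracle_transmit <- function(gt) {
  switch(gt,
    hom_ref = 0L, het = c(0L, 1L), hom_alt = 1L,
    hemi_ref = 0L, hemi_alt = 1L,
    c(0L, 1L)
  )
}

oracle_dose <- function(gt) {
  c(hom_ref = 0, het = 1, hom_alt = 2, hemi_ref = 0, hemi_alt = 1)[[gt]]
}

oracle_trio_ok <- function(child_gt, father_gt, mother_gt, child_sex, chrom) {
  if (chrom == "X") {
    if (child_sex == "male") {
      if (child_gt == "het") {
        return(FALSE)
      }
      return(oracle_dose(child_gt) %in% oracle_transmit(mother_gt))
    }
    pat <- oracle_dose(father_gt) # father hemizygous: his X goes to daughters
    return(any(outer(pat, oracle_transmit(mother_gt), `+`) == oracle_dose(child_gt)))
  }
  any(outer(oracle_transmit(father_gt), oracle_transmit(mother_gt), `+`) ==
    oracle_dose(child_gt))
}

oracle_consistent <- function(ped, gts, chrom) {
  sex <- setNames(ped$sex, ped$individual_id)
  kids <- ped[!is.na(ped$father_id), ]
  if (chrom == "X") {
    males <- ped$individual_id[ped$sex == "male"]
    if (any(gts[males] == "het")) {
      return(FALSE)
    }
  }
  for (i in seq_len(nrow(kids))) {
    id <- kids$individual_id[i]
    if (!oracle_trio_ok(
      gts[[id]], gts[[kids$father_id[i]]], gts[[kids$mother_id[i]]],
      sex[[id]], chrom
    )) {
      return(FALSE)
    }
  }
  TRUE
}

# ---- brute-force inheritance-side oracle: enumerate every Mendelian-
# ---- consistent genotype assignment to ungenotyped members, keep the
# ---- assignments with the fewest carrier founders (single-entry parsimony),
# ---- and report a side only when all of them agree

oracle_side <- function(ped, genotypes, chrom) {
  ids <- ped$individual_id
  gts <- setNames(rep(NA_character_, length(ids)), ids)
  got <- intersect(names(genotypes), ids)
  gts[got] <- ifelse(genotypes[got] == "missing", NA, genotypes[got])
  unknown <- ids[is.na(gts)]
  space <- lapply(unknown, function(id) {
    if (chrom == "X" && ped$sex[ped$individual_id == id] == "male") {
      c("hemi_ref", "hemi_alt")
    } else {
      c("hom_ref", "het", "hom_alt")
    }
  })
  grid <- if (length(unknown) == 0) {
    list(character(0))
  } else {
    g <- do.call(expand.grid, c(space, stringsAsFactors = FALSE))
    lapply(seq_len(nrow(g)), function(i) setNames(unlist(g[i, ]), unknown))
  }
  is_founder <- is.na(ped$father_id)
  founder_ids <- ids[is_founder]
  founder_side <- setNames(
    c(
      tumor_side = "tumor_side", married_in = "non_tumor_side",
      none = "undetermined"
    )[ped$side_label[is_founder]],
    founder_ids
  )
  carrier <- function(gt) gt %in% c("het", "hom_alt", "hemi_alt")

  entries <- list()
  for (asg in grid) {
    full <- gts
    full[names(asg)] <- asg
    if (!oracle_consistent(ped, full, chrom)) next
    entry <- founder_ids[vapply(full[founder_ids], carrier, logical(1))]
    entries[[length(entries) + 1L]] <- entry
  }
  if (length(entries) == 0) {
    return("undetermined")
  }
  n_entry <- lengths(entries)
  keep <- entries[n_entry == min(n_entry)]
  sides <- unique(unlist(lapply(keep, function(e) unique(unname(founder_side[e])))))
  if (identical(sides, "tumor_side")) {
    "tumor_side"
  } else if (identical(sides, "non_tumor_side")) {
    "non_tumor_side"
  } else {
    "undetermined"
  }
}

# ---- random small pedigree + gene-drop generator for the side-inference and
# ---- relabeling properties (<= 8 members)

random_small_family <- function(chrom = "2", three_gen = FALSE) {
  fam <- "R"
  mk <- function(id, fa, mo, sex, side = "none") {
    tibble::tibble(
      family_id = fam, individual_id = id, father_id = fa, mother_id = mo,
      sex = sex, affection = "unaffected", histology = NA_character_,
      grade = NA_character_, age_band = NA_character_, sampled = TRUE,
      side_label = side
    )
  }
  sides <- sample(c("tumor_side", "married_in", "none"), 2, replace = TRUE)
  rows <- list(
    mk("I-1", NA, NA, "male", sides[1]),
    mk("I-2", NA, NA, "female", sides[2])
  )
  k <- sample(2:3, 1)
  kid_sex <- sample(c("male", "female"), k, replace = TRUE)
  for (i in seq_len(k)) {
    rows[[length(rows) + 1]] <- mk(paste0("II-", i), "I-1", "I-2", kid_sex[i])
  }
  if (three_gen) {
    sp_side <- sample(c("tumor_side", "married_in", "none"), 1)
    sp_sex <- if (kid_sex[1] == "male") "female" else "male"
    rows[[length(rows) + 1]] <- mk("II-sp", NA, NA, sp_sex, sp_side)
    fa <- if (kid_sex[1] == "male") "II-1" else "II-sp"
    mo <- if (kid_sex[1] == "male") "II-sp" else "II-1"
    for (i in seq_len(sample(1:2, 1))) {
      rows[[length(rows) + 1]] <- mk(paste0("III-", i), fa, mo, sample(c("male", "female"), 1))
    }
  }
  famseg::pedigree(dplyr::bind_rows(rows))
}

# drop one alternate allele from a random founder through the pedigree
gene_drop_genotypes <- function(ped, chrom = "2", carrier_founder = NULL) {
  ids <- ped$individual_id
  sex <- setNames(ped$sex, ids)
  on_x <- chrom == "X"
  hap <- list()
  founder_ids <- ids[is.na(ped$father_id)]
  carrier_founder <- carrier_founder %||% sample(founder_ids, 1)
  for (i in seq_along(ids)) {
    id <- ids[i]
    if (is.na(ped$father_id[i])) {
      a <- c(0L, 0L)
      if (id == carrier_founder) a[1] <- 1L
      if (on_x && sex[[id]] == "male") a[2] <- NA_integer_
    } else {
      f <- hap[[ped$father_id[i]]]
      m <- hap[[ped$mother_id[i]]]
      mat <- m[sample(1:2, 1)]
      if (on_x) {
        pat <- f[1]
        a <- if (sex[[id]] == "male") c(mat, NA_integer_) else c(pat, mat)
      } else {
        pat <- f[sample(1:2, 1)]
        a <- c(pat, mat)
      }
    }
    hap[[id]] <- a
  }
  vapply(ids, function(id) {
    a <- hap[[id]]
    if (on_x && sex[[id]] == "male") {
      if (a[1] == 1L) "hemi_alt" else "hemi_ref"
    } else {
      c("hom_ref", "het", "hom_alt")[sum(a) + 1L]
    }
  }, character(1))
}

# ---- independent all-criteria oracle: evaluates each criterion on its own
# ---- from first principles and intersects

oracle_candidates <- function(coh, criteria = prioritization_criteria()) {
  ann <- coh$ann
  variants <- coh$variants$variant_id
  ped <- coh$ped
  fams <- unique(ped$family_id)
  pred_mat <- as.matrix(ann[, c(
    "SIFT", "PolyPhen", "LRT", "MutationTaster",
    "MutationAssessor", "FATHMM_MKL", "MetaSVM", "MetaLR"
  )])
  per_variant <- lapply(variants, function(v) {
    i <- match(v, ann$variant_id)
    af <- if (is.na(i) || is.na(ann$af_fin[i])) 0 else ann$af_fin[i]
    rare <- af < criteria$af_fin_max
    n_av <- sum(!is.na(pred_mat[i, ]))
    n_dm <- sum(pred_mat[i, ] == "damaging", na.rm = TRUE)
    damaging <- n_av > 0 && n_dm > n_av / 2
    relevant <- isTRUE(ann$brain_expressed[i]) || isTRUE(ann$glioma_relevant[i])
    sup <- character()
    shared_all <- TRUE
    side_ok <- TRUE
    for (f in fams) {
      p <- ped[ped$family_id == f, ]
      aff_ids <- intersect(
        p$individual_id[p$affection == "brain_tumor"],
        colnames(coh$geno)
      )
      g <- coh$geno[v, aff_ids]
      typed <- aff_ids[!is.na(g)]
      carriers <- typed[famseg:::code_is_carrier(coh$geno[v, typed])]
      if (length(carriers) == 0) next
      sup <- c(sup, f)
      if (length(carriers) < length(typed)) shared_all <- FALSE
      if (criteria$require_tumor_side != "none") {
        side <- famseg:::side_for(coh, v, f)
        if (side == "non_tumor_side") side_ok <- FALSE
      }
    }
    list(
      variant_id = v, gene = coh$variants$gene[match(v, coh$variants$variant_id)],
      qualifies = rare && damaging && relevant && length(sup) >= 1 &&
        shared_all && side_ok,
      support = sup
    )
  })
  qual <- Filter(function(z) z$qualifies, per_variant)
  gene_fams <- list()
  for (z in qual) {
    gene_fams[[z$gene]] <- union(gene_fams[[z$gene]] %||% character(), z$support)
  }
  cand <- Filter(function(z) {
    length(z$support) >= criteria$min_families ||
      (criteria$gene_level_aggregation &&
        length(gene_fams[[z$gene]]) >= criteria$min_families)
  }, qual)
  sort(vapply(cand, `[[`, character(1), "variant_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
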