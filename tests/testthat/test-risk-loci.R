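test_that("detection summary reproduces the CCDC26 risk-variant counts", {
  coh <- fixture()
  det <- detection_summary(coh)
  rs <- det[det$variant_id == vkey$rs, ]
  expect_equal(rs$n_affected_carriers, 8)
  expect_equal(rs$n_families_affected, 6)
  expect_equal(rs$het_affected, 7)
  expect_equal(rs$hom_affected, 1)
  expect_true(rs$detected_in_affected)
  expect_false(rs$unaffected_only)
  # locus absent from every carrier
  coh2 <- coh
  coh2$geno[vkey$rs, ] <- ifelse(is.na(coh2$geno[vkey$rs, ]), NA_integer_, 0L)
  det2 <- detection_summary(coh2)
  rs2 <- det2[det2$variant_id == vkey$rs, ]
  expect_equal(rs2$n_affected_carriers, 0)
  expect_false(rs2$detected_in_affected)
  # carried by one unaffected member only
  coh3 <- coh2
  coh3$geno[vkey$rs, "A_II-3"] <- 1L
  det3 <- detection_summary(coh3)
  expect_true(det3$unaffected_only[det3$variant_id == vkey$rs])
})

test_that("co-occurrence flags families whose affecteds carry both alleles", {
  coh <- fixture()
  cand <- prioritize_variants(coh)
  co <- co_occurrence(coh, cand)
  rs_co <- co[co$risk_variant == vkey$rs & co$co_occurs, ]
  expect_setequal(rs_co$family_id, c("B", "C", "Q"))
  expect_equal(rs_co$candidate_genes[rs_co$family_id == "Q"], "AR")
  # no risk-allele carriers anywhere -> nothing co-occurs
  coh2 <- coh
  coh2$geno[coh2$risk_loci$variant_id, ] <-
    ifelse(is.na(coh2$geno[coh2$risk_loci$variant_id, ]), NA_integer_, 0L)
  co2 <- co_occurrence(coh2, cand)
  expect_false(any(co2$co_occurs))
})

test_that("co-occurrence equals an exhaustive pairwise scan on random cohorts", {
  coh <- simulate_cohort(sim_config(n_families = 6, background = list(n_variants = 80)),
    seed = 44
  )
  cand <- prioritize_variants(coh, prioritization_criteria(
    min_families = 1, require_tumor_side = "none", require_gene_relevance = FALSE
  ))
  co <- co_occurrence(coh, cand)
  # brute force: loop over every affected member x risk locus x candidate
  fam_of <- setNames(coh$ped$family_id, coh$ped$individual_id)
  aff_ids <- coh$ped$individual_id[coh$ped$affection == "brain_tumor"]
  for (i in seq_len(nrow(co))) {
    f <- co$family_id[i]
    rl <- co$risk_variant[i]
    found <- FALSE
    for (ind in intersect(aff_ids[fam_of[aff_ids] == f], colnames(coh$geno))) {
      risk_ok <- isTRUE(famseg:::code_dosage(coh$geno[rl, ind]) > 0)
      cand_ok <- any(famseg:::code_is_carrier(coh$geno[cand$variants$variant_id, ind]))
      if (risk_ok && cand_ok) found <- TRUE
    }
    expect_equal(co$co_occurs[i], found, info = paste(f, rl))
  }
})

test_that("the PRS is the dosage-weighted sum of log odds ratios", {
  ped <- pedigree(tibble::tibble(
    family_id = "F", individual_id = c("a", "b", "c"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = c("male", "female", "male"),
    affection = c("brain_tumor", "unaffected", "unaffected")
  ))
  variants <- variant_table(c("8", "5", "X"), c(10, 20, 30), "A", "G")
  loci <- risk_locus_table(
    c("8", "5", "X"), c(10, 20, 30), "A", "G",
    risk_allele = "G", odds_ratio = c(6.3, 1.2, 2.0)
  )
  g <- matrix(NA_integer_, 3, 3, dimnames = list(variants$variant_id, ped$individual_id))
  g[, "a"] <- c(1L, 0L, 3L) # het at the OR 6.3 locus
  g[, "b"] <- c(2L, 1L, 0L) # hom + het
  g[, "c"] <- c(0L, 0L, 4L) # hemizygous risk allele
  coh <- cohort(ped, variants, g, risk_loci = loci)
  scores <- prs(coh)
  expect_equal(scores$score[scores$individual_id == "a"], log(6.3))
  expect_equal(
    scores$score[scores$individual_id == "b"],
    2 * log(6.3) + log(1.2)
  )
  # hemizygous dosage counts once, no doubling
  expect_equal(scores$score[scores$individual_id == "c"], log(2.0))
  # all dosages zero -> zero score
  coh0 <- coh
  coh0$geno[] <- 0L
  coh0$geno[3, c("a", "c")] <- 3L
  expect_equal(prs(coh0)$score, rep(0, 3))
  # additivity over disjoint locus sets
  s12 <- prs(coh, loci = loci[1:2, ])$score
  s3 <- prs(coh, loci = loci[3, ])$score
  expect_equal(prs(coh)$score, s12 + s3)
  # risk allele on the reference strand flips the dosage
  flipped <- loci
  flipped$risk_allele <- "A"
  s_ref <- prs(coh, loci = flipped[1, ])
  expect_equal(s_ref$score[s_ref$individual_id == "a"], log(6.3)) # het: one ref allele
  expect_equal(s_ref$score[s_ref$individual_id == "c"], 2 * log(6.3)) # hom ref
})

test_that("prs_compare is deterministic, bounded and detects extreme shifts", {
  coh <- fixture()
  a <- prs_compare(coh, seed = 5)
  b <- prs_compare(coh, seed = 5)
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$perm_stats, b$perm_stats)
  expect_gte(a$p_value, 1 / (a$n_perm + 1))
  expect_lte(a$p_value, 1)
  # shift every affected score far beyond the largest locus effect
  shifted <- coh
  extra <- variant_table("12", 999, "A", "G")
  loci <- dplyr::bind_rows(
    coh$risk_loci,
    risk_locus_table("12", 999, "A", "G", "G", odds_ratio = exp(10))
  )
  g2 <- rbind(coh$geno, matrix(0L, 1, ncol(coh$geno),
    dimnames = list(extra$variant_id, colnames(coh$geno))
  ))
  aff <- shifted$ped$individual_id[shifted$ped$affection == "brain_tumor"]
  g2[extra$variant_id, aff] <- 2L
  shifted <- cohort(shifted$ped, dplyr::bind_rows(shifted$variants, extra), g2,
    annotations = shifted$ann, risk_loci = loci
  )
  res <- prs_compare(shifted, n_perm = 499, scheme = "pooled", seed = 2)
  expect_equal(res$p_value, 1 / 500)
  # degenerate groups error
  all_aff <- coh
  all_aff$ped$affection <- "brain_tumor"
  expect_error(prs_compare(all_aff, seed = 1), "at least one")
})

test_that("within-family permutation preserves family label counts", {
  # scores constant within families: every within-family relabeling leaves the
  # statistic unchanged, so the permutation p-value must be 1
  coh <- fixture()
  uniform <- coh
  fam_score <- setNames(seq_along(unique(coh$ped$family_id)), unique(coh$ped$family_id))
  # give each family a family-specific dosage at one locus only
  uniform$geno[coh$risk_loci$variant_id, ] <- 0L
  for (f in unique(coh$ped$family_id)) {
    ids <- intersect(coh$ped$individual_id[coh$ped$family_id == f], colnames(coh$geno))
    uniform$geno[coh$risk_loci$variant_id[1], ids] <- as.integer(fam_score[f] %% 3 > 0)
  }
  res <- prs_compare(uniform, n_perm = 199, scheme = "within_family", seed = 3)
  expect_equal(res$p_value, 1)
  expect_true(all(abs(res$perm_stats - res$observed) < 1e-12))
})
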