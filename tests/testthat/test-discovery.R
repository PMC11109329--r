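# small hand-built cohort: one planted shared variant, several private ones
make_discovery_cohort <- function() {
  ped <- pedigree(tibble::tibble(
    family_id = rep(c("F1", "F2"), each = 4),
    individual_id = paste0(rep(c("F1", "F2"), each = 4), "_", rep(c("I-1", "I-2", "II-1", "II-2"), 2)),
    father_id = rep(c(NA, NA, "I-1", "I-1"), 2),
    mother_id = rep(c(NA, NA, "I-2", "I-2"), 2),
    sex = rep(c("male", "female", "male", "female"), 2),
    affection = rep(c("unaffected", "unaffected", "brain_tumor", "brain_tumor"), 2)
  ) |>
    dplyr::mutate(
      father_id = ifelse(is.na(father_id), NA, paste0(family_id, "_", father_id)),
      mother_id = ifelse(is.na(mother_id), NA, paste0(family_id, "_", mother_id)),
      side_label = ifelse(grepl("I-1$", individual_id) & is.na(father_id), "tumor_side",
        ifelse(is.na(father_id), "married_in", "none")
      )
    ))
  variants <- variant_table(
    chrom = rep("3", 6), pos = 1:6 * 1000, ref = "A", alt = "G",
    gene = paste0("G", 1:6),
    consequence = c("missense", "missense", "missense", "synonymous", "missense", "missense")
  )
  g <- matrix(0L, 6, 8, dimnames = list(variants$variant_id, ped$individual_id))
  g[1, c("F1_I-1", "F1_II-1", "F1_II-2")] <- 1L # shared in F1
  g[2, "F1_II-1"] <- 1L # private, not shared (II-2 wild type)
  g[3, c("F2_I-2", "F2_II-1")] <- 1L # not shared in F2
  g[4, c("F1_II-1", "F1_II-2")] <- 1L # shared but synonymous
  g[5, c("F2_II-1", "F2_II-2")] <- 1L # shared in F2, common allele
  g[6, c("F1_I-2", "F1_II-1", "F1_II-2", "F2_II-1", "F2_II-2")] <- 1L # shared in both
  ann <- annotation_table(
    variants$variant_id,
    af_fin = c(1e-4, 1e-4, 1e-4, 1e-4, 0.05, 0.002),
    SIFT = "damaging", PolyPhen = "damaging", MetaLR = "damaging",
    brain_expressed = TRUE
  )
  cohort(ped, variants, g, annotations = ann)
}

test_that("merge_callsets equals set algebra", {
  a <- c("1:1:A:C", "1:2:A:C")
  b <- c("1:3:A:C", "1:4:A:C")
  expect_setequal(merge_callsets(a, b, "union"), c(a, b))
  expect_length(merge_callsets(a, b, "intersection"), 0)
  expect_setequal(merge_callsets(a, a, "intersection"), a)
  set.seed(3)
  for (i in 1:25) {
    u <- paste0("1:", sample(1:40, 15), ":A:C")
    v <- paste0("1:", sample(1:40, 15), ":A:C")
    expect_setequal(merge_callsets(u, v, "union"), unique(c(u, v)))
    expect_setequal(merge_callsets(u, v, "intersection"), intersect(u, v))
  }
})

test_that("the discovery filter applies strict rarity and consequence class", {
  coh <- fixture()
  kept <- filter_discovery(coh, filter_config())
  expect_true(vkey$r185c %in% kept) # af 8.0e-5 missense
  expect_false(vkey$rs %in% kept) # intronic and common
  expect_false(any(vkey$tp53_rare %in% kept)) # intronic/synonymous
  # boundary: af exactly at the threshold is removed (strict inequality)
  coh2 <- coh
  coh2$ann$af_fin[coh2$ann$variant_id == vkey$r185c] <- 0.01
  expect_false(vkey$r185c %in% filter_discovery(coh2, filter_config()))
  # absent frequency counts as zero (never observed)
  coh3 <- coh
  coh3$ann$af_fin[coh3$ann$variant_id == vkey$r185c] <- NA
  expect_true(vkey$r185c %in% filter_discovery(coh3, filter_config()))
})

test_that("filtering is monotone in the frequency threshold and merge mode", {
  coh <- fixture()
  tighter <- filter_discovery(coh, filter_config(discovery_af_max = 1e-4))
  looser <- filter_discovery(coh, filter_config(discovery_af_max = 0.01))
  expect_true(all(tighter %in% looser))
  a <- filter_discovery(coh, filter_config())
  u <- merge_callsets(a, character(), "union")
  i <- merge_callsets(a, character(), "intersection")
  expect_true(all(i %in% u))
})

test_that("shared_in_family requires every genotyped affected to carry", {
  coh <- fixture()
  expect_true(shared_in_family(coh, vkey$r185c, "A"))
  # affected member wild type while unaffected relatives carry
  expect_false(shared_in_family(coh, vkey$a504v, "O"))
  # a family with no genotyped affected member is uninformative
  coh2 <- coh
  coh2$geno[, c("E_II-1", "E_II-2")] <- NA_integer_
  expect_true(is.na(shared_in_family(coh2, vkey$rs, "E")))
  # missing genotype drops from the denominator
  coh3 <- coh
  coh3$geno[vkey$r185c, "A_II-2"] <- NA_integer_
  expect_true(shared_in_family(coh3, vkey$r185c, "A"))
})

test_that("build_panel keeps exactly the shared discovery variants", {
  coh <- make_discovery_cohort()
  panel <- build_panel(coh, filter_config(), literature = "9:9:A:G")
  # enumeration oracle: rare, protein-altering, shared in >= 1 family
  expected <- c("3:1000:A:G", "3:6000:A:G")
  expect_setequal(panel$wes_candidates, expected)
  expect_equal(panel$literature, "9:9:A:G")
  expect_equal(nrow(panel$regions), 0)
  empty <- build_panel(coh, filter_config())
  expect_length(empty$literature, 0)
  # invariant to sample and family ordering
  perm <- rev(seq_len(nrow(coh$ped)))
  coh_shuffled <- cohort(
    coh$ped[perm, ], coh$variants,
    coh$geno[, coh$ped$individual_id[perm]],
    annotations = coh$ann
  )
  expect_setequal(
    build_panel(coh_shuffled, filter_config())$wes_candidates,
    panel$wes_candidates
  )
})

test_that("targeted QC drops exactly the low-call-rate and low-depth variants", {
  coh <- make_discovery_cohort()
  qc <- qc_targeted(coh, filter_config())
  expect_setequal(qc$kept, rownames(coh$geno)) # complete data passes
  # force 10% of a simulated matrix below the call-rate threshold
  set.seed(9)
  sim <- simulate_cohort(sim_config(
    n_families = 4,
    background = list(n_variants = 200), missingness = 0
  ), seed = 21)
  forced <- sample(rownames(sim$geno), 20)
  sim$geno[forced, sample(ncol(sim$geno), ceiling(0.5 * ncol(sim$geno)))] <- NA_integer_
  qc2 <- qc_targeted(sim, filter_config(qc_min_call_rate = 0.9))
  recount <- rownames(sim$geno)[rowMeans(!is.na(sim$geno)) < 0.9]
  expect_setequal(setdiff(rownames(sim$geno), qc2$kept), recount)
  expect_true(all(forced %in% qc2$report$variant_id[!qc2$report$kept]))
  expect_match(qc2$report$reason[!qc2$report$kept], "call rate")
  # zero call rate is always dropped
  sim$geno[forced[1], ] <- NA_integer_
  qc3 <- qc_targeted(sim, filter_config())
  expect_false(forced[1] %in% qc3$kept)
})
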