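test_that("read_ped parses a multiplex family with its extension sidecar", {
  ped_path <- withr::local_tempfile(fileext = ".ped")
  side_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "A\tI-1\t0\t0\t1\t1",
    "A\tI-2\t0\t0\t2\t1",
    "A\tII-1\tI-1\tI-2\t2\t2",
    "A\tII-2\tI-1\tI-2\t2\t2",
    "A\tII-3\tI-1\tI-2\t2\t1"
  ), ped_path)
  readr::write_tsv(tibble::tibble(
    family_id = "A", individual_id = c("I-1", "I-2", "II-1", "II-2", "II-3"),
    histology = c(NA, NA, "PA", "A", NA), grade = c(NA, NA, "I", "II", NA),
    age_band = c(NA, NA, "20-24", "35-39", NA), sampled = TRUE,
    side_label = c("tumor_side", "married_in", "none", "none", "none")
  ), side_path)
  ped <- read_ped(ped_path, sidecar = side_path)
  expect_equal(nrow(ped), 5)
  expect_equal(sum(ped$affection == "brain_tumor"), 2)
  expect_equal(sort(founders(ped)$individual_id), c("I-1", "I-2"))
  expect_equal(ped$age_band[ped$individual_id == "II-1"], "20-24")
  expect_equal(ped$side_label[ped$individual_id == "I-1"], "tumor_side")

  # round trip
  out_ped <- withr::local_tempfile(fileext = ".ped")
  out_side <- withr::local_tempfile(fileext = ".tsv")
  write_ped(ped, out_ped, sidecar = out_side)
  expect_equal(read_ped(out_ped, sidecar = out_side), ped)
})

test_that("structural errors are caught with informative messages", {
  tmp <- withr::local_tempfile(fileext = ".ped")
  writeLines("A\tI-1\tI-1\t0\t1\t1", tmp)
  expect_error(read_ped(tmp), "one recorded parent")
  writeLines(c("A\tI-2\t0\t0\t2\t1", "A\tI-1\tI-1\tI-2\t1\t1"), tmp)
  expect_error(read_ped(tmp), "own parent")
  writeLines("A\tII-1\tI-9\tI-8\t1\t2", tmp)
  expect_error(read_ped(tmp), "I-9|not in pedigree")
  # father listed with female sex
  writeLines(c(
    "A\tI-1\t0\t0\t2\t1", "A\tI-2\t0\t0\t2\t1",
    "A\tII-1\tI-1\tI-2\t1\t2"
  ), tmp)
  expect_error(read_ped(tmp), "sex/role")
  # two-member parent cycle
  bad <- tibble::tibble(
    family_id = "A", individual_id = c("X", "Y", "Z", "W"),
    father_id = c("Y", "X", NA, NA), mother_id = c("Z", "W", NA, NA),
    sex = c("male", "male", "female", "female"),
    affection = "unaffected"
  )
  expect_error(pedigree(bad), "cycle")
})

test_that("an empty PED file yields an empty pedigree collection", {
  tmp <- withr::local_tempfile(fileext = ".ped")
  file.create(tmp)
  ped <- read_ped(tmp)
  expect_s3_class(ped, "tbl_df")
  expect_equal(nrow(ped), 0)
})

test_that("founders are exactly the members without recorded parents", {
  coh <- fixture()
  # three-generation family: generation-I members only
  expect_setequal(founders(coh$ped, "B")$individual_id, c("B_I-1", "B_I-2", "B_II-1"))
  single <- pedigree(tibble::tibble(
    family_id = "S", individual_id = "S1", father_id = NA, mother_id = NA,
    sex = "female", affection = "unknown"
  ))
  expect_equal(founders(single)$individual_id, "S1")
  # traversal oracle: a founder is never reachable as a child
  ped <- coh$ped
  expect_setequal(
    founders(ped)$individual_id,
    setdiff(ped$individual_id, ped$individual_id[!is.na(ped$father_id)])
  )
})

test_that("side_of maps founder labels and mixes lineages correctly", {
  coh <- fixture()
  expect_equal(unname(side_of(coh$ped, "A_I-1", family = "A")), "tumor_side")
  expect_equal(unname(side_of(coh$ped, "A_I-2", family = "A")), "non_tumor_side")
  # children of a tumor-side x married-in couple are mixed
  expect_equal(unname(side_of(coh$ped, "A_II-1", family = "A")), "mixed")
  # unlabeled founders give undetermined
  expect_equal(unname(side_of(coh$ped, "P_II-1", family = "P")), "undetermined")
  expect_error(side_of(coh$ped, "nobody", family = "A"), "not in pedigree")
})

test_that("side_of swaps outputs under founder-label relabeling", {
  set.seed(11)
  for (i in 1:20) {
    ped <- random_small_family(three_gen = i %% 2 == 0)
    swapped <- ped
    swapped$side_label <- c(
      tumor_side = "married_in", married_in = "tumor_side", none = "none"
    )[ped$side_label]
    for (id in ped$individual_id) {
      a <- unname(side_of(ped, id))
      b <- unname(side_of(swapped, id))
      expected <- c(
        tumor_side = "non_tumor_side", non_tumor_side = "tumor_side",
        mixed = "mixed", undetermined = "undetermined"
      )[[a]]
      expect_equal(b, expected)
    }
  }
})

test_that("mendelian_violations flags impossible trios and male X hets", {
  coh <- fixture()
  pA <- coh$ped[coh$ped$family_id == "A", ]
  # de novo pattern: child het, both parents hom_ref
  v <- mendelian_violations(
    pA,
    c("I-1" = "hom_ref", "I-2" = "hom_ref", "A_II-1" = "het",
      "A_I-1" = "hom_ref", "A_I-2" = "hom_ref"),
    chrom = "2"
  )
  expect_equal(nrow(v), 1)
  expect_equal(v$individual_id, "A_II-1")
  # X-linked fixture family: het carrier mother, hemizygous-ref father,
  # hemizygous-alt son is consistent
  expect_equal(nrow(mendelian_violations(
    coh$ped, family_genotypes(coh, vkey$ar, "Q"), "X", family = "Q"
  )), 0)
  # heterozygous male on chrX is itself a violation
  v <- mendelian_violations(
    coh$ped,
    c("Q_I-1" = "het", "Q_I-2" = "het", "Q_II-1" = "hemi_ref"),
    "X",
    family = "Q"
  )
  expect_equal(nrow(v), 1)
  expect_match(v$reason, "male")
  # missing genotypes skip the check
  expect_equal(nrow(mendelian_violations(
    pA, c("A_II-1" = "het"), "2"
  )), 0)
})

test_that("the worked-example cohort is Mendelian-consistent everywhere", {
  coh <- fixture()
  total <- 0
  for (f in unique(coh$ped$family_id)) {
    for (v in rownames(coh$geno)) {
      chrom <- coh$variants$chrom[match(v, coh$variants$variant_id)]
      total <- total + nrow(mendelian_violations(
        coh$ped, family_genotypes(coh, v, f), chrom, family = f
      ))
    }
  }
  expect_equal(total, 0)
})

test_that("inheritance side follows carrier parents and obligate carriers", {
  coh <- fixture()
  # wild-type father, carrier child, unsampled tumor-side mother
  expect_equal(
    infer_inheritance_side(coh$ped, family_genotypes(coh, vkey$n1483s, "J"),
      "5",
      family = "J"
    ),
    "tumor_side"
  )
  # rare TP53 variants entered through the married-in side
  expect_equal(
    infer_inheritance_side(coh$ped, family_genotypes(coh, vkey$tp53_rare[1], "O"),
      "17",
      family = "O"
    ),
    "non_tumor_side"
  )
  # X-linked: hemizygous affected man receives from the tumor-side mother
  expect_equal(
    infer_inheritance_side(coh$ped, family_genotypes(coh, vkey$ar, "Q"),
      "X",
      family = "Q"
    ),
    "tumor_side"
  )
  # both parents unsampled, founders unlabeled
  g_p <- family_genotypes(coh, vkey$rs, "P")
  g_p[["P_II-1"]] <- "het"
  expect_equal(
    infer_inheritance_side(coh$ped, g_p, "8", family = "P"),
    "undetermined"
  )
  expect_error(
    infer_inheritance_side(coh$ped, family_genotypes(coh, vkey$r185c, "P"),
      "2",
      family = "P"
    ),
    "no affected carrier"
  )
})

test_that("inheritance-side inference matches the enumeration oracle", {
  set.seed(202)
  n_checked <- 0
  for (i in 1:150) {
    chrom <- sample(c("2", "X"), 1)
    ped <- random_small_family(chrom, three_gen = i %% 3 == 0)
    gts <- gene_drop_genotypes(ped, chrom)
    ped$affection <- sample(c("brain_tumor", "unaffected"),
      nrow(ped),
      replace = TRUE
    )
    # mask a random subset as ungenotyped
    mask <- runif(nrow(ped)) < 0.4
    obs <- gts
    obs[mask] <- "missing"
    names(obs) <- ped$individual_id
    carriers <- ped$individual_id[obs %in% c("het", "hom_alt", "hemi_alt")]
    affected_carriers <- intersect(
      carriers, ped$individual_id[ped$affection == "brain_tumor"]
    )
    if (length(affected_carriers) == 0) next
    n_checked <- n_checked + 1
    expect_equal(
      infer_inheritance_side(ped, obs, chrom),
      oracle_side(ped, obs, chrom),
      info = paste0("case ", i, " chrom ", chrom)
    )
  }
  expect_gt(n_checked, 40)
})
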