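make_trio_ped <- function() {
  pedigree(tibble::tibble(
    family_id = "T", individual_id = c("dad", "mom", "kid"),
    father_id = c(NA, NA, "dad"), mother_id = c(NA, NA, "mom"),
    sex = c("male", "female", "male"), affection = "unaffected"
  ))
}

test_that("variant_table enforces its invariants", {
  expect_error(variant_table("2", 100, "A", "A"), "differ")
  expect_error(variant_table("2", 0, "A", "C"), ">= 1")
  expect_error(variant_table("25", 100, "A", "C"), "chromosome")
  expect_error(variant_table("2", 100, "A", "C", consequence = "weird"), "consequence")
  v <- variant_table(c("2", "X"), c(10, 20), c("A", "G"), c("C", "T"))
  expect_equal(v$variant_id, c("2:10:A:C", "X:20:G:T"))
})

test_that("read_vcf loads biallelic sites, missing calls and haploid X", {
  ped <- make_trio_ped()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", "dad", "mom", "kid"), collapse = "\t"),
    "2\t100\trs1\tA\tC\t.\tPASS\t.\tGT:DP\t0/1:30\t0/0:25\t./.:0",
    "X\t500\t.\tG\tT\t.\tPASS\t.\tGT:DP\t1:20\t0/1:22\t0:18"
  ), vcf)
  frag <- read_vcf(vcf, ped)
  expect_equal(nrow(frag$variants), 2)
  expect_equal(dim(frag$geno), c(2, 3))
  g <- frag$geno
  expect_equal(unname(g["2:100:A:C", ]), c(1L, 0L, NA))
  # haploid GT on X reads as hemizygous; female diploid stays diploid
  expect_equal(unname(g["X:500:G:T", ]), c(4L, 1L, 3L))
  expect_equal(unname(frag$depth["2:100:A:C", "dad"]), 30)
  # unknown sample name
  bad_ped <- ped[ped$individual_id != "kid", ]
  bad_ped <- pedigree(dplyr::mutate(bad_ped, father_id = NA_character_, mother_id = NA_character_))
  expect_error(read_vcf(vcf, bad_ped), "kid")
})

test_that("diploid male chrX calls are coerced to hemizygous with a warning", {
  ped <- make_trio_ped()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", "dad", "mom", "kid"), collapse = "\t"),
    "X\t500\t.\tG\tT\t.\tPASS\t.\tGT\t1/1\t0/1\t0/1"
  ), vcf)
  expect_warning(frag <- read_vcf(vcf, ped), "hemizygous")
  expect_equal(unname(frag$geno[1, ]), c(4L, 1L, NA))
})

test_that("multiallelic decomposition conserves alternate-allele carriers", {
  ped <- make_trio_ped()
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT", "dad", "mom", "kid"), collapse = "\t"),
    "7\t900\t.\tA\tC,G\t.\tPASS\t.\tGT\t1/2\t0/2\t0/1"
  ), vcf)
  frag <- read_vcf(vcf, ped)
  expect_equal(nrow(frag$variants), 2)
  expect_setequal(frag$variants$variant_id, c("7:900:A:C", "7:900:A:G"))
  carriers_per_record <- rowSums(matrix(
    famseg:::code_is_carrier(frag$geno),
    nrow = 2
  ))
  # every sample is a non-reference carrier at the original site
  expect_equal(sum(carriers_per_record >= 1), 2)
  expect_equal(unname(frag$geno["7:900:A:C", ]), c(1L, 0L, 1L))
  expect_equal(unname(frag$geno["7:900:A:G", ]), c(1L, 1L, 0L))
})

test_that("write_vcf / read_vcf round-trips genotypes bit-exactly", {
  coh <- fixture()
  out <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(coh, out)
  frag <- read_vcf(out, coh$ped)
  expect_setequal(rownames(frag$geno), rownames(coh$geno))
  ord <- rownames(coh$geno)
  expect_identical(frag$geno[ord, colnames(coh$geno)], coh$geno)
})

test_that("read_annotations parses predictor calls and validates frequencies", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  hdr <- c(
    "chrom", "pos", "ref", "alt", "af_fin", "af_nfe", "af_global",
    "SIFT", "PolyPhen", "LRT", "MutationTaster", "MutationAssessor",
    "FATHMM_MKL", "MetaSVM", "MetaLR", "cadd_phred"
  )
  writeLines(c(
    paste(hdr, collapse = "\t"),
    paste(c("2", "155099285", "C", "T", "8.0e-5", "7.7e-6", "1.8e-5",
      rep("damaging", 8), "31.0"), collapse = "\t"),
    paste(c("5", "16680150", "A", "G", "9.3e-5", "0", "8.0e-6",
      "tolerated", "damaging", "", rep("damaging", 5), "23.0"), collapse = "\t")
  ), tsv)
  ann <- read_annotations(tsv)
  r <- ann[ann$variant_id == "2:155099285:C:T", ]
  expect_equal(r$af_fin, 8.0e-5)
  expect_equal(r$cadd_phred, 31.0)
  expect_true(damaging_consensus(r, rule = "all"))
  # empty predictor cell reads as unavailable
  expect_true(is.na(ann$LRT[ann$variant_id == "5:16680150:A:G"]))
  # out-of-range frequency is rejected with the row identified
  writeLines(c(
    paste(hdr, collapse = "\t"),
    paste(c("2", "100", "A", "C", "1.2", "0", "0", rep("damaging", 8), "10"), collapse = "\t")
  ), tsv)
  expect_error(read_annotations(tsv), "af_fin.*row")
})

test_that("carrier and genotyped predicates follow the genotype alphabet", {
  expect_true(is_carrier("het"))
  expect_true(is_carrier("hemi_alt"))
  expect_false(is_carrier("hemi_ref"))
  expect_false(is_carrier("missing"))
  expect_false(is_genotyped("missing"))
  expect_true(is_genotyped("hom_ref"))
  expect_equal(is_carrier(c("het", NA, "hom_alt")), c(TRUE, FALSE, TRUE))
})

test_that("damaging_consensus evaluates available predictors under each rule", {
  coh <- fixture()
  ann <- coh$ann
  r185c <- ann[ann$variant_id == vkey$r185c, ] # 8/8
  n1483s <- ann[ann$variant_id == vkey$n1483s, ] # 6/7
  expect_true(damaging_consensus(r185c, "majority"))
  expect_true(damaging_consensus(r185c, "all"))
  expect_true(damaging_consensus(r185c, "at_least_k", k = 8))
  expect_true(damaging_consensus(n1483s, "majority"))
  expect_false(damaging_consensus(n1483s, "all"))
  zero <- r185c
  for (p in c("SIFT", "PolyPhen", "LRT", "MutationTaster", "MutationAssessor",
    "FATHMM_MKL", "MetaSVM", "MetaLR")) {
    zero[[p]] <- dplyr::if_else(is.na(zero[[p]]), NA_character_, "tolerated")
  }
  expect_false(damaging_consensus(zero, "majority"))
  none <- zero
  for (p in c("SIFT", "PolyPhen", "LRT", "MutationTaster", "MutationAssessor",
    "FATHMM_MKL", "MetaSVM", "MetaLR")) {
    none[[p]] <- NA_character_
  }
  expect_error(damaging_consensus(none), "available")
})

test_that("damaging_consensus is monotone in added damaging calls", {
  set.seed(5)
  preds <- c("SIFT", "PolyPhen", "LRT", "MutationTaster", "MutationAssessor",
    "FATHMM_MKL", "MetaSVM", "MetaLR")
  for (i in 1:50) {
    calls <- sample(c("damaging", "tolerated", NA), 8, replace = TRUE)
    if (all(is.na(calls) | calls != "damaging") && all(is.na(calls))) next
    base <- tibble::as_tibble(setNames(as.list(calls), preds))
    base$variant_id <- "v"
    if (sum(!is.na(calls)) == 0) next
    before <- damaging_consensus(base, "majority")
    flip <- which(is.na(calls) | calls == "tolerated")
    if (length(flip) == 0) next
    upgraded <- base
    upgraded[[preds[flip[1]]]] <- "damaging"
    after <- damaging_consensus(upgraded, "majority")
    expect_true(!before || after)
  }
})
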