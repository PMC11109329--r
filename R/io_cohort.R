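#' Write a cohort to plain-text files
#'
#' Emits `cohort.ped` + `cohort.fam.tsv` (pedigree core and extension
#' sidecar), `genotypes.vcf`, `variants.tsv` (the variant table with gene,
#' consequence and provenance), `annotations.tsv` and `risk_loci.tsv` into
#' `dir`. [read_cohort()] restores an identical cohort.
#'
#' @param x An `fs_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(x, dir) {
  stopifnot(inherits(x, "fs_cohort"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(dir, mode = 2) != 0) {
    abort(paste0("cannot write to directory: ", dir))
  }
  write_ped(x$ped, file.path(dir, "cohort.ped"), sidecar = file.path(dir, "cohort.fam.tsv"))
  write_vcf(x, file.path(dir, "genotypes.vcf"))
  readr::write_tsv(x$variants, file.path(dir, "variants.tsv"), progress = FALSE)
  if (!is.null(x$ann)) {
    ann <- x$variants |>
      select("variant_id", "chrom", "pos", "ref", "alt") |>
      inner_join(x$ann, by = "variant_id") |>
      select(-"variant_id")
    readr::write_tsv(ann, file.path(dir, "annotations.tsv"), progress = FALSE)
  }
  if (!is.null(x$risk_loci)) {
    readr::write_tsv(
      x$risk_loci |> select(-"variant_id"),
      file.path(dir, "risk_loci.tsv"),
      progress = FALSE
    )
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the files.
#' @return An `fs_cohort`.
#' @export
read_cohort <- function(dir) {
  ped <- read_ped(file.path(dir, "cohort.ped"), sidecar = file.path(dir, "cohort.fam.tsv"))
  variants <- readr::read_tsv(file.path(dir, "variants.tsv"),
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), rsid = readr::col_character(),
      gene = readr::col_character(), hgvs_c = readr::col_character(),
      hgvs_p = readr::col_character()
    )
  )
  frag <- read_vcf(file.path(dir, "genotypes.vcf"), ped)
  # restore gene/consequence/provenance from the variant table
  keep <- match(frag$variants$variant_id, variants$variant_id)
  if (anyNA(keep)) abort("genotypes.vcf and variants.tsv disagree on variant keys")
  vt <- variants[keep, , drop = FALSE]
  ann_path <- file.path(dir, "annotations.tsv")
  ann <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  risk_path <- file.path(dir, "risk_loci.tsv")
  risk <- if (file.exists(risk_path)) read_risk_loci(risk_path) else NULL
  cohort(ped, vt, frag$geno, annotations = ann, depths = frag$depth, risk_loci = risk)
}
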