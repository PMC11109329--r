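#' Run the full analysis pipeline
#'
#' Orchestrates the stages in discovery order: load inputs, targeted-genotype
#' QC, per-family segregation, all-criteria prioritization, risk-locus
#' detection / co-occurrence / PRS comparison, detection-power estimate and
#' (when read counts are supplied) the LOH screen. Every filter stage logs
#' variants-in/variants-out; all tables are written as TSV into `out_dir`.
#' Deterministic given `seed`.
#'
#' @param config Either a named list or a YAML file path with entries:
#'   `ped`, `sidecar`, `vcf`, `variants` (variant TSV carrying gene,
#'   consequence and provenance), `annotations`, `risk_loci` (paths; alternatively
#'   pass `cohort_dir` for a [write_cohort()] directory), optional
#'   `loh_counts` (TSV of read counts), `filter` and `criteria` (parameter
#'   lists for [filter_config()] / [prioritization_criteria()]), `power`
#'   (list with `p`, `n_families`, `rule`, `n_sim`), `prs` (list with
#'   `n_perm`, `scheme`, `exclude`), `seed` and `out_dir`.
#' @param cohort Optionally, an already-assembled `fs_cohort` (paths in
#'   `config` are then ignored).
#' @return Invisibly, the report bundle: list with `cohort`, `qc`,
#'   `candidates`, `detection`, `co_occurrence`, `prs_test`, `power`, `loh`,
#'   `log`.
#' @export
run_pipeline <- function(config = list(), cohort = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% tempfile("famseg_run_")
  seed <- config$seed %||% 1L

  if (is.null(cohort)) {
    if (!is.null(config$cohort_dir)) {
      check_exists(config$cohort_dir, "cohort_dir")
      cohort <- read_cohort(config$cohort_dir)
    } else {
      for (f in c("ped", "vcf", "annotations")) check_exists(config[[f]], f)
      for (f in c("sidecar", "risk_loci", "variants")) {
        if (!is.null(config[[f]])) check_exists(config[[f]], f)
      }
      ped <- read_ped(config$ped, sidecar = config$sidecar)
      frag <- read_vcf(config$vcf, ped)
      vt <- frag$variants
      if (!is.null(config$variants)) {
        # gene / consequence / provenance live in the variant TSV, not the VCF
        extra <- readr::read_tsv(config$variants,
          show_col_types = FALSE, progress = FALSE,
          col_types = readr::cols(
            chrom = readr::col_character(), ref = readr::col_character(),
            alt = readr::col_character(), gene = readr::col_character()
          )
        )
        keep <- match(vt$variant_id, extra$variant_id)
        for (col in intersect(
          c("gene", "hgvs_c", "hgvs_p", "consequence", "source", "rsid"),
          names(extra)
        )) {
          vt[[col]] <- dplyr::coalesce(extra[[col]][keep], vt[[col]])
        }
      }
      ann <- read_annotations(config$annotations)
      risk <- if (!is.null(config$risk_loci)) read_risk_loci(config$risk_loci) else NULL
      cohort <- cohort(ped, vt, frag$geno,
        annotations = ann,
        depths = frag$depth, risk_loci = risk
      )
    }
  }
  if (!is.null(config$loh_counts)) check_exists(config$loh_counts, "loh_counts")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, n_in = n_in, n_out = n_out)
  }

  fcfg <- do.call(filter_config, config$filter %||% list())
  crit <- do.call(prioritization_criteria, config$criteria %||% list())

  n0 <- nrow(cohort$variants)
  qc <- qc_targeted(cohort, fcfg)
  cohort_qc <- subset_variants(cohort, qc$kept)
  note("genotype_qc", n0, length(qc$kept))
  readr::write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"), progress = FALSE)

  cand <- prioritize_variants(cohort_qc, crit)
  note("prioritize", length(qc$kept), nrow(cand$variants))
  readr::write_tsv(cand$variants, file.path(out_dir, "candidates.tsv"), progress = FALSE)
  readr::write_tsv(cand$genes, file.path(out_dir, "candidate_genes.tsv"), progress = FALSE)
  readr::write_tsv(cand$segregation, file.path(out_dir, "segregation.tsv"), progress = FALSE)

  detection <- NULL
  coocc <- NULL
  prs_test <- NULL
  if (!is.null(cohort_qc$risk_loci) && nrow(cohort_qc$risk_loci) > 0) {
    loci <- cohort_qc$risk_loci[cohort_qc$risk_loci$variant_id %in% rownames(cohort_qc$geno), ]
    if (nrow(loci) > 0) {
      detection <- detection_summary(cohort_qc, loci)
      coocc <- co_occurrence(cohort_qc, cand, loci)
      prs_cfg <- config$prs %||% list()
      prs_test <- prs_compare(cohort_qc,
        loci = loci,
        n_perm = prs_cfg$n_perm %||% 999,
        scheme = prs_cfg$scheme %||% "within_family",
        exclude = prs_cfg$exclude, seed = seed
      )
      readr::write_tsv(detection, file.path(out_dir, "risk_locus_detection.tsv"), progress = FALSE)
      readr::write_tsv(coocc, file.path(out_dir, "co_occurrence.tsv"), progress = FALSE)
      readr::write_tsv(tidy(prs_test), file.path(out_dir, "prs.tsv"), progress = FALSE)
      readr::write_tsv(glance(prs_test), file.path(out_dir, "prs_test.tsv"), progress = FALSE)
    }
  }

  pw_cfg <- config$power %||% list()
  pw <- power_mc(
    p = pw_cfg$p %||% 0.2,
    n_families = pw_cfg$n_families %||% length(unique(cohort$ped$family_id)),
    rule = pw_cfg$rule %||% "any_family_carries",
    n_sim = pw_cfg$n_sim %||% 1e5, seed = seed
  )
  readr::write_tsv(
    tibble(power = pw$power, se = pw$se, ci_lo = pw$ci[1], ci_hi = pw$ci[2]),
    file.path(out_dir, "power.tsv"),
    progress = FALSE
  )

  loh <- NULL
  if (!is.null(config$loh_counts)) {
    counts <- readr::read_tsv(config$loh_counts, show_col_types = FALSE, progress = FALSE)
    loh <- loh_screen(counts, alpha = config$loh_alpha %||% 0.05)
    readr::write_tsv(loh, file.path(out_dir, "loh.tsv"), progress = FALSE)
  }

  log_tbl <- bind_rows(log)
  readr::write_tsv(log_tbl, file.path(out_dir, "stage_log.tsv"), progress = FALSE)
  invisible(list(
    cohort = cohort_qc, qc = qc, candidates = cand, detection = detection,
    co_occurrence = coocc, prs_test = prs_test, power = pw, loh = loh,
    log = log_tbl, out_dir = out_dir
  ))
}

check_exists <- function(path, what) {
  if (is.null(path)) abort(paste0("config entry `", what, "` is required"))
  if (!file.exists(path)) abort(paste0(what, " not found: ", path))
  invisible(path)
}
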