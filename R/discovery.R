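#' Discovery-stage filter configuration
#'
#' Thresholds for the exome discovery cascade: the Finnish-population allele
#' frequency cutoff (strict `<`, default 0.01, matching the prioritization
#' rarity criterion), the consequence classes counted as protein-altering,
#' how the two variant callers' sets are merged (default `"union"`, the
#' sensitivity-maximizing choice at discovery), and targeted-panel genotype QC
#' thresholds (call rate >= 0.9, median depth >= 10 by default; both
#' config-exposed).
#'
#' @param discovery_af_max Strict upper bound on `af_fin`.
#' @param protein_altering Consequence classes retained by the functional
#'   filter.
#' @param caller_merge_mode `"union"` or `"intersection"`.
#' @param qc_min_call_rate,qc_min_depth Targeted-panel QC thresholds.
#' @return A `filter_config` list.
#' @export
filter_config <- function(discovery_af_max = 0.01,
                          protein_altering = c("missense", "frameshift", "stopgain", "splice"),
                          caller_merge_mode = c("union", "intersection"),
                          qc_min_call_rate = 0.9, qc_min_depth = 10) {
  stopifnot(
    discovery_af_max >= 0, discovery_af_max <= 1,
    qc_min_call_rate >= 0, qc_min_call_rate <= 1, qc_min_depth >= 0
  )
  bad <- setdiff(protein_altering, CONSEQUENCES)
  if (length(bad) > 0) abort(paste0("unknown consequence class(es): ", paste(bad, collapse = ", ")))
  structure(
    list(
      discovery_af_max = discovery_af_max,
      protein_altering = protein_altering,
      caller_merge_mode = match.arg(caller_merge_mode),
      qc_min_call_rate = qc_min_call_rate,
      qc_min_depth = qc_min_depth
    ),
    class = "filter_config"
  )
}

#' Merge two caller variant sets
#'
#' Combines the variant keys reported by two callers by union (default;
#' maximizes discovery sensitivity) or intersection.
#'
#' @param a,b Character vectors of variant keys, or tibbles with a
#'   `variant_id` column.
#' @param mode `"union"` or `"intersection"`.
#' @return Character vector of variant keys.
#' @export
merge_callsets <- function(a, b, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  key <- function(x) if (is.data.frame(x)) x$variant_id else as.character(x)
  if (mode == "union") union(key(a), key(b)) else intersect(key(a), key(b))
}

#' Apply the discovery frequency/functional filter
#'
#' Retains variants with Finnish-population allele frequency strictly below
#' `discovery_af_max` (a variant absent from the frequency panel counts as
#' frequency 0, i.e. never observed) whose consequence is in the
#' protein-altering set.
#'
#' @param x An `fs_cohort` (with annotations).
#' @param cfg A [filter_config()].
#' @return Character vector of retained variant keys.
#' @export
filter_discovery <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "fs_cohort"))
  if (is.null(x$ann)) abort("cohort has no annotation table")
  tab <- x$variants |>
    left_join(x$ann, by = "variant_id") |>
    mutate(af_fin = dplyr::coalesce(.data$af_fin, 0))
  tab$variant_id[tab$af_fin < cfg$discovery_af_max &
    tab$consequence %in% cfg$protein_altering]
}

#' Is a variant shared by the affected members of a family?
#'
#' `TRUE` iff every genotyped affected member of the family carries the
#' variant and at least one affected carrier exists. Missing genotypes drop
#' out of the denominator. A family with no genotyped affected member is
#' uninformative and returns `NA`.
#'
#' @param x An `fs_cohort`.
#' @param variant Variant key.
#' @param family Family id.
#' @return Logical scalar (`NA` when the family is uninformative).
#' @export
shared_in_family <- function(x, variant, family) {
  stopifnot(inherits(x, "fs_cohort"))
  if (!variant %in% rownames(x$geno)) abort(paste0("variant not in genotype matrix: ", variant))
  aff <- x$ped$individual_id[x$ped$family_id == family &
    x$ped$affection == "brain_tumor"]
  aff <- intersect(aff, colnames(x$geno))
  g <- x$geno[variant, aff]
  typed <- !is.na(g)
  if (!any(typed)) {
    return(NA)
  }
  carriers <- code_is_carrier(g[typed])
  all(carriers) && any(carriers)
}

#' Assemble the targeted sequencing panel
#'
#' Panel = exome candidates that pass the discovery filter and are shared by
#' the affected members of at least one sequenced family, plus the literature
#' variants and gene regions (e.g. TP53 coding intervals), each with its
#' provenance preserved.
#'
#' @param x Discovery `fs_cohort`.
#' @param cfg A [filter_config()].
#' @param literature Character vector of literature variant keys.
#' @param regions Optional tibble of 1-based inclusive intervals
#'   (`chrom`, `start`, `end`, `label`).
#' @return A `panel_spec` list with `wes_candidates`, `literature`, `regions`.
#' @export
build_panel <- function(x, cfg = filter_config(), literature = character(),
                        regions = NULL) {
  filtered <- filter_discovery(x, cfg)
  fams <- unique(x$ped$family_id)
  shared_any <- vapply(filtered, function(v) {
    any(vapply(fams, function(f) isTRUE(shared_in_family(x, v, f)), logical(1)))
  }, logical(1))
  structure(
    list(
      wes_candidates = filtered[shared_any],
      literature = as.character(literature),
      regions = if (is.null(regions)) {
        tibble(chrom = character(), start = integer(), end = integer(), label = character())
      } else {
        as_tibble(regions)
      }
    ),
    class = "panel_spec"
  )
}

#' Targeted-panel genotype quality control
#'
#' Drops panel variants whose call rate falls below `qc_min_call_rate` or
#' whose median read depth (when depths are available) falls below
#' `qc_min_depth`, and reports every drop with its reason.
#'
#' @param x An `fs_cohort` of targeted genotypes.
#' @param cfg A [filter_config()].
#' @return List with `kept` (variant keys) and `report` (tibble with
#'   `variant_id`, `call_rate`, `median_depth`, `kept`, `reason`).
#' @export
qc_targeted <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "fs_cohort"))
  # call rate is over the sequenced samples: individuals without genotype
  # data (sampled = FALSE) are not attempted calls
  sampled <- x$ped$individual_id[x$ped$sampled]
  g <- x$geno[, intersect(colnames(x$geno), sampled), drop = FALSE]
  call_rate <- rowMeans(!is.na(g))
  med_depth <- if (!is.null(x$depth)) {
    d <- x$depth[, colnames(g), drop = FALSE]
    apply(d, 1, function(di) median(di, na.rm = TRUE))
  } else {
    rep(NA_real_, nrow(g))
  }
  low_cr <- call_rate < cfg$qc_min_call_rate
  low_dp <- !is.na(med_depth) & med_depth < cfg$qc_min_depth
  report <- tibble(
    variant_id = rownames(g),
    call_rate = call_rate,
    median_depth = med_depth,
    kept = !(low_cr | low_dp),
    reason = case_when(
      low_cr & low_dp ~ "call rate and median depth below threshold",
      low_cr ~ "call rate below threshold",
      low_dp ~ "median depth below threshold",
      TRUE ~ NA_character_
    )
  )
  list(kept = report$variant_id[report$kept], report = report)
}

#' Drop variants from a cohort
#'
#' Restricts a cohort to the given variant keys (used after QC and panel
#' assembly).
#'
#' @param x An `fs_cohort`.
#' @param keep Character vector of variant keys to retain.
#' @return The restricted `fs_cohort`.
#' @export
subset_variants <- function(x, keep) {
  stopifnot(inherits(x, "fs_cohort"))
  x$variants <- x$variants[x$variants$variant_id %in% keep, , drop = FALSE]
  x$geno <- x$geno[rownames(x$geno) %in% keep, , drop = FALSE]
  if (!is.null(x$depth)) x$depth <- x$depth[rownames(x$geno), , drop = FALSE]
  if (!is.null(x$ann)) x$ann <- x$ann[x$ann$variant_id %in% keep, , drop = FALSE]
  x
}
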