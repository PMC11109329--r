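#' Risk-locus table
#'
#' Previously reported (literature/GWAS) risk loci: variant key, the risk
#' allele (which may be the reference allele), the published per-allele odds
#' ratio and a source label.
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @param risk_allele Risk allele (must equal `ref` or `alt`).
#' @param odds_ratio Published odds ratio (> 0, finite).
#' @param source Source label (e.g. the reporting study).
#' @return Tibble keyed by `variant_id`.
#' @export
risk_locus_table <- function(chrom, pos, ref, alt, risk_allele, odds_ratio,
                             source = NA_character_) {
  if (any(!is.finite(odds_ratio) | odds_ratio <= 0)) {
    abort("odds_ratio must be finite and > 0")
  }
  if (any(risk_allele != ref & risk_allele != alt)) {
    abort("risk_allele must equal ref or alt")
  }
  tibble(
    variant_id = variant_key(chrom, pos, ref, alt),
    chrom = normalize_chrom(chrom), pos = as.integer(pos), ref = ref, alt = alt,
    risk_allele = risk_allele, odds_ratio = odds_ratio,
    source = rep_len(source, length(odds_ratio))
  )
}

#' Read a risk-locus TSV
#'
#' Columns: `chrom pos ref alt risk_allele odds_ratio source`.
#'
#' @param path Path to the TSV.
#' @return Risk-locus tibble.
#' @export
read_risk_loci <- function(path) {
  x <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(), risk_allele = readr::col_character()
    )
  )
  risk_locus_table(
    x$chrom, x$pos, x$ref, x$alt, x$risk_allele, x$odds_ratio,
    source = x$source %||% NA_character_
  )
}

# risk-allele dosage matrix for given loci: rows = variant_id, cols = individual
risk_dosage <- function(x, loci) {
  miss <- setdiff(loci$variant_id, rownames(x$geno))
  if (length(miss) > 0) {
    abort(paste0("risk locus/loci not genotyped in cohort: ", paste(miss, collapse = ", ")))
  }
  g <- x$geno[loci$variant_id, , drop = FALSE]
  d <- matrix(code_dosage(g), nrow = nrow(g), dimnames = dimnames(g))
  flip <- loci$risk_allele == loci$ref
  if (any(flip)) {
    # dosage of the reference allele: diploid 2 - alt dose, hemizygous 1 - alt
    ploidy <- matrix(ifelse(!is.na(g) & g >= 3L, 1, 2), nrow = nrow(g))
    d[flip, ] <- (ploidy - d)[flip, ]
  }
  d
}

#' Per-variant detection summary of risk loci
#'
#' For each risk locus: how many genotyped affected individuals carry the risk
#' allele, in how many distinct families, whether the locus was detected in
#' any affected individual or only in unaffected members, and zygosity tallies
#' (heterozygous / homozygous / hemizygous risk-allele carriers) among
#' affected and unaffected members separately.
#'
#' @param x An `fs_cohort`.
#' @param loci Risk-locus tibble (default: the cohort's own).
#' @return Tibble, one row per risk locus.
#' @export
detection_summary <- function(x, loci = NULL) {
  stopifnot(inherits(x, "fs_cohort"))
  loci <- loci %||% x$risk_loci
  if (is.null(loci)) abort("no risk loci supplied or stored in cohort")
  d <- risk_dosage(x, loci)
  g <- x$geno[loci$variant_id, , drop = FALSE]
  ped <- x$ped
  aff_ids <- intersect(ped$individual_id[ped$affection == "brain_tumor"], colnames(d))
  una_ids <- intersect(ped$individual_id[ped$affection == "unaffected"], colnames(d))
  fam_of <- setNames(ped$family_id, ped$individual_id)
  zyg <- function(dose, code) {
    hemi <- !is.na(code) & code >= 3L
    list(
      het = sum(dose == 1 & !hemi, na.rm = TRUE),
      hom = sum(dose == 2, na.rm = TRUE),
      hemi = sum(dose == 1 & hemi, na.rm = TRUE)
    )
  }
  purrr::map(seq_len(nrow(loci)), function(i) {
    da <- d[i, aff_ids]
    du <- d[i, una_ids]
    carriers_aff <- aff_ids[!is.na(da) & da > 0]
    carriers_una <- una_ids[!is.na(du) & du > 0]
    za <- zyg(da, g[i, aff_ids])
    zu <- zyg(du, g[i, una_ids])
    tibble(
      variant_id = loci$variant_id[i],
      n_affected_carriers = length(carriers_aff),
      n_affected_genotyped = sum(!is.na(da)),
      n_families_affected = dplyr::n_distinct(fam_of[carriers_aff]),
      n_unaffected_carriers = length(carriers_una),
      detected_in_affected = length(carriers_aff) > 0,
      unaffected_only = length(carriers_aff) == 0 & length(carriers_una) > 0,
      het_affected = za$het, hom_affected = za$hom, hemi_affected = za$hemi,
      het_unaffected = zu$het, hom_unaffected = zu$hom, hemi_unaffected = zu$hemi
    )
  }) |> bind_rows()
}

#' Co-occurrence of rare candidate variants and risk alleles
#'
#' Per family x risk locus: does at least one affected member carry both a
#' prioritized candidate variant and the risk allele? Lists the candidate
#' genes observed in such affected members.
#'
#' @param x An `fs_cohort`.
#' @param candidates An `fs_candidates` ([prioritize_variants()]).
#' @param loci Risk-locus tibble (default: the cohort's own).
#' @return Tibble with `family_id`, `risk_variant`, `co_occurs`,
#'   `candidate_genes`.
#' @export
co_occurrence <- function(x, candidates, loci = NULL) {
  stopifnot(inherits(x, "fs_cohort"), inherits(candidates, "fs_candidates"))
  loci <- loci %||% x$risk_loci
  if (is.null(loci)) abort("no risk loci supplied or stored in cohort")
  d <- risk_dosage(x, loci)
  ped <- x$ped
  aff <- ped[ped$affection == "brain_tumor", ]
  cand_ids <- intersect(candidates$variants$variant_id, rownames(x$geno))
  gene_of <- setNames(candidates$variants$gene, candidates$variants$variant_id)
  cg <- x$geno[cand_ids, , drop = FALSE]
  out <- list()
  for (f in unique(ped$family_id)) {
    members <- intersect(aff$individual_id[aff$family_id == f], colnames(d))
    for (i in seq_len(nrow(loci))) {
      risk_carr <- members[!is.na(d[i, members]) & d[i, members] > 0]
      genes <- character()
      for (ind in risk_carr) {
        has <- cand_ids[code_is_carrier(cg[, ind])]
        genes <- union(genes, unname(gene_of[has]))
      }
      out[[length(out) + 1L]] <- tibble(
        family_id = f, risk_variant = loci$variant_id[i],
        co_occurs = length(genes) > 0,
        candidate_genes = paste(sort(genes), collapse = ",")
      )
    }
  }
  bind_rows(out)
}

#' Polygenic risk score
#'
#' Standard log-additive score: for each individual the sum over loci of the
#' risk-allele dosage times `ln(odds_ratio)`. Diploid dosage is 0/1/2;
#' hemizygous male X genotypes contribute 0/1 (no doubling). A missing
#' genotype contributes 0 and is reflected in the `completeness` field
#' (fraction of loci genotyped).
#'
#' @param x An `fs_cohort`.
#' @param loci Risk-locus tibble (default: the cohort's own).
#' @param exclude Variant keys to drop (e.g. a single high-OR locus).
#' @return Tibble with `individual_id`, `family_id`, `affection`, `score`,
#'   `n_loci`, `completeness`.
#' @export
prs <- function(x, loci = NULL, exclude = NULL) {
  stopifnot(inherits(x, "fs_cohort"))
  loci <- loci %||% x$risk_loci
  if (is.null(loci)) abort("no risk loci supplied or stored in cohort")
  if (!is.null(exclude)) loci <- loci[!loci$variant_id %in% exclude, , drop = FALSE]
  if (nrow(loci) == 0) abort("no risk loci left to score")
  d <- risk_dosage(x, loci)
  typed <- colSums(!is.na(d))
  if (all(typed == 0)) abort("no individual genotyped at any risk locus")
  # an individual is scored only when genotyped at >= 1 locus
  d <- d[, typed > 0, drop = FALSE]
  typed <- typed[colnames(d)]
  w <- log(loci$odds_ratio)
  d0 <- d
  d0[is.na(d0)] <- 0
  score <- as.vector(crossprod(d0, w))
  tibble(
    individual_id = colnames(d),
    family_id = x$ped$family_id[match(colnames(d), x$ped$individual_id)],
    affection = x$ped$affection[match(colnames(d), x$ped$individual_id)],
    score = score,
    n_loci = nrow(loci),
    completeness = typed / nrow(loci)
  )
}

#' Permutation comparison of PRS between affected and unaffected
#'
#' Statistic: difference of group mean scores (affected minus unaffected).
#' The null is built by permuting affection labels, by default within
#' families (preserving each family's affected/unaffected counts exactly, to
#' respect relatedness), or pooled across the cohort. Two-sided p-value
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`; deterministic under `seed`.
#'
#' @param x An `fs_cohort`.
#' @param loci Risk-locus tibble (default: the cohort's own).
#' @param n_perm Number of permutations.
#' @param scheme `"within_family"` or `"pooled"`.
#' @param exclude Risk loci to drop before scoring (e.g. `rs55705857`'s key).
#' @param exclude_families Families to drop entirely (e.g. all carriers of a
#'   given locus).
#' @param seed Optional integer seed.
#' @return An `fs_prs_compare` object; `tidy()` returns per-individual scores,
#'   `glance()` the test summary.
#' @export
prs_compare <- function(x, loci = NULL, n_perm = 999,
                        scheme = c("within_family", "pooled"),
                        exclude = NULL, exclude_families = NULL, seed = NULL) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) abort("n_perm must be >= 1")
  scores <- prs(x, loci = loci, exclude = exclude)
  if (!is.null(exclude_families)) {
    scores <- scores[!scores$family_id %in% exclude_families, , drop = FALSE]
  }
  scores <- scores[scores$affection %in% c("brain_tumor", "unaffected"), , drop = FALSE]
  is_aff <- scores$affection == "brain_tumor"
  if (sum(is_aff) == 0 || sum(!is_aff) == 0) {
    abort("need at least one affected and one unaffected scored individual")
  }
  stat <- function(aff_flag) {
    mean(scores$score[aff_flag]) - mean(scores$score[!aff_flag])
  }
  observed <- stat(is_aff)
  fam_idx <- split(seq_len(nrow(scores)), scores$family_id)
  perm_stats <- with_seed_local(seed, {
    vapply(seq_len(n_perm), function(i) {
      flag <- is_aff
      if (scheme == "pooled") {
        flag <- sample(is_aff)
      } else {
        for (idx in fam_idx) flag[idx] <- sample(is_aff[idx])
      }
      stat(flag)
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm_stats) >= abs(observed))) / (n_perm + 1)
  structure(
    list(
      scores = scores, observed = observed,
      group_means = c(
        affected = mean(scores$score[is_aff]),
        unaffected = mean(scores$score[!is_aff])
      ),
      perm_stats = perm_stats, p_value = p, n_perm = n_perm,
      scheme = scheme, seed = seed, excluded = exclude
    ),
    class = "fs_prs_compare"
  )
}

#' @export
print.fs_prs_compare <- function(x, ...) {
  cat("<fs_prs_compare> difference of mean PRS (affected - unaffected)\n")
  cat(sprintf(
    "  observed = %.4f, p = %.4g (%d permutations, %s)\n",
    x$observed, x$p_value, x$n_perm, x$scheme
  ))
  invisible(x)
}

#' @rdname prs_compare
#' @param ... Unused.
#' @method tidy fs_prs_compare
#' @export
tidy.fs_prs_compare <- function(x, ...) x$scores

#' @rdname prs_compare
#' @method glance fs_prs_compare
#' @export
glance.fs_prs_compare <- function(x, ...) {
  tibble(
    statistic = x$observed,
    mean_affected = unname(x$group_means["affected"]),
    mean_unaffected = unname(x$group_means["unaffected"]),
    p_value = x$p_value, n_perm = x$n_perm, scheme = x$scheme
  )
}
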