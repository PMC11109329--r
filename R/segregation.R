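#' Prioritization criteria
#'
#' The all-criteria rule set for calling a variant a candidate: rare in the
#' Finnish population (strict `< af_fin_max`), shared by the genotyped
#' affected members of every family that supports it, observed in affected
#' individuals in at least `min_families` families (counted at the variant
#' level or, with `gene_level_aggregation`, pooled over a gene's qualifying
#' variants), inherited from the tumor side, predicted damaging by the
#' consensus rule, and located in a gene with curated relevance to brain or
#' glioma. Every enabled criterion must hold (AND logic).
#'
#' @param af_fin_max Strict upper bound on Finnish allele frequency.
#' @param min_families Minimum number of distinct supporting families.
#' @param require_shared Require complete sharing among genotyped affecteds in
#'   every supporting family.
#' @param require_tumor_side `"all_determinable"` (default: no supporting
#'   family may resolve to the non-tumor side; undetermined families do not
#'   veto), `"at_least_one"` (at least one supporting family must resolve to
#'   the tumor side), or `"none"`.
#' @param damaging_rule,damaging_k Consensus rule passed to
#'   [damaging_consensus()]; variants with no available predictor fail the
#'   criterion.
#' @param require_gene_relevance Require `brain_expressed` or
#'   `glioma_relevant`.
#' @param gene_level_aggregation Count family support over all of a gene's
#'   qualifying variants (a family counts once).
#' @return A `prioritization_criteria` list.
#' @export
prioritization_criteria <- function(af_fin_max = 0.01, min_families = 2,
                                    require_shared = TRUE,
                                    require_tumor_side = c("all_determinable", "at_least_one", "none"),
                                    damaging_rule = c("majority", "all", "at_least_k"),
                                    damaging_k = NULL,
                                    require_gene_relevance = TRUE,
                                    gene_level_aggregation = TRUE) {
  stopifnot(min_families >= 1, af_fin_max >= 0, af_fin_max <= 1)
  structure(
    list(
      af_fin_max = af_fin_max, min_families = as.integer(min_families),
      require_shared = isTRUE(require_shared),
      require_tumor_side = match.arg(require_tumor_side),
      damaging_rule = match.arg(damaging_rule), damaging_k = damaging_k,
      require_gene_relevance = isTRUE(require_gene_relevance),
      gene_level_aggregation = isTRUE(gene_level_aggregation)
    ),
    class = "prioritization_criteria"
  )
}

seg_counts_family <- function(x, family, variants = NULL) {
  g <- x$geno
  if (!is.null(variants)) g <- g[variants, , drop = FALSE]
  p <- x$ped[x$ped$family_id == family, ]
  aff <- intersect(p$individual_id[p$affection == "brain_tumor"], colnames(g))
  una <- intersect(p$individual_id[p$affection == "unaffected"], colnames(g))
  ga <- g[, aff, drop = FALSE]
  gu <- g[, una, drop = FALSE]
  n_aff_gt <- rowSums(!is.na(ga))
  n_aff_carr <- rowSums(matrix(code_is_carrier(ga), nrow = nrow(g)))
  n_una_gt <- rowSums(!is.na(gu))
  n_una_carr <- rowSums(matrix(code_is_carrier(gu), nrow = nrow(g)))
  tibble(
    family_id = family,
    variant_id = rownames(g),
    n_affected_genotyped = unname(n_aff_gt),
    n_affected_carriers = unname(n_aff_carr),
    shared_by_affected = unname(if_else(n_aff_gt > 0, n_aff_carr == n_aff_gt & n_aff_carr > 0, NA)),
    n_unaffected_genotyped = unname(n_una_gt),
    n_unaffected_carriers = unname(n_una_carr)
  )
}

side_for <- function(x, variant, family) {
  p <- x$ped[x$ped$family_id == family, ]
  g <- x$geno[variant, intersect(p$individual_id, colnames(x$geno))]
  chrom <- x$variants$chrom[match(variant, x$variants$variant_id)]
  aff <- p$affection[match(names(g), p$individual_id)]
  if (!any(code_is_carrier(g) & aff == "brain_tumor")) {
    return("undetermined")
  }
  infer_inheritance_side(p, setNames(code_to_gt(g), names(g)), chrom)
}

#' Classify segregation of a variant in one family
#'
#' Counts carriers among genotyped affected and unaffected members, tests
#' complete sharing among affecteds, infers the inheritance side
#' ([infer_inheritance_side()]) and assigns a penetrance class: `incomplete`
#' iff at least one unaffected member carries the variant, `not_assessable`
#' when nobody carries it, `complete` otherwise.
#'
#' @param x An `fs_cohort`.
#' @param variant Variant key.
#' @param family Family id.
#' @return One-row segregation tibble.
#' @export
classify <- function(x, variant, family) {
  stopifnot(inherits(x, "fs_cohort"))
  if (!variant %in% rownames(x$geno)) {
    abort(paste0("variant not in genotype matrix: ", variant))
  }
  counts <- seg_counts_family(x, family, variants = variant)
  counts |>
    mutate(
      inheritance_side = side_for(x, variant, family),
      penetrance_class = case_when(
        .data$n_affected_carriers + .data$n_unaffected_carriers == 0 ~ "not_assessable",
        .data$n_unaffected_carriers >= 1 ~ "incomplete",
        TRUE ~ "complete"
      )
    ) |>
    select("family_id", "variant_id", dplyr::everything())
}

#' Per-family segregation table for many variants
#'
#' Vectorized [classify()] over variants x families. Rows are emitted for
#' families with at least one genotype call for the variant. Side inference is
#' optional because it is the only per-cell non-vectorized step.
#'
#' @param x An `fs_cohort`.
#' @param variants Optional variant keys (default: all).
#' @param families Optional family ids (default: all).
#' @param side Compute `inheritance_side` (default `TRUE`).
#' @return Segregation tibble, one row per variant x family.
#' @export
segregation_table <- function(x, variants = NULL, families = NULL, side = TRUE) {
  stopifnot(inherits(x, "fs_cohort"))
  families <- families %||% unique(x$ped$family_id)
  variants <- variants %||% rownames(x$geno)
  out <- purrr::map(families, seg_counts_family, x = x, variants = variants) |>
    bind_rows() |>
    filter(.data$n_affected_genotyped + .data$n_unaffected_genotyped > 0)
  out <- out |>
    mutate(
      penetrance_class = case_when(
        .data$n_affected_carriers + .data$n_unaffected_carriers == 0 ~ "not_assessable",
        .data$n_unaffected_carriers >= 1 ~ "incomplete",
        TRUE ~ "complete"
      )
    )
  if (side) {
    out$inheritance_side <- purrr::map2_chr(
      out$variant_id, out$family_id,
      function(v, f) side_for(x, v, f)
    )
  }
  out
}

#' Number of families supporting a variant
#'
#' A family supports a variant through affected carriers only: the count is
#' the number of distinct families with at least one affected carrier.
#' Unaffected-only carriage contributes nothing.
#'
#' @param x An `fs_cohort`.
#' @param variant Variant key.
#' @return Integer count.
#' @export
families_supporting <- function(x, variant) {
  stopifnot(inherits(x, "fs_cohort"))
  fams <- unique(x$ped$family_id)
  sum(vapply(fams, function(f) {
    seg_counts_family(x, f, variants = variant)$n_affected_carriers > 0
  }, logical(1)))
}

#' Family support of a gene over its qualifying variants
#'
#' A qualifying variant passes every per-variant criterion except the
#' family-count threshold; the gene's support is the union over its
#' qualifying variants of families with at least one affected carrier (a
#' family counts once even if it carries several of the gene's variants).
#'
#' @param x An `fs_cohort`.
#' @param gene Gene symbol.
#' @param criteria A [prioritization_criteria()].
#' @return List with `n_families`, `families` and `qualifying_variants`.
#' @export
gene_support <- function(x, gene, criteria = prioritization_criteria()) {
  pr <- prioritize_internal(x, criteria)
  qual <- pr$per_variant |>
    filter(.data$gene %in% !!gene, .data$qualifies)
  fams <- pr$support |>
    filter(.data$variant_id %in% qual$variant_id) |>
    pull("family_id") |>
    unique()
  list(
    n_families = length(fams), families = sort(fams),
    qualifying_variants = qual$variant_id
  )
}

prioritize_internal <- function(x, criteria) {
  if (is.null(x$ann)) abort("cohort has no annotation table")
  tab <- x$variants |>
    filter(.data$variant_id %in% rownames(x$geno)) |>
    left_join(x$ann, by = "variant_id") |>
    mutate(af_fin = dplyr::coalesce(.data$af_fin, 0))

  counts <- predictor_counts(tab)
  damaging <- rep(FALSE, nrow(tab))
  avail <- counts$n_predictors > 0
  if (any(avail)) {
    damaging[avail] <- damaging_consensus(
      tab[avail, , drop = FALSE],
      rule = criteria$damaging_rule, k = criteria$damaging_k
    )
  }
  tab$crit_rare <- tab$af_fin < criteria$af_fin_max
  tab$crit_damaging <- damaging
  tab$crit_gene_relevance <- if (criteria$require_gene_relevance) {
    dplyr::coalesce(tab$brain_expressed, FALSE) | dplyr::coalesce(tab$glioma_relevant, FALSE)
  } else {
    TRUE
  }

  seg <- segregation_table(x, variants = tab$variant_id, side = FALSE)
  support <- seg |> filter(.data$n_affected_carriers > 0)
  support_n <- support |>
    dplyr::count(.data$variant_id, name = "n_supporting_families")
  shared_ok <- support |>
    group_by(.data$variant_id) |>
    summarise(crit_shared = all(.data$shared_by_affected), .groups = "drop")

  tab <- tab |>
    left_join(support_n, by = "variant_id") |>
    left_join(shared_ok, by = "variant_id") |>
    mutate(
      n_supporting_families = dplyr::coalesce(.data$n_supporting_families, 0L),
      crit_shared = if (criteria$require_shared) {
        dplyr::coalesce(.data$crit_shared, FALSE)
      } else {
        TRUE
      },
      crit_support_any = .data$n_supporting_families >= 1
    )

  # inheritance side: only evaluated for variants still alive (it is the
  # expensive per-family step)
  pre_ok <- tab$crit_rare & tab$crit_damaging & tab$crit_gene_relevance &
    tab$crit_shared & tab$crit_support_any
  tab$crit_side <- FALSE
  side_tbl <- tibble(
    variant_id = character(), family_id = character(),
    inheritance_side = character()
  )
  if (criteria$require_tumor_side == "none") {
    tab$crit_side <- TRUE
  } else if (any(pre_ok)) {
    alive <- tab$variant_id[pre_ok]
    side_tbl <- support |>
      filter(.data$variant_id %in% alive) |>
      mutate(inheritance_side = purrr::map2_chr(
        .data$variant_id, .data$family_id,
        function(v, f) side_for(x, v, f)
      )) |>
      select("variant_id", "family_id", "inheritance_side")
    side_crit <- side_tbl |>
      group_by(.data$variant_id) |>
      summarise(
        crit_side = if (criteria$require_tumor_side == "all_determinable") {
          !any(.data$inheritance_side == "non_tumor_side")
        } else {
          any(.data$inheritance_side == "tumor_side")
        },
        .groups = "drop"
      )
    tab$crit_side[match(side_crit$variant_id, tab$variant_id)] <- side_crit$crit_side
  }

  tab$qualifies <- pre_ok & tab$crit_side
  list(per_variant = tab, support = support, seg = seg, side_tbl = side_tbl)
}

#' Prioritize rare damaging segregating variants
#'
#' Applies the AND of all enabled criteria (see [prioritization_criteria()])
#' to every genotyped variant. The family-count criterion is satisfied at the
#' variant level or, when `gene_level_aggregation` is on, at the gene level
#' over the gene's qualifying variants. Output is deterministic, sorted by
#' gene, chromosome and position.
#'
#' @param x An `fs_cohort` with annotations.
#' @param criteria A [prioritization_criteria()].
#' @return An object of class `fs_candidates`: a list with `variants`
#'   (candidate variants and their evidence), `genes` (candidate genes with
#'   supporting families and distinct qualifying variants), `segregation`
#'   (per-family detail for candidate variants) and `criteria`. `tidy()`
#'   returns the variant table, `glance()` a one-row summary.
#' @export
prioritize_variants <- function(x, criteria = prioritization_criteria()) {
  stopifnot(inherits(x, "fs_cohort"))
  pr <- prioritize_internal(x, criteria)
  tab <- pr$per_variant

  qual <- tab |> filter(.data$qualifies)
  gene_fams <- pr$support |>
    inner_join(qual |> select("variant_id", "gene"), by = "variant_id") |>
    distinct(.data$gene, .data$family_id)
  gene_n <- gene_fams |>
    dplyr::count(.data$gene, name = "n_supporting_families")

  qual <- qual |>
    left_join(gene_n, by = "gene", suffix = c("", "_gene")) |>
    mutate(
      gene_families = dplyr::coalesce(.data$n_supporting_families_gene, 0L),
      candidate = .data$n_supporting_families >= criteria$min_families |
        (criteria$gene_level_aggregation & .data$gene_families >= criteria$min_families)
    )

  cand <- qual |>
    filter(.data$candidate) |>
    arrange(.data$gene, match(.data$chrom, VALID_CHROMS), .data$pos)
  cand_fams <- pr$support |>
    filter(.data$variant_id %in% cand$variant_id) |>
    group_by(.data$variant_id) |>
    summarise(families = paste(sort(unique(.data$family_id)), collapse = ","), .groups = "drop")
  counts <- predictor_counts(cand)
  variants_out <- cand |>
    left_join(cand_fams, by = "variant_id") |>
    left_join(counts, by = "variant_id") |>
    select(
      "variant_id", "chrom", "pos", "ref", "alt", "gene", "hgvs_c", "hgvs_p",
      "consequence", "source", "n_supporting_families", "families",
      "af_fin", "af_nfe", "af_global", "n_damaging", "n_predictors",
      "cadd_phred", "gerp_rs", "phylop100", "siphy"
    )

  genes_out <- cand |>
    group_by(.data$gene) |>
    summarise(
      n_supporting_families = first(.data$gene_families),
      n_qualifying_variants = dplyr::n_distinct(.data$variant_id),
      qualifying_variants = paste(sort(unique(.data$variant_id)), collapse = ","),
      .groups = "drop"
    ) |>
    left_join(
      gene_fams |>
        group_by(.data$gene) |>
        summarise(families = paste(sort(unique(.data$family_id)), collapse = ","), .groups = "drop"),
      by = "gene"
    ) |>
    arrange(.data$gene)

  seg_detail <- pr$seg |>
    filter(.data$variant_id %in% variants_out$variant_id) |>
    left_join(pr$side_tbl, by = c("variant_id", "family_id")) |>
    mutate(inheritance_side = dplyr::coalesce(.data$inheritance_side, "undetermined"))

  structure(
    list(
      variants = variants_out, genes = genes_out, segregation = seg_detail,
      per_variant = tab |> select("variant_id", "gene", dplyr::starts_with("crit_"), "qualifies"),
      criteria = criteria
    ),
    class = "fs_candidates"
  )
}

#' @export
print.fs_candidates <- function(x, ...) {
  cat(
    "<fs_candidates> ", nrow(x$variants), " candidate variants in ",
    nrow(x$genes), " genes\n",
    sep = ""
  )
  if (nrow(x$genes) > 0) {
    print(x$genes |> select("gene", "n_supporting_families", "families"))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname prioritize_variants
#' @param x An `fs_candidates` object.
#' @param ... Unused.
#' @method tidy fs_candidates
#' @export
tidy.fs_candidates <- function(x, ...) x$variants

#' @rdname prioritize_variants
#' @method glance fs_candidates
#' @export
glance.fs_candidates <- function(x, ...) {
  tibble(
    n_candidate_variants = nrow(x$variants),
    n_candidate_genes = nrow(x$genes),
    genes = paste(x$genes$gene, collapse = ",")
  )
}
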