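#' @importFrom ggplot2 ggplot aes geom_histogram geom_vline geom_tile
#'   geom_text geom_boxplot geom_jitter labs theme_minimal scale_fill_gradient
#'   facet_wrap autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the permutation null of a PRS comparison
#'
#' Histogram of permuted difference-of-means statistics with the observed
#' statistic marked.
#'
#' @param object An `fs_prs_compare`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fs_prs_compare
#' @export
autoplot.fs_prs_compare <- function(object, ...) {
  ggplot(tibble(stat = object$perm_stats), aes(x = .data$stat)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    geom_vline(xintercept = object$observed, colour = "firebrick", linewidth = 1) +
    labs(
      x = "permuted difference of mean PRS (affected - unaffected)",
      y = "count",
      title = sprintf(
        "PRS permutation test: observed = %.3f, p = %.3g (%d perms, %s)",
        object$observed, object$p_value, object$n_perm, object$scheme
      )
    ) +
    theme_minimal()
}

#' Plot per-individual polygenic risk scores by affection status
#'
#' @param x An `fs_cohort`.
#' @param loci Risk-locus tibble (default: the cohort's own).
#' @param exclude Risk loci to drop before scoring.
#' @return A ggplot.
#' @export
plot_prs <- function(x, loci = NULL, exclude = NULL) {
  scores <- prs(x, loci = loci, exclude = exclude) |>
    filter(.data$affection %in% c("brain_tumor", "unaffected"))
  ggplot(scores, aes(x = .data$affection, y = .data$score)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, height = 0, alpha = 0.6, aes(colour = .data$family_id)) +
    labs(
      x = NULL, y = "polygenic risk score (sum of dosage x ln OR)",
      colour = "family"
    ) +
    theme_minimal()
}

#' Plot candidate-variant segregation across families
#'
#' Tile map of affected-carrier counts per candidate variant and family, with
#' the inheritance side printed in each tile.
#'
#' @param object An `fs_candidates` ([prioritize_variants()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fs_candidates
#' @export
autoplot.fs_candidates <- function(object, ...) {
  seg <- object$segregation |>
    inner_join(
      object$variants |> select("variant_id", "gene", "hgvs_p"),
      by = "variant_id"
    ) |>
    mutate(label = paste0(.data$gene, " ", dplyr::coalesce(.data$hgvs_p, .data$variant_id)))
  ggplot(seg, aes(x = .data$family_id, y = .data$label)) +
    geom_tile(aes(fill = .data$n_affected_carriers), colour = "white") +
    geom_text(aes(label = substr(.data$inheritance_side, 1, 1)), size = 3) +
    scale_fill_gradient(low = "grey95", high = "firebrick") +
    labs(
      x = "family", y = NULL, fill = "affected\ncarriers",
      title = "Candidate variant segregation (t = tumor side, n = non-tumor side, u = undetermined)"
    ) +
    theme_minimal()
}
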