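#' Closed-form detection power of a family sequencing design
#'
#' Probability that at least one of `n` sequenced families carries a variant
#' present in a fraction `p` of families: `1 - (1 - p)^n` (the
#' any-family-carries detection rule).
#'
#' @param p Fraction of families carrying the variant.
#' @param n Number of families sequenced.
#' @return Detection probability; vectorized and monotone increasing in both
#'   arguments.
#' @export
#' @examples
#' power_closed_form(0.2, 4) # 0.5904
power_closed_form <- function(p, n) {
  stopifnot(all(p >= 0), all(p <= 1), all(n >= 1))
  1 - (1 - p)^n
}

#' Monte-Carlo detection power with configurable detection rules
#'
#' Simulates the discovery design: each of `n_families` sequenced families
#' carries the variant with probability `p`. Under the
#' `"any_family_carries"` rule a carrier family is detected outright. Under
#' `"shared_by_affected_in_a_family"` each carrier family is additionally
#' gene-dropped (carrier founder, `n_children` offspring), affection is drawn
#' from the penetrance model (`f1` for carriers, `f0` for non-carriers), and
#' the family detects the variant only if it has at least one affected carrier
#' and every affected member is a carrier — the sharing rule the discovery
#' filter applies. With `f1 = 1, f0 = 0` the two rules coincide.
#'
#' @param p Fraction of families carrying the variant.
#' @param n_families Number of families sequenced.
#' @param rule Detection rule.
#' @param n_sim Number of simulated designs (>= 1).
#' @param f1,f0 Penetrance for carriers / phenocopy rate for non-carriers
#'   (shared rule only).
#' @param n_children Sibship size of the simulated families (shared rule only).
#' @param seed Optional integer seed.
#' @return List with `power`, `se` and the normal-approximation 95% `ci`.
#' @export
power_mc <- function(p, n_families, rule = c("any_family_carries", "shared_by_affected_in_a_family"),
                     n_sim = 1e5, f1 = 1, f0 = 0, n_children = 2, seed = NULL) {
  rule <- match.arg(rule)
  if (n_sim < 1) abort("n_sim must be >= 1")
  stopifnot(p >= 0, p <= 1, n_families >= 1, f1 >= f0)
  detected <- with_seed_local(seed, {
    carries <- matrix(
      rbinom(n_sim * n_families, 1L, p) == 1L,
      nrow = n_sim
    )
    if (rule == "any_family_carries") {
      rowSums(carries) > 0
    } else {
      idx <- which(carries)
      m <- length(idx) # every carrier family, across all simulations
      det_carrier <- rep(FALSE, length(carries))
      if (m > 0) {
        # founder couple: one carrier (het) + one non-carrier, n_children kids
        kid_carries <- matrix(rbinom(m * n_children, 1L, 0.5) == 1L, nrow = m)
        founder_aff <- rbinom(m, 1L, f1) == 1L # the carrier founder
        spouse_aff <- rbinom(m, 1L, f0) == 1L
        kid_aff <- matrix(
          rbinom(m * n_children, 1L, ifelse(kid_carries, f1, f0)) == 1L,
          nrow = m
        )
        any_aff <- founder_aff | spouse_aff | rowSums(kid_aff) > 0
        noncarrier_aff <- spouse_aff | rowSums(kid_aff & !kid_carries) > 0
        det_carrier[idx] <- any_aff & !noncarrier_aff
      }
      rowSums(matrix(det_carrier, nrow = n_sim)) > 0
    }
  })
  est <- mean(detected)
  se <- sqrt(est * (1 - est) / n_sim)
  list(power = est, se = se, ci = c(
    max(0, est - qnorm(0.975) * se),
    min(1, est + qnorm(0.975) * se)
  ))
}

#' Loss-of-heterozygosity test at one germline-heterozygous site
#'
#' Two-sided Fisher exact test on the 2x2 table of reference/alternate read
#' counts in tumor versus normal, with the allele-fraction shift
#' (tumor alt fraction minus normal alt fraction). The test is symmetric in
#' allele labels.
#'
#' @param tumor_ref,tumor_alt Tumor read counts.
#' @param normal_ref,normal_alt Normal read counts (site heterozygous by
#'   genotype).
#' @return List with `p_value` and `shift`.
#' @export
loh_test <- function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
  counts <- c(tumor_ref, tumor_alt, normal_ref, normal_alt)
  if (any(counts < 0)) abort("read counts must be >= 0")
  if (tumor_ref + tumor_alt < 1) abort("tumor depth must be >= 1")
  if (normal_ref + normal_alt < 1) abort("normal depth must be >= 1")
  tab <- matrix(counts, nrow = 2, byrow = TRUE)
  p <- fisher.test(tab)$p.value
  shift <- tumor_alt / (tumor_ref + tumor_alt) - normal_alt / (normal_ref + normal_alt)
  list(p_value = p, shift = shift)
}

#' LOH screen across candidate loci
#'
#' Applies [loh_test()] to every row and flags sites significant after
#' Benjamini-Hochberg correction across the tested loci.
#'
#' @param counts Tibble with columns `variant_id`, `tumor_ref`, `tumor_alt`,
#'   `normal_ref`, `normal_alt` (and optionally `sample_id`).
#' @param alpha FDR level (default 0.05).
#' @return Input tibble with `p_value`, `shift`, `q_value` and `flag` added.
#' @export
loh_screen <- function(counts, alpha = 0.05) {
  counts <- as_tibble(counts)
  res <- purrr::pmap(
    counts[, c("tumor_ref", "tumor_alt", "normal_ref", "normal_alt")],
    function(tumor_ref, tumor_alt, normal_ref, normal_alt) {
      loh_test(tumor_ref, tumor_alt, normal_ref, normal_alt)
    }
  )
  counts$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  counts$shift <- vapply(res, `[[`, numeric(1), "shift")
  counts$q_value <- p.adjust(counts$p_value, method = "BH")
  counts$flag <- counts$q_value < alpha
  counts
}
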