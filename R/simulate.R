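#' Simulation configuration for synthetic multiplex-family cohorts
#'
#' Defaults emulate the study design the package targets: 19 multiplex
#' brain-tumor families of 2-3 generations ascertained for at least two
#' cases each, a rare incompletely penetrant causal allele segregating on one
#' labeled tumor-side founder lineage in a subset of families, an
#' exome-like background of variants on a rare-shifted allele-frequency
#' spectrum (~79% protein-altering), and a set of common risk loci led by one
#' at Finnish frequency 0.09 with OR 3.4 plus low-risk loci (OR 1.2-1.5,
#' frequencies 0.10-0.80).
#'
#' Because the emulated families are ascertained as multiplex, every
#' non-carrier family receives a private latent liability allele (gene-dropped
#' but never genotyped) so that its aggregation of cases has a familial cause
#' without the typed causal variant; affection is then drawn per individual
#' with penetrance `penetrance` for liability carriers and sporadic rate
#' `sporadic` otherwise, and families are redrawn until they reach
#' `ascertain_min_affected` cases (capped at `max_tries` redraws).
#'
#' @param n_families Number of families.
#' @param generations 2 or 3.
#' @param sibship Integer range of generation-II sibship sizes.
#' @param grandchild_sibship Integer range of generation-III sibship sizes.
#' @param causal List: `gene`, `n_variants`, `n_carrier_families`, `af_fin`,
#'   `penetrance` (f1 for carriers), `sporadic` (f0), `chrom` (may be `"X"`).
#' @param background List: `n_variants`, beta allele-frequency spectrum
#'   parameters `af_shape1`/`af_shape2`, `prop_protein_altering`,
#'   `predictor_damaging_rate` (per-predictor false damaging call rate),
#'   `predictor_unavailable_rate`, `brain_expressed_rate`.
#' @param risk_loci Tibble with `freq`, `odds_ratio` (and optionally `rsid`);
#'   default one high-OR locus (0.09, OR 3.4) plus 14 low-risk loci.
#' @param missingness Per-genotype missing rate after sampling.
#' @param founder_sampled_prob Probability a founder has genotype data.
#' @param ascertain_min_affected,max_tries Multiplex ascertainment.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 19, generations = 3, sibship = 2:4,
                       grandchild_sibship = 1:3,
                       causal = list(), background = list(), risk_loci = NULL,
                       missingness = 0.05, founder_sampled_prob = 0.8,
                       ascertain_min_affected = 2, max_tries = 50) {
  stopifnot(generations %in% 2:3, n_families >= 1, missingness >= 0, missingness <= 1)
  causal <- modifyList(list(
    gene = "CAUSAL1", n_variants = 2, n_carrier_families = 2,
    af_fin = 5e-5, penetrance = 0.6, sporadic = 0.001, chrom = "2"
  ), causal)
  if (causal$penetrance < causal$sporadic) {
    abort("causal penetrance must be >= sporadic rate")
  }
  stopifnot(
    causal$penetrance >= 0, causal$penetrance <= 1,
    causal$sporadic >= 0, causal$sporadic <= 1,
    causal$n_carrier_families <= n_families
  )
  background <- modifyList(list(
    n_variants = 10000, af_shape1 = 0.2, af_shape2 = 2,
    prop_protein_altering = 0.79, predictor_damaging_rate = 0.1,
    predictor_unavailable_rate = 0.05, brain_expressed_rate = 0.5
  ), background)
  if (is.null(risk_loci)) {
    risk_loci <- tibble(
      freq = c(0.09, 0.10, 0.15, 0.20, 0.23, 0.28, 0.33, 0.38, 0.41, 0.46, 0.52, 0.57, 0.63, 0.71, 0.80),
      odds_ratio = c(3.4, 1.5, 1.4, 1.3, 1.2, 1.45, 1.35, 1.25, 1.2, 1.3, 1.4, 1.2, 1.25, 1.3, 1.2)
    )
  }
  structure(
    list(
      n_families = n_families, generations = generations, sibship = sibship,
      grandchild_sibship = grandchild_sibship, causal = causal,
      background = background, risk_loci = as_tibble(risk_loci),
      missingness = missingness, founder_sampled_prob = founder_sampled_prob,
      ascertain_min_affected = ascertain_min_affected, max_tries = max_tries
    ),
    class = "sim_config"
  )
}

# build one family's pedigree scaffold (structure only)
sim_family_structure <- function(fam, cfg) {
  label <- function(x) paste0(fam, "_", x)
  rows <- list(
    tibble(
      individual_id = label("I-1"), father_id = NA, mother_id = NA,
      sex = "male", side_label = "tumor_side"
    ),
    tibble(
      individual_id = label("I-2"), father_id = NA, mother_id = NA,
      sex = "female", side_label = "married_in"
    )
  )
  k <- sample(cfg$sibship, 1)
  kid_sex <- sample(c("male", "female"), k, replace = TRUE)
  for (i in seq_len(k)) {
    rows[[length(rows) + 1L]] <- tibble(
      individual_id = label(paste0("II-", i)), father_id = label("I-1"),
      mother_id = label("I-2"), sex = kid_sex[i], side_label = "none"
    )
  }
  if (cfg$generations == 3) {
    parent <- label("II-1")
    spouse_sex <- if (kid_sex[1] == "male") "female" else "male"
    rows[[length(rows) + 1L]] <- tibble(
      individual_id = label("II-sp"), father_id = NA, mother_id = NA,
      sex = spouse_sex, side_label = "married_in"
    )
    m <- sample(cfg$grandchild_sibship, 1)
    fa <- if (kid_sex[1] == "male") parent else label("II-sp")
    mo <- if (kid_sex[1] == "male") label("II-sp") else parent
    for (i in seq_len(m)) {
      rows[[length(rows) + 1L]] <- tibble(
        individual_id = label(paste0("III-", i)), father_id = fa, mother_id = mo,
        sex = sample(c("male", "female"), 1), side_label = "none"
      )
    }
  }
  bind_rows(rows) |> mutate(family_id = fam)
}

# gene-drop haplotypes through one family; loci described by af and x flag
sim_family_genotypes <- function(ped_fam, af, x_locus, plant_idx = integer()) {
  n <- length(af)
  ids <- ped_fam$individual_id
  male <- ped_fam$sex == "male"
  H1 <- matrix(0L, n, length(ids), dimnames = list(NULL, ids))
  H2 <- H1
  for (j in seq_along(ids)) {
    if (is.na(ped_fam$father_id[j])) {
      H1[, j] <- rbinom(n, 1L, af)
      H2[, j] <- rbinom(n, 1L, af)
      if (male[j] && any(x_locus)) H2[x_locus, j] <- 0L
      if (j == 1L && length(plant_idx) > 0) {
        # plant the causal allele on the tumor-side founder (one copy)
        H1[plant_idx, j] <- 1L
        H2[plant_idx, j] <- 0L
      }
    } else {
      fj <- match(ped_fam$father_id[j], ids)
      mj <- match(ped_fam$mother_id[j], ids)
      pick_f <- rbinom(n, 1L, 0.5) == 1L
      pick_m <- rbinom(n, 1L, 0.5) == 1L
      pat <- ifelse(pick_f, H1[, fj], H2[, fj])
      mat <- ifelse(pick_m, H1[, mj], H2[, mj])
      if (any(x_locus)) {
        pat[x_locus] <- H1[x_locus, fj] # father's single X
      }
      H1[, j] <- pat
      H2[, j] <- mat
      if (male[j] && any(x_locus)) {
        H1[x_locus, j] <- mat[x_locus] # sons: X from the mother
        H2[x_locus, j] <- 0L
      }
    }
  }
  codes <- H1 + H2
  if (any(x_locus) && any(male)) {
    codes[x_locus, male] <- 3L + H1[x_locus, male, drop = FALSE]
  }
  codes
}

#' Simulate a synthetic multiplex-family cohort
#'
#' Gene-drop simulation under the model described in [sim_config()]: founder
#' haplotypes are drawn from Hardy-Weinberg at every locus except the causal
#' allele, which is planted (one copy) in the labeled tumor-side founder of
#' each carrier family; transmission is fair meiosis over independent loci
#' with X-linked rules for X loci; affection is drawn from the penetrance
#' model; annotations are emitted so causal variants read as rare and damaging
#' while background variants follow the configured predictor error rates.
#' Fully reproducible under `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed.
#' @return An `fs_cohort`; `attr(, "truth")` records the planted gene,
#'   variants, carrier families and per-individual causal-carrier status.
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_local(seed, simulate_cohort_impl(cfg))
}

simulate_cohort_impl <- function(cfg) {
  bg <- cfg$background
  cz <- cfg$causal
  n_bg <- bg$n_variants
  n_cz <- cz$n_variants
  n_rl <- nrow(cfg$risk_loci)

  # locus table: background, causal, risk loci, + 1 latent liability slot
  bg_af <- rbeta(n_bg, bg$af_shape1, bg$af_shape2)
  af <- c(bg_af, rep(cz$af_fin, n_cz), cfg$risk_loci$freq, 0)
  chrom <- c(
    sample(as.character(1:22), n_bg, replace = TRUE),
    rep(normalize_chrom(cz$chrom), n_cz),
    sample(as.character(1:22), n_rl, replace = TRUE),
    "1"
  )
  n_loci <- length(af)
  liability_row <- n_loci
  causal_rows <- n_bg + seq_len(n_cz)
  risk_rows <- n_bg + n_cz + seq_len(n_rl)
  x_locus <- chrom == "X"
  x_locus[liability_row] <- FALSE

  pos <- sample.int(2e8, n_loci)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_loci, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  vid <- variant_key(chrom, pos, ref, alt)

  carrier_fams <- paste0("F", seq_len(cz$n_carrier_families))
  fams <- paste0("F", seq_len(cfg$n_families))
  # causal variants are distributed one per carrier family, cycling
  plant_of <- setNames(
    causal_rows[((seq_along(carrier_fams) - 1L) %% n_cz) + 1L],
    carrier_fams
  )

  peds <- list()
  genos <- list()
  truth_carriers <- list()
  for (fam in fams) {
    is_carrier_fam <- fam %in% carrier_fams
    tries <- 0L
    repeat {
      tries <- tries + 1L
      ped_fam <- sim_family_structure(fam, cfg)
      plant <- if (is_carrier_fam) c(plant_of[[fam]]) else liability_row
      codes <- sim_family_genotypes(ped_fam, af, x_locus, plant_idx = plant)
      liab_dose <- if (is_carrier_fam) {
        code_dosage(codes[plant_of[[fam]], ])
      } else {
        code_dosage(codes[liability_row, ])
      }
      affected <- rbinom(nrow(ped_fam), 1L, ifelse(liab_dose > 0, cz$penetrance, cz$sporadic)) == 1L
      if (sum(affected) >= cfg$ascertain_min_affected || tries >= cfg$max_tries) break
    }
    ped_fam$affection <- if_else(affected, "brain_tumor", "unaffected")
    ped_fam$sampled <- TRUE
    is_founder <- is.na(ped_fam$father_id)
    ped_fam$sampled[is_founder] <- runif(sum(is_founder)) < cfg$founder_sampled_prob
    peds[[fam]] <- ped_fam
    truth_carriers[[fam]] <- tibble(
      individual_id = ped_fam$individual_id,
      causal_carrier = if (is_carrier_fam) liab_dose > 0 else FALSE
    )
    codes <- codes[-liability_row, , drop = FALSE]
    codes[, !ped_fam$sampled] <- NA_integer_
    if (cfg$missingness > 0) {
      drop <- runif(length(codes)) < cfg$missingness
      codes[drop] <- NA_integer_
    }
    genos[[fam]] <- codes
  }

  ped <- bind_rows(peds) |>
    mutate(histology = NA_character_, grade = NA_character_, age_band = NA_character_) |>
    select(
      "family_id", "individual_id", "father_id", "mother_id", "sex", "affection",
      "histology", "grade", "age_band", "sampled", "side_label"
    ) |>
    pedigree()
  geno <- do.call(cbind, genos)
  rownames(geno) <- vid[-liability_row]

  # variant + annotation tables
  n_genes <- max(1L, n_bg %/% 2L)
  bg_gene <- paste0("BG", ((seq_len(n_bg) - 1L) %% n_genes) + 1L)
  gene <- c(bg_gene, rep(cz$gene, n_cz), paste0("RL", seq_len(n_rl)))
  consequence <- c(
    if_else(runif(n_bg) < bg$prop_protein_altering, "missense",
      sample(c("synonymous", "intronic"), n_bg, replace = TRUE)
    ),
    rep("missense", n_cz), rep("intronic", n_rl)
  )
  source <- c(rep("wes_candidate", n_bg + n_cz), rep("literature", n_rl))
  variants <- variant_table(
    chrom[-liability_row], pos[-liability_row], ref[-liability_row],
    alt[-liability_row],
    rsid = c(rep(NA_character_, n_bg + n_cz), paste0("rsRL", seq_len(n_rl))),
    gene = gene, consequence = consequence, source = source
  )

  n_var <- n_loci - 1L
  pred <- matrix(NA_character_, n_var, length(PREDICTORS),
    dimnames = list(NULL, PREDICTORS)
  )
  for (j in seq_along(PREDICTORS)) {
    u <- runif(n_var)
    p_dmg <- c(
      rep(bg$predictor_damaging_rate, n_bg), rep(0.95, n_cz),
      rep(0, n_rl)
    )
    call <- if_else(u < p_dmg, "damaging", "tolerated")
    call[runif(n_var) < bg$predictor_unavailable_rate] <- NA_character_
    pred[, j] <- call
  }
  pred[risk_rows, ] <- NA_character_ # non-coding: no predictor calls
  gene_brain <- setNames(
    runif(n_genes) < bg$brain_expressed_rate,
    paste0("BG", seq_len(n_genes))
  )
  ann <- tibble(
    variant_id = variants$variant_id,
    af_fin = af[-liability_row],
    af_nfe = af[-liability_row], af_global = af[-liability_row]
  )
  for (p in PREDICTORS) ann[[p]] <- pred[, p]
  ann$cadd_phred <- c(runif(n_bg, 0, 25), runif(n_cz, 25, 35), runif(n_rl, 0, 10))
  ann$gerp_rs <- runif(n_var, -2, 6)
  ann$phylop100 <- runif(n_var, -2, 10)
  ann$siphy <- runif(n_var, 0, 20)
  ann$clinvar_class <- NA_character_
  ann$clinvar_stars <- NA_integer_
  ann$domain <- NA_character_
  ann$ctcf_site <- FALSE
  ann$brain_expressed <- c(
    unname(gene_brain[bg_gene]), rep(TRUE, n_cz),
    rep(FALSE, n_rl)
  )
  ann$glioma_relevant <- c(rep(FALSE, n_bg), rep(TRUE, n_cz), rep(TRUE, n_rl))
  validate_annotations(ann)

  risk_loci <- risk_locus_table(
    chrom[risk_rows], pos[risk_rows], ref[risk_rows], alt[risk_rows],
    risk_allele = alt[risk_rows], odds_ratio = cfg$risk_loci$odds_ratio,
    source = "gwas"
  )

  out <- cohort(ped, variants, geno, annotations = ann, risk_loci = risk_loci)
  attr(out, "truth") <- list(
    causal_gene = cz$gene,
    causal_variants = vid[causal_rows],
    carrier_families = carrier_fams,
    carriers = bind_rows(truth_carriers, .id = "family_id")
  )
  out
}
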