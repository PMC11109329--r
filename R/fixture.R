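#' Deterministic worked-example cohort of Finnish familial glioma pedigrees
#'
#' A synthetic, hand-encoded cohort of 12 multiplex brain-tumor families
#' (A, B, C, E, F, I, J, L, N, O, P, Q) used throughout the examples, tests
#' and vignette. It carries five rare candidate variants (two in GALNT13, two
#' in MYO10, one X-linked in AR) segregating on tumor-side founder lineages
#' with incomplete penetrance, the common glioma risk SNP rs55705857 in
#' CCDC26 (Finnish frequency 0.09; eight affected carriers in six families,
#' seven heterozygous and one homozygous), the CHEK2 c.1100delC frameshift on
#' a non-tumor-side lineage, three rare benign TP53 intronic/synonymous
#' variants on a non-tumor-side lineage, two common TP53 GWAS variants and
#' five low-risk GWAS loci (OR 1.2-1.5). Genotypes of relatives without
#' stated data are missing, never imputed; age at diagnosis is carried as
#' printed bands. The encoding is Mendelian-consistent.
#'
#' @return An `fs_cohort` with annotations and a risk-locus table.
#' @export
#' @examples
#' coh <- example_glioma_cohort()
#' prioritize_variants(coh)
example_glioma_cohort <- function() {
  ped <- fixture_pedigree()
  variants <- fixture_variants()
  ann <- fixture_annotations(variants)
  geno <- fixture_genotypes(ped, variants)
  risk <- risk_locus_table(
    chrom = c("8", "5", "7", "9", "20", "11"),
    pos = c(130645692L, 1286516L, 55192707L, 22048070L, 62309839L, 118477367L),
    ref = c("A", "A", "A", "G", "A", "T"),
    alt = c("G", "C", "G", "A", "G", "C"),
    risk_allele = c("G", "C", "G", "A", "G", "C"),
    odds_ratio = c(3.4, 1.4, 1.25, 1.3, 1.3, 1.2),
    source = c("gwas_ccdc26", "gwas_tert", "gwas_egfr", "gwas_cdkn2b_as1", "gwas_rtel1", "gwas_phldb1")
  )
  cohort(ped, variants, geno, annotations = ann, risk_loci = risk)
}

fixture_pedigree <- function() {
  mk <- function(fam, id, fa, mo, sex, aff, hist = NA, grade = NA, band = NA,
                 sampled = TRUE, side = "none") {
    tibble(
      family_id = fam, individual_id = paste0(fam, "_", id),
      father_id = if (is.na(fa)) NA_character_ else paste0(fam, "_", fa),
      mother_id = if (is.na(mo)) NA_character_ else paste0(fam, "_", mo),
      sex = sex, affection = aff, histology = as.character(hist),
      grade = as.character(grade), age_band = as.character(band),
      sampled = sampled, side_label = side
    )
  }
  bind_rows(
    # Family A: two affected sisters, variants from the tumor-side father
    mk("A", "I-1", NA, NA, "male", "unaffected", side = "tumor_side"),
    mk("A", "I-2", NA, NA, "female", "unaffected", side = "married_in"),
    mk("A", "II-1", "I-1", "I-2", "female", "brain_tumor", "PA", "I", "20-24"),
    mk("A", "II-2", "I-1", "I-2", "female", "brain_tumor", "A", "II", "35-39"),
    mk("A", "II-3", "I-1", "I-2", "female", "unaffected"),
    # Family B: three generations, variant from the tumor-side grandmother
    mk("B", "I-1", NA, NA, "female", "unaffected", side = "tumor_side"),
    mk("B", "I-2", NA, NA, "male", "unaffected", side = "married_in"),
    mk("B", "II-1", NA, NA, "male", "unaffected", side = "married_in"),
    mk("B", "II-2", "I-2", "I-1", "female", "brain_tumor", "O", "II", "35-39"),
    mk("B", "II-3", "I-2", "I-1", "female", "unaffected"),
    mk("B", "III-1", "II-1", "II-2", "male", "brain_tumor", "PA", "I", "0-4"),
    # Family C: two affected siblings, variant from the tumor-side father
    mk("C", "I-1", NA, NA, "male", "unaffected", side = "tumor_side"),
    mk("C", "I-2", NA, NA, "female", "unaffected", side = "married_in"),
    mk("C", "II-1", "I-1", "I-2", "male", "brain_tumor", "A", "II", "30-34"),
    mk("C", "II-2", "I-1", "I-2", "female", "brain_tumor", "PA", "I", "5-10"),
    # Family E: two affected rs55705857 carriers, parents not sampled
    mk("E", "I-1", NA, NA, "male", "unaffected", sampled = FALSE, side = "tumor_side"),
    mk("E", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "married_in"),
    mk("E", "II-1", "I-1", "I-2", "male", "brain_tumor", "PA", "I", "10-14"),
    mk("E", "II-2", "I-1", "I-2", "female", "brain_tumor", "PA", "I", "15-19"),
    # Family F: affected woman, wild-type father, tumor-side mother unsampled
    mk("F", "I-1", NA, NA, "male", "unaffected", side = "married_in"),
    mk("F", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "tumor_side"),
    mk("F", "II-1", "I-1", "I-2", "female", "brain_tumor", "A", "II", "30-34"),
    # Family I: CHEK2 carrier; wild-type tumor-side father
    mk("I", "I-1", NA, NA, "male", "unaffected", side = "tumor_side"),
    mk("I", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "married_in"),
    mk("I", "II-1", "I-1", "I-2", "female", "brain_tumor", "O", "II", "30-34"),
    mk("I", "II-2", "I-1", "I-2", "male", "unaffected"),
    # Family J: affected man, wild-type father, tumor-side mother unsampled
    mk("J", "I-1", NA, NA, "male", "unaffected", side = "married_in"),
    mk("J", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "tumor_side"),
    mk("J", "II-1", "I-1", "I-2", "male", "brain_tumor", "GBM", "IV", "45-49"),
    mk("J", "II-2", "I-1", "I-2", "female", "unaffected"),
    # Family L: two affected rs55705857 carriers, parents not sampled
    mk("L", "I-1", NA, NA, "male", "unaffected", sampled = FALSE, side = "tumor_side"),
    mk("L", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "married_in"),
    mk("L", "II-1", "I-1", "I-2", "female", "brain_tumor", "PA", "I", "5-10"),
    mk("L", "II-2", "I-1", "I-2", "male", "brain_tumor", "A", "II", "40-44"),
    # Family N: TP53 GWAS variants in an unaffected member only
    mk("N", "I-1", NA, NA, "male", "unaffected", sampled = FALSE),
    mk("N", "I-2", NA, NA, "female", "unaffected", sampled = FALSE),
    mk("N", "II-1", "I-1", "I-2", "male", "brain_tumor", "A", "II", "20-24"),
    mk("N", "II-2", "I-1", "I-2", "female", "unaffected"),
    # Family O: affected member wild type for MYO10 A504V; TP53 rare variants
    # from the married-in side
    mk("O", "I-1", NA, NA, "male", "unaffected", side = "tumor_side"),
    mk("O", "I-2", NA, NA, "female", "unaffected", sampled = FALSE, side = "married_in"),
    mk("O", "II-1", "I-1", "I-2", "male", "brain_tumor", "PA", "I", "10-14"),
    mk("O", "II-2", "I-1", "I-2", "female", "unaffected"),
    mk("O", "II-3", "I-1", "I-2", "male", "unaffected"),
    # Family P: TP53 GWAS variants in two affected siblings, parents unlabeled
    mk("P", "I-1", NA, NA, "male", "unaffected", sampled = FALSE),
    mk("P", "I-2", NA, NA, "female", "unaffected", sampled = FALSE),
    mk("P", "II-1", "I-1", "I-2", "female", "brain_tumor", "O", "II", "10-14"),
    mk("P", "II-2", "I-1", "I-2", "male", "brain_tumor", "ganglioglioma", "I", "30-34"),
    mk("P", "II-3", "I-1", "I-2", "female", "unaffected"),
    mk("P", "II-4", "I-1", "I-2", "male", "unaffected"),
    # Family Q: X-linked AR variant from the tumor-side mother; rs55705857
    # homozygote
    mk("Q", "I-1", NA, NA, "male", "unaffected", side = "married_in"),
    mk("Q", "I-2", NA, NA, "female", "unaffected", side = "tumor_side"),
    mk("Q", "II-1", "I-1", "I-2", "male", "brain_tumor", "A", "II", "20-24")
  ) |> pedigree()
}

fixture_variants <- function() {
  variant_table(
    chrom = c("2", "2", "5", "5", "X", "8", "22", "17", "17", "17", "17", "17", "5", "7", "9", "20", "11"),
    pos = c(
      155099285L, 155252560L, 16680150L, 16762730L, 66937326L, 130645692L,
      29091856L, 7573997L, 7578560L, 7579538L, 7571752L, 7578591L,
      1286516L, 55192707L, 22048070L, 62309839L, 118477367L
    ),
    ref = c("C", "T", "A", "C", "G", "A", "AC", "T", "T", "G", "A", "G", "A", "A", "G", "A", "T"),
    alt = c("T", "A", "G", "T", "T", "G", "A", "C", "C", "A", "C", "A", "C", "G", "A", "G", "C"),
    rsid = c(
      NA, NA, NA, NA, NA, "rs55705857", "rs555607708", NA, NA, NA, NA, NA,
      "rs2736100", "rs11979158", "rs4977756", "rs6010620", "rs498872"
    ),
    gene = c(
      "GALNT13", "GALNT13", "MYO10", "MYO10", "AR", "CCDC26", "CHEK2",
      "TP53", "TP53", "TP53", "TP53", "TP53",
      "TERT", "EGFR", "CDKN2B-AS1", "RTEL1", "PHLDB1"
    ),
    hgvs_c = c(
      "c.553C>T", "c.1214T>A", "c.4448A>G", "c.1511C>T", "c.2180G>T", NA,
      "c.1100delC", "c.993+12T>C", "c.376-86T>C", "c.108G>A",
      "c.*1175A>C", "c.376-117G>A", NA, NA, NA, NA, NA
    ),
    hgvs_p = c(
      "p.R185C", "p.L405Q", "p.N1483S", "p.A504V", "p.R727L", NA, NA, NA, NA,
      "p.Pro36=", NA, NA, NA, NA, NA, NA, NA
    ),
    consequence = c(
      "missense", "missense", "missense", "missense", "missense", "intronic",
      "frameshift", "intronic", "intronic", "synonymous", "utr3", "intronic",
      "intronic", "intronic", "intronic", "intronic", "intronic"
    ),
    source = c(
      rep("wes_candidate", 5), "literature", "literature",
      rep("tp53_region", 5), rep("literature", 5)
    )
  )
}

fixture_annotations <- function(variants) {
  dmg <- function(which) {
    out <- setNames(rep(NA_character_, length(PREDICTORS)), PREDICTORS)
    out[PREDICTORS[which]] <- "damaging"
    avail <- setdiff(seq_along(PREDICTORS), attr(which, "unavailable") %||% integer())
    out[PREDICTORS[setdiff(avail, which)]] <- "tolerated"
    out
  }
  with_na <- function(which, unavailable) {
    attr(which, "unavailable") <- unavailable
    which
  }
  pred <- rbind(
    dmg(1:8), # GALNT13 R185C: 8/8
    dmg(1:8), # GALNT13 L405Q: 8/8
    dmg(with_na(c(2, 4, 5, 6, 7, 8), 3)), # MYO10 N1483S: 6/7, LRT unavailable
    dmg(with_na(c(1, 2, 4, 5, 6, 7, 8), 3)), # MYO10 A504V: 7/7, LRT unavailable
    dmg(with_na(c(1, 2, 3, 4, 6, 7, 8), 5)), # AR R727L: 7/7, MutationAssessor unavailable
    matrix(NA_character_, 1, 8), # rs55705857: non-coding
    dmg(with_na(c(4, 6), c(1, 2, 3, 5, 7, 8))), # CHEK2 frameshift: 2/2
    matrix(NA_character_, 5, 8), # TP53 non-coding/synonymous
    matrix(NA_character_, 5, 8) # low-risk GWAS loci
  )
  colnames(pred) <- PREDICTORS
  ann <- tibble(
    variant_id = variants$variant_id,
    af_fin = c(8.0e-5, 4.6e-5, 9.3e-5, 1.6e-3, 8.4e-3, 0.09, 0.009, 0.004, 0.004, 0.003, 0.02, 0.03, 0.41, 0.23, 0.57, 0.80, 0.31),
    af_nfe = c(7.7e-6, 0, 0, 8.3e-5, 3.1e-4, 0.04, 0.005, 0.004, 0.004, 0.003, 0.02, 0.03, 0.41, 0.23, 0.57, 0.80, 0.31),
    af_global = c(1.8e-5, 4.0e-6, 8.0e-6, 2.0e-4, 9.6e-4, 0.04, 0.003, 0.004, 0.004, 0.003, 0.02, 0.03, 0.41, 0.23, 0.57, 0.80, 0.31)
  )
  for (p in PREDICTORS) ann[[p]] <- unname(pred[, p])
  ann$cadd_phred <- c(31.0, 27.7, 23.0, 29.3, 29.7, 5.6, 24.0, 2.1, 1.4, 3.0, 10.1, 4.2, 3.1, 2.4, 4.0, 2.8, 3.3)
  ann$gerp_rs <- c(5.6, 5.0, 4.2, 5.6, 4.9, rep(NA_real_, 12))
  ann$phylop100 <- c(1.1, 7.9, 1.7, 9.6, 9.9, rep(NA_real_, 12))
  ann$siphy <- c(15.1, 13.9, 12.8, 19.7, 14.5, rep(NA_real_, 12))
  ann$clinvar_class <- c(rep(NA_character_, 6), "pathogenic", rep(NA_character_, 10))
  ann$clinvar_stars <- c(rep(NA_integer_, 6), 2L, rep(NA_integer_, 10))
  ann$domain <- c(
    "glycosyltransferase catalytic subdomain A (substrate-binding site)",
    NA, "PH2", "myosin motor", "ligand-binding domain",
    rep(NA_character_, 12)
  )
  ann$ctcf_site <- c(FALSE, FALSE, TRUE, rep(FALSE, 14))
  ann$brain_expressed <- c(TRUE, TRUE, TRUE, TRUE, TRUE, rep(FALSE, 12))
  ann$glioma_relevant <- c(rep(TRUE, 12), rep(TRUE, 5))
  validate_annotations(ann)
  ann
}

fixture_genotypes <- function(ped, variants) {
  k <- function(gene, i = 1) variants$variant_id[which(variants$gene == gene)[i]]
  r185c <- k("GALNT13", 1)
  l405q <- k("GALNT13", 2)
  n1483s <- k("MYO10", 1)
  a504v <- k("MYO10", 2)
  ar <- k("AR")
  rs <- k("CCDC26")
  chek2 <- k("CHEK2")
  tp53_rare <- variants$variant_id[variants$gene == "TP53"][1:3]
  tp53_gwas1 <- variants$variant_id[variants$gene == "TP53"][4] # c.*1175A>C
  tp53_gwas2 <- variants$variant_id[variants$gene == "TP53"][5] # c.376-117G>A
  lowrisk <- c(
    TERT = k("TERT"), EGFR = k("EGFR"), CDKN2B = k("CDKN2B-AS1"),
    RTEL1 = k("RTEL1"), PHLDB1 = k("PHLDB1")
  )

  # baseline: every sampled individual reference (hemizygous-reference for
  # males at X loci); unsampled individuals missing everywhere
  male <- setNames(ped$sex == "male", ped$individual_id)
  on_x <- variants$chrom == "X"
  g <- matrix(NA_integer_,
    nrow = nrow(variants), ncol = nrow(ped),
    dimnames = list(variants$variant_id, ped$individual_id)
  )
  sampled <- ped$individual_id[ped$sampled]
  g[, sampled] <- 0L
  g[on_x, intersect(sampled, names(male)[male])] <- 3L

  set_gt <- function(variant, id, label) {
    g[variant, id] <<- gt_to_code(label)
  }
  het <- function(variant, ids) for (id in ids) set_gt(variant, id, "het")

  # Family A: GALNT13 R185C + X-linked AR R727L from the father
  het(r185c, c("A_I-1", "A_II-1", "A_II-2"))
  set_gt(ar, "A_I-1", "hemi_alt")
  het(ar, c("A_II-1", "A_II-2", "A_II-3"))
  # Family C: GALNT13 L405Q from the father; rs55705857 in II-1
  het(l405q, c("C_I-1", "C_II-1", "C_II-2"))
  het(rs, c("C_I-1", "C_II-1"))
  # Family B: MYO10 N1483S from the grandmother; rs55705857 in II-2 (and, as
  # in the stated incomplete-penetrance pattern, in unaffected relatives)
  het(n1483s, c("B_I-1", "B_II-2", "B_II-3", "B_III-1"))
  het(rs, c("B_I-1", "B_II-2", "B_II-3"))
  # Family J: MYO10 N1483S, obligate from the unsampled tumor-side mother
  het(n1483s, c("J_II-1", "J_II-2"))
  # Family F: MYO10 A504V, obligate from the unsampled tumor-side mother
  het(a504v, "F_II-1")
  # Family O: A504V in two unaffected members only; rare TP53 variants in the
  # affected member from the unsampled married-in mother
  het(a504v, c("O_II-2", "O_II-3"))
  for (v in tp53_rare) het(v, "O_II-1")
  # Family Q: AR from the tumor-side mother; son hemizygous; rs homozygote
  het(ar, "Q_I-2")
  set_gt(ar, "Q_II-1", "hemi_alt")
  set_gt(rs, "Q_I-1", "hom_alt")
  het(rs, "Q_I-2")
  set_gt(rs, "Q_II-1", "hom_alt")
  # Family I: CHEK2 c.1100delC not from the tumor side; rs in the affected
  # member and the unaffected sibling
  het(chek2, c("I_II-1", "I_II-2"))
  het(rs, c("I_II-1", "I_II-2"))
  # Families E and L: rs55705857 in two affected members each
  het(rs, c("E_II-1", "E_II-2", "L_II-1", "L_II-2"))
  # Family P: TP53 GWAS variants; Family N: unaffected carrier only
  het(tp53_gwas1, c("P_II-1", "P_II-2", "P_II-3", "P_II-4", "N_II-2"))
  het(tp53_gwas2, c("P_II-1", "P_II-2", "P_II-3", "N_II-2"))
  # Low-risk GWAS loci: family-uniform heterozygosity (Mendelian-consistent,
  # no affected/unaffected contrast by construction)
  fam_loci <- list(
    A = c("TERT", "EGFR"), B = c("TERT", "CDKN2B", "RTEL1"),
    C = c("EGFR", "PHLDB1"), E = "TERT", F = c("TERT", "RTEL1"),
    I = c("RTEL1", "PHLDB1"), J = "CDKN2B", L = c("EGFR", "CDKN2B"),
    N = "RTEL1", O = c("EGFR", "RTEL1"),
    P = c("TERT", "PHLDB1"), Q = c("TERT", "EGFR", "CDKN2B", "PHLDB1")
  )
  for (fam in names(fam_loci)) {
    ids <- intersect(ped$individual_id[ped$family_id == fam], sampled)
    for (locus in fam_loci[[fam]]) het(lowrisk[[locus]], ids)
  }
  g
}
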