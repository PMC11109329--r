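#' Construct a variant table
#'
#' One row per biallelic variant, keyed by `variant_id = chrom:pos:ref:alt`
#' (hg19, 1-based). `source` records provenance through the pipeline:
#' `"wes_candidate"` (discovery exomes), `"literature"` (previously reported
#' variants) or `"tp53_region"` (variants called inside the TP53 coding
#' regions of the targeted panel).
#'
#' @param chrom,pos,ref,alt Variant coordinates and alleles.
#' @param rsid,gene,hgvs_c,hgvs_p Optional identifiers.
#' @param consequence Consequence class (one of `r paste(CONSEQUENCES, collapse = ", ")`).
#' @param source Provenance label.
#' @return Tibble with a `variant_id` key column.
#' @export
variant_table <- function(chrom, pos, ref, alt, rsid = NA_character_,
                          gene = NA_character_, hgvs_c = NA_character_,
                          hgvs_p = NA_character_, consequence = "other",
                          source = "wes_candidate") {
  chrom <- normalize_chrom(chrom)
  pos <- as.integer(pos)
  if (any(pos < 1L)) abort("pos must be >= 1")
  if (any(ref == alt)) abort("ref and alt alleles must differ")
  bad_csq <- setdiff(unique(consequence), CONSEQUENCES)
  if (length(bad_csq) > 0) {
    abort(paste0("invalid consequence(s): ", paste(bad_csq, collapse = ", ")))
  }
  bad_src <- setdiff(unique(source), c("wes_candidate", "literature", "tp53_region"))
  if (length(bad_src) > 0) {
    abort(paste0("invalid source label(s): ", paste(bad_src, collapse = ", ")))
  }
  out <- tibble(
    variant_id = variant_key(chrom, pos, ref, alt),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    rsid = rsid, gene = gene, hgvs_c = hgvs_c, hgvs_p = hgvs_p,
    consequence = consequence, source = source
  )
  if (anyDuplicated(out$variant_id)) abort("duplicated variant keys")
  out
}

#' Assemble a cohort
#'
#' The cohort is the unit every pipeline stage consumes: pedigrees, the
#' variant table, a genotype matrix (variants x individuals), optional
#' per-genotype depths, the annotation table and an optional risk-locus table.
#'
#' @param ped Pedigree tibble ([pedigree()]); individual ids must be unique
#'   across families.
#' @param variants Variant tibble ([variant_table()]).
#' @param genotypes Either an integer code matrix (rows = `variant_id`,
#'   columns = `individual_id`) or a long tibble with columns `variant_id`,
#'   `individual_id`, `genotype` (labels).
#' @param annotations Optional annotation tibble ([read_annotations()] or
#'   [annotation_table()]).
#' @param depths Optional integer depth matrix matching `genotypes`.
#' @param risk_loci Optional risk-locus tibble ([risk_locus_table()]).
#' @return An object of class `fs_cohort`.
#' @export
cohort <- function(ped, variants, genotypes, annotations = NULL, depths = NULL,
                   risk_loci = NULL) {
  validate_pedigree(ped)
  if (anyDuplicated(ped$individual_id)) {
    abort("cohort individual ids must be unique across families")
  }
  if (is.data.frame(genotypes)) {
    genotypes <- long_to_matrix(genotypes, variants$variant_id)
  }
  if (!all(rownames(genotypes) %in% variants$variant_id)) {
    abort("genotype matrix rows must be variant ids present in `variants`")
  }
  extra <- setdiff(colnames(genotypes), ped$individual_id)
  if (length(extra) > 0) {
    abort(paste0(
      "genotyped individual(s) absent from pedigrees: ",
      paste(extra, collapse = ", ")
    ))
  }
  storage.mode(genotypes) <- "integer"
  if (!is.null(annotations)) {
    missing_ann <- setdiff(annotations$variant_id, variants$variant_id)
    if (length(missing_ann) > 0) {
      abort(paste0(
        "annotated variant(s) absent from variant table: ",
        paste(head(missing_ann, 5), collapse = ", ")
      ))
    }
  }
  if (!is.null(depths) && !identical(dim(depths), dim(genotypes))) {
    abort("depth matrix must match the genotype matrix dimensions")
  }
  structure(
    list(
      ped = ped, variants = as_tibble(variants), geno = genotypes,
      depth = depths, ann = if (is.null(annotations)) NULL else as_tibble(annotations),
      risk_loci = if (is.null(risk_loci)) NULL else as_tibble(risk_loci)
    ),
    class = "fs_cohort"
  )
}

long_to_matrix <- function(long, variant_ids) {
  inds <- unique(long$individual_id)
  m <- matrix(NA_integer_,
    nrow = length(variant_ids), ncol = length(inds),
    dimnames = list(variant_ids, inds)
  )
  m[cbind(match(long$variant_id, variant_ids), match(long$individual_id, inds))] <-
    gt_to_code(long$genotype)
  m
}

#' @export
print.fs_cohort <- function(x, ...) {
  cat(
    "<fs_cohort> ", length(unique(x$ped$family_id)), " families, ",
    nrow(x$ped), " individuals, ", nrow(x$variants), " variants (",
    ncol(x$geno), " genotyped individuals)\n",
    sep = ""
  )
  invisible(x)
}

#' Long-format genotype calls of a cohort
#'
#' @param x An `fs_cohort`.
#' @param variants Optional variant ids to restrict to.
#' @return Tibble with `variant_id`, `individual_id`, `genotype` (label,
#'   `NA` = missing) and `depth` when depths are stored.
#' @export
genotype_calls <- function(x, variants = NULL) {
  stopifnot(inherits(x, "fs_cohort"))
  g <- x$geno
  if (!is.null(variants)) g <- g[rownames(g) %in% variants, , drop = FALSE]
  out <- tibble(
    variant_id = rep(rownames(g), times = ncol(g)),
    individual_id = rep(colnames(g), each = nrow(g)),
    genotype = code_to_gt(as.vector(g))
  )
  if (!is.null(x$depth)) {
    d <- x$depth[rownames(g), colnames(g), drop = FALSE]
    out$depth <- as.vector(d)
  }
  out
}

#' Carrier and genotyped predicates
#'
#' `is_carrier()` is `TRUE` for genotypes carrying at least one alternate
#' allele (`het`, `hom_alt`, `hemi_alt`); a missing genotype is `FALSE` and
#' distinguishable through `is_genotyped()`. Sharing and carrier counts in the
#' package always drop missing genotypes from denominators rather than
#' counting them either way.
#'
#' @param genotype Character vector of genotype labels (or `NA`/`"missing"`).
#' @return Logical vector.
#' @export
is_carrier <- function(genotype) {
  code_is_carrier(gt_to_code(genotype))
}

#' @rdname is_carrier
#' @export
is_genotyped <- function(genotype) {
  !is.na(gt_to_code(genotype))
}

#' Build an annotation table
#'
#' Per-variant functional annotations: gnomAD-style population allele
#' frequencies (`af_fin`, `af_nfe`, `af_global`), binarized calls from the 8
#' pathogenicity predictors (SIFT, PolyPhen, LRT, MutationTaster,
#' MutationAssessor, FATHMM_MKL, MetaSVM, MetaLR; `"damaging"`,
#' `"tolerated"`, `NA` = unavailable), CADD phred, three conservation scores
#' (GERP++ RS, phyloP 100-way, SiPhy 29-way), optional ClinVar classification
#' with review stars (consulted by filters only at >= 2 stars), protein domain
#' label, CTCF-site flag and curated gene-relevance flags (`brain_expressed`,
#' `glioma_relevant`).
#'
#' @param variant_id Variant keys.
#' @param ... Annotation columns; unspecified fields default to `NA`/`FALSE`.
#' @return Annotation tibble keyed by `variant_id`.
#' @export
annotation_table <- function(variant_id, ...) {
  dots <- list(...)
  n <- length(variant_id)
  defaults <- c(
    list(af_fin = 0, af_nfe = 0, af_global = 0),
    setNames(rep(list(NA_character_), length(PREDICTORS)), PREDICTORS),
    list(
      cadd_phred = NA_real_, gerp_rs = NA_real_, phylop100 = NA_real_,
      siphy = NA_real_, clinvar_class = NA_character_,
      clinvar_stars = NA_integer_, domain = NA_character_, ctcf_site = FALSE,
      brain_expressed = FALSE, glioma_relevant = FALSE
    )
  )
  cols <- modifyList(defaults, dots)
  out <- as_tibble(c(list(variant_id = variant_id), lapply(cols, rep_len, n)))
  validate_annotations(out)
  out
}

validate_annotations <- function(ann, rows = seq_len(nrow(ann))) {
  for (col in c("af_fin", "af_nfe", "af_global")) {
    bad <- !is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1)
    if (any(bad)) {
      abort(paste0(
        col, " outside [0,1] at row(s): ",
        paste(head(rows[bad], 5), collapse = ", ")
      ))
    }
  }
  for (p in PREDICTORS) {
    bad <- !is.na(ann[[p]]) & !ann[[p]] %in% c("damaging", "tolerated")
    if (any(bad)) {
      abort(paste0("invalid ", p, " call at row(s): ", paste(head(rows[bad], 5), collapse = ", ")))
    }
  }
  bad <- !is.na(ann$clinvar_stars) & (ann$clinvar_stars < 0 | ann$clinvar_stars > 4)
  if (any(bad)) abort("clinvar_stars must be in 0..4")
  invisible(ann)
}

#' Read an annotation TSV
#'
#' Tab-separated, one row per variant, with the fixed header
#' `chrom pos ref alt af_fin af_nfe af_global SIFT PolyPhen LRT MutationTaster
#' MutationAssessor FATHMM_MKL MetaSVM MetaLR cadd_phred gerp_rs phylop100
#' siphy clinvar_class clinvar_stars domain ctcf_site brain_expressed
#' glioma_relevant`. Empty predictor cells are recorded as unavailable (`NA`).
#'
#' @param path Path to the TSV.
#' @return Annotation tibble keyed by `variant_id`.
#' @export
read_annotations <- function(path) {
  ann <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), ref = readr::col_character(),
      alt = readr::col_character(),
      .default = readr::col_guess()
    )
  )
  needed <- c("chrom", "pos", "ref", "alt", "af_fin", "af_nfe", "af_global", PREDICTORS)
  missing_cols <- setdiff(needed, names(ann))
  if (length(missing_cols) > 0) {
    abort(paste0("annotation TSV missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (p in PREDICTORS) ann[[p]] <- as.character(ann[[p]])
  optional <- list(
    cadd_phred = NA_real_, gerp_rs = NA_real_, phylop100 = NA_real_, siphy = NA_real_,
    clinvar_class = NA_character_, clinvar_stars = NA_integer_, domain = NA_character_,
    ctcf_site = FALSE, brain_expressed = FALSE, glioma_relevant = FALSE
  )
  for (nm in names(optional)) if (!nm %in% names(ann)) ann[[nm]] <- optional[[nm]]
  # all-NA columns are type-ambiguous in TSV; coerce to their declared types
  for (nm in c("clinvar_class", "domain")) ann[[nm]] <- as.character(ann[[nm]])
  for (nm in c("cadd_phred", "gerp_rs", "phylop100", "siphy")) ann[[nm]] <- as.numeric(ann[[nm]])
  ann$clinvar_stars <- as.integer(ann$clinvar_stars)
  out <- ann |>
    mutate(
      variant_id = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      ctcf_site = as.logical(.data$ctcf_site),
      brain_expressed = as.logical(.data$brain_expressed),
      glioma_relevant = as.logical(.data$glioma_relevant)
    ) |>
    select(
      "variant_id", "af_fin", "af_nfe", "af_global", dplyr::all_of(PREDICTORS),
      "cadd_phred", "gerp_rs", "phylop100", "siphy", "clinvar_class",
      "clinvar_stars", "domain", "ctcf_site", "brain_expressed", "glioma_relevant"
    )
  validate_annotations(out)
  out
}

#' Consensus pathogenicity call over available predictors
#'
#' Aggregates the binarized calls of the 8 predictors, evaluated over the
#' available (non-missing) predictors only. The default `"majority"` rule
#' requires more than half of the available predictors to call damaging;
#' `"all"` requires every available predictor; `"at_least_k"` requires `k`.
#'
#' @param ann Annotation tibble (rows are variants) or a named character
#'   vector of predictor calls.
#' @param rule Consensus rule.
#' @param k Count for `rule = "at_least_k"`.
#' @return Logical vector, one element per variant.
#' @export
#' @examples
#' calls <- c(SIFT = "damaging", PolyPhen = "damaging", LRT = NA)
#' damaging_consensus(calls)
damaging_consensus <- function(ann, rule = c("majority", "all", "at_least_k"), k = NULL) {
  rule <- match.arg(rule)
  if (!is.data.frame(ann)) {
    ann <- as_tibble(as.list(ann))
    for (p in setdiff(PREDICTORS, names(ann))) ann[[p]] <- NA_character_
  }
  calls <- as.matrix(ann[, PREDICTORS, drop = FALSE])
  n_avail <- rowSums(!is.na(calls))
  n_dmg <- rowSums(calls == "damaging", na.rm = TRUE)
  if (any(n_avail == 0)) {
    abort("no available predictor call for at least one variant")
  }
  switch(rule,
    majority = n_dmg > n_avail / 2,
    all = n_dmg == n_avail,
    at_least_k = {
      if (is.null(k)) abort("rule \"at_least_k\" requires `k`")
      n_dmg >= k
    }
  )
}

# counts used by reports (n damaging / n available), tolerant of 0 available
predictor_counts <- function(ann) {
  calls <- as.matrix(ann[, PREDICTORS, drop = FALSE])
  tibble(
    variant_id = ann$variant_id,
    n_damaging = rowSums(calls == "damaging", na.rm = TRUE),
    n_predictors = rowSums(!is.na(calls))
  )
}
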