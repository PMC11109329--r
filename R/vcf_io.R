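#' Read germline genotypes from a VCF
#'
#' Parses a VCF (v4.x, via \pkg{vcfR}), decomposes multiallelic sites into one
#' record per alternate allele, and returns the cohort fragment (variant
#' table, genotype code matrix, optional depth matrix). Sample names must
#' match pedigree individual ids. Diploid male genotype calls on chrX are
#' coerced to hemizygous codes with a warning (a heterozygous male chrX call
#' becomes missing); haploid GT fields are read as hemizygous directly.
#'
#' @param path Path to the VCF file (plain text or bgzipped).
#' @param ped Pedigree tibble used to check sample names and sex.
#' @param consequence,source,gene Optional vectors (recycled) for fields a
#'   plain VCF does not carry; usually supplied by the annotation table
#'   instead.
#' @return List with `variants` (tibble), `geno` (integer matrix) and `depth`
#'   (matrix or `NULL`); pass to [cohort()].
#' @export
read_vcf <- function(path, ped, consequence = "other", source = "wes_candidate",
                     gene = NA_character_) {
  if (!file.exists(path)) abort(paste0("VCF file not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fm <- vcfR::getFIX(v)
  if (!is.matrix(fm)) fm <- matrix(fm, nrow = 1, dimnames = list(NULL, names(fm)))
  fix <- as.data.frame(fm, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, ped$individual_id)
  if (length(unknown) > 0) {
    abort(paste0(
      "VCF sample(s) absent from pedigrees: ",
      paste(unknown, collapse = ", ")
    ))
  }
  if (nrow(fix) == 0) {
    return(list(
      variants = variant_table(character(), integer(), character(), character()),
      geno = matrix(NA_integer_, 0, length(samples), dimnames = list(NULL, samples)),
      depth = NULL
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  has_dp <- grepl("DP", v@gt[, "FORMAT"][1] %||% "")
  dp <- if (has_dp) {
    suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  } else {
    NULL
  }
  sex <- setNames(ped$sex, ped$individual_id)[samples]
  male <- !is.na(sex) & sex == "male"
  if (!is.matrix(gt)) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, samples))
  gt <- gt[, samples, drop = FALSE]

  # biallelic sites: dictionary lookup over the whole matrix
  dict <- c(
    "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L, "0" = 3L, "1" = 4L
  )
  chroms <- normalize_chrom(fix$CHROM)
  n_alt <- lengths(strsplit(fix$ALT, ",", fixed = TRUE))
  multi <- which(n_alt > 1)

  codes <- matrix(unname(dict[gt]), nrow = nrow(gt), dimnames = dimnames(gt))
  # coerce diploid male chrX calls to hemizygous
  x_rows <- chroms == "X" & n_alt == 1
  if (any(x_rows) && any(male)) {
    sub <- codes[x_rows, male, drop = FALSE]
    if (any(sub %in% 0:2)) {
      warn("diploid male chrX genotypes coerced to hemizygous (het calls set missing)")
      sub[sub == 0L] <- 3L
      sub[sub == 2L] <- 4L
      sub[sub == 1L] <- NA_integer_
      codes[x_rows, male] <- sub
    }
  }
  rec <- tibble(
    chrom = chroms, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    rsid = if_else(is.na(fix$ID) | fix$ID == ".", NA_character_, fix$ID)
  )
  geno_rows <- lapply(seq_len(nrow(rec)), function(i) codes[i, ])
  depth_rows <- if (!is.null(dp)) lapply(seq_len(nrow(rec)), function(i) dp[i, samples]) else list()

  # multiallelic sites: decompose into one record per alternate allele
  if (length(multi) > 0) {
    keep <- setdiff(seq_len(nrow(rec)), multi)
    rec <- rec[keep, , drop = FALSE]
    geno_rows <- geno_rows[keep]
    if (!is.null(dp)) depth_rows <- depth_rows[keep]
    for (i in multi) {
      alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
      alleles <- strsplit(gsub("\\|", "/", ifelse(is.na(gt[i, ]), ".", gt[i, ])),
        "/",
        fixed = TRUE
      )
      for (k in seq_along(alts)) {
        code_k <- vapply(seq_along(samples), function(j) {
          a <- alleles[[j]]
          if (any(a == ".")) {
            return(NA_integer_)
          }
          dose <- sum(a == as.character(k))
          if (length(a) == 1L) {
            if (dose == 1L) 4L else 3L
          } else if (chroms[i] == "X" && male[[j]]) {
            if (dose == 2L) 4L else if (dose == 0L) 3L else NA_integer_
          } else {
            dose
          }
        }, integer(1))
        rec <- bind_rows(rec, tibble(
          chrom = chroms[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[[k]],
          rsid = if (is.na(fix$ID[i]) || fix$ID[i] == ".") NA_character_ else fix$ID[i]
        ))
        geno_rows[[length(geno_rows) + 1L]] <- setNames(code_k, samples)
        if (!is.null(dp)) depth_rows[[length(depth_rows) + 1L]] <- dp[i, samples]
      }
    }
  }
  variants <- variant_table(rec$chrom, rec$pos, rec$ref, rec$alt,
    rsid = rec$rsid,
    gene = gene, consequence = consequence, source = source
  )
  geno <- do.call(rbind, geno_rows)
  dimnames(geno) <- list(variants$variant_id, samples)
  depth <- if (length(depth_rows) > 0) {
    d <- do.call(rbind, depth_rows)
    dimnames(d) <- dimnames(geno)
    d
  } else {
    NULL
  }
  list(variants = variants, geno = geno, depth = depth)
}

#' Write cohort genotypes to a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT (and DP when depths are stored) that
#' round-trips through [read_vcf()]. Hemizygous codes are written as haploid
#' GT fields.
#'
#' @param x An `fs_cohort` or a fragment list as returned by [read_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  variants <- x$variants
  geno <- x$geno
  depth <- x$depth
  ord <- order(match(variants$chrom, VALID_CHROMS), variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  geno <- geno[variants$variant_id, , drop = FALSE]
  if (!is.null(depth)) depth <- depth[variants$variant_id, , drop = FALSE]
  samples <- colnames(geno)
  gt_str <- matrix(
    c("0/0", "0/1", "1/1", "0", "1")[geno + 1L],
    nrow = nrow(geno)
  )
  gt_str[is.na(geno)] <- "./."
  fmt <- "GT"
  if (!is.null(depth)) {
    fmt <- "GT:DP"
    dstr <- ifelse(is.na(depth), ".", as.character(depth))
    gt_str <- matrix(paste(gt_str, dstr, sep = ":"), nrow = nrow(geno))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=famseg",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(depth)) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      samples
    ), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(i) {
    paste(c(
      variants$chrom[i], variants$pos[i],
      if (is.na(variants$rsid[i])) "." else variants$rsid[i],
      variants$ref[i], variants$alt[i], ".", "PASS", ".", fmt,
      gt_str[i, ]
    ), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
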