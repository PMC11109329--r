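#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows distinct rename n across pull
#'   if_else row_number first case_when
#' @importFrom tibble tibble as_tibble tribble
#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats rbinom rbeta runif fisher.test p.adjust setNames qnorm
#'   median chisq.test
#' @importFrom utils head modifyList
NULL

# Genotype alphabet. Genotypes are stored as character labels in tibbles and as
# integer codes (0:4, NA = missing) inside the cohort genotype matrix.
GT_LEVELS <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt")
GT_CODES <- setNames(0:4, GT_LEVELS)

PREDICTORS <- c(
  "SIFT", "PolyPhen", "LRT", "MutationTaster", "MutationAssessor",
  "FATHMM_MKL", "MetaSVM", "MetaLR"
)

CONSEQUENCES <- c(
  "missense", "synonymous", "intronic", "utr3", "utr5", "frameshift",
  "stopgain", "splice", "downstream", "upstream", "intergenic", "other"
)

VALID_CHROMS <- c(as.character(1:22), "X", "Y", "MT")

gt_to_code <- function(x) {
  bad <- !is.na(x) & !x %in% c(GT_LEVELS, "missing")
  if (any(bad)) {
    abort(paste0("unknown genotype label(s): ", paste(unique(x[bad]), collapse = ", ")))
  }
  out <- unname(GT_CODES[x])
  out[!is.na(x) & x == "missing"] <- NA_integer_
  as.integer(out)
}

code_to_gt <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  out[ok] <- GT_LEVELS[x[ok] + 1L]
  out
}

code_is_carrier <- function(x) !is.na(x) & x %in% c(1L, 2L, 4L)
code_is_ref <- function(x) !is.na(x) & x %in% c(0L, 3L)

# Alternate-allele dosage of a genotype code (hemizygous counts once).
code_dosage <- function(x) {
  out <- rep(NA_real_, length(x))
  out[!is.na(x)] <- c(0, 1, 2, 0, 1)[x[!is.na(x)] + 1L]
  out
}

#' Build a variant key
#'
#' Variant identity throughout the package is the string
#' `chrom:pos:ref:alt` on hg19 (1-based positions); rsid and HGVS names are
#' annotations, never identity.
#'
#' @param chrom Chromosome as `1`--`22`, `X`, `Y` or `MT` (no `chr` prefix).
#' @param pos 1-based position.
#' @param ref,alt Reference and alternate alleles.
#' @return Character vector of keys.
#' @export
#' @examples
#' variant_key("2", 155099285, "C", "T")
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), pos, ref, alt, sep = ":")
}

normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  bad <- !x %in% VALID_CHROMS
  if (any(bad)) {
    abort(paste0("invalid chromosome(s): ", paste(unique(chrom[bad]), collapse = ", ")))
  }
  x
}

is_x <- function(chrom) normalize_chrom(chrom) == "X"
is_y <- function(chrom) normalize_chrom(chrom) == "Y"

# Local RNG scope: run code under a seed without disturbing the global stream.
with_seed_local <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- rlang::`%||%`
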