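#' Phased trio cohort container
#'
#' In-memory representation of a phased, biallelic SNP cohort of
#' mother--father--child trios (or mother--child duos). Haplotypes are stored
#' as two sample-by-variant integer matrices (`hap1`, `hap2`) with entries in
#' \{0, 1\} (0 = reference allele) and `NA` for missing calls; phase is taken
#' as given.
#'
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (single-nucleotide alleles), optionally `dr2` (imputation quality).
#' @param samples data.frame with columns `sample_id`, `role`
#'   (`"mother"`, `"father"` or `"child"`).
#' @param pedigree data.frame with columns `child`, `mother`, `father`
#'   (`NA` father denotes a duo).
#' @param hap1,hap2 integer matrices, samples x variants, rownames =
#'   `sample_id`, colnames = variant `id`.
#' @return An object of class `trio_cohort`.
#' @export
trio_cohort <- function(variants, samples, pedigree, hap1, hap2) {
  variants <- as.data.frame(variants)
  samples <- as.data.frame(samples)
  pedigree <- as.data.frame(pedigree)
  obj <- structure(
    list(variants = variants, samples = samples, pedigree = pedigree,
         hap1 = as.matrix(hap1), hap2 = as.matrix(hap2)),
    class = "trio_cohort")
  validate_trio_cohort(obj)
  obj
}

validate_trio_cohort <- function(x) {
  v <- x$variants
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  if (any(duplicated(v$id))) stop("duplicate variant ids")
  nt <- c("A", "C", "G", "T")
  if (!all(v$ref %in% nt) || !all(v$alt %in% nt))
    stop("ref/alt must be single nucleotides (A,C,G,T); non-SNP record found")
  if (any(v$ref == v$alt)) stop("ref == alt for some variant")
  if (any(v$pos < 1)) stop("positions must be >= 1 (1-based)")
  ord <- order(chrom_rank(v$chrom), v$pos)
  if (!identical(ord, seq_len(nrow(v))))
    stop("variants not sorted by (chrom, pos); refusing to reorder silently")
  if (anyDuplicated(cbind(chrom_rank(v$chrom), v$pos)))
    stop("variant order not strictly increasing by (chrom, pos)")
  s <- x$samples
  if (!all(c("sample_id", "role") %in% names(s)))
    stop("samples must have sample_id and role")
  if (!all(s$role %in% c("mother", "father", "child")))
    stop("unknown sample role")
  p <- x$pedigree
  if (!all(c("child", "mother", "father") %in% names(p)))
    stop("pedigree must have child, mother, father")
  if (!all(p$child %in% s$sample_id))
    stop("pedigree child absent from samples")
  if (any(is.na(p$mother)) || !all(p$mother %in% s$sample_id))
    stop("pedigree error: every child must have a mother in the cohort")
  fa <- p$father[!is.na(p$father)]
  if (!all(fa %in% s$sample_id)) stop("pedigree father absent from samples")
  for (h in list(x$hap1, x$hap2)) {
    if (!identical(dim(h), c(nrow(s), nrow(v))))
      stop("haplotype matrix dimensions do not match samples x variants")
    if (!all(h %in% c(0L, 1L, NA_integer_)))
      stop("haplotype alleles must be 0/1/NA")
  }
  if (!identical(rownames(x$hap1), s$sample_id) ||
      !identical(rownames(x$hap2), s$sample_id))
    stop("haplotype rownames must equal sample ids")
  invisible(x)
}

# numeric ordering for chromosome labels ("1".."22"); non-numeric sorts last
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(as.character(chrom)))
  n[is.na(n)] <- Inf
  n
}

#' @export
print.trio_cohort <- function(x, ...) {
  p <- x$pedigree
  cat("Phased trio cohort:", nrow(x$samples), "samples,",
      nrow(x$variants), "variants\n")
  cat("  ", sum(!is.na(p$father)), "trios,", sum(is.na(p$father)),
      "duos\n")
  invisible(x)
}

#' Allele dosage matrix
#'
#' @param cohort a `trio_cohort`.
#' @param samples optional character vector of sample ids (default all).
#' @return integer matrix of alternate-allele dosages (0/1/2, `NA` missing),
#'   samples x variants.
#' @export
dosages <- function(cohort, samples = NULL) {
  d <- cohort$hap1 + cohort$hap2
  if (!is.null(samples)) {
    missing <- setdiff(samples, rownames(d))
    if (length(missing))
      stop("samples absent from cohort: ", paste(missing, collapse = ", "))
    d <- d[samples, , drop = FALSE]
  }
  d
}

#' Sample ids by pedigree role
#'
#' Mothers/fathers are founders; `mothers_of()` returns mothers aligned to the
#' pedigree's child order.
#' @param cohort a `trio_cohort`.
#' @return character vector of sample ids.
#' @export
founders <- function(cohort) {
  cohort$samples$sample_id[cohort$samples$role %in% c("mother", "father")]
}

#' @rdname founders
#' @export
mothers <- function(cohort) {
  cohort$samples$sample_id[cohort$samples$role == "mother"]
}

#' Subset a cohort to a set of variants (order preserved)
#' @param cohort a `trio_cohort`.
#' @param variant_ids character vector of variant ids to keep.
#' @return a `trio_cohort`.
#' @export
subset_variants <- function(cohort, variant_ids) {
  keep <- cohort$variants$id %in% variant_ids
  if (!any(keep)) stop("no requested variant present in cohort")
  trio_cohort(cohort$variants[keep, , drop = FALSE],
              cohort$samples, cohort$pedigree,
              cohort$hap1[, keep, drop = FALSE],
              cohort$hap2[, keep, drop = FALSE])
}
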