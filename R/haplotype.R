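#' Infer parental origin of child alleles at one site
#'
#' When mother or child is homozygous the transmission is resolved by
#' Mendelian logic alone. When both are heterozygous, the child haplotype of
#' maternal origin is identified by local haplotype sharing: each child
#' haplotype is compared with the maternal haplotype carrying the same allele
#' at the site, and the contiguous exact match extending left and right
#' (up to `window` variants each side, same chromosome) is measured; the
#' child haplotype with the longer flanking match is taken as maternal. An
#' exact tie is reported unresolved. The paternal transmitted allele is the
#' child allele not attributed to the mother.
#'
#' @param cohort a [trio_cohort].
#' @param pair_index row of the cohort pedigree.
#' @param variant_id variant to resolve.
#' @param window flanking variants compared on each side (default 25).
#' @return list with `resolved` (logical) and, when resolved, integer alleles
#'   `mt` (maternal transmitted), `mnt` (maternal non-transmitted), `pt`
#'   (paternal transmitted).
#' @export
infer_transmission <- function(cohort, pair_index, variant_id, window = 25L) {
  i <- match(variant_id, cohort$variants$id)
  if (is.na(i)) stop("variant not found: ", variant_id)
  ped <- cohort$pedigree[pair_index, ]
  mi <- match(ped$mother, cohort$samples$sample_id)
  ci <- match(ped$child, cohort$samples$sample_id)
  m <- unname(c(cohort$hap1[mi, i], cohort$hap2[mi, i]))
  ch <- unname(c(cohort$hap1[ci, i], cohort$hap2[ci, i]))
  unresolved <- list(resolved = FALSE)
  if (anyNA(m) || anyNA(ch)) return(unresolved)
  if (m[1] == m[2]) {                       # mother homozygous
    if (!m[1] %in% ch) return(unresolved)   # Mendelian inconsistency
    pt <- if (ch[1] == m[1]) ch[2] else ch[1]
    return(list(resolved = TRUE, mt = m[1], mnt = m[1], pt = pt))
  }
  if (ch[1] == ch[2]) {                     # child homozygous, mother het
    if (!ch[1] %in% m) return(unresolved)
    return(list(resolved = TRUE, mt = ch[1], mnt = m[1] + m[2] - ch[1],
                pt = ch[1]))
  }
  # double heterozygote: local haplotype sharing
  same_chrom <- cohort$variants$chrom == cohort$variants$chrom[i]
  lo <- max(1L, i - window); hi <- min(nrow(cohort$variants), i + window)
  rng <- lo:hi
  rng <- rng[same_chrom[rng]]
  score <- numeric(2)
  for (h in 1:2) {
    chap <- if (h == 1L) cohort$hap1[ci, ] else cohort$hap2[ci, ]
    k <- if (m[1] == chap[i]) 1L else 2L    # maternal hap sharing the allele
    mhap <- if (k == 1L) cohort$hap1[mi, ] else cohort$hap2[mi, ]
    score[h] <- flank_match(chap, mhap, i, rng)
  }
  if (score[1] == score[2]) return(unresolved)
  hm <- which.max(score)
  mt <- if (hm == 1L) ch[1] else ch[2]
  list(resolved = TRUE, mt = mt, mnt = 1L - mt,
       pt = if (hm == 1L) ch[2] else ch[1])
}

# contiguous exact match around site i, restricted to positions rng
flank_match <- function(a, b, i, rng) {
  eq <- a[rng] == b[rng]
  eq[is.na(eq)] <- FALSE
  at <- match(i, rng)
  len <- 0L
  j <- at - 1L
  while (j >= 1L && eq[j]) { len <- len + 1L; j <- j - 1L }
  j <- at + 1L
  while (j <= length(eq) && eq[j]) { len <- len + 1L; j <- j + 1L }
  len
}

#' Haplotype allele-count decomposition per mother--child pair
#'
#' Sums BP-increasing allele indicators over the resolved sites of
#' `variant_set`, separately for the maternal transmitted, maternal
#' non-transmitted and paternal transmitted haplotypes. Unresolved sites are
#' excluded from all three sums and tallied. For duos (no father in the
#' pedigree) the paternal count is reported as `NA`.
#'
#' @param cohort a [trio_cohort].
#' @param counted_alleles named character vector (variant -> counted allele).
#' @param variant_set variant ids to score (default: all of
#'   `counted_alleles`).
#' @param window flanking window for [infer_transmission()].
#' @return data.frame: `pair_id` (child id), `mt_count`, `mnt_count`,
#'   `pt_count`, `n_resolved`, `n_unresolved`.
#' @export
haplotype_scores <- function(cohort, counted_alleles,
                             variant_set = names(counted_alleles),
                             window = 25L) {
  miss <- setdiff(variant_set, cohort$variants$id)
  if (length(miss))
    stop("variant absent from cohort: ", paste(miss, collapse = ", "))
  vi <- match(variant_set, cohort$variants$id)
  counted01 <- ifelse(counted_alleles[variant_set] ==
                        cohort$variants$alt[vi], 1L, 0L)
  bad <- counted_alleles[variant_set] != cohort$variants$alt[vi] &
    counted_alleles[variant_set] != cohort$variants$ref[vi]
  if (any(bad))
    stop("counted allele matches neither ref nor alt for: ",
         paste(variant_set[bad], collapse = ", "))
  ped <- cohort$pedigree
  out <- data.frame(pair_id = ped$child,
                    mt_count = 0L, mnt_count = 0L, pt_count = 0L,
                    n_resolved = 0L, n_unresolved = 0L,
                    stringsAsFactors = FALSE)
  for (p in seq_len(nrow(ped))) {
    has_father <- !is.na(ped$father[p])
    for (s in seq_along(variant_set)) {
      tr <- infer_transmission(cohort, p, variant_set[s], window)
      if (!tr$resolved) {
        out$n_unresolved[p] <- out$n_unresolved[p] + 1L
        next
      }
      out$n_resolved[p] <- out$n_resolved[p] + 1L
      out$mt_count[p] <- out$mt_count[p] + (tr$mt == counted01[s])
      out$mnt_count[p] <- out$mnt_count[p] + (tr$mnt == counted01[s])
      out$pt_count[p] <- out$pt_count[p] + (tr$pt == counted01[s])
    }
    if (!has_father) out$pt_count[p] <- NA_integer_
  }
  out
}
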