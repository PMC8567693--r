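#' Per-variant quality-control metrics
#'
#' Call rate is the fraction of non-missing genotypes over all samples; MAF
#' and the 1-df Hardy--Weinberg chi-square test are computed on founders
#' (mothers and fathers) so transmitted copies are not double-counted; DR2 is
#' taken from the cohort's variant table when present.
#'
#' @param cohort a [trio_cohort].
#' @return data.frame with `id`, `call_rate`, `maf`, `hwe_p`, `dr2`.
#' @export
variant_qc <- function(cohort) {
  dos_all <- dosages(cohort)
  call_rate <- colMeans(!is.na(dos_all))
  dof <- dosages(cohort, founders(cohort))
  af <- colMeans(dof, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- apply(dof, 2L, hwe_test)
  dr2 <- if ("dr2" %in% names(cohort$variants)) cohort$variants$dr2 else NA_real_
  data.frame(id = cohort$variants$id, call_rate = call_rate, maf = maf,
             hwe_p = hwe_p, dr2 = dr2, row.names = NULL)
}

# 1-df chi-square HWE test on a founder dosage vector (0/1/2)
hwe_test <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0L) return(NA_real_)
  obs <- c(sum(d == 0L), sum(d == 1L), sum(d == 2L))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stats::pchisq(sum((obs - expd)^2 / expd), df = 1L, lower.tail = FALSE)
}

#' Variant quality-control filter
#'
#' Removes variants with call rate < 95%, MAF < 0.01, Hardy--Weinberg
#' p < 1e-5 (founders), imputation DR2 < 0.7 (when available) or a
#' non-autosomal chromosome label.
#'
#' @param cohort a [trio_cohort].
#' @param thresholds named list overriding the default cutoffs
#'   (`call_rate`, `maf`, `hwe_p`, `dr2`).
#' @return list with `cohort` (filtered) and `report` (per-variant metrics
#'   with an `excluded` reason column, `""` for retained variants).
#' @export
qc_filter <- function(cohort,
                      thresholds = list(call_rate = 0.95, maf = 0.01,
                                        hwe_p = 1e-5, dr2 = 0.7)) {
  qc <- variant_qc(cohort)
  chrom_num <- suppressWarnings(as.integer(as.character(cohort$variants$chrom)))
  autosomal <- !is.na(chrom_num) & chrom_num >= 1L & chrom_num <= 22L
  reason <- character(nrow(qc))
  flag <- function(bad, label) ifelse(bad & reason == "", label, reason)
  reason <- flag(!autosomal, "non_autosomal")
  reason <- flag(qc$call_rate < thresholds$call_rate, "call_rate")
  reason <- flag(qc$maf < thresholds$maf, "maf")
  reason <- flag(!is.na(qc$hwe_p) & qc$hwe_p < thresholds$hwe_p, "hwe")
  reason <- flag(!is.na(qc$dr2) & qc$dr2 < thresholds$dr2, "dr2")
  qc$excluded <- reason
  keep <- qc$id[reason == ""]
  if (length(keep) == 0L) stop("no variant left after QC")
  list(cohort = subset_variants(cohort, keep), report = qc)
}

#' LD-clumping parameters
#'
#' Defaults mirror classic PLINK-style clumping:
#' `--clump-p1 1 --clump-p2 1 --clump-r2 0.1 --clump-kb 1000`.
#'
#' @param p1 index-variant p-value ceiling.
#' @param p2 secondary (clumped) p-value ceiling.
#' @param r2 LD pruning threshold.
#' @param kb window half-width in kilobases.
#' @export
clump_params <- function(p1 = 1, p2 = 1, r2 = 0.1, kb = 1000) {
  if (r2 <= 0 || r2 >= 1) stop("r2 must be in (0, 1)")
  if (kb <= 0) stop("kb must be positive")
  list(p1 = p1, p2 = p2, r2 = r2, kb = kb)
}

#' Greedy LD clumping
#'
#' Sorts variants by ascending association p-value (ties by chromosome then
#' position), repeatedly takes the best unclaimed variant as an index, and
#' discards every unclaimed variant within +/- `kb` kilobases whose squared
#' correlation with the index is at least `r2`. LD is computed from the
#' mothers' alternate-allele dosages of the target cohort itself.
#'
#' @param sumstats summary-statistic data.frame (one trait).
#' @param cohort a [trio_cohort]; every sumstat variant must be present.
#' @param params a [clump_params()] list.
#' @return character vector of retained (index) variant ids, in selection
#'   order.
#' @export
ld_clump <- function(sumstats, cohort, params = clump_params()) {
  v <- cohort$variants
  miss <- setdiff(sumstats$variant_id, v$id)
  if (length(miss))
    stop("variant absent from cohort: ", paste(utils::head(miss, 5),
                                               collapse = ", "))
  ss <- sumstats[sumstats$p_value <= params$p2, , drop = FALSE]
  idx <- match(ss$variant_id, v$id)
  ord <- order(ss$p_value, chrom_rank(v$chrom[idx]), v$pos[idx])
  ss <- ss[ord, , drop = FALSE]
  idx <- idx[ord]
  dos <- dosages(cohort, mothers(cohort))
  alive <- rep(TRUE, nrow(ss))
  keep <- character(0)
  win <- params$kb * 1000
  for (k in seq_len(nrow(ss))) {
    if (!alive[k]) next
    if (ss$p_value[k] > params$p1) break
    keep <- c(keep, ss$variant_id[k])
    alive[k] <- FALSE
    near <- which(alive &
                    v$chrom[idx] == v$chrom[idx[k]] &
                    abs(v$pos[idx] - v$pos[idx[k]]) <= win)
    if (length(near)) {
      r <- suppressWarnings(
        stats::cor(dos[, idx[k]], dos[, idx[near], drop = FALSE]))
      r[is.na(r)] <- 0
      alive[near[r^2 >= params$r2]] <- FALSE
    }
  }
  keep
}

# align sumstat (effect, other) alleles to cohort (ref, alt); returns signed
# weight per alt-allele copy, NA for unmatched rows (palindromic/mismatch)
align_weights <- function(sumstats, variants) {
  i <- match(sumstats$variant_id, variants$id)
  ref <- variants$ref[i]; alt <- variants$alt[i]
  w <- rep(NA_real_, nrow(sumstats))
  fwd <- sumstats$effect_allele == alt & sumstats$other_allele == ref
  rev <- sumstats$effect_allele == ref & sumstats$other_allele == alt
  w[fwd] <- sumstats$beta[fwd]
  w[rev] <- -sumstats$beta[rev]
  if (any(is.na(w) & !is.na(i)))
    warning("dropping ", sum(is.na(w) & !is.na(i)),
            " variant(s) with allele mismatch (strand flips not attempted)")
  w
}

#' Dosage-weighted PGS at a ladder of p-value thresholds
#'
#' For each threshold, the raw score per mother is the sum over retained
#' clumped variants with p <= threshold of the BP-increasing-allele dosage
#' times the normalized effect size, then z-scaled across mothers. When trait
#' values are supplied, the adjusted R-squared of each score against the
#' trait is recorded and the threshold maximizing it is marked selected.
#'
#' @param sumstats summary statistics (one trait).
#' @param cohort a [trio_cohort].
#' @param clumped character vector of clumped variant ids ([ld_clump()]).
#' @param thresholds p-value thresholds.
#' @param trait_values optional numeric trait per mother (mother order).
#' @return object of class `pgs_result`: list with per-threshold entries
#'   (`threshold`, `variant_ids`, `raw`, `z`, `degenerate`, `empty`),
#'   `adjusted_r2`, `selected` and `weights`.
#' @export
threshold_and_score <- function(sumstats, cohort, clumped,
                                thresholds = c(1e-6, 1e-5, 1e-4, 1e-3),
                                trait_values = NULL) {
  ss <- sumstats[sumstats$variant_id %in% clumped, , drop = FALSE]
  w <- align_weights(ss, cohort$variants)
  ok <- !is.na(w)
  ss <- ss[ok, , drop = FALSE]; w <- w[ok]
  mom <- mothers(cohort)
  dos <- dosages(cohort, mom)
  scores <- vector("list", length(thresholds))
  adj_r2 <- rep(NA_real_, length(thresholds))
  for (j in seq_along(thresholds)) {
    sel <- ss$p_value <= thresholds[j]
    if (!any(sel)) {
      scores[[j]] <- list(threshold = thresholds[j], variant_ids = character(0),
                          raw = stats::setNames(rep(0, length(mom)), mom),
                          z = stats::setNames(rep(0, length(mom)), mom),
                          degenerate = TRUE, empty = TRUE)
      next
    }
    cols <- match(ss$variant_id[sel], cohort$variants$id)
    raw <- as.numeric(dos[, cols, drop = FALSE] %*% w[sel])
    zs <- zscale(raw)
    scores[[j]] <- list(threshold = thresholds[j],
                        variant_ids = ss$variant_id[sel],
                        raw = stats::setNames(raw, mom),
                        z = stats::setNames(zs$z, mom),
                        degenerate = zs$degenerate, empty = FALSE)
    if (!is.null(trait_values) && !zs$degenerate)
      adj_r2[j] <- summary(stats::lm(trait_values ~ raw))$adj.r.squared
  }
  names(scores) <- format(thresholds, scientific = TRUE)
  structure(list(scores = scores, thresholds = thresholds,
                 adjusted_r2 = stats::setNames(adj_r2, names(scores)),
                 selected = if (all(is.na(adj_r2))) NA_integer_
                            else which.max(adj_r2),
                 weights = stats::setNames(w, ss$variant_id)),
            class = "pgs_result")
}

#' @export
print.pgs_result <- function(x, ...) {
  cat("PGS at", length(x$thresholds), "p-value thresholds\n")
  for (j in seq_along(x$scores)) {
    s <- x$scores[[j]]
    cat(sprintf("  p <= %-8s %4d variants  adj.R2 %s%s\n",
                format(s$threshold, scientific = TRUE),
                length(s$variant_ids),
                ifelse(is.na(x$adjusted_r2[j]), "NA",
                       sprintf("%.3f", x$adjusted_r2[j])),
                if (!is.na(x$selected) && j == x$selected) "  [selected]" else ""))
  }
  invisible(x)
}

#' SBP-increasing counted allele per annotated variant
#'
#' The allele counted in the unweighted risk scores is the SBP-increasing
#' allele from the annotation table -- including for the DBP-discordant
#' variants, whose SBP-increasing allele decreases DBP.
#'
#' @param annotation annotation data.frame ([read_annotation()]).
#' @param variant_ids variants required to be covered (default: all annotated).
#' @return named character vector, counted allele per variant.
#' @export
orient_sbp_increasing <- function(annotation, variant_ids = NULL) {
  if (is.null(variant_ids)) variant_ids <- annotation$variant_id
  miss <- setdiff(variant_ids, annotation$variant_id)
  if (length(miss))
    stop("variants missing from annotation: ", paste(miss, collapse = ", "))
  i <- match(variant_ids, annotation$variant_id)
  stats::setNames(annotation$sbp_increasing_allele[i], variant_ids)
}

#' Derive SBP-increasing alleles from summary statistics
#'
#' For cohorts without a curated annotation: the counted allele is the effect
#' allele when the SBP beta is positive, the other allele otherwise.
#'
#' @param sumstats_sbp SBP summary statistics.
#' @return named character vector, counted allele per variant.
#' @export
sbp_increasing_from_sumstats <- function(sumstats_sbp) {
  stats::setNames(ifelse(sumstats_sbp$beta > 0, sumstats_sbp$effect_allele,
                         sumstats_sbp$other_allele),
                  sumstats_sbp$variant_id)
}

#' Unweighted BP-increasing allele count per mother
#'
#' @param cohort a [trio_cohort].
#' @param counted_alleles named character vector (variant id -> counted
#'   allele), e.g. from [orient_sbp_increasing()].
#' @param subset variant ids to sum over (default: all of `counted_alleles`).
#' @param samples sample ids to score (default: mothers).
#' @return named integer vector of allele counts in `[0, 2 * |subset|]`.
#' @export
unweighted_score <- function(cohort, counted_alleles,
                             subset = names(counted_alleles),
                             samples = mothers(cohort)) {
  if (length(subset) == 0L) stop("empty variant subset")
  miss <- setdiff(subset, cohort$variants$id)
  if (length(miss))
    stop("variant absent from cohort: ", paste(miss, collapse = ", "))
  i <- match(subset, cohort$variants$id)
  counted <- counted_alleles[subset]
  is_alt <- counted == cohort$variants$alt[i]
  is_ref <- counted == cohort$variants$ref[i]
  if (any(!is_alt & !is_ref))
    stop("counted allele matches neither ref nor alt for: ",
         paste(subset[!is_alt & !is_ref], collapse = ", "))
  dos <- dosages(cohort, samples)[, i, drop = FALSE]
  dos[, is_ref] <- 2L - dos[, is_ref, drop = FALSE]
  rowSums(dos)
}

#' Partition variants by vasculature classification
#'
#' @param annotation annotation data.frame.
#' @param variant_ids variants to partition (default: all annotated).
#' @return list with elements `vasculature_related`, `unlikely_related`,
#'   `unknown` (disjoint, exhaustive).
#' @export
subdivide_by_class <- function(annotation, variant_ids = NULL) {
  if (is.null(variant_ids)) variant_ids <- annotation$variant_id
  miss <- setdiff(variant_ids, annotation$variant_id)
  if (length(miss))
    stop("unlabeled variants: ", paste(miss, collapse = ", "))
  cls <- annotation$vasc_class[match(variant_ids, annotation$variant_id)]
  list(vasculature_related = variant_ids[cls == "vasculature-related"],
       unlikely_related = variant_ids[cls == "unlikely related"],
       unknown = variant_ids[cls == "unknown"])
}

#' Exclude pleiotropic variants
#'
#' Removes variants associated with any of the auxiliary traits (BMI, T2D,
#' HbA1c) at or below the chosen p-value threshold; variants absent from an
#' auxiliary table are kept.
#'
#' @param variant_ids character vector.
#' @param aux_sumstats list of auxiliary summary-statistic data.frames.
#' @param threshold p-value threshold (1e-8, 1e-6 or 1e-4 in the standard
#'   battery, but any value in (0, 1] is accepted).
#' @return reduced character vector.
#' @export
exclude_pleiotropic <- function(variant_ids, aux_sumstats, threshold) {
  bad <- character(0)
  for (aux in aux_sumstats) {
    hit <- aux$variant_id[aux$p_value <= threshold]
    bad <- union(bad, hit)
  }
  setdiff(variant_ids, bad)
}
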