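test_that("Hardy-Weinberg and MAF filters behave at the textbook cases", {
  # founders at exact HWE proportions: chi-square 0, retained
  h1 <- matrix(c(rep(0L, 25), rep(0L, 50), rep(1L, 25)), ncol = 1)
  h2 <- matrix(c(rep(0L, 25), rep(1L, 50), rep(1L, 25)), ncol = 1)
  expect_equal(hwe_test(as.numeric(h1 + h2)), 1)
  co <- mothers_cohort(h1, h2)
  expect_equal(qc_filter(co)$report$excluded, "")

  # monomorphic variant: maf 0, removed (and sole-variant cohorts error out)
  co0 <- mothers_cohort(cbind(h1, 0L), cbind(h2, 0L), mk_variants(2))
  res <- qc_filter(co0)
  expect_equal(res$report$excluded, c("", "maf"))
  expect_equal(nrow(res$cohort$variants), 1L)
})

test_that("planted QC failures are removed exactly", {
  study <- simulate_study(tiny_config(seed = 61))
  co <- study$cohort
  ids <- co$variants$id
  bad_dr2 <- ids[c(3, 17, 30)]
  bad_call <- ids[c(8, 44)]
  bad_mono <- ids[c(12, 50)]
  co$variants$dr2[match(bad_dr2, ids)] <- 0.5
  co$hap1[seq_len(10), match(bad_call, ids)] <- NA_integer_
  co$hap1[, match(bad_mono, ids)] <- 0L
  co$hap2[, match(bad_mono, ids)] <- 0L
  res <- qc_filter(co)
  planted <- sort(c(bad_dr2, bad_call, bad_mono))
  expect_equal(sort(res$report$id[res$report$excluded != ""]), planted)
})

test_that("non-autosomal variants are excluded", {
  v <- mk_variants(2); v$chrom <- c("1", "X")
  h <- matrix(rbinom(40, 1, 0.4), ncol = 2)
  co <- mothers_cohort(h, matrix(rbinom(40, 1, 0.4), ncol = 2), v)
  expect_equal(qc_filter(co)$report$excluded[2], "non_autosomal")
})

test_that("clumping keeps the stronger of two correlated variants", {
  set.seed(71)
  h1 <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  h2 <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  v <- mk_variants(2, pos = c(1000L, 11000L))  # 10 kb apart
  perf <- mothers_cohort(cbind(h1, h1), cbind(h2, h2), v)   # r2 = 1
  ss <- data.frame(variant_id = v$id, chrom = "1", pos = v$pos,
                   effect_allele = "G", other_allele = "A",
                   beta = c(0.1, 0.1), p_value = c(1e-8, 1e-6),
                   trait = "SBP")
  expect_equal(ld_clump(ss, perf), "v001")

  h1b <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  h2b <- matrix(rbinom(40, 1, 0.5), ncol = 1)
  indep <- mothers_cohort(cbind(h1, h1b), cbind(h2, h2b), v)
  got <- ld_clump(ss, indep)
  expect_setequal(got, c("v001", "v002"))
})

test_that("greedy clumping equals brute-force clumping on small cohorts", {
  for (seed in c(81, 82, 83, 84)) {
    cfg <- sim_config(n_trios = 30, n_blocks = 3, block_size = 5,
                      within_block_r2 = 0.9, n_causal = 3, seed = seed)
    study <- simulate_study(cfg)
    ss <- study$sumstats$SBP
    got <- ld_clump(ss, study$cohort)
    expect_equal(got, brute_clump(ss, study$cohort))
    # one index per high-LD block
    expect_equal(length(got), 3L)
    # invariant: no retained pair within the window has r2 >= 0.1
    dos <- dosages(study$cohort, mothers(study$cohort))
    vv <- study$cohort$variants
    ii <- match(got, vv$id)
    for (x in seq_along(ii)) for (y in seq_len(x - 1L)) {
      if (vv$chrom[ii[x]] == vv$chrom[ii[y]] &&
          abs(vv$pos[ii[x]] - vv$pos[ii[y]]) <= 1e6)
        expect_lt(suppressWarnings(cor(dos[, ii[x]], dos[, ii[y]]))^2, 0.1)
    }
  }
})

test_that("dosage-weighted scoring is plain arithmetic with allele alignment", {
  # one mother with dosages 0,1,2 and betas 0.1, -0.2, 0.3 -> raw 0.4
  h1 <- rbind(c(0L, 0L, 1L)); h2 <- rbind(c(0L, 1L, 1L))
  co <- mothers_cohort(h1, h2, mk_variants(3))
  ss <- data.frame(variant_id = c("v001", "v002", "v003"), chrom = "1",
                   pos = 1:3 * 1000L, effect_allele = "G",
                   other_allele = "A", beta = c(0.1, -0.2, 0.3),
                   p_value = rep(1e-9, 3), trait = "SBP")
  res <- threshold_and_score(ss, co, ss$variant_id, thresholds = 1e-6)
  expect_equal(unname(res$scores[[1]]$raw), 0.4)
  expect_true(res$scores[[1]]$degenerate)  # single sample cannot be z-scaled

  # swapping (effect, other) with a beta sign flip leaves the score unchanged
  ss_fl <- ss
  ss_fl$effect_allele <- "A"; ss_fl$other_allele <- "G"
  ss_fl$beta <- -ss$beta
  res_fl <- threshold_and_score(ss_fl, co, ss$variant_id, thresholds = 1e-6)
  expect_equal(res_fl$scores[[1]]$raw, res$scores[[1]]$raw)
  # per-allele weights are identical after alignment
  expect_equal(align_weights(ss_fl, co$variants), align_weights(ss, co$variants))

  # all-zero betas: flagged degenerate, not NaN
  ss0 <- ss; ss0$beta <- 0
  res0 <- threshold_and_score(ss0, co, ss$variant_id, thresholds = 1e-6)
  expect_true(res0$scores[[1]]$degenerate)
  expect_false(anyNA(res0$scores[[1]]$z))
})

test_that("thresholded variant sets nest and the score recovers the liability", {
  study <- simulate_study(tiny_config(seed = 91, n_trios = 60))
  qc <- qc_filter(study$cohort)
  ss <- study$sumstats$SBP
  ss <- ss[ss$variant_id %in% qc$cohort$variants$id, ]
  clumped <- ld_clump(ss, qc$cohort)
  res <- threshold_and_score(ss, qc$cohort, clumped)
  sets <- lapply(res$scores, `[[`, "variant_ids")
  for (j in seq_len(length(sets) - 1L))
    expect_true(all(sets[[j]] %in% sets[[j + 1L]]))
  liab <- study$truth$liability[match(mothers(qc$cohort),
                                      mothers(study$cohort))]
  best <- res$scores[[length(res$scores)]]
  expect_gt(cor(best$raw, liab), 0.9)
  # z-scores are standardized to machine precision
  expect_lt(abs(mean(best$z)), 1e-9)
  expect_lt(abs(sd(best$z) - 1), 1e-9)
})

test_that("SBP-increasing orientation honours the annotation, incl. discordant", {
  ann <- annotation_bp41()
  counted <- orient_sbp_increasing(ann)
  expect_equal(length(counted), 41L)
  expect_identical(unname(counted), ann$sbp_increasing_allele)
  disc <- ann$variant_id[ann$dbp_discordant]
  expect_equal(length(disc), 7L)
  expect_identical(counted[disc],
                   setNames(ann$sbp_increasing_allele[ann$dbp_discordant],
                            disc))
  expect_error(orient_sbp_increasing(ann, c(ann$variant_id[1], "rsNOPE")),
               "rsNOPE")
})

test_that("unweighted allele counts sum over subsets (partition identity)", {
  h1 <- rbind(rep(1L, 5), rep(0L, 5))
  h2 <- rbind(rep(1L, 5), rep(0L, 5))
  v <- mk_variants(5)
  co <- mothers_cohort(h1, h2, v)
  counted <- setNames(rep("G", 5), v$id)   # alt allele everywhere
  sc <- unweighted_score(co, counted)
  expect_equal(unname(sc), c(10L, 0L))     # hom counted at 5 SNPs; none
  part <- list(v$id[1:2], v$id[3], v$id[4:5])
  sums <- Reduce(`+`, lapply(part, function(s)
    unweighted_score(co, counted, subset = s)))
  expect_equal(sums, sc)
  expect_error(unweighted_score(co, counted, subset = character(0)), "empty")
})

test_that("vasculature partitions match the packaged panels", {
  p41 <- subdivide_by_class(annotation_bp41())
  expect_equal(lengths(p41)[c("vasculature_related", "unlikely_related",
                              "unknown")],
               c(vasculature_related = 18L, unlikely_related = 12L,
                 unknown = 11L))
  p67 <- subdivide_by_class(annotation_sbp67())
  expect_equal(unname(lengths(p67)), c(21L, 30L, 16L))
  p0 <- subdivide_by_class(annotation_bp41(), character(0))
  expect_equal(unname(lengths(p0)), c(0L, 0L, 0L))
  expect_error(subdivide_by_class(annotation_bp41(), "rsNOPE"), "unlabeled")
})

test_that("pleiotropy exclusion removes planted variants monotonically", {
  study <- simulate_study(tiny_config(seed = 95), n_pleiotropic = 2L)
  ids <- study$cohort$variants$id
  aux <- study$sumstats[c("BMI", "T2D", "HbA1c")]
  kept8 <- exclude_pleiotropic(ids, aux, 1e-8)
  kept6 <- exclude_pleiotropic(ids, aux, 1e-6)
  kept4 <- exclude_pleiotropic(ids, aux, 1e-4)
  expect_false(any(study$truth$pleiotropic %in% kept8))
  expect_false(any(study$truth$pleiotropic %in% kept4))
  expect_true(all(kept6 %in% kept8))
  expect_true(all(kept4 %in% kept6))
  # with no aux association below threshold the set is unchanged
  null_aux <- list(data.frame(variant_id = ids, p_value = 1))
  expect_equal(exclude_pleiotropic(ids, null_aux, 1e-8), ids)
})
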