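#' Simulation configuration
#'
#' Assembles (and validates) the configuration of the synthetic trio-cohort
#' generator. Defaults describe the study conditions the package is designed
#' around: 93 mother--child pairs of Japanese ancestry, blood-pressure GWAS
#' heritabilities of 0.0569/0.04/0.0496/0.0438 (SBP/DBP/MAP/PP), a mediation
#' structure in which the maternal BP-increasing genetic liability lowers
#' placental weight (path a = -0.396), placental weight raises birth weight
#' (path b = 0.661) and a small direct path (c' = -0.049), with log
#' pre-pregnancy BMI as a shared confounder of mediator and outcome.
#'
#' @param n_trios number of mother--father--child trios.
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param maf_range range the (block-constant) minor allele frequency is drawn
#'   from.
#' @param within_block_r2 target squared correlation between adjacent variants
#'   within a block.
#' @param a,b,c_direct generating path coefficients on the z scale:
#'   exposure -> mediator, mediator -> outcome, exposure -> outcome direct.
#' @param g_bmi_m,g_bmi_y effect of standardized log BMI on mediator/outcome.
#' @param h2 named per-trait PGS heritability targets.
#' @param n_causal number of causal variants (one per block, in the first
#'   `n_causal` blocks).
#' @param n_gwas notional GWAS sample size governing summary-statistic noise.
#' @param bp_pgs_share variance share of measured BP explained by the genetic
#'   liability (small: the cohort-scale PGS/BP association is null).
#' @param velocity_link shift (g/week per SD of mediator) of the weekly EFW
#'   increment after gestational week 30.
#' @param efw_noise multiplicative (log-scale) SD of ultrasound EFW
#'   measurement noise.
#' @param obs_range integer range of ultrasound observations per fetus,
#'   drawn from the antenatal checkup schedule (every 4 weeks until week 24,
#'   every 2 weeks until 36, weekly beyond).
#' @param seed integer seed (required).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_trios = 93L,
                       n_blocks = 60L,
                       block_size = 50L,
                       maf_range = c(0.1, 0.5),
                       within_block_r2 = 0.8,
                       a = -0.396,
                       b = 0.661,
                       c_direct = -0.049,
                       g_bmi_m = 0.1,
                       g_bmi_y = 0.1,
                       h2 = c(SBP = 0.0569, DBP = 0.04, MAP = 0.0496,
                              PP = 0.0438),
                       n_causal = 40L,
                       n_gwas = 136000L,
                       bp_pgs_share = 0.005,
                       velocity_link = 40,
                       efw_noise = 0.05,
                       obs_range = c(6L, 12L),
                       seed = NULL) {
  if (is.null(seed)) stop("seed is required")
  if (maf_range[1] <= 0 || maf_range[2] >= 0.5 + 1e-12 ||
      maf_range[1] > maf_range[2])
    stop("maf_range bounds must lie in (0, 0.5]")
  if (within_block_r2 < 0 || within_block_r2 >= 1)
    stop("within_block_r2 must be in [0, 1)")
  if (any(abs(c(a, b, c_direct)) >= 1))
    stop("|a|, |b|, |c_direct| must be < 1")
  if (n_causal > n_blocks) stop("n_causal cannot exceed n_blocks")
  if (obs_range[1] < 4L)
    stop("at least 4 ultrasound observations per fetus are required")
  resid_y <- 1 - (b^2 + c_direct^2 + g_bmi_y^2 +
                    2 * a * b * c_direct + 2 * b * g_bmi_m * g_bmi_y)
  resid_m <- 1 - a^2 - g_bmi_m^2
  if (resid_m <= 0 || resid_y <= 0)
    stop("config error: negative residual variance for mediator or outcome")
  structure(list(
    n_trios = as.integer(n_trios), n_blocks = as.integer(n_blocks),
    block_size = as.integer(block_size), maf_range = maf_range,
    within_block_r2 = within_block_r2, a = a, b = b, c_direct = c_direct,
    g_bmi_m = g_bmi_m, g_bmi_y = g_bmi_y, h2 = h2,
    n_causal = as.integer(n_causal), n_gwas = as.integer(n_gwas),
    bp_pgs_share = bp_pgs_share, velocity_link = velocity_link,
    efw_noise = efw_noise, obs_range = as.integer(obs_range),
    seed = as.integer(seed)), class = "sim_config")
}

#' Simulate a pool of LD-blocked phased haplotypes
#'
#' Haplotypes are built block-by-block with a copying chain: within a block
#' all variants share one MAF drawn from `maf_range`, the first allele is
#' Bernoulli(maf), and each subsequent allele copies its left neighbour with
#' probability `sqrt(within_block_r2)` (else a fresh Bernoulli draw). For
#' equal-frequency Bernoulli variables this gives adjacent allelic correlation
#' r = copy probability, hence adjacent r-squared near the target. Blocks are
#' mutually independent. Variants are laid out 1 kb apart within a block with
#' 5 Mb gaps between blocks, all on chromosome labels cycling over 1..22.
#'
#' @param config a [sim_config].
#' @param pool_size number of haplotypes in the pool (default 8 per trio,
#'   minimum 400 so LD summaries are stable).
#' @return list with `haps` (pool_size x n_variants 0/1 matrix), `variants`
#'   (data.frame as in [trio_cohort]), `block` (block index per variant) and
#'   `maf` (block MAF per variant).
#' @export
simulate_haplotype_pool <- function(config, pool_size = NULL) {
  if (is.null(pool_size)) pool_size <- max(400L, 8L * config$n_trios)
  set.seed(config$seed)
  n_var <- config$n_blocks * config$block_size
  copy_p <- sqrt(config$within_block_r2)
  haps <- matrix(0L, nrow = pool_size, ncol = n_var)
  block <- rep(seq_len(config$n_blocks), each = config$block_size)
  maf_block <- stats::runif(config$n_blocks, config$maf_range[1],
                            config$maf_range[2])
  maf <- maf_block[block]
  for (b in seq_len(config$n_blocks)) {
    cols <- which(block == b)
    m <- matrix(0L, nrow = pool_size, ncol = length(cols))
    m[, 1] <- stats::rbinom(pool_size, 1L, maf_block[b])
    for (j in seq_along(cols)[-1]) {
      copy <- stats::runif(pool_size) < copy_p
      fresh <- stats::rbinom(pool_size, 1L, maf_block[b])
      m[, j] <- ifelse(copy, m[, j - 1L], fresh)
    }
    haps[, cols] <- m
  }
  chrom <- as.character(((block - 1L) %% 22L) + 1L)
  within <- stats::ave(seq_len(n_var), block, FUN = seq_along)
  block_on_chrom <- stats::ave(block, chrom,
                               FUN = function(x) match(x, unique(x)))
  pos <- (block_on_chrom - 1L) * 5000000L + within * 1000L
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(n_var)),
    chrom = chrom, pos = as.integer(pos),
    ref = rep(c("A", "C", "G", "T"), length.out = n_var),
    alt = rep(c("G", "T", "A", "C"), length.out = n_var),
    dr2 = rep(1.0, n_var),
    stringsAsFactors = FALSE)
  ord <- order(chrom_rank(variants$chrom), variants$pos)
  list(haps = haps[, ord, drop = FALSE], variants = variants[ord, ],
       block = block[ord], maf = maf[ord])
}

#' Simulate trios from a haplotype pool
#'
#' Each parent draws two pool haplotypes; each child receives one maternal and
#' one paternal haplotype chosen uniformly, with no recombination inside the
#' simulated region, so the transmitted haplotype identity is exact and is
#' recorded in the returned truth.
#'
#' @param pool result of [simulate_haplotype_pool()].
#' @param config a [sim_config].
#' @return list with `cohort` (a [trio_cohort]) and `truth` (list holding the
#'   per-trio transmitted haplotype indices and the pool bookkeeping).
#' @export
simulate_trios <- function(pool, config) {
  n <- config$n_trios
  if (n < 1L) stop("n_trios must be >= 1")
  set.seed(config$seed + 1L)
  pool_n <- nrow(pool$haps)
  pick <- function() sample.int(pool_n, 1L)
  mid <- sprintf("M%03d", seq_len(n))
  fid <- sprintf("F%03d", seq_len(n))
  cid <- sprintf("C%03d", seq_len(n))
  ids <- c(mid, fid, cid)
  n_var <- ncol(pool$haps)
  h1 <- matrix(0L, nrow = 3L * n, ncol = n_var, dimnames = list(ids, NULL))
  h2 <- h1
  mat_transmitted <- integer(n)   # 1 or 2: which maternal haplotype the child got
  pat_transmitted <- integer(n)
  for (i in seq_len(n)) {
    m <- c(pick(), pick()); f <- c(pick(), pick())
    h1[i, ] <- pool$haps[m[1], ]; h2[i, ] <- pool$haps[m[2], ]
    h1[n + i, ] <- pool$haps[f[1], ]; h2[n + i, ] <- pool$haps[f[2], ]
    tm <- sample.int(2L, 1L); tf <- sample.int(2L, 1L)
    mat_transmitted[i] <- tm; pat_transmitted[i] <- tf
    h1[2L * n + i, ] <- pool$haps[m[tm], ]   # child hap1 = maternal
    h2[2L * n + i, ] <- pool$haps[f[tf], ]   # child hap2 = paternal
  }
  colnames(h1) <- colnames(h2) <- pool$variants$id
  samples <- data.frame(
    sample_id = ids,
    role = rep(c("mother", "father", "child"), each = n),
    stringsAsFactors = FALSE)
  pedigree <- data.frame(child = cid, mother = mid, father = fid,
                         stringsAsFactors = FALSE)
  cohort <- trio_cohort(pool$variants, samples, pedigree, h1, h2)
  truth <- list(pair_id = sprintf("P%03d", seq_len(n)),
                mother = mid, father = fid, child = cid,
                mat_transmitted = mat_transmitted,
                pat_transmitted = pat_transmitted,
                block = pool$block, maf = pool$maf)
  list(cohort = cohort, truth = truth)
}

#' Simulate phenotypes and GWAS summary statistics
#'
#' Builds the maternal genetic liability from the causal variants (scaled to
#' the per-trait heritability target), then generates standardized mediator
#' (placental weight) and outcome (birth weight) through the linear mediation
#' structure of [sim_config()], back-transforms both weights to grams through
#' a reference chart, simulates serial antenatal BP readings with a small
#' genetic share, and emits per-trait GWAS summary-statistic tables whose
#' betas are LD-propagated marginal effects plus sampling noise at the
#' notional GWAS sample size.
#'
#' @param sim result of [simulate_trios()].
#' @param config a [sim_config].
#' @param chart a `reference_chart` (default: the packaged synthetic chart).
#' @param n_pleiotropic number of causal variants additionally planted as
#'   BMI-associated in the auxiliary tables (for pleiotropy-exclusion tests).
#' @return list with `phenotypes` (a `pheno_table`), `sumstats` (one
#'   data.frame per trait incl. auxiliary BMI/T2D/HbA1c), and the augmented
#'   `truth` (generating betas, causal flags, liability, mediator/outcome z,
#'   log-BMI z, per-pair stratum).
#' @export
simulate_phenotypes <- function(sim, config, chart = placmed_chart(),
                                n_pleiotropic = 0L) {
  cohort <- sim$cohort; truth <- sim$truth
  set.seed(config$seed + 2L)
  n <- config$n_trios
  v <- cohort$variants
  n_var <- nrow(v)
  causal <- truth$block <= config$n_causal &
    stats::ave(seq_len(n_var), truth$block, FUN = seq_along) == 1L
  p <- truth$maf
  # per-variant base beta sized so the causal set explains h2[SBP] of trait var
  base_share <- config$h2[["SBP"]] / sum(causal)
  beta_base <- ifelse(causal,
                      sample(c(-1, 1), n_var, replace = TRUE) *
                        sqrt(base_share / (2 * p * (1 - p))),
                      0)
  dos_m <- dosages(cohort, mothers(cohort))
  raw <- as.numeric(dos_m %*% beta_base)
  G_z <- zscale(raw)$z
  sem <- simulate_sem(n, a = config$a, b = config$b,
                      c_direct = config$c_direct, g_bmi_m = config$g_bmi_m,
                      g_bmi_y = config$g_bmi_y, exposure = G_z)
  log_bmi <- sem$log_bmi
  B_z <- sem$B_z; M_z <- sem$M_z; Y_z <- sem$Y_z
  ga <- round(stats::runif(n, 37, 41.5), 1)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  parity <- sample(c("nulliparous", "parous"), n, replace = TRUE)
  strat <- chart_lookup(chart, floor(ga), sex, parity)
  bw <- strat$bw_mean + Y_z * strat$bw_sd
  pw <- strat$pw_mean + M_z * strat$pw_sd
  pair_id <- truth$pair_id
  pairs <- data.frame(
    pair_id = pair_id, mother = truth$mother,
    pre_pregnancy_bmi = exp(log_bmi),
    birth_weight = bw, placental_weight = pw,
    gestational_age_at_delivery = ga, fetal_sex = sex, parity = parity,
    hypertension_flag = "none", stringsAsFactors = FALSE)
  # serial BP: checkups every 4w to 24, every 2w to 36, weekly after
  share <- config$bp_pgs_share
  bp <- do.call(rbind, lapply(seq_len(n), function(i) {
    weeks <- c(seq(8, 24, 4), seq(26, 36, 2), seq(37, floor(ga[i])))
    weeks <- weeks[weeks <= ga[i]]
    liab <- sqrt(share) * G_z[i] + sqrt(1 - share) * stats::rnorm(1)
    dbp <- 65 + 6 * liab + stats::rnorm(length(weeks), 0, 4)
    pp <- pmax(42 + 5 * stats::rnorm(1) + stats::rnorm(length(weeks), 0, 3), 15)
    data.frame(pair_id = pair_id[i], gestational_week = weeks,
               sbp = dbp + pp, dbp = dbp)
  }))
  phenotypes <- structure(list(pairs = pairs, bp = bp), class = "pheno_table")
  # emitted summary statistics: marginal (LD-propagated) betas + GWAS noise
  se <- 1 / sqrt(2 * p * (1 - p) * config$n_gwas)
  marg <- marginal_betas(cohort, truth$block, beta_base)
  flip <- stats::runif(n_var) < 0.5    # emit half the rows effect-allele = ref
  mk_trait <- function(trait, scale) {
    bhat <- marg * scale + stats::rnorm(n_var, 0, se)
    pval <- pmax(2 * stats::pnorm(-abs(bhat) / se), 1e-300)
    data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
               effect_allele = ifelse(flip, v$ref, v$alt),
               other_allele = ifelse(flip, v$alt, v$ref),
               beta = ifelse(flip, -bhat, bhat),
               p_value = pval, trait = trait, stringsAsFactors = FALSE)
  }
  h2 <- config$h2
  sumstats <- list(
    SBP = mk_trait("SBP", 1),
    DBP = mk_trait("DBP", sqrt(h2[["DBP"]] / h2[["SBP"]])),
    MAP = mk_trait("MAP", sqrt(h2[["MAP"]] / h2[["SBP"]])),
    PP  = mk_trait("PP",  sqrt(h2[["PP"]]  / h2[["SBP"]])))
  aux_beta <- rep(0, n_var)
  pleio <- integer(0)
  if (n_pleiotropic > 0L) {
    pleio <- which(causal)[seq_len(min(n_pleiotropic, sum(causal)))]
    aux_beta[pleio] <- 0.1
  }
  mk_aux <- function(trait) {
    bhat <- aux_beta + stats::rnorm(n_var, 0, se)
    pval <- pmax(2 * stats::pnorm(-abs(bhat) / se), 1e-300)
    data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
               effect_allele = v$alt, other_allele = v$ref,
               beta = bhat, p_value = pval, trait = trait,
               stringsAsFactors = FALSE)
  }
  sumstats$BMI <- mk_aux("BMI")
  sumstats$T2D <- mk_aux("T2D")
  sumstats$HbA1c <- mk_aux("HbA1c")
  truth$beta <- beta_base
  truth$causal <- causal
  truth$pleiotropic <- v$id[pleio]
  truth$liability <- raw
  truth$G_z <- G_z
  truth$M_z <- M_z
  truth$Y_z <- Y_z
  truth$B_z <- B_z
  truth$a <- config$a; truth$b <- config$b
  truth$c_direct <- config$c_direct
  list(phenotypes = phenotypes, sumstats = sumstats, truth = truth)
}

#' Simulate the linear mediation structural equation layer
#'
#' Draws standardized exposure, confounder, mediator and outcome according to
#' the generating model
#' `M = a G + g_m B + e_m`, `Y = b M + c' G + g_y B + e_y`,
#' with residual SDs chosen so mediator and outcome have unit variance
#' (errors if the requested coefficients leave negative residual variance).
#' Used internally by [simulate_phenotypes()] and directly useful for
#' studying the mediation estimator without genotypes.
#'
#' @param n sample size.
#' @param a,b,c_direct,g_bmi_m,g_bmi_y generating coefficients (z scale).
#' @param exposure optional standardized exposure vector (default: standard
#'   normal draws, z-scaled).
#' @param seed optional seed.
#' @return data.frame with `G_z`, `B_z`, `M_z`, `Y_z`, `log_bmi`.
#' @export
simulate_sem <- function(n, a = -0.396, b = 0.661, c_direct = -0.049,
                         g_bmi_m = 0.1, g_bmi_y = 0.1, exposure = NULL,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sd_m2 <- 1 - a^2 - g_bmi_m^2
  sd_y2 <- 1 - (b^2 + c_direct^2 + g_bmi_y^2 +
                  2 * a * b * c_direct + 2 * b * g_bmi_m * g_bmi_y)
  if (sd_m2 <= 0 || sd_y2 <= 0)
    stop("config error: negative residual variance for mediator or outcome")
  G_z <- if (is.null(exposure)) zscale(stats::rnorm(n))$z else exposure
  log_bmi <- stats::rnorm(n, log(21), 0.12)
  B_z <- zscale(log_bmi)$z
  M_z <- a * G_z + g_bmi_m * B_z + stats::rnorm(n, 0, sqrt(sd_m2))
  Y_z <- b * M_z + c_direct * G_z + g_bmi_y * B_z +
    stats::rnorm(n, 0, sqrt(sd_y2))
  data.frame(G_z = G_z, B_z = B_z, M_z = M_z, Y_z = Y_z, log_bmi = log_bmi)
}

# expected marginal GWAS beta per variant: LD-weighted sum of causal betas
# within its block (blocks are independent); correlations from the cohort
marginal_betas <- function(cohort, block, beta) {
  out <- numeric(length(beta))
  dos <- dosages(cohort, founders(cohort))
  for (b in unique(block[beta != 0])) {
    cols <- which(block == b)
    cz <- cols[beta[cols] != 0]
    r <- suppressWarnings(stats::cor(dos[, cols, drop = FALSE],
                                     dos[, cz, drop = FALSE]))
    r[is.na(r)] <- 0
    out[cols] <- as.numeric(r %*% beta[cz])
  }
  out
}

#' Simulate serial ultrasound EFW observations
#'
#' Each fetus follows a smooth logistic weight curve; after gestational week
#' 30 the weekly increment is shifted by `velocity_link` times the fetus's
#' standardized placental-weight (mediator) value, emulating placenta-limited
#' third-trimester growth. Observations are drawn at 6--12 times between
#' weeks 12 and 38 with multiplicative log-normal measurement noise. The true
#' weekly curve and velocity are kept in the returned truth.
#'
#' @param pheno result of [simulate_phenotypes()].
#' @param config a [sim_config].
#' @return list with `ultrasound` (long data.frame) and `truth` augmented with
#'   `true_weeks`, `true_efw` and `true_velocity` per fetus.
#' @export
simulate_ultrasound <- function(pheno, config) {
  truth <- pheno$truth
  set.seed(config$seed + 3L)
  if (config$obs_range[1] < 4L)
    stop("at least 4 ultrasound observations per fetus are required")
  n <- config$n_trios
  weeks_grid <- 10:42
  K <- 5000 * exp(stats::rnorm(n, 0, 0.07))
  true_curves <- vector("list", n)
  true_vel <- vector("list", n)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    base <- K[i] / (1 + exp(-0.16 * (weeks_grid - 33)))
    inc <- diff(base)
    late <- weeks_grid[-1] > 30
    inc[late] <- pmax(inc[late] + config$velocity_link * truth$M_z[i], 5)
    efw <- cumsum(c(base[1], inc))
    true_curves[[i]] <- efw
    true_vel[[i]] <- inc
    # scan times follow the antenatal checkup schedule (every 4 weeks to
    # 24, every 2 weeks to 36, weekly beyond), with jitter and dropout
    schedule <- c(seq(12, 24, 4), seq(26, 36, 2), 37, 38)
    schedule <- schedule[schedule <= 38]
    n_obs <- sample(seq(min(config$obs_range[1], length(schedule)),
                        min(config$obs_range[2], length(schedule))), 1L)
    w <- sort(sample(schedule, n_obs)) +
      stats::runif(n_obs, -0.2, 0.2)
    w <- round(pmin(pmax(w, 12), 38), 1)
    while (any(diff(w) <= 0)) w <- w[c(TRUE, diff(w) > 0)]
    e_true <- stats::approx(weeks_grid, efw, xout = w)$y
    obs[[i]] <- data.frame(
      pair_id = truth$pair_id[i], gestational_week = w,
      efw = e_true * exp(stats::rnorm(length(w), 0, config$efw_noise)))
  }
  truth$true_weeks <- weeks_grid
  truth$true_efw <- do.call(rbind, true_curves)
  truth$true_velocity <- do.call(rbind, true_vel)
  rownames(truth$true_efw) <- rownames(truth$true_velocity) <- truth$pair_id
  list(ultrasound = do.call(rbind, obs), truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running pool, trio, phenotype and ultrasound
#' simulation from one configuration.
#'
#' @param config a [sim_config].
#' @param chart reference chart for the grams back-transformation.
#' @param n_pleiotropic see [simulate_phenotypes()].
#' @return list with `cohort`, `phenotypes`, `sumstats`, `ultrasound`,
#'   `chart`, `truth`.
#' @export
simulate_study <- function(config, chart = placmed_chart(),
                           n_pleiotropic = 0L) {
  pool <- simulate_haplotype_pool(config)
  sim <- simulate_trios(pool, config)
  ph <- simulate_phenotypes(sim, config, chart, n_pleiotropic)
  us <- simulate_ultrasound(ph, config)
  list(cohort = sim$cohort, phenotypes = ph$phenotypes,
       sumstats = ph$sumstats, ultrasound = us$ultrasound,
       chart = chart, truth = us$truth)
}

#' Write a simulated study to disk
#'
#' Emits the VCF + pedigree, all phenotype/ultrasound/summary-statistic TSVs
#' and a ground-truth TSV into a directory; files are accepted by the
#' package's readers.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_phased_vcf(study$cohort, fp("cohort.vcf"), fp("pedigree.tsv"))
  write_phenotypes(study$phenotypes, fp("phenotypes.tsv"), fp("bp.tsv"))
  write_ultrasound(study$ultrasound, fp("ultrasound.tsv"))
  write_reference_chart(study$chart, fp("chart.tsv"))
  write_summary_stats(do.call(rbind, study$sumstats), fp("sumstats.tsv"))
  tr <- study$truth
  utils::write.table(
    data.frame(pair_id = tr$pair_id, mat_transmitted = tr$mat_transmitted,
               pat_transmitted = tr$pat_transmitted, G_z = tr$G_z,
               M_z = tr$M_z, Y_z = tr$Y_z, B_z = tr$B_z),
    fp("truth_pairs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(variant_id = study$cohort$variants$id, beta = tr$beta,
               causal = tr$causal),
    fp("truth_variants.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
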