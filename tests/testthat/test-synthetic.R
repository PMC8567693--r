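test_that("within-block adjacent r-squared tracks the configured target", {
  cfg0 <- sim_config(n_trios = 10, n_blocks = 8, block_size = 10,
                     within_block_r2 = 0, n_causal = 4, seed = 21)
  pool0 <- simulate_haplotype_pool(cfg0, pool_size = 2000)
  adj_r2 <- function(pool) {
    same_block <- diff(pool$block) == 0
    r <- sapply(which(same_block), function(j)
      suppressWarnings(cor(pool$haps[, j], pool$haps[, j + 1])))
    mean(r^2, na.rm = TRUE)
  }
  expect_lt(adj_r2(pool0), 0.05)

  cfg8 <- sim_config(n_trios = 10, n_blocks = 8, block_size = 10,
                     within_block_r2 = 0.8, n_causal = 4, seed = 22)
  pool8 <- simulate_haplotype_pool(cfg8, pool_size = 2000)
  expect_lt(abs(adj_r2(pool8) - 0.8), 0.1)
})

test_that("the pool is reproducible under a fixed seed", {
  cfg <- tiny_config(seed = 23)
  p1 <- simulate_haplotype_pool(cfg)
  p2 <- simulate_haplotype_pool(cfg)
  expect_identical(p1$haps, p2$haps)
  expect_identical(p1$variants, p2$variants)
})

test_that("trio transmission is Mendelian and matches the recorded truth", {
  cfg <- tiny_config(seed = 24)
  pool <- simulate_haplotype_pool(cfg)
  sim <- simulate_trios(pool, cfg)
  co <- sim$cohort; tr <- sim$truth
  n <- cfg$n_trios
  for (i in seq_len(n)) {
    m <- rbind(co$hap1[tr$mother[i], ], co$hap2[tr$mother[i], ])
    f <- rbind(co$hap1[tr$father[i], ], co$hap2[tr$father[i], ])
    c1 <- co$hap1[tr$child[i], ]; c2 <- co$hap2[tr$child[i], ]
    # child hap1 is exactly the transmitted maternal haplotype
    expect_identical(c1, m[tr$mat_transmitted[i], ])
    expect_identical(c2, f[tr$pat_transmitted[i], ])
    # Mendelian consistency at every site
    expect_true(all(c1 == m[1, ] | c1 == m[2, ]))
    expect_true(all(c2 == f[1, ] | c2 == f[2, ]))
  }
  # child allele frequencies track the pool within 3 binomial SEs (pooled)
  kids <- co$samples$sample_id[co$samples$role == "child"]
  af_child <- colMeans(dosages(co, kids)) / 2
  pool_af <- colMeans(pool$haps)
  se <- sqrt(pool_af * (1 - pool_af) / (2 * n))
  expect_gt(mean(abs(af_child - pool_af) <= 3 * se + 1e-12), 0.95)
})

test_that("a null exposure->mediator path yields a null regression", {
  est <- sapply(1:50, function(k) {
    d <- simulate_sem(93, a = 0, seed = 300 + k)
    coef(lm(M_z ~ G_z + B_z, data = d))[["G_z"]]
  })
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(50))
})

test_that("calibrated paths reproduce the product-of-coefficients oracle", {
  d <- simulate_sem(93, seed = 77)
  fm <- lm(M_z ~ G_z + B_z, data = d)
  fy <- lm(Y_z ~ G_z + M_z + B_z, data = d)
  a_hat <- coef(fm)[["G_z"]]; b_hat <- coef(fy)[["M_z"]]
  se_a <- summary(fm)$coefficients["G_z", "Std. Error"]
  se_b <- summary(fy)$coefficients["M_z", "Std. Error"]
  se_ab <- sqrt(b_hat^2 * se_a^2 + a_hat^2 * se_b^2)  # delta method
  expect_lt(abs(a_hat * b_hat - (-0.396 * 0.661)), 2 * se_ab)
})

test_that("the genetic liability variance hits the heritability target", {
  cfg <- sim_config(n_trios = 20, n_blocks = 20, block_size = 10,
                    n_causal = 20, seed = 31)
  pool <- simulate_haplotype_pool(cfg, pool_size = 1000)
  sim <- simulate_trios(pool, cfg)
  ph <- simulate_phenotypes(sim, cfg)
  beta <- ph$truth$beta
  # fresh large sample of individuals drawn from the pool
  set.seed(99)
  i1 <- sample.int(nrow(pool$haps), 10000, replace = TRUE)
  i2 <- sample.int(nrow(pool$haps), 10000, replace = TRUE)
  cz <- which(beta != 0)
  liab <- (pool$haps[i1, cz] + pool$haps[i2, cz]) %*% beta[cz]
  expect_lt(abs(var(as.numeric(liab)) - 0.0569), 0.01)
})

test_that("ultrasound truth responds to the mediator only after week 30", {
  cfg0 <- tiny_config(seed = 41, velocity_link = 0)
  st0 <- simulate_study(cfg0)
  v34 <- st0$truth$true_velocity[, match(34, st0$truth$true_weeks[-1])]
  r0 <- cor(v34, st0$truth$M_z)
  expect_lt(abs(r0), 2 / sqrt(cfg0$n_trios))

  cfg1 <- tiny_config(seed = 42)  # default positive velocity link
  st1 <- simulate_study(cfg1)
  tw <- st1$truth$true_weeks[-1]
  v36 <- st1$truth$true_velocity[, match(36, tw)]
  v20 <- st1$truth$true_velocity[, match(20, tw)]
  expect_gt(cor(v36, st1$truth$M_z), 0.5)   # lower placenta, lower velocity
  expect_lt(abs(cor(v20, st1$truth$M_z)), 2 / sqrt(cfg1$n_trios))
})

test_that("emitted study files are byte-identical across reruns of one seed", {
  cfg <- tiny_config(seed = 51)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(b = 0.9, c_direct = 0.9, seed = 1),
               "residual variance")
  expect_error(sim_config(obs_range = c(3L, 5L), seed = 1),
               "at least 4")
  expect_error(simulate_trios(simulate_haplotype_pool(tiny_config(1)),
                              tiny_config(1, n_trios = 0L)),
               "n_trios")
})
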