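# small simulation configuration used throughout the unit tests
tiny_config <- function(seed, ...) {
  args <- list(n_trios = 40L, n_blocks = 6L, block_size = 10L,
               n_causal = 4L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

mk_variants <- function(n, chrom = "1", pos = seq_len(n) * 1000L) {
  data.frame(id = sprintf("v%03d", seq_len(n)), chrom = chrom,
             pos = as.integer(pos),
             ref = rep("A", n), alt = rep("G", n),
             stringsAsFactors = FALSE)
}

# a cohort of unrelated mothers with specified haplotype matrices
mothers_cohort <- function(h1, h2, variants = mk_variants(ncol(h1))) {
  ids <- sprintf("M%03d", seq_len(nrow(h1)))
  rownames(h1) <- rownames(h2) <- ids
  trio_cohort(variants,
              data.frame(sample_id = ids, role = "mother",
                         stringsAsFactors = FALSE),
              data.frame(child = character(0), mother = character(0),
                         father = character(0)),
              h1, h2)
}

# independent re-statement of greedy clumping: full r2 matrix + rescans
brute_clump <- function(ss, cohort, r2 = 0.1, kb = 1000) {
  v <- cohort$variants
  dos <- dosages(cohort, mothers(cohort))
  R2 <- suppressWarnings(cor(dos))^2
  R2[is.na(R2)] <- 0
  i <- match(ss$variant_id, v$id)
  alive <- rep(TRUE, nrow(ss))
  keep <- character(0)
  repeat {
    cand <- which(alive)
    if (!length(cand)) break
    ord <- cand[order(ss$p_value[cand], v$pos[i[cand]])]
    k <- ord[1]
    keep <- c(keep, ss$variant_id[k])
    alive[k] <- FALSE
    for (j in which(alive)) {
      if (v$chrom[i[j]] == v$chrom[i[k]] &&
          abs(v$pos[i[j]] - v$pos[i[k]]) <= kb * 1000 &&
          R2[i[j], i[k]] >= r2) alive[j] <- FALSE
    }
  }
  keep
}

# one mother-father-child trio with explicit haplotypes (vectors per variant)
single_trio_cohort <- function(m1, m2, f1, f2, c1, c2,
                               variants = mk_variants(length(m1))) {
  h1 <- rbind(M001 = as.integer(m1), F001 = as.integer(f1),
              C001 = as.integer(c1))
  h2 <- rbind(M001 = as.integer(m2), F001 = as.integer(f2),
              C001 = as.integer(c2))
  trio_cohort(variants,
              data.frame(sample_id = c("M001", "F001", "C001"),
                         role = c("mother", "father", "child"),
                         stringsAsFactors = FALSE),
              data.frame(child = "C001", mother = "M001", father = "F001",
                         stringsAsFactors = FALSE),
              h1, h2)
}
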