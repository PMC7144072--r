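test_that("the study layout yields 840 plots: 56 primary, 16 secondary, 768 test", {
  spec <- design_spec(n_blocks = 56, n_secondary_blocks = 8,
                      split_factor = "row_type")
  expect_equal(n_test_plots(spec), 768L)
  des <- generate_design(spec, sprintf("E%03d", 1:768), seed = 1)
  expect_equal(nrow(des), 840L)
  expect_equal(sum(des$check_class == "primary"), 56L)
  expect_equal(sum(des$check_class == "secondary"), 16L)
  expect_equal(sum(des$check_class == "test"), 768L)
  expect_equal(sort(unique(des$entry_id[des$check_class == "test"])),
               sprintf("E%03d", 1:768))
  expect_length(validate_design(des), 0L)
})

test_that("a single block holds one primary check and 14 test plots", {
  spec <- design_spec(n_blocks = 1, n_secondary_blocks = 0)
  des <- generate_design(spec, sprintf("E%02d", 1:14), seed = 3)
  expect_equal(nrow(des), 15L)
  expect_equal(sum(des$check_class == "primary"), 1L)
  expect_equal(sum(des$check_class == "test"), 14L)
  prim <- des[des$check_class == "primary", ]
  expect_equal(c(prim$plot_row, prim$plot_col), c(3L, 2L))
})

test_that("design generation is seed-deterministic and seed-sensitive", {
  spec <- design_spec(n_blocks = 12, n_secondary_blocks = 4)
  ids <- sprintf("E%03d", seq_len(n_test_plots(spec)))
  a <- generate_design(spec, ids, seed = 5)
  b <- generate_design(spec, ids, seed = 5)
  c <- generate_design(spec, ids, seed = 6)
  expect_identical(as.data.frame(a), as.data.frame(b))
  sec_blocks <- function(d) sort(unique(d$block_id[d$check_class == "secondary"]))
  expect_false(identical(sec_blocks(a), sec_blocks(c)) &&
                 identical(a$entry_id, c$entry_id))
})

test_that("primary-check count equals block count across random specs", {
  set.seed(99)
  for (i in 1:5) {
    nb <- sample(4:30, 1)
    ns <- sample(0:min(nb, 6), 1)
    spec <- design_spec(n_blocks = nb, n_secondary_blocks = ns)
    des <- generate_design(spec, sprintf("X%03d", seq_len(n_test_plots(spec))),
                           seed = i)
    expect_equal(sum(des$check_class == "primary"), nb)
    expect_equal(length(unique(des$block_id)), nb)
  }
})

test_that("entry-count mismatch is rejected with the required count", {
  spec <- design_spec(n_blocks = 2, n_secondary_blocks = 0)
  expect_error(generate_design(spec, c("a", "b"), seed = 1), "28")
})

test_that("genotype generator honours missing rate and maf feasibility", {
  g0 <- generate_genotypes(40, c(25), c(60), ld_rho = 1, missing_rate = 0,
                           seed = 2)
  expect_false(anyNA(g0$genotypes))
  g1 <- generate_genotypes(40, c(25), c(60), ld_rho = 1, missing_rate = 0.2,
                           seed = 2)
  frac <- mean(is.na(g1$genotypes))
  expect_gt(frac, 0.1); expect_lt(frac, 0.3)
  expect_error(generate_genotypes(10, c(5), c(10), 1,
                                  maf_range = c(0.4, 0.6), seed = 1),
               "maf_range")
  expect_error(generate_genotypes(10, c(5), c(10), 1,
                                  maf_range = c(0.3, 0.2), seed = 1),
               "maf_range")
})

test_that("dense maps at large ld_rho approach within-population maximum r2", {
  g <- generate_genotypes(400, c(40), c(0.5), ld_rho = 0.05,
                          structure_delta = 0, maf_range = c(0.3, 0.5),
                          seed = 8)
  adj <- cbind(1:39, 2:40)
  r2 <- pairwise_r2(g$genotypes, adj)
  # copy probability exp(-0.05 * d) with d ~ 0.0125 cM is ~ 1: near-perfect
  # correlation is capped only by unequal marker frequencies
  expect_gt(mean(r2), 0.7)
})

test_that("simulated r2 matches the generator's closed-form expectation", {
  g <- generate_genotypes(700, c(120), c(80), ld_rho = 1.5,
                          structure_delta = 0.1, seed = 13)
  tru <- g$truth
  set.seed(1)
  pr <- cbind(sample(120, 400, replace = TRUE),
              sample(120, 400, replace = TRUE))
  pr <- pr[pr[, 1] != pr[, 2], , drop = FALSE]
  emp <- pairwise_r2(g$genotypes, pr)
  d <- abs(g$map$pos_cM[pr[, 1]] - g$map$pos_cM[pr[, 2]])
  ana <- expected_pair_r2(tru$f_pop1[pr[, 1]], tru$f_pop1[pr[, 2]],
                          tru$f_pop2[pr[, 1]], tru$f_pop2[pr[, 2]],
                          d, tru$ld_rho)
  # sample r2 is biased upward by ~1/n; compare binned means within
  # Monte-Carlo error
  bins <- cut(d, c(0, 0.5, 2, 5, 20, 80))
  emp_m <- tapply(emp, bins, mean)
  ana_m <- tapply(ana, bins, mean)
  expect_true(all(abs(emp_m - ana_m) < 0.05 + 2 / 700, na.rm = TRUE))
})

test_that("degenerate generator gives identical plots; seeding is exact", {
  spec <- design_spec(n_blocks = 4, n_secondary_blocks = 2)
  ids <- sprintf("E%02d", seq_len(n_test_plots(spec)))
  des <- generate_design(spec, ids, seed = 4)
  g <- generate_genotypes(length(ids), c(10), c(50), 1, seed = 4)
  rownames(g$genotypes) <- ids
  arch <- genetic_architecture(trait_covariance = {
    m <- matrix(0, 6, 6)
    dimnames(m) <- list(tillerqtl:::agronomic_traits(),
                        tillerqtl:::agronomic_traits())
    m
  }, survival_line_sd = 0, survival_plot_sd = 0)
  ph <- simulate_phenotypes(des, g$genotypes, arch,
                            spatial_model(noise_sd = 0, week_jitter_sd = 0),
                            seed = 9)
  for (tr in trait_names(ph)) {
    expect_equal(stats::sd(ph[[tr]]), 0,
                 info = tr, tolerance = 1e-12)
  }
  ph2 <- simulate_phenotypes(des, g$genotypes, arch,
                             spatial_model(noise_sd = 0, week_jitter_sd = 0),
                             seed = 9)
  expect_identical(as.data.frame(ph), as.data.frame(ph2))
})

test_that("a coded tiller QTL separates homozygote groups by its effect", {
  spec <- design_spec(n_blocks = 24, n_secondary_blocks = 4)
  ids <- sprintf("E%03d", seq_len(n_test_plots(spec)))
  des <- generate_design(spec, ids, seed = 2)
  g <- generate_genotypes(length(ids), c(40), c(60), 1,
                          maf_range = c(0.3, 0.5), seed = 3)
  rownames(g$genotypes) <- ids
  arch <- genetic_architecture(
    qtl = data.frame(marker = 7L, trait = "tiller_max", effect = 5))
  ph <- simulate_phenotypes(des, g$genotypes, arch,
                            spatial_model(noise_sd = 1, week_jitter_sd = 0.25),
                            seed = 6)
  df <- as.data.frame(ph)[as.data.frame(ph)$check_class == "test", ]
  dos <- unclass(g$genotypes)[df$entry_id, 7L]
  a <- df$tiller_max[dos == 0]; b <- df$tiller_max[dos == 2]
  tt <- t.test(b, a)
  diff <- unname(tt$estimate[1] - tt$estimate[2])
  expect_lt(abs(diff - 5), 3 * sqrt(sum((tt$stderr)^2, 0.04)))
  expect_lt(tt$p.value, 1e-6)
})

test_that("heritability targets are recovered through the ANOVA estimator", {
  spec <- design_spec(n_blocks = 24, n_secondary_blocks = 4)
  ids <- sprintf("E%03d", seq_len(n_test_plots(spec)))
  dA <- generate_design(spec, ids, year = 2014, seed = 21)
  dB <- generate_design(spec, ids, year = 2015, seed = 22)
  des <- trait_table(rbind(as.data.frame(dA), as.data.frame(dB)),
                     character(0))
  g <- generate_genotypes(length(ids), c(30), c(60), 1, seed = 23)
  rownames(g$genotypes) <- ids
  arch <- genetic_architecture(h2_targets = c(tiller_max = 0.5))
  ph <- simulate_phenotypes(des, g$genotypes, arch,
                            spatial_model(noise_sd = 1.5), seed = 24)
  df <- as.data.frame(ph)[as.data.frame(ph)$check_class == "test", ]
  h <- heritability(df, "tiller_max")
  expect_gt(h$H2, 0.5 - 0.13)   # 316 lines: wider band than the 500-line case
  expect_lt(h$H2, 0.5 + 0.13)
})

test_that("pure row gradient with zero noise is annihilated by M1 exactly", {
  spec <- design_spec(n_blocks = 16, n_secondary_blocks = 6)
  ids <- sprintf("E%03d", seq_len(n_test_plots(spec)))
  des <- generate_design(spec, ids, seed = 31)
  g <- generate_genotypes(length(ids), c(10), c(50), 1, seed = 32)
  rownames(g$genotypes) <- ids
  arch <- genetic_architecture(trait_covariance = {
    m <- matrix(0, 6, 6)
    dimnames(m) <- list(tillerqtl:::agronomic_traits(),
                        tillerqtl:::agronomic_traits())
    m
  })
  ph <- simulate_phenotypes(des, g$genotypes, arch,
                            spatial_model(row_gradient = 2, noise_sd = 0,
                                          week_jitter_sd = 0),
                            seed = 33)
  adj <- adjust_m1(ph, "plant_height")
  sec <- ph$check_class == "secondary"
  vars <- as.numeric(tapply(adj[sec], ph$entry_id[sec], stats::var))
  expect_equal(vars, rep(0, length(vars)), tolerance = 1e-20)
})
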