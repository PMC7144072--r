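test_that("marker filters implement the missing/het and strict-MAF rules", {
  calls <- cbind(
    bad_miss = c(rep(NA_integer_, 6), rep(0L, 3), 2L),   # 60% missing
    bad_het  = c(rep(1L, 6), rep(0L, 2), 2L, 2L),        # 60% het
    ok_mix   = c(rep(NA_integer_, 3), 1L, rep(0L, 3), rep(2L, 3)),  # 40%
    low_maf  = c(rep(0L, 10)),                            # MAF 0
    at_cut   = c(rep(0L, 7), rep(2L, 3)))                 # MAF 0.30
  toy <- toy_genotypes(calls)
  res <- filter_genotypes(toy$genotypes, toy$map, max_missing_het = 0.5,
                          min_maf = 0.30)
  expect_setequal(colnames(res$genotypes), c("ok_mix", "at_cut"))
  expect_equal(res$report$removed[res$report$rule == "missing_het"], 2L)
  expect_equal(res$report$removed[res$report$rule == "maf"], 1L)
  # MAF exactly at the cutoff is retained (removal is strictly less-than)
  expect_true("at_cut" %in% res$map$marker_id)
  expect_error(filter_genotypes(toy$genotypes, toy$map,
                                max_missing_het = 0.0, min_maf = 0.9),
               "all markers")
})

test_that("two-pass filtering also drops bad lines, with counts reported", {
  set.seed(2)
  calls <- matrix(sample(c(0L, 2L), 20 * 30, TRUE), 20)
  calls[1, seq(1, 30, 2)] <- NA       # line 1: 50% missing
  toy <- toy_genotypes(calls)
  res <- filter_genotypes(toy$genotypes, toy$map, max_missing_het = 0.05,
                          min_maf = 0, filter_lines = TRUE)
  expect_false("L01" %in% rownames(res$genotypes))
  expect_equal(res$report$removed[res$report$rule == "lines"], 1L)
})

test_that("imputation is a no-op without missing data and copies perfect proxies", {
  set.seed(3)
  calls <- matrix(sample(c(0L, 2L), 30 * 10, TRUE), 30)
  toy <- toy_genotypes(calls)
  expect_identical(unclass(impute_ld_knn(toy$genotypes)),
                   unclass(toy$genotypes))

  twin <- cbind(calls, calls[, 1])    # marker 11 duplicates marker 1
  dimnames(twin) <- list(sprintf("L%02d", 1:30), sprintf("M%02d", 1:11))
  twin[c(4, 9, 20), 11] <- NA
  g <- genotype_matrix(twin)
  done <- impute_ld_knn(g)
  expect_equal(unname(unclass(done)[c(4, 9, 20), 11]),
               unname(calls[c(4, 9, 20), 1]))
})

test_that("mask-and-recover accuracy exceeds 95% under strong LD", {
  g <- generate_genotypes(250, c(80), c(8), ld_rho = 0.25,
                          structure_delta = 0, maf_range = c(0.2, 0.5),
                          seed = 4)
  full <- unclass(g$genotypes)
  set.seed(5)
  mask <- which(stats::runif(length(full)) < 0.05)
  masked <- full
  masked[mask] <- NA_integer_
  rec <- unclass(impute_ld_knn(genotype_matrix(masked)))
  expect_false(anyNA(rec))
  acc <- mean(rec[mask] == full[mask])
  expect_gt(acc, 0.95)
})

test_that("PC covariates are orthogonal and BIC picks structure only when real", {
  g <- generate_genotypes(200, c(60), c(60), ld_rho = 1,
                          structure_delta = 0.25, seed = 6)
  pcs <- pc_covariates(g$genotypes, max_pcs = 5)
  cp <- crossprod(pcs$scores)
  off <- cp[upper.tri(cp)]
  expect_equal(unname(off), rep(0, length(off)), tolerance = 1e-6)
  expect_true(all(diff(pcs$var_explained) <= 1e-12))

  # trait equal to PC1 -> exactly 1 PC chosen; null traits mostly 0
  set.seed(7)
  traits <- data.frame(pc1_trait = pcs$scores[, 1],
                       matrix(stats::rnorm(200 * 10), 200,
                              dimnames = list(NULL, paste0("null", 1:10))))
  sel <- pc_covariates(g$genotypes, traits, max_pcs = 5)
  expect_equal(unname(sel$n_pcs["pc1_trait"]), 1L)
  expect_gt(mean(sel$n_pcs[paste0("null", 1:10)] == 0L), 0.5)
})

test_that("a perfect marker signal is recovered with ~100% variance and unit effect", {
  g <- generate_genotypes(120, c(50), c(70), ld_rho = 2,
                          structure_delta = 0, seed = 8)
  dose <- unclass(g$genotypes)[, 25]
  trait <- stats::setNames(as.numeric(dose), rownames(g$genotypes))
  scan <- single_marker_scan(g$genotypes, g$map, trait, maf_cutoff = 0.03)
  hit <- scan[scan$marker_id == colnames(g$genotypes)[25], ]
  expect_lt(hit$p_value, 1e-100)
  expect_equal(hit$effect, 1, tolerance = 1e-10)
  expect_equal(hit$pct_variance, 100, tolerance = 1e-6)
  expect_true(hit$significant)
})

test_that("scan effects are trait-scale equivariant with unchanged p-values", {
  g <- generate_genotypes(150, c(40), c(60), ld_rho = 1.5,
                          structure_delta = 0, seed = 9)
  set.seed(10)
  trait <- stats::setNames(
    unclass(g$genotypes)[, 5] * 0.4 + stats::rnorm(150),
    rownames(g$genotypes))
  s1 <- single_marker_scan(g$genotypes, g$map, trait)
  s2 <- single_marker_scan(g$genotypes, g$map, trait * 3)
  expect_equal(s2$effect, 3 * s1$effect, tolerance = 1e-10)
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-10)
  expect_equal(s2$pct_variance, s1$pct_variance, tolerance = 1e-8)
})

test_that("permuted traits give ~5% raw positives and small subsets are refused", {
  g <- generate_genotypes(200, c(150), c(90), ld_rho = 2,
                          structure_delta = 0, seed = 11)
  set.seed(12)
  trait <- stats::setNames(stats::rnorm(200), rownames(g$genotypes))
  fr <- replicate(4, {
    perm <- stats::setNames(sample(trait), names(trait))
    s <- single_marker_scan(g$genotypes, g$map, perm)
    mean(s$p_value < 0.05)
  })
  expect_gt(mean(fr), 0.02)
  expect_lt(mean(fr), 0.09)
  expect_error(single_marker_scan(g$genotypes, g$map, trait,
                                  lines = rownames(g$genotypes)[1:10]),
               "need >= 30")
})

test_that("QTL merging is single-linkage with chaining beyond 2x cutoff", {
  scan <- data.frame(
    marker_id = paste0("m", 1:6),
    chromosome = c("2H", "2H", "2H", "2H", "2H", "3H"),
    pos_cM = c(10.0, 11.5, 14.0, 16.0, 18.0, 5.0),
    group = "all", trait = "tiller_max",
    effect = 1, p_value = c(1e-8, 1e-6, 1e-9, 1e-7, 1e-5, 1e-4),
    p_adj = 0.01, significant = TRUE, pct_variance = 2,
    stringsAsFactors = FALSE)
  q <- merge_qtl(scan, cutoff_cM = 2)
  q2h <- q[q$chromosome == "2H", ]
  expect_equal(nrow(q2h), 2L)
  expect_equal(q2h$cM_start, c(10.0, 14.0))
  expect_equal(q2h$cM_end, c(11.5, 18.0))      # chained 14-16-18 spans 4 cM
  expect_equal(q2h$peak_marker, c("m1", "m3"))
  single <- q[q$chromosome == "3H", ]
  expect_equal(single$cM_start, single$cM_end)
  # partition: every significant marker lands in exactly one QTL
  members <- unlist(strsplit(q$members, ";"))
  expect_setequal(members, scan$marker_id)
  expect_equal(anyDuplicated(members), 0L)
})

test_that("QTL overlap counting matches exhaustive pairwise checking", {
  mk <- function(chrom, s, e) data.frame(
    chromosome = chrom, cM_start = s, cM_end = e, n_markers = 1,
    peak_marker = "x", peak_p = 1e-5, peak_effect = 1,
    peak_pct_variance = 1, traits = "t", groups = "all", members = "x",
    stringsAsFactors = FALSE)
  tiller <- mk(c("1H", "2H", "3H"), c(10, 50, 5), c(12, 55, 5))
  heading <- mk(c("1H", "2H", "4H"), c(13, 70, 1), c(14, 75, 2))
  rowtype <- mk(c("3H", "2H"), c(5.5, 52), c(6, 53))
  ov <- qtl_overlap(list(tiller = tiller, heading = heading,
                         rowtype = rowtype), cutoff_cM = 2)
  expect_equal(unname(ov$counts), c(3L, 3L, 2L))
  # brute force oracle
  gap_ok <- function(a, b) a$chromosome == b$chromosome &&
    max(a$cM_start, b$cM_start) - min(a$cM_end, b$cM_end) <= 2
  brute <- function(qa, qb) {
    sum(vapply(seq_len(nrow(qa)), function(i) {
      any(vapply(seq_len(nrow(qb)), function(j) {
        gap_ok(qa[i, ], qb[j, ])
      }, logical(1)))
    }, logical(1)))
  }
  expect_equal(ov$pairwise["tiller", "heading"], brute(tiller, heading))
  expect_equal(ov$pairwise["tiller", "rowtype"], brute(tiller, rowtype))
  expect_equal(ov$pairwise["heading", "rowtype"], brute(heading, rowtype))
  # identical lists overlap completely; disjoint chromosomes never do
  ident <- qtl_overlap(list(a = tiller, b = tiller))
  expect_equal(ident$pairwise["a", "b"], 3L)
  far <- qtl_overlap(list(a = mk("1H", 10, 12), b = mk("5H", 10, 12)))
  expect_equal(far$pairwise["a", "b"], 0L)
})
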