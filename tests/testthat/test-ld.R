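test_that("pairwise r2 matches hand-computed correlations", {
  calls <- cbind(a = c(0, 0, 2, 2), b = c(2, 2, 0, 0),
                 c = c(0, 2, 0, 2), d = c(0, 0, 2, 2),
                 mono = c(2, 2, 2, 2))
  g <- toy_genotypes(calls)$genotypes
  expect_equal(pairwise_r2(g, cbind(1, 4)), 1)      # identical columns
  expect_equal(pairwise_r2(g, cbind(1, 2)), 1)      # perfect negative
  expect_equal(pairwise_r2(g, cbind(3, 1)), 0)      # hand-computed cor 0
  expect_true(is.na(pairwise_r2(g, cbind(1, 5))))   # monomorphic
})

test_that("r2 is symmetric and invariant to allele-label flips", {
  set.seed(3)
  calls <- matrix(sample(c(0L, 2L), 40 * 6, TRUE), 40)
  g <- toy_genotypes(calls)$genotypes
  pr <- cbind(c(1, 2, 3), c(4, 5, 6))
  fwd <- pairwise_r2(g, pr)
  rev <- pairwise_r2(g, pr[, 2:1])
  expect_equal(fwd, rev)
  flipped <- calls
  flipped[, 4] <- 2L - flipped[, 4]
  g2 <- toy_genotypes(flipped)$genotypes
  expect_equal(pairwise_r2(g2, pr), fwd)
})

test_that("background LD is the type-7 75th percentile of interchromosomal r2", {
  set.seed(5)
  calls <- matrix(sample(c(0L, 2L), 12 * 7, TRUE), 12)
  toy <- toy_genotypes(calls, chrom = c(rep("1H", 3), rep("2H", 4)),
                       pos_cM = c(1, 2, 3, 1, 2, 3, 4))
  bg <- background_ld(toy$genotypes, toy$map, max_pairs = Inf)
  # oracle: all 3 x 4 cross pairs via plain cor(), quantiled by the
  # interpolation formula q = x[k] + g*(x[k+1]-x[k]), h = 0.75*(n-1)+1
  r2 <- as.vector(stats::cor(calls[, 1:3], calls[, 4:7])^2)
  r2s <- sort(r2)
  h <- 0.75 * (length(r2s) - 1) + 1
  manual <- r2s[floor(h)] + (h - floor(h)) * (r2s[ceiling(h)] - r2s[floor(h)])
  expect_equal(bg$background_r2[bg$chromosome == "1H"], manual,
               tolerance = 1e-12)
  expect_equal(stats::quantile(c(0, 0.1, 0.2, 0.3), 0.75, names = FALSE),
               0.225)   # the interpolation rule itself
  g1 <- genotype_matrix(unclass(toy$genotypes)[, 1:3])
  expect_error(background_ld(g1, toy$map[toy$map$chromosome == "1H", ]),
               "chromosome")
})

test_that("independent chromosomes give near-null background; line order irrelevant", {
  g <- generate_genotypes(700, c(25, 25), c(100, 100), ld_rho = 2,
                          structure_delta = 0, seed = 6)
  bg <- background_ld(g$genotypes, g$map, max_pairs = Inf)
  expect_true(all(bg$background_r2 > 0.3 / 700))
  expect_true(all(bg$background_r2 < 4 / 700))
  perm <- g$genotypes[sample(nrow(g$genotypes)), ]
  bg2 <- background_ld(genotype_matrix(perm), g$map, max_pairs = Inf)
  expect_equal(bg$background_r2, bg2$background_r2, tolerance = 1e-12)
})

test_that("Hill-Weir fit recovers rho from expectation-generated data", {
  set.seed(7)
  d <- stats::runif(600, 0.01, 30)
  r2 <- hill_weir_expectation(d, rho = 2, n = 700) +
    stats::rnorm(600, sd = 0.002)
  fit <- hill_weir_fit(d, r2, n = 700, background = 0.05)
  expect_true(fit$converged)
  expect_lt(abs(fit$rho - 2) / 2, 0.05)
  # decay distance solves E[r2](d) = background
  expect_equal(fit$fitted(fit$decay_distance), 0.05, tolerance = 1e-6)
})

test_that("decay distance edge rules and monotonicity in background hold", {
  set.seed(8)
  d <- stats::runif(200, 0.01, 20)
  r2 <- hill_weir_expectation(d, 1.5, 500)
  high_bg <- hill_weir_fit(d, r2, 500, background = 0.9)
  expect_equal(high_bg$decay_distance, 0)
  # never-crossing background: capped at the maximum observed distance
  low_bg <- hill_weir_fit(d, r2, 500, background = 1e-9)
  expect_equal(low_bg$decay_distance, max(d))
  bgs <- c(0.05, 0.1, 0.2, 0.4)
  dd <- vapply(bgs, function(b) hill_weir_fit(d, r2, 500, b)$decay_distance,
               numeric(1))
  expect_true(all(diff(dd) <= 1e-9))
  # fitted curve is monotone decreasing
  fit <- hill_weir_fit(d, r2, 500, 0.1)
  grid <- seq(0, 20, length.out = 50)
  expect_true(all(diff(fit$fitted(grid)) < 0))
})

test_that("fitted decay distance tracks the generator's decay rate", {
  # faster generator LD decay must give a shorter fitted decay distance
  # against the same kind of structured background
  decay_at <- function(rho) {
    g <- generate_genotypes(400, c(150, 80), c(60, 60), ld_rho = rho,
                            structure_delta = 0.2, seed = 82)
    bg <- background_ld(g$genotypes, g$map, max_pairs = Inf)
    idx <- which(g$map$chromosome == "1H")
    pairs <- t(utils::combn(idx, 2))
    set.seed(83)
    keep <- sample(nrow(pairs), 4000)
    r2c <- pairwise_r2(g$genotypes, pairs[keep, ])
    dc <- abs(g$map$pos_cM[pairs[keep, 1]] - g$map$pos_cM[pairs[keep, 2]])
    f <- hill_weir_fit(dc, r2c, n = 400,
                       background = bg$background_r2[bg$chromosome == "1H"])
    expect_true(f$converged)
    f$decay_distance
  }
  dd <- vapply(c(0.3, 1, 3), decay_at, numeric(1))
  expect_true(all(dd > 0))
  expect_true(all(diff(dd) < 0))
})

test_that("windowed profiles do the 4950-pair window arithmetic", {
  g100 <- generate_genotypes(30, c(100), c(50), ld_rho = 1, seed = 9)
  w <- windowed_ld_profile(g100$genotypes, g100$map, "1H")
  expect_equal(nrow(w$points), 1L)
  expect_equal(w$points$n_pairs, choose(100, 2))
  expect_equal(w$points$n_pairs, 4950L)
  expect_true(w$points$complete)

  g250 <- generate_genotypes(30, c(250), c(80), ld_rho = 1, seed = 10)
  w2 <- windowed_ld_profile(g250$genotypes, g250$map, "1H")
  expect_equal(sum(w2$points$complete), 2L)
  expect_equal(sum(!w2$points$complete), 1L)
  expect_equal(w2$points$n_pairs[!w2$points$complete], choose(50, 2))
})

test_that("identical markers give a flat unit profile", {
  calls <- matrix(rep(c(0L, 2L), each = 6, times = 120), nrow = 12)
  toy <- toy_genotypes(calls, pos_cM = seq_len(ncol(calls)))
  w <- windowed_ld_profile(toy$genotypes, toy$map, "1H")
  expect_equal(w$points$mean_r2, rep(1, nrow(w$points)))
  # too few complete windows for a smoother: window means are the profile
  expect_null(w$smoothed)
})

test_that("greedy tagging covers everything and matches brute force when tight", {
  # hand-built 5-marker toy: {1,2,3} mutually duplicated, {4,5} duplicated
  calls <- cbind(m1 = c(0, 0, 2, 2, 0, 2), m2 = c(0, 0, 2, 2, 0, 2),
                 m3 = c(0, 0, 2, 2, 0, 2), m4 = c(2, 0, 0, 2, 2, 0),
                 m5 = c(2, 0, 0, 2, 2, 0))
  toy <- toy_genotypes(calls)
  tags <- greedy_tag(toy$genotypes, toy$map, 0.95)
  expect_length(tags, 2L)
  expect_true(all(c("m1", "m4") %in% tags))   # position tie-break

  # brute-force minimum cover oracle on generated <= 10-marker instances
  min_cover_size <- function(cover) {
    m <- nrow(cover)
    for (k in 1:m) {
      combos <- utils::combn(m, k)
      for (ci in seq_len(ncol(combos))) {
        if (all(apply(cover[, combos[, ci], drop = FALSE], 1, any))) {
          return(k)
        }
      }
    }
    m
  }
  for (seed in 1:6) {
    g <- generate_genotypes(80, c(9), c(3), ld_rho = 0.4,
                            structure_delta = 0, maf_range = c(0.2, 0.5),
                            seed = seed)
    r2 <- stats::cor(unclass(g$genotypes))^2
    cover <- !is.na(r2) & r2 >= 0.95
    diag(cover) <- TRUE
    tags <- greedy_tag(g$genotypes, g$map, 0.95)
    # every marker is covered by a retained tag
    tag_idx <- match(tags, colnames(g$genotypes))
    expect_true(all(apply(cover[, tag_idx, drop = FALSE], 1, any)))
    expect_equal(length(tags), min_cover_size(cover))
  }

  # trivial extremes
  dup <- toy_genotypes(matrix(rep(c(0L, 2L, 0L, 2L), 4), 4))
  expect_length(greedy_tag(dup$genotypes, dup$map, 0.95), 1L)
  set.seed(11)
  indep <- generate_genotypes(500, c(6), c(200), ld_rho = 5,
                              structure_delta = 0, seed = 12)
  expect_length(greedy_tag(indep$genotypes, indep$map, 0.95), 6L)
})

test_that("distance thinning follows the left-to-right scan", {
  map <- marker_map(c("a", "b", "c", "d"), "1H",
                    pos_cM = c(0, 0.5, 1.4, 2.0))
  expect_equal(thin_by_distance(map, 1.3), c("a", "c"))
  expect_equal(thin_by_distance(map, 10), "a")
  expect_equal(thin_by_distance(map, 1e-9), c("a", "b", "c", "d"))
  two <- marker_map(c("a", "b", "c", "d"), c("1H", "1H", "2H", "2H"),
                    pos_cM = c(0, 5, 0, 0.2))
  expect_equal(sort(thin_by_distance(two, 1)), c("a", "b", "c"))
})
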