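#' Pairwise linkage disequilibrium (r2) between markers
#'
#' r2 is the squared Pearson correlation of minor-allele dosage vectors
#' over pairwise-complete lines.  Monomorphic markers yield `NA` for their
#' pairs.  r2 is symmetric and invariant to allele-label flips.
#'
#' @param genotypes a [genotype_matrix()].
#' @param pairs two-column integer matrix of marker-column index pairs.
#' @return numeric vector of r2, one per row of `pairs`.
#' @export
pairwise_r2 <- function(genotypes, pairs) {
  stopifnot(is.matrix(pairs), ncol(pairs) == 2L)
  g <- unclass(genotypes)
  vapply(seq_len(nrow(pairs)), function(i) {
    x <- g[, pairs[i, 1L]]; y <- g[, pairs[i, 2L]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2L) return(NA_real_)
    sx <- stats::sd(x[ok]); sy <- stats::sd(y[ok])
    if (sx == 0 || sy == 0) return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1L))
}

# r2 of all column pairs of a complete-ish dosage matrix, via the
# correlation matrix (pairwise-complete); NA for monomorphic columns
r2_matrix <- function(genotypes) {
  suppressWarnings(
    stats::cor(unclass(genotypes), use = "pairwise.complete.obs"))^2
}

#' Interchromosomal background LD per chromosome
#'
#' For each chromosome, the 75th percentile (type-7 linear interpolation)
#' of r2 over pairs between its markers and markers on all other
#' chromosomes.  The quadratic pair count can be subsampled with a seeded
#' draw; `max_pairs = Inf` gives the exact value.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [marker_map()] covering the matrix.
#' @param probs quantile defining "background" (0.75).
#' @param max_pairs per-chromosome cap on sampled interchromosomal pairs.
#' @param seed seed for the subsample.
#' @return data.frame with `chromosome`, `background_r2`, `n_pairs`.
#' @export
background_ld <- function(genotypes, map, probs = 0.75, max_pairs = 2e6,
                          seed = 1L) {
  map <- check_map_covers(genotypes, map)
  chroms <- unique(map$chromosome)
  if (length(chroms) < 2L) {
    stop("background LD needs markers on >= 2 chromosomes")
  }
  set.seed(as.integer(seed))
  out <- lapply(chroms, function(ch) {
    own <- which(map$chromosome == ch)
    oth <- which(map$chromosome != ch)
    n_tot <- length(own) * length(oth)
    if (n_tot <= max_pairs) {
      pairs <- cbind(rep(own, each = length(oth)), rep(oth, length(own)))
    } else {
      draw <- sample.int(n_tot, max_pairs)
      pairs <- cbind(own[(draw - 1L) %/% length(oth) + 1L],
                     oth[(draw - 1L) %% length(oth) + 1L])
    }
    r2 <- pairwise_r2(genotypes, pairs)
    data.frame(chromosome = ch,
               background_r2 = unname(stats::quantile(r2, probs,
                                                      na.rm = TRUE)),
               n_pairs = sum(!is.na(r2)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hill-Weir expectation of r2 at recombination intensity C
#'
#' The drift-mutation expectation of sample r2 for sample size n:
#' \deqn{E[r^2] = \frac{10 + C}{(2 + C)(11 + C)}
#'   \left(1 + \frac{(3 + C)(12 + 12C + C^2)}{n(2 + C)(11 + C)}\right)}
#' with `C = rho * distance`.
#'
#' @param d distances (cM or Mb).
#' @param rho scale parameter (C per distance unit).
#' @param n sample size (number of lines).
#' @return expected r2.
#' @export
hill_weir_expectation <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir decay model and locate the decay distance
#'
#' Fits `rho` by nonlinear least squares of observed pairwise r2 on
#' distance under [hill_weir_expectation()], then solves for the distance
#' at which the fitted curve crosses the chromosome's background LD level
#' (0 if the curve starts below background; capped at the largest observed
#' distance if it never crosses).
#'
#' @param distances,r2 intrachromosomal pair distances and r2 values.
#' @param n sample size used in the expectation.
#' @param background background r2 level for the chromosome.
#' @param start_rho starting value for the optimiser.
#' @return a `hill_weir_fit` list: `rho`, `n`, `background`,
#'   `decay_distance`, `converged`, `fitted` (function of distance).
#' @export
hill_weir_fit <- function(distances, r2, n, background, start_rho = 1) {
  ok <- !is.na(distances) & !is.na(r2)
  distances <- distances[ok]; r2 <- r2[ok]
  if (length(r2) < 50L) stop("need >= 50 pairs to fit the decay model")
  if (diff(range(distances)) <= 0) stop("pairs span zero distance range")
  df <- data.frame(d = distances, r2 = r2)
  fit <- tryCatch(
    minpack.lm::nlsLM(r2 ~ hill_weir_expectation(d, rho, n), data = df,
                      start = list(rho = start_rho),
                      lower = c(rho = 1e-8),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(rho = NA_real_, n = n, background = background,
                          decay_distance = NA_real_, converged = FALSE,
                          fitted = NULL),
                     class = "hill_weir_fit"))
  }
  rho <- unname(stats::coef(fit)[["rho"]])
  f <- function(d) hill_weir_expectation(d, rho, n)
  d_max <- max(distances)
  decay <- if (f(0) <= background) {
    0
  } else if (f(d_max) > background) {
    d_max
  } else {
    stats::uniroot(function(d) f(d) - background, c(0, d_max),
                   tol = 1e-10)$root
  }
  structure(list(rho = rho, n = n, background = background,
                 decay_distance = decay, converged = TRUE, fitted = f),
            class = "hill_weir_fit")
}

#' @method print hill_weir_fit
#' @export
print.hill_weir_fit <- function(x, ...) {
  cat(sprintf("Hill-Weir fit: rho = %.4g, decay distance = %.4g (background %.4g)%s\n",
              x$rho, x$decay_distance, x$background,
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Windowed intrachromosomal LD profile with LOESS smoothing
#'
#' Orders a chromosome's markers by position, forms non-overlapping
#' 100-SNP windows (each complete window contributing its 4950 pairwise
#' comparisons), averages r2 and pair-midpoint positions per window, and
#' smooths the window means by local regression.
#'
#' @param genotypes,map as in [background_ld()].
#' @param chromosome chromosome label.
#' @param window_size SNPs per window (100).
#' @param span LOESS span.
#' @param unit `"cM"` or `"bp"` positions.
#' @return a `windowed_ld_profile` list: `points` (data.frame of window
#'   mean position / mean r2 / n pairs / complete flag), `smoothed`
#'   (LOESS fit over complete windows, NULL if fewer than 3), `chromosome`.
#' @export
windowed_ld_profile <- function(genotypes, map, chromosome,
                                window_size = 100L, span = 0.3,
                                unit = c("cM", "bp")) {
  unit <- match.arg(unit)
  map <- check_map_covers(genotypes, map)
  idx <- which(map$chromosome == chromosome)
  if (length(idx) == 0L) stop("no markers on chromosome ", chromosome)
  pos <- if (unit == "cM") map$pos_cM[idx] else map$pos_bp[idx]
  ord <- idx[order(pos)]
  pos <- sort(pos)
  n <- length(ord)
  n_win <- n %/% window_size
  partial <- n %% window_size
  windows <- split(seq_len(n_win * window_size),
                   rep(seq_len(n_win), each = window_size))
  if (n_win == 0L) {
    windows <- list(seq_len(n))   # single partial window, flagged
  } else if (partial > 0L) {
    windows <- c(windows, list(seq.int(n_win * window_size + 1L, n)))
  }
  pts <- lapply(windows, function(w) {
    m <- length(w)
    pr <- t(utils::combn(w, 2L))
    r2 <- pairwise_r2(genotypes, cbind(ord[pr[, 1L]], ord[pr[, 2L]]))
    mid <- (pos[pr[, 1L]] + pos[pr[, 2L]]) / 2
    data.frame(mean_pos = mean(mid), mean_r2 = mean(r2, na.rm = TRUE),
               n_pairs = nrow(pr), complete = m == window_size)
  })
  pts <- do.call(rbind, pts)
  comp <- pts[pts$complete, , drop = FALSE]
  smoothed <- NULL
  if (nrow(comp) >= 3L) {
    lo <- stats::loess(mean_r2 ~ mean_pos, data = comp, span = span,
                       degree = 2L)
    smoothed <- data.frame(mean_pos = comp$mean_pos,
                           smoothed_r2 = stats::fitted(lo))
  }
  structure(list(chromosome = chromosome, points = pts,
                 smoothed = smoothed, window_size = window_size),
            class = "windowed_ld_profile")
}

#' Greedy SNP tagging at an r2 threshold
#'
#' Per chromosome, iteratively retains the marker that covers the most
#' still-untagged markers at `r2 >= r2_threshold` (itself included) until
#' every marker is covered.  Ties break deterministically by map position,
#' then marker id.  Every non-retained marker is guaranteed to have
#' `r2 >= r2_threshold` with at least one retained marker.
#'
#' @param genotypes,map as in [background_ld()].
#' @param r2_threshold tagging cutoff in (0, 1].
#' @return character vector of retained marker ids (map order).
#' @export
greedy_tag <- function(genotypes, map, r2_threshold = 0.95) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  map <- check_map_covers(genotypes, map)
  retained <- character(0)
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    r2 <- r2_matrix(genotypes[, idx, drop = FALSE])
    cover <- !is.na(r2) & r2 >= r2_threshold
    diag(cover) <- TRUE
    untagged <- rep(TRUE, length(idx))
    pos <- map$pos_cM[idx]
    if (all(is.na(pos))) pos <- map$pos_bp[idx]
    ids <- map$marker_id[idx]
    while (any(untagged)) {
      gain <- colSums(cover & untagged)
      best <- which(gain == max(gain))
      if (length(best) > 1L) {
        best <- best[order(pos[best], ids[best])][1L]
      }
      retained <- c(retained, ids[best])
      untagged[cover[, best]] <- FALSE
    }
  }
  map$marker_id[map$marker_id %in% retained]
}

#' Thin markers to a minimum genetic spacing
#'
#' Left-to-right greedy scan along each chromosome keeping a marker iff its
#' cM distance to the last kept marker is at least `min_spacing` (the first
#' marker of each chromosome is always kept).
#'
#' @param map a [marker_map()].
#' @param min_spacing minimum cM gap (> 0), e.g. the LD decay distance.
#' @return character vector of retained marker ids.
#' @export
thin_by_distance <- function(map, min_spacing) {
  stopifnot(min_spacing > 0)
  kept <- character(0)
  for (ch in unique(map$chromosome)) {
    sub <- map[map$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_cM), , drop = FALSE]
    last <- -Inf
    for (i in seq_len(nrow(sub))) {
      if (sub$pos_cM[i] - last >= min_spacing) {
        kept <- c(kept, sub$marker_id[i])
        last <- sub$pos_cM[i]
      }
    }
  }
  kept
}
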