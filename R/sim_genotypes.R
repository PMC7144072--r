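#' Simulate inbred-line genotypes with map-distance-dependent LD
#'
#' Lines are drawn from a hidden two-subpopulation mixture.  Along each
#' chromosome a line carries a latent uniform value that is copied from the
#' previous marker with probability `exp(-ld_rho * d)` (d = cM gap) and
#' refreshed otherwise; the allele at marker j is `1{u_j < f_j}` where `f_j`
#' is the subpopulation's allele frequency.  This gives exact closed-form
#' pairwise r2 (see [expected_pair_r2()]); at equal frequencies the
#' within-population decay is `r2(d) = exp(-2 * ld_rho * d)`.  Lines are
#' inbred, so calls are 0/2 (dosage of the low-frequency allele).
#'
#' @param n_lines number of lines.
#' @param markers_per_chrom integer vector, markers on each chromosome.
#' @param map_length_cM numeric vector, genetic length of each chromosome.
#' @param ld_rho decay rate (per cM) of the latent copying probability.
#' @param maf_range length-2 vector; marker base frequencies are drawn
#'   uniformly from this range (must sit in (0, 0.5]).
#' @param missing_rate fraction of calls set missing, in [0, 1).
#' @param structure_delta half-distance between the two subpopulations'
#'   allele frequencies (0 = no structure).
#' @param seed integer seed.
#' @return list with `genotypes`, `map` (cM positions uniform along each
#'   chromosome; bp = cM * 5e6), and `truth` (subpopulation labels, the two
#'   frequency vectors, `ld_rho`).
#' @export
generate_genotypes <- function(n_lines, markers_per_chrom, map_length_cM,
                               ld_rho, maf_range = c(0.05, 0.5),
                               missing_rate = 0, structure_delta = 0.1,
                               seed = 1L) {
  stopifnot(length(markers_per_chrom) == length(map_length_cM),
            ld_rho > 0, missing_rate >= 0, missing_rate < 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("infeasible maf_range: need 0 < low <= high <= 0.5")
  }
  set.seed(as.integer(seed))
  n_chrom <- length(markers_per_chrom)
  chrom_names <- paste0(seq_len(n_chrom), "H")
  pop <- sample(c(1L, 2L), n_lines, replace = TRUE)
  line_ids <- sprintf("L%04d", seq_len(n_lines))

  calls_list <- vector("list", n_chrom)
  map_list <- vector("list", n_chrom)
  f1_all <- f2_all <- numeric(0)
  for (ch in seq_len(n_chrom)) {
    m <- markers_per_chrom[ch]
    pos <- sort(stats::runif(m, 0, map_length_cM[ch]))
    f0 <- stats::runif(m, maf_range[1], maf_range[2])
    f1 <- pmin(pmax(f0 + structure_delta, 0.01), 0.99)
    f2 <- pmin(pmax(f0 - structure_delta, 0.01), 0.99)
    fmat <- rbind(f1, f2)[pop, , drop = FALSE]        # n_lines x m
    u <- matrix(NA_real_, n_lines, m)
    u[, 1L] <- stats::runif(n_lines)
    if (m > 1L) {
      s <- exp(-ld_rho * diff(pos))
      for (j in 2L:m) {
        copy <- stats::runif(n_lines) < s[j - 1L]
        u[, j] <- ifelse(copy, u[, j - 1L], stats::runif(n_lines))
      }
    }
    calls_list[[ch]] <- 2L * (u < fmat)
    ids <- sprintf("%s_%05d", chrom_names[ch], seq_len(m))
    map_list[[ch]] <- marker_map(ids, chrom_names[ch], pos_cM = pos,
                                 pos_bp = as.integer(round(pmin(
                                   pos * 5e6, .Machine$integer.max))))
    f1_all <- c(f1_all, f1); f2_all <- c(f2_all, f2)
  }
  calls <- do.call(cbind, calls_list)
  map <- do.call(rbind, map_list)
  rownames(map) <- NULL
  dimnames(calls) <- list(line_ids, map$marker_id)
  if (missing_rate > 0) {
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_
  }
  list(genotypes = genotype_matrix(calls), map = map,
       truth = list(pop = stats::setNames(pop, line_ids),
                    f_pop1 = stats::setNames(f1_all, map$marker_id),
                    f_pop2 = stats::setNames(f2_all, map$marker_id),
                    ld_rho = ld_rho,
                    structure_delta = structure_delta))
}

#' Closed-form expected r2 of the genotype generator
#'
#' For two markers with subpopulation-1 frequencies `f1j, f1k`,
#' subpopulation-2 frequencies `f2j, f2k`, cM gap `d` and copying rate
#' `rho` (equal mixture of the two subpopulations), the latent-uniform
#' construction gives, with `S = exp(-rho * d)` (S = 0 across chromosomes):
#' within-population covariance `S * (min(fj, fk) - fj * fk)`, plus a
#' structure term `(f1j - f2j) * (f1k - f2k) / 4` from the mixture.  The
#' squared Pearson correlation of the resulting Bernoulli alleles (and of
#' the 0/2 dosages) is returned.
#'
#' @param f1j,f1k,f2j,f2k allele frequencies (vectorised).
#' @param d cM distance (`Inf` for different chromosomes).
#' @param rho copying-decay rate used by the generator.
#' @return expected population r2 for each pair.
#' @export
expected_pair_r2 <- function(f1j, f1k, f2j, f2k, d, rho) {
  S <- exp(-rho * d)
  S[!is.finite(d)] <- 0
  cov1 <- S * (pmin(f1j, f1k) - f1j * f1k)
  cov2 <- S * (pmin(f2j, f2k) - f2j * f2k)
  cov_pool <- 0.5 * (cov1 + cov2) + 0.25 * (f1j - f2j) * (f1k - f2k)
  fbj <- (f1j + f2j) / 2; fbk <- (f1k + f2k) / 2
  denom <- fbj * (1 - fbj) * fbk * (1 - fbk)
  out <- cov_pool^2 / denom
  out[denom <= 0] <- NA_real_
  out
}

#' @rdname expected_pair_r2
#' @param frac decay fraction; the returned distance is where the
#'   equal-frequency within-population r2 curve `exp(-2 rho d)` has lost
#'   `frac` of its initial value.
#' @export
ld_decay_length <- function(rho, frac = 0.95) -log(1 - frac) / (2 * rho)
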