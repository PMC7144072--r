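#' Genetic architecture and spatial model for the phenotype simulator
#'
#' `genetic_architecture()` collects the genetic inputs of
#' [simulate_phenotypes()]: standalone QTL (each a marker index, target
#' trait and effect, where *effect* is the mean difference between the two
#' homozygote classes), a spike row-type locus (dosage 2 = 6-row),
#' heading-date loci with effects in days, pleiotropic links from heading
#' date and row-type to the tiller asymptote, per-trait broad-sense
#' heritability targets, and the residual covariance among agronomic
#' traits.  Heritability targets are met by adding a line-level polygenic
#' term whose variance is solved from
#' `Vg = h2/(1-h2) * Ve/n_env` minus the variance already contributed by
#' the explicit loci (checked, not forced).
#'
#' @param qtl data.frame with columns `marker` (index into the genotype
#'   matrix), `trait`, `effect`; or NULL.
#' @param row_type_marker marker index controlling 2-row/6-row, or NULL
#'   (all lines 2-row).
#' @param heading_markers,heading_effects marker indices and per-locus
#'   homozygote-difference effects (days) on heading date.
#' @param heading_base mean days to heading.
#' @param heading_effect_on_tillers tillers per day of heading deviation.
#' @param rowtype_effect_on_tillers mean tiller advantage of 2-rows over
#'   6-rows (tillers).
#' @param h2_targets named vector of target broad-sense heritabilities in
#'   [0, 1) for any of the simulated traits.
#' @param trait_covariance named positive semi-definite matrix of residual
#'   covariances among agronomic traits; defaults to independent unit-ish
#'   field-scale variances.
#' @param survival_mean,survival_line_sd,survival_plot_sd tiller survival
#'   fraction: mean, line-level SD (genetic) and plot-level SD.
#' @return a `genetic_architecture` list.
#' @export
genetic_architecture <- function(qtl = NULL, row_type_marker = NULL,
                                 heading_markers = integer(0),
                                 heading_effects = numeric(0),
                                 heading_base = 55,
                                 heading_effect_on_tillers = 0,
                                 rowtype_effect_on_tillers = 0,
                                 h2_targets = NULL,
                                 trait_covariance = NULL,
                                 survival_mean = 0.75,
                                 survival_line_sd = 0.05,
                                 survival_plot_sd = 0.05) {
  stopifnot(length(heading_markers) == length(heading_effects))
  if (!is.null(qtl)) {
    stopifnot(is.data.frame(qtl),
              all(c("marker", "trait", "effect") %in% names(qtl)),
              all(is.finite(qtl$effect)))
  }
  if (!is.null(h2_targets)) {
    stopifnot(!is.null(names(h2_targets)),
              all(h2_targets >= 0 & h2_targets < 1))
  }
  if (!is.null(trait_covariance)) {
    stopifnot(is.matrix(trait_covariance),
              isSymmetric(unname(trait_covariance)),
              min(eigen(trait_covariance, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-8)
  }
  structure(list(qtl = qtl, row_type_marker = row_type_marker,
                 heading_markers = heading_markers,
                 heading_effects = heading_effects,
                 heading_base = heading_base,
                 heading_effect_on_tillers = heading_effect_on_tillers,
                 rowtype_effect_on_tillers = rowtype_effect_on_tillers,
                 h2_targets = h2_targets,
                 trait_covariance = trait_covariance,
                 survival_mean = survival_mean,
                 survival_line_sd = survival_line_sd,
                 survival_plot_sd = survival_plot_sd),
            class = "genetic_architecture")
}

#' @rdname genetic_architecture
#' @param row_gradient additive field effect per block-row (trait units).
#' @param col_gradient additive field effect per block-column.
#' @param smooth_amplitude amplitude of a low-frequency isotropic 2-D
#'   surface over the block grid (one value per block; 0 disables it).
#' @param noise_sd plot-level residual SD shared by all weekly counts of a
#'   plot (plot-vigour noise) and, via `trait_covariance`, scale-free for
#'   agronomic traits.
#' @param week_jitter_sd additional independent weekly measurement jitter
#'   on tiller counts.
#' @export
spatial_model <- function(row_gradient = 0, col_gradient = 0,
                          smooth_amplitude = 0, noise_sd = 0,
                          week_jitter_sd = 0.25) {
  stopifnot(noise_sd >= 0, week_jitter_sd >= 0)
  structure(list(row_gradient = row_gradient, col_gradient = col_gradient,
                 smooth_amplitude = smooth_amplitude, noise_sd = noise_sd,
                 week_jitter_sd = week_jitter_sd),
            class = "spatial_model")
}

agronomic_traits <- function() {
  c("days_to_heading", "seeds_per_spike", "kernel_wt", "leaf_width",
    "plant_height", "stem_diameter")
}

default_trait_covariance <- function() {
  v <- c(days_to_heading = 9, seeds_per_spike = 9, kernel_wt = 0.04,
         leaf_width = 1, plant_height = 25, stem_diameter = 0.09)
  m <- diag(v)
  dimnames(m) <- list(names(v), names(v))
  m
}

# Logistic rise to a plateau at the peak week, linear decline afterwards.
trajectory_shape <- function(weeks, midpoint = 4, scale = 1.1,
                             peak_week = 6, decline = 0.08) {
  peak_val <- stats::plogis((peak_week - midpoint) * scale)
  ifelse(weeks <= peak_week,
         stats::plogis((weeks - midpoint) * scale) / peak_val,
         1 - decline * (weeks - peak_week))
}

#' Simulate plot-level phenotypes on an augmented field layout
#'
#' Fills the trait columns of a design skeleton (possibly spanning several
#' years; line genetic values are drawn once and shared across years).
#' Weekly tiller counts follow a logistic rise to a genotype-specific
#' asymptote with a mild post-peak decline; counts are the rounded,
#' non-negative latent values.  Agronomic traits are genetic value +
#' block-level spatial surface + correlated residual.  Checks carry fixed
#' synthetic genotypes (all-reference, except the half-2 primary/secondary
#' checks which are 6-row), so check-based adjustment never absorbs
#' genetic signal.
#'
#' @param design a [trait_table()] skeleton from [generate_design()] (rbind
#'   several years for multi-environment data).
#' @param genotypes a [genotype_matrix()] covering every test entry.
#' @param arch a [genetic_architecture()].
#' @param spatial a [spatial_model()].
#' @param weeks integer weeks past emergence for tiller counts.
#' @param tiller_base mean asymptote of the tiller trajectory in year 1.
#' @param year_tiller_shift additive asymptote shift per later year
#'   (year-specific growing conditions; the study's year 2 tillered far
#'   more than year 1).
#' @param seed integer seed.
#' @return the design as a [trait_table()] with trait columns
#'   `tiller_<w>wpe`, `tiller_max`, `tiller_productive`, `row_type` and the
#'   agronomic traits; attribute `"truth"` holds line-level genetic values,
#'   the block-level spatial surface and the calibrated variances.
#' @export
simulate_phenotypes <- function(design, genotypes, arch, spatial,
                                weeks = 2:7, tiller_base = 9,
                                year_tiller_shift = 6, seed = 1L) {
  stopifnot(inherits(design, "trait_table"),
            inherits(arch, "genetic_architecture"),
            inherits(spatial, "spatial_model"))
  set.seed(as.integer(seed))
  df <- as.data.frame(design)
  years <- sort(unique(df$year))
  n_env <- length(years)
  test_entries <- unique(df$entry_id[df$check_class == "test"])
  check_entries <- unique(df$entry_id[df$check_class != "test"])
  miss <- setdiff(test_entries, rownames(genotypes))
  if (length(miss) > 0L) {
    stop("no genotype for test entries: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  entries <- c(test_entries, check_entries)
  n_mark <- ncol(genotypes)

  # dosage rows for all entries; checks are genetically invariant
  dos <- matrix(0L, length(entries), n_mark,
                dimnames = list(entries, colnames(genotypes)))
  dos[test_entries, ] <- unclass(genotypes)[test_entries, , drop = FALSE]
  dos[is.na(dos)] <- 0L
  if (!is.null(arch$row_type_marker)) {
    half2_checks <- grep("_B", check_entries, value = TRUE)
    dos[half2_checks, arch$row_type_marker] <- 2L
  }

  row_type <- rep(2, length(entries))
  if (!is.null(arch$row_type_marker)) {
    row_type <- ifelse(dos[, arch$row_type_marker] == 2L, 6, 2)
  }
  names(row_type) <- entries

  heading_gv <- rep(arch$heading_base, length(entries))
  if (length(arch$heading_markers) > 0L) {
    heading_gv <- heading_gv +
      as.numeric(dos[, arch$heading_markers, drop = FALSE] %*%
                   (arch$heading_effects / 2))
  }
  names(heading_gv) <- entries

  traits <- c(sprintf("tiller_%dwpe", weeks), "tiller_max",
              "tiller_productive", "row_type", agronomic_traits())
  gv <- matrix(0, length(entries), length(traits),
               dimnames = list(entries, traits))
  if (!is.null(arch$qtl)) {
    for (i in seq_len(nrow(arch$qtl))) {
      tr <- arch$qtl$trait[i]
      if (!tr %in% traits) stop("QTL targets unknown trait: ", tr)
      gv[, tr] <- gv[, tr] + arch$qtl$effect[i] * dos[, arch$qtl$marker[i]] / 2
    }
  }
  # pleiotropy into the tiller asymptote
  tiller_gv <- gv[, "tiller_max"] +
    arch$heading_effect_on_tillers * (heading_gv - arch$heading_base) +
    ifelse(row_type == 2, 0.5, -0.5) * arch$rowtype_effect_on_tillers
  gv[, "days_to_heading"] <- gv[, "days_to_heading"] +
    heading_gv - arch$heading_base
  # row-type morphology: 6-rows more seeds, lighter kernels, wider leaves,
  # thicker stems (field-scale offsets)
  is6 <- row_type == 6
  gv[, "seeds_per_spike"] <- gv[, "seeds_per_spike"] + ifelse(is6, 18, 0)
  gv[, "kernel_wt"] <- gv[, "kernel_wt"] + ifelse(is6, -0.35, 0)
  gv[, "leaf_width"] <- gv[, "leaf_width"] + ifelse(is6, 1.5, 0)
  gv[, "stem_diameter"] <- gv[, "stem_diameter"] + ifelse(is6, 0.4, 0)

  sigma <- if (is.null(arch$trait_covariance)) default_trait_covariance() else
    arch$trait_covariance
  agro <- intersect(agronomic_traits(), colnames(sigma))

  # polygenic calibration toward h2 targets (test entries only)
  rounding_var <- 1 / 12
  ve_eff <- c(stats::setNames(diag(sigma)[agro], agro),
              tiller_max = spatial$noise_sd^2 + spatial$week_jitter_sd^2 +
                rounding_var)
  poly_sd <- stats::setNames(numeric(length(traits)), traits)
  if (!is.null(arch$h2_targets)) {
    for (tr in names(arch$h2_targets)) {
      if (!tr %in% names(ve_eff)) next
      t2 <- arch$h2_targets[[tr]]
      vg_need <- t2 / (1 - t2) * ve_eff[[tr]] / n_env
      v_real <- if (tr == "tiller_max") {
        stats::var(tiller_gv[test_entries])
      } else stats::var(gv[test_entries, tr])
      poly_sd[tr] <- sqrt(max(0, vg_need - v_real))
    }
  }
  for (tr in names(poly_sd)[poly_sd > 0]) {
    draw <- stats::rnorm(length(entries), 0, poly_sd[tr])
    draw[match(check_entries, entries)] <- 0
    if (tr == "tiller_max") tiller_gv <- tiller_gv + draw else
      gv[, tr] <- gv[, tr] + draw
  }
  survival_line <- pmin(pmax(
    stats::rnorm(length(entries), arch$survival_mean, arch$survival_line_sd),
    0.05), 1)
  survival_line[match(check_entries, entries)] <- arch$survival_mean
  names(survival_line) <- entries

  # block-level spatial surface, per year
  blocks <- unique(df[, c("year", "block_id", "block_row", "block_col")])
  br_max <- max(blocks$block_row); bc_max <- max(blocks$block_col)
  surf <- numeric(nrow(blocks))
  for (i in seq_len(n_env)) {
    sel <- blocks$year == years[i]
    # low-frequency sinusoid product (0.7 periods across the grid, small
    # phase jitter): smooth variation "in many directions" with a large
    # non-additive (row x col interaction) component, while keeping real
    # row/column margins — a surface with flat margins would be invisible
    # to the check ANOVA, which no physical fertility patch is
    phase <- stats::runif(2, -pi / 6, pi / 6)
    surf[sel] <- spatial$row_gradient * blocks$block_row[sel] +
      spatial$col_gradient * blocks$block_col[sel] +
      spatial$smooth_amplitude *
        sin(2 * pi * 0.7 * blocks$block_row[sel] / (br_max + 1) + phase[1]) *
        sin(2 * pi * 0.7 * blocks$block_col[sel] / (bc_max + 1) + phase[2])
  }
  blocks$surface <- surf
  bkey <- paste(df$year, df$block_id)
  plot_surface <- surf[match(bkey, paste(blocks$year, blocks$block_id))]

  n_plot <- nrow(df)
  ent_idx <- match(df$entry_id, entries)
  year_idx <- match(df$year, years)
  shape <- trajectory_shape(weeks)

  plot_noise <- stats::rnorm(n_plot, 0, spatial$noise_sd)
  asym <- tiller_base + tiller_gv[ent_idx] +
    year_tiller_shift * (year_idx - 1) + plot_surface + plot_noise
  week_mat <- matrix(NA_real_, n_plot, length(weeks))
  for (w in seq_along(weeks)) {
    week_mat[, w] <- pmax(0, round(
      asym * shape[w] + stats::rnorm(n_plot, 0, spatial$week_jitter_sd)))
  }
  colnames(week_mat) <- sprintf("tiller_%dwpe", weeks)
  tiller_max <- apply(week_mat, 1L, max)
  survival <- pmin(pmax(survival_line[ent_idx] +
                          stats::rnorm(n_plot, 0, arch$survival_plot_sd),
                        0), 1)
  tiller_productive <- pmax(0, round(tiller_max * survival))

  resid <- matrix(0, n_plot, length(agro), dimnames = list(NULL, agro))
  if (length(agro) > 0L) {
    ev <- eigen(sigma[agro, agro, drop = FALSE], symmetric = TRUE)
    rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(agro)) %*%
      t(ev$vectors)
    resid <- matrix(stats::rnorm(n_plot * length(agro)), n_plot) %*% rt
    colnames(resid) <- agro
  }
  base_means <- c(days_to_heading = 0, seeds_per_spike = 22, kernel_wt = 2.0,
                  leaf_width = 12, plant_height = 80, stem_diameter = 3.0)
  out <- df
  for (w in colnames(week_mat)) out[[w]] <- week_mat[, w]
  out$tiller_max <- tiller_max
  out$tiller_productive <- tiller_productive
  out$row_type <- row_type[ent_idx]
  for (tr in agro) {
    out[[tr]] <- base_means[[tr]] + gv[ent_idx, tr] + plot_surface + resid[, tr]
  }
  out$days_to_heading <- out$days_to_heading + arch$heading_base

  result <- trait_table(out, c(colnames(week_mat), "tiller_max",
                               "tiller_productive", "row_type", agro))
  attr(result, "truth") <- list(
    line_values = data.frame(entry_id = entries, row_type = row_type,
                             heading_gv = heading_gv,
                             tiller_gv = tiller_gv,
                             gv[, agro, drop = FALSE],
                             survival = survival_line,
                             stringsAsFactors = FALSE, row.names = NULL),
    spatial_surface = blocks,
    poly_sd = poly_sd, ve_eff = ve_eff)
  result
}

#' Simulate a line-level panel for regression variance partitioning
#'
#' A direct line-level generator for studying the multiple-linear-regression
#' pipeline: standardized days-to-heading and seeds-per-spike (the row-type
#' proxy) carry known population variance shares of maximum tiller number,
#' and the remaining predictors are pure noise.  With shares `s_h` and
#' `s_s`, the response is
#' `sqrt(s_h)*DH + sqrt(s_s)*SPS + sqrt(1-s_h-s_s)*E` on standardized
#' scales, so the population R2 of the two informative predictors is
#' exactly `s_h + s_s`.
#'
#' @param n_lines panel size.
#' @param share_heading,share_seeds population variance shares (sum < 1).
#' @param noise_traits names of uninformative predictor columns to add.
#' @param seed integer seed.
#' @return data.frame with `tiller_max`, `days_to_heading`,
#'   `seeds_per_spike` and the noise traits; attribute `"truth"` records
#'   the shares.
#' @export
simulate_mlr_panel <- function(n_lines, share_heading = 0.2,
                               share_seeds = 0.1,
                               noise_traits = c("kernel_wt", "leaf_width",
                                                "plant_height",
                                                "stem_diameter"),
                               seed = 1L) {
  stopifnot(share_heading >= 0, share_seeds >= 0,
            share_heading + share_seeds < 1)
  set.seed(as.integer(seed))
  dh <- stats::rnorm(n_lines)
  sps <- stats::rnorm(n_lines)
  e <- stats::rnorm(n_lines)
  y <- sqrt(share_heading) * dh + sqrt(share_seeds) * sps +
    sqrt(1 - share_heading - share_seeds) * e
  out <- data.frame(tiller_max = 20 + 6 * y,
                    days_to_heading = 55 + 5 * dh,
                    seeds_per_spike = 30 + 8 * sps)
  for (tr in noise_traits) out[[tr]] <- stats::rnorm(n_lines)
  attr(out, "truth") <- list(share_heading = share_heading,
                             share_seeds = share_seeds)
  out
}
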