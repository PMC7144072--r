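#' Marker and line quality filtering
#'
#' Drops markers whose missing-plus-heterozygous call fraction exceeds
#' `max_missing_het` or whose minor allele frequency is below `min_maf`
#' (strictly less than: a marker exactly at the cutoff is retained).  In
#' two-pass mode (post-imputation refilter) lines exceeding the
#' missing/het fraction are dropped as well.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [marker_map()] covering the matrix.
#' @param max_missing_het maximum tolerated missing+het fraction
#'   (platform presets: 0.5 for GBS, 0.2 for the 50K array, 0.05 for the
#'   merged second pass).
#' @param min_maf MAF removal threshold (0.03).
#' @param filter_lines also drop lines above `max_missing_het` (the
#'   second-pass rule).
#' @return list with filtered `genotypes`, `map`, and a `report`
#'   data.frame of per-rule removal counts.
#' @export
filter_genotypes <- function(genotypes, map, max_missing_het = 0.5,
                             min_maf = 0.03, filter_lines = FALSE) {
  map <- check_map_covers(genotypes, map)
  g <- unclass(genotypes)
  mh_frac <- colMeans(is.na(g) | (!is.na(g) & g == 1L))
  maf <- apply(g, 2L, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(NA_real_)
    f <- mean(x) / 2
    min(f, 1 - f)
  })
  drop_mh <- mh_frac > max_missing_het
  drop_maf <- !drop_mh & (is.na(maf) | maf < min_maf)
  keep <- !drop_mh & !drop_maf
  report <- data.frame(
    rule = c("missing_het", "maf", "lines"),
    removed = c(sum(drop_mh), sum(drop_maf), 0L),
    stringsAsFactors = FALSE)
  g <- g[, keep, drop = FALSE]
  map <- map[keep, , drop = FALSE]
  if (filter_lines) {
    line_mh <- rowMeans(is.na(g) | (!is.na(g) & g == 1L))
    drop_line <- line_mh > max_missing_het
    report$removed[report$rule == "lines"] <- sum(drop_line)
    g <- g[!drop_line, , drop = FALSE]
  }
  if (ncol(g) == 0L) stop("all markers removed by filtering")
  list(genotypes = genotype_matrix(g), map = map, report = report)
}

#' LD-kNN genotype imputation
#'
#' For each missing call, the `l_sites` markers in highest r2 with the
#' target marker are selected genome-wide (no distance cap), taxa distances
#' are mismatch fractions over those sites, and the call is imputed by an
#' inverse-distance-weighted vote of the `k_taxa` nearest lines with
#' non-missing target calls.  Vote ties break toward the major allele.
#' Markers with fewer than `k_taxa` non-missing calls leave their missing
#' calls untouched, with a warning.
#'
#' @param genotypes a [genotype_matrix()].
#' @param l_sites number of high-LD support markers (20).
#' @param k_taxa number of nearest neighbours (5).
#' @return completed [genotype_matrix()].
#' @export
impute_ld_knn <- function(genotypes, l_sites = 20L, k_taxa = 5L) {
  g <- unclass(genotypes)
  n_miss_col <- colSums(is.na(g))
  targets <- which(n_miss_col > 0L)
  if (length(targets) == 0L) return(genotypes)
  r2 <- r2_matrix(g)
  diag(r2) <- NA
  skipped <- 0L
  for (j in targets) {
    non_missing <- which(!is.na(g[, j]))
    if (length(non_missing) < k_taxa) {
      skipped <- skipped + 1L
      next
    }
    r2j <- r2[, j]
    r2j[is.na(r2j)] <- -Inf
    sites <- order(r2j, decreasing = TRUE)[seq_len(min(l_sites, ncol(g) - 1L))]
    sub <- g[, sites, drop = FALSE]
    maj <- round(mean(g[non_missing, j]) / 2) * 2L   # major dosage class
    for (i in which(is.na(g[, j]))) {
      cmp <- sub[non_missing, , drop = FALSE] != rep(sub[i, ],
                                                     each = length(non_missing))
      dist <- rowMeans(cmp, na.rm = TRUE)
      dist[is.nan(dist)] <- 1
      nb <- non_missing[order(dist)[seq_len(k_taxa)]]
      w <- 1 / (dist[order(dist)[seq_len(k_taxa)]] + 1e-6)
      votes <- tapply(w, factor(g[nb, j], levels = c(0, 1, 2)), sum)
      votes[is.na(votes)] <- 0
      top <- which(votes == max(votes)) - 1L
      g[i, j] <- if (length(top) > 1L && maj %in% top) maj else top[1L]
    }
  }
  if (skipped > 0L) {
    warning(sprintf("%d marker(s) had < k_taxa non-missing calls; left as is",
                    skipped), call. = FALSE)
  }
  genotype_matrix(g)
}

#' Principal-component covariates with per-trait BIC selection
#'
#' Computes principal components of the centred dosage matrix and, for
#' each trait, picks the number of leading PCs (0..`max_pcs`) minimising
#' the BIC of `trait ~ PCs`.
#'
#' @param genotypes filtered, imputed [genotype_matrix()].
#' @param traits data.frame of line-level trait values, rows aligned with
#'   (or named by) the genotype lines.
#' @param max_pcs most PCs considered.
#' @return list with `scores` (lines x max_pcs), `n_pcs` (named integer
#'   per trait), `var_explained`.
#' @export
pc_covariates <- function(genotypes, traits = NULL, max_pcs = 10L) {
  g <- unclass(genotypes)
  if (anyNA(g)) stop("impute genotypes before computing PCs")
  keep <- apply(g, 2L, stats::sd) > 0
  pr <- stats::prcomp(g[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  k <- min(max_pcs, ncol(pr$x))
  scores <- pr$x[, seq_len(k), drop = FALSE]
  var_explained <- (pr$sdev^2 / sum(pr$sdev^2))[seq_len(k)]
  n_pcs <- integer(0)
  if (!is.null(traits)) {
    n_pcs <- vapply(names(traits), function(tr) {
      y <- traits[[tr]]
      ok <- !is.na(y)
      bics <- vapply(0:k, function(m) {
        fit <- if (m == 0L) stats::lm(y[ok] ~ 1) else
          stats::lm(y[ok] ~ scores[ok, seq_len(m), drop = FALSE])
        stats::BIC(fit)
      }, numeric(1L))
      which.min(bics) - 1L
    }, integer(1L))
  }
  list(scores = scores, n_pcs = n_pcs, var_explained = var_explained)
}

#' PC-corrected single-marker association scan
#'
#' Per marker passing the group MAF cutoff, regresses the trait on marker
#' dosage plus the chosen principal components; the marker p-value comes
#' from its t-test, significance from Benjamini-Hochberg FDR (or
#' Bonferroni), the allele-substitution effect from the dosage
#' coefficient, and percent variance from the R2 difference between models
#' with and without the marker.
#'
#' @param genotypes imputed [genotype_matrix()].
#' @param map a [marker_map()] covering the matrix.
#' @param trait named numeric vector of line-level trait values (names =
#'   line ids), already adjusted/aggregated.
#' @param group label recorded in the results (`"all"`, `"two_row"`, ...).
#' @param lines optional subset of line ids defining the group.
#' @param maf_cutoff group MAF cutoff (0.03 for all lines, 0.05 for
#'   subsets).
#' @param pcs PC score matrix (columns used as covariates), or NULL.
#' @param n_pcs how many leading columns of `pcs` to use.
#' @param alpha significance level.
#' @param p_adjust `"BH"` or `"bonferroni"`.
#' @param min_lines refuse to scan smaller subsets.
#' @param trait_name trait label recorded in the results.
#' @return data.frame (one row per tested marker): `marker_id`,
#'   `chromosome`, `pos_cM`, `group`, `effect`, `p_value`, `p_adj`,
#'   `significant`, `pct_variance`, `maf`, `n`.
#' @export
single_marker_scan <- function(genotypes, map, trait, group = "all",
                               lines = NULL, maf_cutoff = 0.03, pcs = NULL,
                               n_pcs = 0L, alpha = 0.05,
                               p_adjust = c("BH", "bonferroni"),
                               min_lines = 30L, trait_name = "trait") {
  p_adjust <- match.arg(p_adjust)
  map <- check_map_covers(genotypes, map)
  g <- unclass(genotypes)
  if (is.null(names(trait))) stop("trait must be named by line id")
  use <- intersect(rownames(g), names(trait)[!is.na(trait)])
  if (!is.null(lines)) use <- intersect(use, lines)
  if (length(use) < min_lines) {
    stop(sprintf("only %d line(s) in group '%s' (need >= %d)",
                 length(use), group, min_lines))
  }
  g <- g[use, , drop = FALSE]
  y <- as.numeric(trait[use])
  if (anyNA(g)) stop("impute genotypes before scanning")
  covar <- NULL
  if (!is.null(pcs) && n_pcs > 0L) {
    covar <- pcs[use, seq_len(n_pcs), drop = FALSE]
  }
  n <- length(y)
  maf <- pmin(colMeans(g) / 2, 1 - colMeans(g) / 2)
  test <- maf >= maf_cutoff
  # residualize trait and dosages on covariates once, then vectorized
  # marker regressions on the residuals
  q <- cbind(rep(1, n), covar)
  qr_q <- qr(q)
  y_r <- stats::residuals(stats::lm.fit(q, y))
  x_r <- g[, test, drop = FALSE] - q %*% qr.coef(qr_q, g[, test, drop = FALSE])
  ssy <- sum(y_r^2)
  ssx <- colSums(x_r^2)
  sxy <- colSums(x_r * y_r)
  beta <- sxy / ssx
  rss <- ssy - sxy^2 / ssx
  df_res <- n - ncol(q) - 1L
  tstat <- beta / sqrt(rss / df_res / ssx)
  p <- 2 * stats::pt(abs(tstat), df_res, lower.tail = FALSE)
  # delta-R2 relative to total trait variance (covariate model vs + marker)
  ssy_tot <- sum((y - mean(y))^2)
  pct_var <- 100 * (sxy^2 / ssx) / ssy_tot
  p_adj <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(
    marker_id = colnames(g)[test],
    chromosome = map$chromosome[test],
    pos_cM = map$pos_cM[test],
    group = group, trait = trait_name,
    effect = unname(beta), p_value = unname(p), p_adj = unname(p_adj),
    significant = unname(p_adj < alpha),
    pct_variance = unname(pmax(pct_var, 0)),
    maf = unname(maf[test]), n = n, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge significant markers into QTL by single-linkage cM clustering
#'
#' Per chromosome, significant markers closer than `cutoff_cM` to any
#' member of a cluster join it (single linkage), so chained intervals may
#' exceed twice the cutoff.  Each cluster becomes one QTL: interval =
#' [min cM, max cM], peak = member with the smallest p-value, traits and
#' groups of the members unioned.
#'
#' @param scan data.frame from [single_marker_scan()] (or several
#'   rbind-ed); only rows with `significant == TRUE` are used unless
#'   `already_filtered`.
#' @param cutoff_cM linkage distance (2).
#' @param already_filtered treat every row as significant.
#' @return data.frame of QTL: `chromosome`, `cM_start`, `cM_end`,
#'   `n_markers`, `peak_marker`, `peak_p`, `peak_effect`,
#'   `peak_pct_variance`, `traits`, `groups`, `members` (the last three
#'   are `;`-joined strings).
#' @export
merge_qtl <- function(scan, cutoff_cM = 2.0, already_filtered = FALSE) {
  sig <- if (already_filtered) scan else scan[scan$significant, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chromosome = character(0), cM_start = numeric(0),
                      cM_end = numeric(0), n_markers = integer(0),
                      peak_marker = character(0), peak_p = numeric(0),
                      peak_effect = numeric(0),
                      peak_pct_variance = numeric(0), traits = character(0),
                      groups = character(0), members = character(0),
                      stringsAsFactors = FALSE))
  }
  if (anyNA(sig$pos_cM)) stop("significant markers lack cM positions")
  out <- list()
  for (ch in unique(sig$chromosome)) {
    sub <- sig[sig$chromosome == ch, , drop = FALSE]
    sub <- sub[order(sub$pos_cM), , drop = FALSE]
    upos <- unique(sub$pos_cM)
    cl_of_pos <- cumsum(c(1, diff(upos) > cutoff_cM))
    cl <- cl_of_pos[match(sub$pos_cM, upos)]
    for (cc in unique(cl)) {
      m <- sub[cl == cc, , drop = FALSE]
      peak <- which.min(m$p_value)
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, cM_start = min(m$pos_cM), cM_end = max(m$pos_cM),
        n_markers = length(unique(m$marker_id)),
        peak_marker = m$marker_id[peak], peak_p = m$p_value[peak],
        peak_effect = m$effect[peak],
        peak_pct_variance = m$pct_variance[peak],
        traits = paste(sort(unique(m$trait)), collapse = ";"),
        groups = paste(sort(unique(m$group)), collapse = ";"),
        members = paste(unique(m$marker_id), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Count QTL overlaps between trait classes (Venn cells)
#'
#' Two QTL overlap iff they sit on the same chromosome and the gap between
#' their cM intervals is at most `cutoff_cM`.  For each QTL the set of
#' trait classes it overlaps (its own plus any class with an overlapping
#' QTL) defines its Venn cell; cells are counted per class of origin.
#'
#' @param qtl_sets named list (trait class -> [merge_qtl()] data.frame).
#' @param cutoff_cM interval gap tolerance (2).
#' @return list with `counts` (QTL per class), `cells` (data.frame: one
#'   row per Venn region of each origin class), and `pairwise` (matrix of
#'   overlap counts, rows = origin class).
#' @export
qtl_overlap <- function(qtl_sets, cutoff_cM = 2.0) {
  stopifnot(length(qtl_sets) >= 2L, !is.null(names(qtl_sets)))
  classes <- names(qtl_sets)
  overlaps_any <- function(q, set) {
    if (nrow(set) == 0L) return(rep(FALSE, nrow(q)))
    vapply(seq_len(nrow(q)), function(i) {
      same <- set$chromosome == q$chromosome[i]
      any(same &
            pmax(set$cM_start, q$cM_start[i]) -
            pmin(set$cM_end, q$cM_end[i]) <= cutoff_cM)
    }, logical(1L))
  }
  pairwise <- matrix(0L, length(classes), length(classes),
                     dimnames = list(classes, classes))
  cells <- list()
  for (a in classes) {
    qa <- qtl_sets[[a]]
    memb <- matrix(FALSE, nrow(qa), length(classes),
                   dimnames = list(NULL, classes))
    memb[, a] <- TRUE
    for (b in setdiff(classes, a)) {
      hit <- overlaps_any(qa, qtl_sets[[b]])
      memb[, b] <- hit
      pairwise[a, b] <- sum(hit)
    }
    pairwise[a, a] <- nrow(qa)
    key <- apply(memb, 1L, function(z) paste(classes[z], collapse = "&"))
    if (nrow(qa) > 0L) {
      tab <- table(key)
      cells[[a]] <- data.frame(origin = a, cell = names(tab),
                               count = as.integer(tab),
                               stringsAsFactors = FALSE)
    }
  }
  list(counts = vapply(qtl_sets, nrow, integer(1L)),
       cells = do.call(rbind, cells), pairwise = pairwise)
}
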