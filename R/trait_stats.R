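#' Broad-sense heritability from two-way ANOVA mean squares
#'
#' Fits the additive fixed-effect model `Trait ~ Env + Line` to line values
#' observed in every environment (year or rep), and derives
#' genetic variance `Vg = (MS_line - MS_resid) / n_env` and
#' `H2 = Vg / (Vg + MS_resid / n_env)`.  Lines missing the trait in any
#' environment are dropped and counted.  Negative `Vg` (line MS below the
#' residual MS) is reported as computed, with `H2 <= 0` flagged rather than
#' clamped.
#'
#' @param data data.frame with one row per line x environment.
#' @param trait name of the trait column.
#' @param env name of the environment column (e.g. `"year"`).
#' @param line name of the line-identifier column.
#' @return a `heritability_result` list: `trait`, `n_lines`, `n_env`,
#'   `line_ms`, `resid_ms`, `genetic_variance`, `H2`, `line_p`,
#'   `n_dropped`, `negative_vg`.
#' @export
heritability <- function(data, trait, env = "year", line = "entry_id") {
  stopifnot(all(c(trait, env, line) %in% names(data)))
  df <- data.frame(y = as.numeric(data[[trait]]),
                   env = factor(data[[env]]),
                   line = as.character(data[[line]]),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$y), , drop = FALSE]
  n_env <- nlevels(droplevels(df$env))
  if (n_env < 2L) stop("heritability needs >= 2 environments")
  counts <- table(df$line, df$env)
  complete <- rownames(counts)[apply(counts > 0, 1L, all)]
  n_dropped <- length(unique(df$line)) - length(complete)
  df <- df[df$line %in% complete, , drop = FALSE]
  # one value per line x environment: average duplicates (replicated checks)
  agg <- stats::aggregate(y ~ line + env, df, mean)
  agg$line <- factor(agg$line)
  if (nlevels(agg$line) < 2L) stop("heritability needs >= 2 lines")
  tab <- stats::anova(stats::aov(y ~ env + line, data = agg))
  line_ms <- tab["line", "Mean Sq"]
  resid_ms <- tab["Residuals", "Mean Sq"]
  line_p <- tab["line", "Pr(>F)"]
  vg <- (line_ms - resid_ms) / n_env
  h2 <- vg / (vg + resid_ms / n_env)
  if (!is.finite(h2)) h2 <- 0
  structure(list(trait = trait, n_lines = nlevels(agg$line), n_env = n_env,
                 line_ms = line_ms, resid_ms = resid_ms,
                 genetic_variance = vg, H2 = h2, line_p = line_p,
                 n_dropped = n_dropped, negative_vg = vg < 0),
            class = "heritability_result")
}

#' @method print heritability_result
#' @export
print.heritability_result <- function(x, ...) {
  cat(sprintf("H2(%s) = %.3f  (Vg = %.3g, line p = %.3g, %d lines x %d env%s)\n",
              x$trait, x$H2, x$genetic_variance, x$line_p, x$n_lines,
              x$n_env, if (x$negative_vg) ", negative Vg" else ""))
  invisible(x)
}

#' Tukey-Kramer group comparison with compact letter display
#'
#' One-way ANOVA followed by Tukey-Kramer pairwise comparisons (exact for
#' unequal group sizes via the studentized range), Benjamini-Hochberg
#' adjustment of the pairwise p-values, and letters assigned by
#' insert-and-absorb so that two groups share a letter iff their adjusted
#' p-value is at least `alpha`.
#'
#' @param values numeric response.
#' @param groups group labels (coerced to factor).
#' @param alpha significance level applied to the adjusted p-values.
#' @return a `group_comparison` list: `groups`, `n`, `means`, `letters`,
#'   `adj_p` (symmetric matrix), `dropped` (singleton groups).
#' @export
compare_groups <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]; g <- droplevels(g[ok])
  sizes <- table(g)
  single <- names(sizes)[sizes < 2L]
  if (length(single) > 0L) {
    warning("excluding singleton group(s): ", paste(single, collapse = ", "),
            call. = FALSE)
    keep <- !(g %in% single)
    values <- values[keep]; g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) stop("compare_groups needs >= 2 groups with >= 2 obs")
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  adj <- stats::p.adjust(tk[, "p adj"], method = "BH")
  lev <- levels(g)
  pm <- matrix(1, nlevels(g), nlevels(g), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    pm[a, b] <- pm[b, a] <- adj[i]
  }
  # degenerate residual (all groups internally constant): identical groups
  # are not significantly different, different means certainly are
  if (anyNA(pm)) {
    mns <- tapply(values, g, mean)
    for (a in lev) for (b in lev) {
      if (is.na(pm[a, b])) pm[a, b] <- if (isTRUE(all.equal(mns[a], mns[b]))) 1 else 0
    }
  }
  letters <- letter_display(pm, alpha)
  structure(list(groups = lev, n = as.integer(table(g)[lev]),
                 means = tapply(values, g, mean)[lev],
                 letters = letters, adj_p = pm, dropped = single),
            class = "group_comparison")
}

# insert-and-absorb compact letter display: groups sharing a letter are
# exactly the pairs with p >= alpha
letter_display <- function(p_matrix, alpha) {
  lev <- rownames(p_matrix)
  k <- length(lev)
  sets <- list(seq_len(k))                 # letter -> member indices
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (p_matrix[i, j] >= alpha) next      # non-significant, may share
    nxt <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        # split the violated letter set; insert both offspring
        nxt <- c(nxt, list(setdiff(s, j)), list(setdiff(s, i)))
      } else nxt <- c(nxt, list(s))
    }
    # absorb: drop letter sets contained in another (duplicates keep the
    # earliest copy)
    keep <- rep(TRUE, length(nxt))
    for (a in seq_along(nxt)) {
      if (!keep[a]) next
      for (b in seq_along(nxt)) {
        if (a == b || !keep[b]) next
        sub <- all(nxt[[a]] %in% nxt[[b]])
        if (sub && (length(nxt[[a]]) < length(nxt[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- nxt[keep]
  }
  sets <- sets[order(vapply(sets, min, numeric(1L)))]
  out <- character(k)
  for (s in seq_along(sets)) {
    out[sets[[s]]] <- paste0(out[sets[[s]]], letters[s])
  }
  stats::setNames(out, lev)
}

#' Pairwise trait correlation matrix with significance masking
#'
#' Pearson or Spearman correlations over pairwise-complete observations,
#' with a `masked` flag set when the p-value exceeds `ns_alpha` (default
#' 0.01, the "n.s." convention of the trait-correlation tables).
#'
#' @param data data.frame of line-level trait columns.
#' @param traits columns to correlate (default: all numeric columns).
#' @param method `"pearson"` or `"spearman"`.
#' @param ns_alpha masking threshold on the p-value.
#' @return list of matrices `r`, `p`, `masked` and the sample-size matrix
#'   `n`; constant or under-observed pairs get `NA` coefficients.
#' @export
correlation_matrix <- function(data, traits = NULL,
                               method = c("pearson", "spearman"),
                               ns_alpha = 0.01) {
  method <- match.arg(method)
  if (is.null(traits)) {
    traits <- names(data)[vapply(data, is.numeric, logical(1L))]
  }
  k <- length(traits)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) {
    diag(n)[i] <- sum(!is.na(data[[traits[i]]]))
    for (j in seq_len(k)) {
      if (j <= i) next
      x <- data[[traits[i]]]; y <- data[[traits[j]]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
      ct <- suppressWarnings(
        stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, masked = !is.na(p) & p > ns_alpha, n = n)
}
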