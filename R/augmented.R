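#' Check-based spatial adjustment for Type-2 modified augmented designs
#'
#' The design replicates a primary check at the centre of every block and
#' two secondary checks in a subset of blocks.  Two corrections are
#' supported.  Method 1 (M1) removes additive block-row/block-column field
#' trends using primary-check margins:
#' \deqn{adj = raw - Check1RowAve - Check1ColAve + 2\,Check1Ave}
#' Method 3 (M3) regresses primary-check values on the within-block mean of
#' the secondary checks and removes the block deviation scaled by that
#' slope:
#' \deqn{adj = raw - Slope (Check1Block - Check1Ave)}
#' All context terms are computed within a single stratum: one year and one
#' check set (field half).  Use [adjust_trait_table()] to apply the
#' procedure across strata of a full trial.
#'
#' @name augmented_adjustment
NULL

# one stratum = one year x one primary-check entry (field half); returns a
# list of row-index vectors into `table`
stratum_indices <- function(table) {
  df <- as.data.frame(table)
  prim <- df[df$check_class == "primary", , drop = FALSE]
  bkey <- paste(df$year, df$block_id, sep = "\r")
  pkey <- paste(prim$year, prim$block_id, sep = "\r")
  orphan <- setdiff(unique(bkey), pkey)
  if (length(orphan) > 0L) {
    stop("block(s) without a primary check: ",
         paste(utils::head(gsub("\r", "/", orphan), 5L), collapse = ", "))
  }
  half <- prim$entry_id[match(bkey, pkey)]
  split(seq_len(nrow(df)), paste(df$year, half, sep = "/"), drop = TRUE)
}

single_stratum <- function(table, caller) {
  idx <- stratum_indices(table)
  if (length(idx) != 1L) {
    stop(caller, "() expects a single (year, check-set) stratum; ",
         "use adjust_trait_table() for multi-stratum tables")
  }
  invisible(table)
}

# primary-check margins within one stratum
adjustment_context <- function(table, trait) {
  df <- as.data.frame(table)
  prim <- df[df$check_class == "primary", , drop = FALSE]
  val <- prim[[trait]]
  ok <- !is.na(val)
  list(
    row_ave = tapply(val[ok], prim$block_row[ok], mean),
    col_ave = tapply(val[ok], prim$block_col[ok], mean),
    grand_ave = mean(val[ok]),
    block_val = stats::setNames(val, prim$block_id))
}

#' Two-way ANOVA of primary-check values on block row and column
#'
#' Tests whether the field varies across block rows and/or block columns,
#' the first of the two criteria for deciding whether trait values should
#' be spatially corrected.  With zero residual variance (all checks equal)
#' the p-values are reported as missing and treated as "no spatial effect".
#'
#' @param table single-stratum [trait_table()].
#' @param trait trait name.
#' @return list with `row_p` and `col_p` (NA when a factor has fewer than
#'   two levels or the residual is degenerate).
#' @export
check_anova <- function(table, trait) {
  single_stratum(table, "check_anova")
  df <- as.data.frame(table)
  prim <- df[df$check_class == "primary" & !is.na(df[[trait]]), , drop = FALSE]
  prim$row_f <- factor(prim$block_row)
  prim$col_f <- factor(prim$block_col)
  n_row <- nlevels(prim$row_f); n_col <- nlevels(prim$col_f)
  if (n_row < 2L && n_col < 2L) return(list(row_p = NA_real_, col_p = NA_real_))
  if (nrow(prim) < 2L || stats::sd(prim[[trait]]) == 0) {
    # all checks identical: no spatial variance to test
    return(list(row_p = NA_real_, col_p = NA_real_))
  }
  form <- if (n_row >= 2L && n_col >= 2L) {
    stats::as.formula(paste(trait, "~ row_f + col_f"))
  } else if (n_row >= 2L) {
    stats::as.formula(paste(trait, "~ row_f"))
  } else stats::as.formula(paste(trait, "~ col_f"))
  tab <- stats::anova(stats::aov(form, data = prim))
  pick <- function(term) {
    if (!term %in% rownames(tab)) return(NA_real_)
    p <- tab[term, "Pr(>F)"]
    if (is.nan(p) || !is.finite(tab[term, "F value"])) NA_real_ else p
  }
  list(row_p = pick("row_f"), col_p = pick("col_f"))
}

#' @rdname augmented_adjustment
#' @param table single-stratum [trait_table()].
#' @param trait trait name.
#' @return a numeric vector of adjusted values, aligned with the rows of
#'   `table`; missing raw values stay missing.
#' @export
adjust_m1 <- function(table, trait) {
  single_stratum(table, "adjust_m1")
  ctx <- adjustment_context(table, trait)
  df <- as.data.frame(table)
  ra <- ctx$row_ave[as.character(df$block_row)]
  ca <- ctx$col_ave[as.character(df$block_col)]
  orphan <- which(is.na(ra) | is.na(ca))
  if (length(orphan) > 0L) {
    o <- orphan[1L]
    stop(sprintf(
      "plot (year=%s, block=%s, plot %s/%s) shares no block row/column with a primary check",
      df$year[o], df$block_id[o], df$plot_row[o], df$plot_col[o]))
  }
  as.numeric(df[[trait]] - ra - ca + 2 * ctx$grand_ave)
}

# slope of primary-check values on within-block secondary-check means,
# over blocks containing both
slope_all_checks <- function(table, trait) {
  df <- as.data.frame(table)
  sec <- df[df$check_class == "secondary" & !is.na(df[[trait]]), , drop = FALSE]
  if (nrow(sec) == 0L) return(NA_real_)
  sec_mean <- tapply(sec[[trait]], sec$block_id, mean)
  ctx <- adjustment_context(table, trait)
  prim_val <- ctx$block_val[names(sec_mean)]
  keep <- !is.na(prim_val)
  if (sum(keep) < 2L || stats::var(sec_mean[keep]) == 0) return(NA_real_)
  unname(stats::coef(stats::lm(prim_val[keep] ~ sec_mean[keep]))[2L])
}

#' @rdname augmented_adjustment
#' @export
adjust_m3 <- function(table, trait) {
  single_stratum(table, "adjust_m3")
  slope <- slope_all_checks(table, trait)
  if (is.na(slope)) {
    stop("M3 slope inestimable (need >= 2 blocks holding both primary and ",
         "secondary checks, with varying secondary means); use M1 or no ",
         "adjustment")
  }
  ctx <- adjustment_context(table, trait)
  df <- as.data.frame(table)
  bv <- ctx$block_val[as.character(df$block_id)]
  as.numeric(df[[trait]] - slope * (bv - ctx$grand_ave))
}

#' Relative efficiency of a spatial correction
#'
#' Mean per-secondary-check-entry variance of the raw values divided by the
#' same for adjusted values; values above one mean the correction removed
#' field heterogeneity.
#'
#' @param raw,adjusted numeric vectors of raw and adjusted values aligned
#'   with the rows of `table`.
#' @param table the [trait_table()] supplying the secondary-check layout.
#' @return a single ratio; `Inf` (with attribute `degenerate = TRUE`) when
#'   the adjusted secondary-check variance is exactly zero.
#' @export
relative_efficiency <- function(raw, adjusted, table) {
  df <- as.data.frame(table)
  sec <- df$check_class == "secondary"
  ent <- df$entry_id[sec]
  per_entry_var <- function(v) {
    x <- split(v[sec], ent)
    x <- x[vapply(x, function(z) sum(!is.na(z)) >= 2L, logical(1L))]
    if (length(x) < 2L) {
      stop("relative efficiency needs >= 2 secondary-check entries with ",
           ">= 2 plots each")
    }
    mean(vapply(x, stats::var, numeric(1L), na.rm = TRUE))
  }
  v_raw <- per_entry_var(raw)
  v_adj <- per_entry_var(adjusted)
  if (v_adj == 0) {
    return(structure(Inf, degenerate = TRUE))
  }
  v_raw / v_adj
}

#' Choose a spatial-correction method for one stratum
#'
#' Applies the two-criterion decision rule: correction is warranted only if
#' the primary-check ANOVA finds a block-row or block-column effect at
#' `alpha` and at least one method achieves relative efficiency above one;
#' the feasible method with the larger relative efficiency wins (ties go to
#' the simpler M1).  Full diagnostics are attached either way.
#'
#' @param table single-stratum [trait_table()].
#' @param trait trait name.
#' @param alpha significance level for the check ANOVA.
#' @return an `adjustment_result` list: `method` ("none", "M1" or "M3"),
#'   `adjusted` (a [trait_table()] of identical shape with the trait column
#'   replaced when a method was chosen), `row_p`, `col_p`,
#'   `relative_efficiency` (named vector for M1/M3), `slope`.
#' @export
select_adjustment <- function(table, trait, alpha = 0.05) {
  single_stratum(table, "select_adjustment")
  an <- check_anova(table, trait)
  raw <- as.data.frame(table)[[trait]]
  cand <- list(M1 = function() adjust_m1(table, trait),
               M3 = function() adjust_m3(table, trait))
  adj_vals <- lapply(cand, function(f) tryCatch(f(), error = function(e) NULL))
  re <- vapply(adj_vals, function(v) {
    if (is.null(v)) return(NA_real_)
    tryCatch(as.numeric(relative_efficiency(raw, v, table)),
             error = function(e) NA_real_)
  }, numeric(1L))
  spatial_effect <- (!is.na(an$row_p) && an$row_p < alpha) ||
    (!is.na(an$col_p) && an$col_p < alpha)
  feasible <- names(re)[!is.na(re) & re > 1]
  method <- "none"
  if (spatial_effect && length(feasible) > 0L) {
    best <- max(re[feasible])
    method <- if ("M1" %in% feasible && re[["M1"]] >= best) "M1" else
      feasible[which.max(re[feasible])]
  }
  adjusted <- table
  if (method != "none") adjusted[[trait]] <- adj_vals[[method]]
  structure(list(method = method, adjusted = adjusted,
                 row_p = an$row_p, col_p = an$col_p,
                 relative_efficiency = re,
                 slope = slope_all_checks(table, trait)),
            class = "adjustment_result")
}

#' @method print adjustment_result
#' @export
print.adjustment_result <- function(x, ...) {
  cat(sprintf("adjustment: method=%s row_p=%.3g col_p=%.3g RE(M1)=%.3f RE(M3)=%.3f\n",
              x$method, x$row_p, x$col_p,
              x$relative_efficiency[["M1"]], x$relative_efficiency[["M3"]]))
  invisible(x)
}

#' Adjust a full trial trait by trait-within-stratum
#'
#' Applies [select_adjustment()] (or a forced method) separately within
#' every (year, check-set) stratum of a complete trial, mirroring the
#' per-trait / per-year / per-field-half procedure, and reassembles the
#' table in the original row order.
#'
#' @param table a [trait_table()] covering one or more strata.
#' @param trait trait name.
#' @param method `"auto"` applies the decision rule; `"m1"`, `"m3"` force a
#'   method; `"none"` returns the input.
#' @param alpha check-ANOVA level for `"auto"`.
#' @return list with `adjusted` ([trait_table()]) and `diagnostics`, one
#'   row per stratum (method, row_p, col_p, RE_M1, RE_M3, slope).
#' @export
adjust_trait_table <- function(table, trait, method = c("auto", "m1", "m3",
                                                        "none"),
                               alpha = 0.05) {
  method <- match.arg(method)
  idx <- stratum_indices(table)
  out <- as.data.frame(table)
  diags <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    sub <- table[idx[[i]], , drop = FALSE]
    if (method == "auto") {
      res <- select_adjustment(sub, trait, alpha)
      out[[trait]][idx[[i]]] <- as.data.frame(res$adjusted)[[trait]]
      diags[[i]] <- data.frame(
        stratum = names(idx)[i], method = res$method, row_p = res$row_p,
        col_p = res$col_p, RE_M1 = res$relative_efficiency[["M1"]],
        RE_M3 = res$relative_efficiency[["M3"]], slope = res$slope,
        stringsAsFactors = FALSE)
    } else {
      vals <- switch(method, m1 = adjust_m1(sub, trait),
                     m3 = adjust_m3(sub, trait),
                     none = as.data.frame(sub)[[trait]])
      out[[trait]][idx[[i]]] <- vals
      diags[[i]] <- data.frame(stratum = names(idx)[i],
                               method = toupper(method), row_p = NA_real_,
                               col_p = NA_real_, RE_M1 = NA_real_,
                               RE_M3 = NA_real_, slope = NA_real_,
                               stringsAsFactors = FALSE)
    }
  }
  list(adjusted = trait_table(out, trait_names(table)),
       diagnostics = do.call(rbind, diags))
}
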