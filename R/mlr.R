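#' Multiple linear regression with listwise deletion
#'
#' Fits `response ~ predictors` by least squares after removing every row
#' with a missing value among the used columns (the rows-used count is
#' reported).
#'
#' @param data data.frame of line-level traits.
#' @param response response trait name.
#' @param predictors character vector of predictor trait names.
#' @return an `mlr_model` list: `fit` (the `lm`), `response`, `predictors`,
#'   `coefficients`, `R2`, `n`.
#' @export
fit_mlr <- function(data, response, predictors) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n <= length(predictors) + 1L) {
    stop(sprintf("too few complete rows (%d) for %d predictors",
                 n, length(predictors)))
  }
  form <- stats::reformulate(predictors, response)
  fit <- stats::lm(form, data = df)
  if (fit$rank < length(predictors) + 1L) {
    al <- stats::alias(fit)$Complete
    stop("rank-deficient fit; collinear predictors: ",
         paste(rownames(al), collapse = ", "))
  }
  structure(list(fit = fit, response = response, predictors = predictors,
                 coefficients = stats::coef(fit),
                 R2 = summary(fit)$r.squared, n = n,
                 data = df),
            class = "mlr_model")
}

#' @method print mlr_model
#' @export
print.mlr_model <- function(x, ...) {
  cat(sprintf("mlr_model: %s ~ %s  (R2 = %.3f, n = %d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$R2, x$n))
  invisible(x)
}

# R2 of the response on the predictor subset `mask` (bitmask), from the
# moment matrices; used by the lmg enumeration
subset_r2 <- function(mask, cxx, cxy, cyy) {
  if (mask == 0L) return(0)
  idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_along(cxy) - 1L)) != 0L)
  b <- solve(cxx[idx, idx, drop = FALSE], cxy[idx])
  sum(b * cxy[idx]) / cyy
}

#' lmg (Shapley) decomposition of regression R2
#'
#' The lmg relative importance of a predictor is its incremental R2 when
#' entering the model, averaged over all orderings of model entry.  Shares
#' are non-negative and sum exactly to the full-model R2.  Subsets are
#' enumerated exactly for up to `exact_limit` predictors (Shapley weights
#' over the subset lattice, algebraically identical to averaging the p!
#' orderings); above that a seeded permutation sample is used.
#'
#' @param data,response,predictors as in [fit_mlr()] (listwise deletion
#'   applied the same way).
#' @param exact_limit largest p for exact enumeration (default 12).
#' @param n_perm permutation draws for the sampling estimate (>= 5000).
#' @param seed seed for the sampling path.
#' @return a `variance_partition` list: `shares` (named, ordered as given),
#'   `total_R2`, `exact`.
#' @export
lmg_shares <- function(data, response, predictors, exact_limit = 12L,
                       n_perm = 5000L, seed = 1L) {
  model <- fit_mlr(data, response, predictors)
  df <- model$data
  p <- length(predictors)
  x <- as.matrix(df[, predictors, drop = FALSE])
  y <- df[[response]]
  cxx <- stats::cov(x); cxy <- stats::cov(x, y)[, 1L]; cyy <- stats::var(y)
  shares <- stats::setNames(numeric(p), predictors)
  if (p <= exact_limit) {
    r2 <- vapply(0:(2^p - 1L), subset_r2, numeric(1L), cxx, cxy, cyy)
    fact <- factorial(0:p)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      masks <- which(bitwAnd(0:(2^p - 1L), bit) == 0L) - 1L
      sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1L))) != 0L), numeric(1L))
      w <- fact[sizes + 1L] * fact[p - sizes] / fact[p + 1L]
      shares[j] <- sum(w * (r2[masks + bit + 1L] - r2[masks + 1L]))
    }
    exact <- TRUE
  } else {
    stopifnot(n_perm >= 1L)
    set.seed(as.integer(seed))
    acc <- numeric(p)
    for (b in seq_len(n_perm)) {
      ord <- sample.int(p)
      mask <- 0L
      prev <- 0
      for (j in ord) {
        mask <- mask + bitwShiftL(1L, j - 1L)
        cur <- subset_r2(mask, cxx, cxy, cyy)
        acc[j] <- acc[j] + (cur - prev)
        prev <- cur
      }
    }
    shares[] <- acc / n_perm
    exact <- FALSE
  }
  structure(list(shares = shares, total_R2 = model$R2, exact = exact,
                 n = model$n),
            class = "variance_partition")
}

#' @method print variance_partition
#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("variance partition (R2 = %.3f%s):\n", x$total_R2,
              if (x$exact) ", exact" else ", sampled"))
  print(round(100 * x$shares, 2))
  invisible(x)
}

#' Bootstrap stepwise predictor selection
#'
#' Refits the full model on `B` bootstrap resamples of the rows, running
#' bidirectional stepwise selection (AIC by default, BIC optionally) from
#' the full model each time, and reports the fraction of resamples
#' selecting each predictor.  Predictors at or above `threshold` are kept.
#'
#' @inheritParams fit_mlr
#' @param B number of bootstrap resamples.
#' @param threshold inclusion-fraction cutoff for keeping a predictor.
#' @param criterion `"AIC"` or `"BIC"`.
#' @param seed integer seed.
#' @return a `selection_report` list: `kept`, `bootstrap_inclusion`,
#'   `n_failed`, `B`.
#' @export
bootstrap_stepwise <- function(data, response, predictors, B = 1000L,
                               threshold = 0.6, criterion = c("AIC", "BIC"),
                               seed = 1L) {
  stopifnot(B >= 1L)
  criterion <- match.arg(criterion)
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  form <- stats::reformulate(predictors, response)
  set.seed(as.integer(seed))
  hits <- stats::setNames(numeric(length(predictors)), predictors)
  n_failed <- 0L
  for (b in seq_len(B)) {
    rows <- sample.int(nrow(df), replace = TRUE)
    sel <- tryCatch({
      boot_df <- df[rows, , drop = FALSE]
      k <- if (criterion == "AIC") 2 else log(nrow(boot_df))
      fit <- stats::lm(form, data = boot_df)
      red <- stats::step(fit, direction = "both", trace = 0, k = k,
                         scope = list(lower = stats::as.formula(paste(response, "~ 1")),
                                      upper = form))
      intersect(predictors, all.vars(stats::formula(red))[-1L])
    }, error = function(e) NULL)
    if (is.null(sel)) n_failed <- n_failed + 1L else hits[sel] <- hits[sel] + 1L
  }
  n_ok <- B - n_failed
  incl <- if (n_ok > 0L) hits / n_ok else hits * NA_real_
  structure(list(kept = predictors[!is.na(incl) & incl >= threshold],
                 bootstrap_inclusion = incl, n_failed = n_failed, B = B,
                 threshold = threshold, criterion = criterion),
            class = "selection_report")
}

#' Iterative outlier removal by Cook's distance
#'
#' Repeatedly removes the single row with the largest Cook's distance and
#' refits, stopping when the last removal improved R2 by less than
#' `delta_R2_stop` or when `max_frac` of the rows have been removed (the
#' termination guarantee for "until R2 stops improving significantly").
#'
#' @inheritParams fit_mlr
#' @param delta_R2_stop minimum R2 improvement to continue (> 0).
#' @param max_frac cap on the fraction of rows removed.
#' @return list with `model` (final [fit_mlr()] model), `removed`
#'   (data.frame: row label, Cook's distance, R2 after removal).
#' @export
cooks_prune <- function(data, response, predictors, delta_R2_stop = 0.005,
                        max_frac = 0.05) {
  stopifnot(delta_R2_stop > 0)
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  max_remove <- floor(max_frac * nrow(df))
  model <- fit_mlr(df, response, predictors)
  removed <- data.frame(row = character(0), cooks_d = numeric(0),
                        R2_after = numeric(0), stringsAsFactors = FALSE)
  while (nrow(removed) < max_remove) {
    cd <- stats::cooks.distance(model$fit)
    worst <- which.max(cd)
    cand <- df[-worst, , drop = FALSE]
    new_model <- fit_mlr(cand, response, predictors)
    if (new_model$R2 - model$R2 < delta_R2_stop) break
    removed <- rbind(removed, data.frame(
      row = rownames(df)[worst], cooks_d = unname(cd[worst]),
      R2_after = new_model$R2, stringsAsFactors = FALSE))
    df <- cand
    model <- new_model
  }
  list(model = model, removed = removed)
}

#' Full variance-partition pipeline for tiller-number models
#'
#' Runs the study's regression procedure in order: listwise deletion, a
#' preliminary lmg pass to order predictors by contribution (reporting
#' only), bootstrap stepwise selection, refit of the kept predictors,
#' iterative Cook's-distance pruning, a VIF collinearity check (warning at
#' `vif_limit`), and the final lmg decomposition on the pruned model.
#'
#' @inheritParams bootstrap_stepwise
#' @param delta_R2_stop,max_frac passed to [cooks_prune()].
#' @param vif_limit VIF above which a hard warning is raised.
#' @return list with `partition` ([lmg_shares()] result on the final
#'   model; `NULL` when no predictor survives selection), `selection`
#'   (`selection_report` plus `removed_outliers` and `vif`), `model`
#'   (final `mlr_model`), `order` (preliminary importance ordering).
#' @export
variance_partition_pipeline <- function(data, response, predictors,
                                        B = 1000L, threshold = 0.6,
                                        criterion = "AIC",
                                        delta_R2_stop = 0.005,
                                        max_frac = 0.05, vif_limit = 5,
                                        seed = 1L) {
  df <- data[, c(response, predictors), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  pre <- lmg_shares(df, response, predictors, seed = seed)
  ord <- names(sort(pre$shares, decreasing = TRUE))
  sel <- bootstrap_stepwise(df, response, ord, B = B, threshold = threshold,
                            criterion = criterion, seed = seed)
  if (length(sel$kept) == 0L) {
    sel$removed_outliers <- data.frame()
    sel$vif <- numeric(0)
    return(list(partition = NULL, selection = sel, model = NULL,
                order = ord))
  }
  pruned <- cooks_prune(df, response, sel$kept,
                        delta_R2_stop = delta_R2_stop, max_frac = max_frac)
  vif <- if (length(sel$kept) >= 2L) {
    car::vif(pruned$model$fit)
  } else stats::setNames(1, sel$kept)
  if (any(vif > vif_limit)) {
    warning("predictors exceed the VIF limit: ",
            paste(names(vif)[vif > vif_limit], collapse = ", "),
            call. = FALSE)
  }
  part <- lmg_shares(pruned$model$data, response, sel$kept, seed = seed)
  sel$removed_outliers <- pruned$removed
  sel$vif <- vif
  list(partition = part, selection = sel, model = pruned$model, order = ord)
}
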