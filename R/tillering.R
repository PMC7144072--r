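#' Weekly tiller series and trajectory metrics
#'
#' A tiller series holds the mean weekly tiller counts of one line (weeks
#' past emergence, typically 2-7) plus its productive-tiller count.  The
#' overall tillering rate is the maximum count divided by the week at which
#' the maximum is (first) reached; finer rates are week-to-week differences
#' and least-squares slopes over windows of at least three consecutive
#' weeks.
#'
#' @param entry_id line identifier.
#' @param week_counts named numeric vector of mean tiller counts; names are
#'   the integer weeks.
#' @param productive_count mean productive (grain-bearing) tiller count.
#' @return a `tiller_series` list with `max_count` (max over non-missing
#'   weeks) and `week_of_max` (earliest week attaining it) filled in.
#' @export
tiller_series <- function(entry_id, week_counts, productive_count = NA_real_) {
  if (is.null(names(week_counts))) {
    stop("week_counts must be named by week")
  }
  weeks <- as.integer(names(week_counts))
  stopifnot(!anyNA(weeks))
  ord <- order(weeks)
  week_counts <- stats::setNames(as.numeric(week_counts)[ord], weeks[ord])
  if (any(week_counts < 0, na.rm = TRUE)) stop("negative tiller count")
  ok <- !is.na(week_counts)
  max_count <- if (any(ok)) max(week_counts[ok]) else NA_real_
  week_of_max <- if (any(ok)) {
    as.integer(names(week_counts)[ok][which.max(week_counts[ok])])
  } else NA_integer_
  structure(list(entry_id = as.character(entry_id),
                 week_counts = week_counts, max_count = max_count,
                 week_of_max = week_of_max,
                 productive_count = as.numeric(productive_count)),
            class = "tiller_series")
}

#' @rdname tiller_series
#' @param series a `tiller_series`.
#' @return [tillering_rate()]: max count / week of max (tillers per week),
#'   `NA` when every weekly count is missing.
#' @export
tillering_rate <- function(series) {
  stopifnot(inherits(series, "tiller_series"))
  if (is.na(series$max_count)) return(NA_real_)
  series$max_count / series$week_of_max
}

#' @rdname tiller_series
#' @return [percent_productive()]: `100 * productive / max`; `NA` when the
#'   maximum is zero or missing.  May exceed 100 (late tillers that headed
#'   after the last weekly count); values are reported, not clipped.
#' @export
percent_productive <- function(series) {
  stopifnot(inherits(series, "tiller_series"))
  if (is.na(series$max_count) || series$max_count == 0 ||
      is.na(series$productive_count)) {
    return(NA_real_)
  }
  100 * series$productive_count / series$max_count
}

#' Week-to-week differences and windowed slopes of a tiller series
#'
#' @param series a [tiller_series()].
#' @param slope_windows list of integer week vectors (each >= 3 consecutive
#'   weeks) over which to fit least-squares slopes; default: the full
#'   observed span.
#' @return list with `differences` (named by `"w1-w2"`, consecutive
#'   observed weeks only) and `slopes` (one per window, `NA` where the
#'   window has a gap or missing counts).
#' @export
weekly_rate_metrics <- function(series, slope_windows = NULL) {
  stopifnot(inherits(series, "tiller_series"))
  wc <- series$week_counts
  weeks <- as.integer(names(wc))
  consec <- which(diff(weeks) == 1L)
  diffs <- stats::setNames(
    wc[consec + 1L] - wc[consec],
    sprintf("%d-%d", weeks[consec], weeks[consec + 1L]))
  if (is.null(slope_windows)) {
    slope_windows <- list(weeks)
  }
  slopes <- vapply(slope_windows, function(win) {
    win <- sort(as.integer(win))
    if (length(win) < 3L || any(diff(win) != 1L)) return(NA_real_)
    idx <- match(win, weeks)
    if (anyNA(idx)) return(NA_real_)
    y <- wc[idx]
    if (anyNA(y)) return(NA_real_)
    unname(stats::coef(stats::lm(y ~ win))[2L])
  }, numeric(1L))
  names(slopes) <- vapply(slope_windows, function(w) {
    sprintf("%d:%d", min(w), max(w))
  }, character(1L))
  list(differences = diffs, slopes = slopes)
}

#' Principal coordinates of tiller trajectories
#'
#' Builds the per-line feature vector (weekly counts for the requested
#' weeks plus the productive count), computes the Euclidean distance
#' matrix, and applies classical metric scaling (double-centering +
#' eigendecomposition).  Lines with any missing feature are dropped with a
#' warning.  Variance explained is each eigenvalue over the sum of the
#' positive eigenvalues.
#'
#' @param series_set list of [tiller_series()].
#' @param k number of coordinates to return (truncated, with a warning, to
#'   the number of positive eigenvalues).
#' @param weeks weeks required in every feature vector.
#' @param standardize standardize features to unit variance first (off by
#'   default: raw counts).
#' @return a `tiller_pcoa` list: `coordinates` (lines x k, rownames =
#'   entry ids), `variance_explained`, `eigenvalues`, `dropped`.
#' @export
tiller_pcoa <- function(series_set, k = 2L, weeks = 2:7,
                        standardize = FALSE) {
  feats <- lapply(series_set, function(s) {
    stopifnot(inherits(s, "tiller_series"))
    c(s$week_counts[as.character(weeks)], productive = s$productive_count)
  })
  mat <- do.call(rbind, feats)
  rownames(mat) <- vapply(series_set, `[[`, character(1L), "entry_id")
  complete <- stats::complete.cases(mat)
  dropped <- rownames(mat)[!complete]
  if (length(dropped) > 0L) {
    warning(sprintf("dropping %d line(s) with missing features",
                    length(dropped)), call. = FALSE)
  }
  mat <- mat[complete, , drop = FALSE]
  if (standardize) mat <- scale(mat)
  d <- stats::dist(mat)
  mds <- stats::cmdscale(d, k = min(k, nrow(mat) - 1L), eig = TRUE)
  eig <- mds$eig
  pos <- eig[eig > sqrt(.Machine$double.eps) * max(abs(eig))]
  k_eff <- min(k, length(pos), ncol(mds$points))
  if (k_eff < k) {
    warning(sprintf("only %d positive eigenvalue(s); k truncated", k_eff),
            call. = FALSE)
  }
  coords <- mds$points[, seq_len(k_eff), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k_eff))
  structure(list(coordinates = coords,
                 variance_explained = pos[seq_len(k_eff)] / sum(pos),
                 eigenvalues = eig, dropped = dropped),
            class = "tiller_pcoa")
}

#' Extract per-line tiller series from a simulated or measured trait table
#'
#' Averages plot values per entry (test entries by default) and builds one
#' [tiller_series()] per line from the `tiller_<w>wpe` columns and
#' `tiller_productive`.
#'
#' @param table a [trait_table()] with weekly tiller-count columns.
#' @param weeks integer weeks to extract.
#' @param include_checks keep check entries too.
#' @return named list of [tiller_series()].
#' @export
tiller_series_from_table <- function(table, weeks = 2:7,
                                     include_checks = FALSE) {
  df <- as.data.frame(table)
  if (!include_checks) df <- df[df$check_class == "test", , drop = FALSE]
  cols <- sprintf("tiller_%dwpe", weeks)
  missing_cols <- setdiff(c(cols, "tiller_productive"), names(df))
  if (length(missing_cols) > 0L) {
    stop("table lacks tiller columns: ", paste(missing_cols, collapse = ", "))
  }
  entries <- unique(df$entry_id)
  out <- lapply(entries, function(e) {
    sub <- df[df$entry_id == e, , drop = FALSE]
    wk <- vapply(cols, function(cc) mean(sub[[cc]], na.rm = TRUE),
                 numeric(1L))
    wk[is.nan(wk)] <- NA_real_
    prod <- mean(sub$tiller_productive, na.rm = TRUE)
    tiller_series(e, stats::setNames(wk, weeks),
                  ifelse(is.nan(prod), NA_real_, prod))
  })
  stats::setNames(out, entries)
}
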