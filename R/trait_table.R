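#' Plot-level trait tables for modified augmented designs
#'
#' A trait table is a plain `data.frame` (class `"trait_table"`) with one row
#' per field plot and the design columns
#' `year`, `block_id`, `block_row`, `block_col`, `plot_row`, `plot_col`,
#' `entry_id`, `check_class`, followed by one numeric column per trait.
#' `check_class` is one of `"primary"`, `"secondary"`, `"test"`.  Plot
#' coordinates are 1-based within a block (5 rows x 3 columns in the barley
#' layout); block rows/columns are 1-based across the field.  The trait
#' columns are recorded in the `"trait_names"` attribute so design columns
#' and traits never get confused.
#'
#' @param df data.frame holding the design columns and trait columns.
#' @param trait_names character vector naming the trait columns of `df`.
#' @return `df` with class `"trait_table"` and a `"trait_names"` attribute.
#' @export
trait_table <- function(df, trait_names) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(design_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("trait table is missing design columns: ",
         paste(missing_cols, collapse = ", "))
  }
  missing_traits <- setdiff(trait_names, names(df))
  if (length(missing_traits) > 0L) {
    stop("trait columns not present in data: ",
         paste(missing_traits, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$entry_id <- as.character(df$entry_id)
  df$check_class <- as.character(df$check_class)
  bad <- setdiff(unique(df$check_class), c("primary", "secondary", "test"))
  if (length(bad) > 0L) {
    stop("unknown check_class token(s): ", paste(bad, collapse = ", "))
  }
  for (tr in trait_names) df[[tr]] <- as.numeric(df[[tr]])
  key <- paste(df$year, df$block_id, df$plot_row, df$plot_col, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf(
      "duplicate plot coordinates (year=%s, block=%s, plot_row=%s, plot_col=%s) at row %d",
      df$year[d], df$block_id[d], df$plot_row[d], df$plot_col[d], d))
  }
  nonfinite <- vapply(trait_names, function(tr) {
    any(!is.na(df[[tr]]) & !is.finite(df[[tr]]))
  }, logical(1L))
  if (any(nonfinite)) {
    stop("non-finite trait values in: ",
         paste(trait_names[nonfinite], collapse = ", "))
  }
  structure(df, trait_names = as.character(trait_names),
            class = c("trait_table", "data.frame"))
}

design_columns <- function() {
  c("year", "block_id", "block_row", "block_col",
    "plot_row", "plot_col", "entry_id", "check_class")
}

#' @rdname trait_table
#' @param x object to query.
#' @export
trait_names <- function(x) attr(x, "trait_names")

#' @method print trait_table
#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("trait_table: %d plots, %d trait(s) [%s]\n", nrow(x),
              length(trait_names(x)),
              paste(trait_names(x), collapse = ", ")))
  NextMethod()
}

# Subsetting drops to data.frame semantics but keeps attributes when the
# design columns survive; used pervasively by the analysis modules.
#' @export
`[.trait_table` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(design_columns() %in% names(out))) {
    tn <- intersect(attr(x, "trait_names"), names(out))
    attr(out, "trait_names") <- tn
    class(out) <- c("trait_table", "data.frame")
  }
  out
}

#' Validate augmented-design invariants of a trait table
#'
#' Checks that every block contains exactly one primary-check plot and (if
#' `central = TRUE`) that it sits at the central plot position of the 5 x 3
#' block layout, and that secondary checks are confined to a subset of
#' blocks.  Violations are reported as warnings by default so that partial
#' tables (e.g. check-only subsets) can still flow through readers.
#'
#' @param table a [trait_table()].
#' @param central require the primary check at the block's central plot.
#' @param strict raise errors instead of warnings.
#' @return invisibly, a character vector of violation messages (empty if ok).
#' @export
validate_design <- function(table, central = TRUE, strict = FALSE) {
  msgs <- character(0)
  for (yr in unique(table$year)) {
    tab <- table[table$year == yr, , drop = FALSE]
    prim <- tab[tab$check_class == "primary", , drop = FALSE]
    counts <- table(factor(prim$block_id, levels = unique(tab$block_id)))
    if (any(counts != 1L)) {
      msgs <- c(msgs, sprintf(
        "year %s: %d block(s) without exactly one primary check",
        yr, sum(counts != 1L)))
    }
    if (central && nrow(prim) > 0L) {
      n_pr <- max(tab$plot_row); n_pc <- max(tab$plot_col)
      ctr_r <- (n_pr + 1L) %/% 2L; ctr_c <- (n_pc + 1L) %/% 2L
      off <- prim$plot_row != ctr_r | prim$plot_col != ctr_c
      if (any(off)) {
        msgs <- c(msgs, sprintf(
          "year %s: %d primary check(s) not at the central plot", yr, sum(off)))
      }
    }
  }
  if (length(msgs) > 0L) {
    if (strict) stop(paste(msgs, collapse = "; "))
    for (m in msgs) warning(m, call. = FALSE)
  }
  invisible(msgs)
}

#' Read / write plot-level trait tables (long CSV)
#'
#' The long CSV dialect has a header row naming the eight design columns
#' (see [trait_table()]) followed by at least one trait column.  Empty cells
#' and `NA` are read as missing; missing values are written as `NA`.
#'
#' @param path CSV file path.
#' @param dialect only `"long_csv"` is defined.
#' @return [read_trait_table()]: a [trait_table()], row order preserved.
#' @export
read_trait_table <- function(path, dialect = c("long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  missing_cols <- setdiff(design_columns(), names(df))
  if (length(missing_cols) > 0L) {
    stop("trait CSV is missing design columns: ",
         paste(missing_cols, collapse = ", "))
  }
  traits <- setdiff(names(df), design_columns())
  if (length(traits) == 0L) stop("trait CSV names no trait columns")
  trait_table(df, traits)
}

#' @rdname read_trait_table
#' @param table a [trait_table()] to write.
#' @return [write_trait_table()]: `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  df <- as.data.frame(table)[, c(design_columns(), trait_names(table)),
                             drop = FALSE]
  for (tr in trait_names(table)) {
    # 17 significant digits: doubles survive the text round trip exactly
    df[[tr]] <- ifelse(is.na(df[[tr]]), NA,
                       formatC(df[[tr]], digits = 17, format = "g"))
  }
  utils::write.csv(df, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}
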