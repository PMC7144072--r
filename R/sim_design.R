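#' Specify a Type-2 modified augmented field design
#'
#' The study layout is 56 blocks of 15 plots (5 plot-rows x 3 plot-columns),
#' the central plot of every block holding a repeated primary check, and 8
#' randomly chosen blocks additionally holding 2 repeated secondary-check
#' plots.  With a split factor the field is divided into two halves (e.g.
#' 2-row vs 6-row germplasm), each with its own primary and secondary check
#' cultivars.
#'
#' @param n_blocks number of blocks (study value 56).
#' @param plots_per_block_rows,plots_per_block_cols within-block plot grid
#'   (5 x 3).
#' @param n_secondary_blocks blocks that carry secondary checks (8).
#' @param secondary_checks_per_block secondary-check plots per such block (2).
#' @param split_factor optional name of the factor splitting the field into
#'   two check-set halves (e.g. `"row_type"`); `NULL` for a single half.
#' @return a `design_spec` list; `n_test_plots(spec)` gives the test-entry
#'   capacity `n_blocks*rows*cols - n_blocks - n_secondary_blocks*per_block`.
#' @export
design_spec <- function(n_blocks = 56L, plots_per_block_rows = 5L,
                        plots_per_block_cols = 3L, n_secondary_blocks = 8L,
                        secondary_checks_per_block = 2L,
                        split_factor = NULL) {
  stopifnot(n_blocks >= 1L, n_secondary_blocks <= n_blocks,
            plots_per_block_rows %% 2L == 1L, plots_per_block_cols %% 2L == 1L)
  if (!is.null(split_factor) && n_blocks %% 2L != 0L) {
    stop("a split design needs an even number of blocks")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 plots_per_block_rows = as.integer(plots_per_block_rows),
                 plots_per_block_cols = as.integer(plots_per_block_cols),
                 n_secondary_blocks = as.integer(n_secondary_blocks),
                 secondary_checks_per_block = as.integer(secondary_checks_per_block),
                 split_factor = split_factor),
            class = "design_spec")
}

#' @rdname design_spec
#' @param spec a `design_spec`.
#' @export
n_test_plots <- function(spec) {
  spec$n_blocks * spec$plots_per_block_rows * spec$plots_per_block_cols -
    spec$n_blocks - spec$n_secondary_blocks * spec$secondary_checks_per_block
}

# Arrange n blocks on a near-square grid; with a split factor the two field
# halves occupy the left and right column ranges so each half is contiguous.
block_grid <- function(n_blocks, split = FALSE) {
  n_rows <- max(1L, floor(sqrt(n_blocks)))
  while (n_blocks %% n_rows != 0L) n_rows <- n_rows - 1L
  n_cols <- n_blocks %/% n_rows
  if (split && n_cols %% 2L != 0L) {
    # need an even number of block columns to halve the field cleanly
    n_cols <- n_cols * n_rows
    n_rows <- 1L
  }
  list(n_rows = n_rows, n_cols = n_cols)
}

default_check_ids <- function(half) {
  if (half == 1L) {
    list(primary = "CHECK1_A", secondary = c("CHECK2_A1", "CHECK2_A2"))
  } else {
    list(primary = "CHECK1_B", secondary = c("CHECK2_B1", "CHECK2_B2"))
  }
}

#' Generate the plot layout of an augmented trial
#'
#' Lays blocks out on a near-square grid, places one primary check at the
#' central plot of every block, places secondary checks on random plots of
#' randomly chosen blocks (within each field half when the design is split),
#' and assigns every test entry to exactly one remaining plot, in seeded
#' random order.
#'
#' @param spec a [design_spec()].
#' @param entry_ids character vector of test-entry ids; length must equal
#'   [n_test_plots()] of the spec.  For a split design the first half of the
#'   vector goes to field half 1, the second half to field half 2.
#' @param year year label stamped on every plot.
#' @param seed integer seed; identical `(spec, entry_ids, seed)` give
#'   bit-identical layouts.
#' @return a [trait_table()] skeleton with zero trait columns.
#' @export
generate_design <- function(spec, entry_ids, year = 2014L, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"))
  need <- n_test_plots(spec)
  if (length(entry_ids) != need) {
    stop(sprintf("design requires exactly %d test entries, got %d",
                 need, length(entry_ids)))
  }
  split <- !is.null(spec$split_factor)
  grid <- block_grid(spec$n_blocks, split)
  rng <- local_rng(seed)
  n_pr <- spec$plots_per_block_rows; n_pc <- spec$plots_per_block_cols
  ctr_r <- (n_pr + 1L) %/% 2L; ctr_c <- (n_pc + 1L) %/% 2L
  blocks <- data.frame(
    block_id = seq_len(spec$n_blocks),
    block_row = rep(seq_len(grid$n_rows), times = grid$n_cols),
    block_col = rep(seq_len(grid$n_cols), each = grid$n_rows))
  blocks$half <- if (split) ifelse(blocks$block_col <= grid$n_cols %/% 2L,
                                   1L, 2L) else 1L
  halves <- sort(unique(blocks$half))
  entry_split <- if (split) {
    split(entry_ids, rep(1:2, each = need %/% 2L))
  } else list(`1` = entry_ids)

  rows <- vector("list", length(halves))
  for (h in halves) {
    bl <- blocks[blocks$half == h, , drop = FALSE]
    checks <- default_check_ids(h)
    n_sec_blocks <- if (split) spec$n_secondary_blocks %/% 2L else
      spec$n_secondary_blocks
    sec_blocks <- sort(rng$sample_int(nrow(bl), n_sec_blocks))
    plot_list <- vector("list", nrow(bl))
    for (b in seq_len(nrow(bl))) {
      pr <- expand.grid(plot_row = seq_len(n_pr), plot_col = seq_len(n_pc))
      pr$block_id <- bl$block_id[b]
      pr$block_row <- bl$block_row[b]
      pr$block_col <- bl$block_col[b]
      pr$entry_id <- NA_character_
      pr$check_class <- "test"
      central <- pr$plot_row == ctr_r & pr$plot_col == ctr_c
      pr$entry_id[central] <- checks$primary
      pr$check_class[central] <- "primary"
      if (b %in% sec_blocks) {
        open <- which(!central)
        pick <- open[rng$sample_int(length(open),
                                    spec$secondary_checks_per_block)]
        sec_ids <- rep_len(checks$secondary, length(pick))
        pr$entry_id[pick] <- sec_ids
        pr$check_class[pick] <- "secondary"
      }
      plot_list[[b]] <- pr
    }
    half_df <- do.call(rbind, plot_list)
    open <- which(is.na(half_df$entry_id))
    ids <- entry_split[[as.character(h)]]
    half_df$entry_id[open] <- ids[rng$sample_int(length(ids), length(ids))]
    rows[[h]] <- half_df
  }
  df <- do.call(rbind, rows)
  df$year <- as.integer(year)
  df <- df[, design_columns(), drop = FALSE]
  rownames(df) <- NULL
  trait_table(df, character(0))
}

# Seeded RNG scoped to the generator: callers' .Random.seed is untouched.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  with_state <- function(f) {
    function(...) {
      outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(outer)) rm(".Random.seed", envir = globalenv()) else
          assign(".Random.seed", outer, globalenv())
      })
      f(...)
    }
  }
  list(
    sample_int = with_state(function(n, k) sample.int(n, k)),
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    rbinom = with_state(stats::rbinom))
}
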