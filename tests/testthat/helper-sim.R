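# shared fixture builders (all fixtures are generated in code)

# minimal augmented layout: blocks on a g_rows x g_cols grid, one primary
# check per block at the central plot, secondary checks in the first
# `sec_blocks` blocks; trait values supplied by `value_fun(block_row,
# block_col, plot_row, plot_col, check_class)`
build_trial <- function(g_rows = 3, g_cols = 3, sec_blocks = 4,
                        value_fun = function(br, bc, pr, pc, cls) 10,
                        year = 2014, trait = "y") {
  rows <- list()
  bid <- 0L
  test_i <- 0L
  for (bc in seq_len(g_cols)) for (br in seq_len(g_rows)) {
    bid <- bid + 1L
    for (pr in 1:5) for (pc in 1:3) {
      cls <- if (pr == 3 && pc == 2) "primary" else "test"
      if (cls == "test" && bid <= sec_blocks && pr == 1 && pc <= 2) {
        cls <- "secondary"
      }
      eid <- switch(cls, primary = "CK1",
                    secondary = paste0("CK2_", pc),
                    test = sprintf("T%03d", test_i <- test_i + 1L))
      rows[[length(rows) + 1L]] <- data.frame(
        year = year, block_id = bid, block_row = br, block_col = bc,
        plot_row = pr, plot_col = pc, entry_id = eid, check_class = cls,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df[[trait]] <- mapply(value_fun, df$block_row, df$block_col,
                        df$plot_row, df$plot_col, df$check_class)
  trait_table(df, trait)
}

# small genotype fixture with named lines/markers
toy_genotypes <- function(calls, chrom = NULL, pos_cM = NULL) {
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("L%02d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("M%02d", seq_len(ncol(calls)))
  }
  g <- genotype_matrix(calls)
  if (is.null(chrom)) chrom <- rep("1H", ncol(calls))
  if (is.null(pos_cM)) pos_cM <- seq_len(ncol(calls))
  list(genotypes = g,
       map = marker_map(colnames(calls), chrom, pos_cM = pos_cM,
                        pos_bp = as.integer(pos_cM * 1e6)))
}

# balanced two-way ANOVA mean squares by direct sums (independent of aov)
hand_two_way_ms <- function(y, line, env) {
  lines <- unique(line); envs <- unique(env)
  L <- length(lines); E <- length(envs)
  grand <- mean(y)
  lm_ <- tapply(y, line, mean)[as.character(lines)]
  em_ <- tapply(y, env, mean)[as.character(envs)]
  ss_line <- E * sum((lm_ - grand)^2)
  ss_env <- L * sum((em_ - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_res <- ss_tot - ss_line - ss_env
  list(line_ms = ss_line / (L - 1), resid_ms = ss_res / ((L - 1) * (E - 1)),
       env_ms = ss_env / (E - 1))
}
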