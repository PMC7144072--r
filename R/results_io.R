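#' Write a set of result tables with a run manifest
#'
#' Writes one CSV per named table into `out_dir` plus a `manifest.json`
#' recording the file list, a hash of the configuration, and the seed, so a
#' run's outputs are self-describing.  Writing the same inputs twice yields
#' byte-identical CSVs.
#'
#' @param tables named list of data.frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param config optional list of run settings folded into the manifest hash.
#' @param seed optional integer seed recorded in the manifest.
#' @return data.frame manifest (name, file) of the data files written.
#' @export
write_results <- function(tables, out_dir, config = list(), seed = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) > 0L && is.null(names(tables))) {
    stop("tables must be named")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(length(tables))
  for (i in seq_along(tables)) {
    files[i] <- file.path(out_dir, paste0(names(tables)[i], ".csv"))
    utils::write.csv(as.data.frame(tables[[i]]), files[i],
                     row.names = FALSE, na = "NA", quote = FALSE)
  }
  cfg_txt <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  tmp <- tempfile(); writeLines(cfg_txt, tmp)
  cfg_hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  manifest <- list(
    files = as.list(stats::setNames(basename(files), names(tables))),
    config_hash = cfg_hash,
    seed = if (is.null(seed)) NA else as.integer(seed))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  data.frame(name = if (length(tables)) names(tables) else character(0),
             file = files, stringsAsFactors = FALSE)
}
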