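#' Genotype matrices and marker maps
#'
#' Genotypes are held as an integer matrix, lines x markers, with dimnames
#' `(line_ids, marker_ids)` and entries in \{0, 1, 2, NA\} counting copies of
#' the *minor* allele (the panel is inbred, so 1 = heterozygous call is rare
#' and is counted against heterozygosity filters).  The marker map is a
#' `data.frame` with columns `marker_id`, `chromosome`, `pos_cM`, `pos_bp`,
#' one row per marker of the matrix, in matrix column order.
#'
#' @param calls integer matrix (lines x markers), entries 0/1/2/NA.
#' @return a validated genotype matrix (class `"genotype_matrix"`).
#' @export
genotype_matrix <- function(calls) {
  stopifnot(is.matrix(calls))
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("genotype matrix needs line (row) and marker (column) names")
  }
  vals <- calls[!is.na(calls)]
  if (length(vals) > 0L && !all(vals %in% c(0, 1, 2))) {
    stop("genotype codes must be 0, 1, 2 or NA (minor-allele dosage)")
  }
  storage.mode(calls) <- "integer"
  structure(calls, class = c("genotype_matrix", class(calls)))
}

#' @rdname genotype_matrix
#' @param marker_id,chromosome,pos_cM,pos_bp map columns (recycled lengths
#'   must match).
#' @export
marker_map <- function(marker_id, chromosome, pos_cM = NA_real_,
                       pos_bp = NA_integer_) {
  map <- data.frame(marker_id = as.character(marker_id),
                    chromosome = as.character(chromosome),
                    pos_cM = as.numeric(pos_cM),
                    pos_bp = as.integer(pos_bp),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$marker_id)) stop("duplicated marker_id in map")
  if (any(!is.na(map$pos_cM) & map$pos_cM < 0)) stop("negative cM position")
  if (any(!is.na(map$pos_bp) & map$pos_bp < 0)) stop("negative bp position")
  map
}

check_map_covers <- function(genotypes, map) {
  missing <- setdiff(colnames(genotypes), map$marker_id)
  if (length(missing) > 0L) {
    stop("markers missing from map: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) sprintf(" (+%d more)", length(missing) - 5L))
  }
  map[match(colnames(genotypes), map$marker_id), , drop = FALSE]
}

# Recode an ALT-dosage matrix so 2 always counts the minor allele.
# Ties (freq exactly 0.5) keep the incoming orientation; r2-based analyses
# are invariant to the flip either way.
recode_minor <- function(calls) {
  freq <- colMeans(calls, na.rm = TRUE) / 2
  flip <- !is.na(freq) & freq > 0.5
  calls[, flip] <- 2L - calls[, flip]
  calls
}

#' Read genotypes from VCF or HapMap-style tab-delimited files
#'
#' Biallelic sites only: multi-allelic sites are skipped with a warning and
#' counted in the returned metadata.  Calls are recoded to minor-allele
#' dosage.  Genetic-map (cM) positions are not carried by either format, so
#' they come from an optional side-car CSV (`marker_id, chromosome, pos_cM,
#' pos_bp`); physical positions default to the file's own coordinates.
#'
#' @param path genotype file.
#' @param format `"vcf"` or `"hapmap_tsv"`.  The HapMap dialect is the
#'   TASSEL-style table: columns `rs#, alleles, chrom, pos, strand, ...`
#'   (11 metadata columns) then one column per line with diploid calls such
#'   as `AA`, `AG`, `NN`.
#' @param map_path optional side-car CSV with cM positions.
#' @return list with `genotypes` ([genotype_matrix()]), `map`
#'   ([marker_map()]), and `n_skipped_multiallelic`.
#' @export
read_genotypes <- function(path, format = c("vcf", "hapmap_tsv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  parsed <- switch(format,
                   vcf = read_genotypes_vcf(path),
                   hapmap_tsv = read_genotypes_hapmap(path))
  calls <- recode_minor(parsed$calls)
  map <- marker_map(parsed$marker_id, parsed$chromosome,
                    pos_cM = NA_real_, pos_bp = parsed$pos_bp)
  if (!is.null(map_path)) {
    side <- utils::read.csv(map_path, stringsAsFactors = FALSE)
    need <- c("marker_id", "pos_cM")
    if (!all(need %in% names(side))) {
      stop("side-car map must have columns marker_id and pos_cM")
    }
    idx <- match(map$marker_id, side$marker_id)
    if (anyNA(idx)) {
      stop("side-car map is missing entries for ",
           sum(is.na(idx)), " marker(s)")
    }
    map$pos_cM <- as.numeric(side$pos_cM[idx])
    if ("chromosome" %in% names(side)) {
      map$chromosome <- as.character(side$chromosome[idx])
    }
    if ("pos_bp" %in% names(side)) map$pos_bp <- as.integer(side$pos_bp[idx])
  }
  if (parsed$n_skipped > 0L) {
    warning(sprintf("skipped %d multi-allelic site(s)", parsed$n_skipped),
            call. = FALSE)
  }
  list(genotypes = genotype_matrix(calls), map = map,
       n_skipped_multiallelic = parsed$n_skipped)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(vcf)),
                dimnames = dimnames(vcfR::getFIX(vcf)))
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!biallelic)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  # ALT-allele dosage from the GT strings; any phasing separator accepted
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                 dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dose[clean %in% c("0/0", "0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1", "1")] <- 2L
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], "_",
    fix[is.na(ids) | ids == ".", "POS"])
  calls <- t(dose)
  colnames(calls) <- ids
  list(calls = calls, marker_id = ids,
       chromosome = as.character(fix[, "CHROM"]),
       pos_bp = as.integer(fix[, "POS"]), n_skipped = n_skipped)
}

read_genotypes_hapmap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  if (ncol(df) < 12L) stop("HapMap table needs 11 metadata columns + samples")
  meta <- df[, 1:11, drop = FALSE]
  samples <- df[, -(1:11), drop = FALSE]
  alleles <- strsplit(as.character(meta[[2]]), "/", fixed = TRUE)
  biallelic <- lengths(alleles) == 2L
  n_skipped <- sum(!biallelic)
  meta <- meta[biallelic, , drop = FALSE]
  samples <- samples[biallelic, , drop = FALSE]
  alleles <- alleles[biallelic]
  n_mark <- nrow(meta); n_line <- ncol(samples)
  calls <- matrix(NA_integer_, nrow = n_line, ncol = n_mark,
                  dimnames = list(colnames(samples), as.character(meta[[1]])))
  for (j in seq_len(n_mark)) {
    a <- alleles[[j]][1]; b <- alleles[[j]][2]
    g <- as.character(samples[j, ])
    dose <- rep(NA_integer_, n_line)
    dose[g == paste0(a, a)] <- 0L
    dose[g %in% c(paste0(a, b), paste0(b, a))] <- 1L
    dose[g == paste0(b, b)] <- 2L
    calls[, j] <- dose
  }
  list(calls = calls, marker_id = as.character(meta[[1]]),
       chromosome = as.character(meta[[3]]),
       pos_bp = as.integer(meta[[4]]), n_skipped = n_skipped)
}

#' Write genotypes as an uncompressed VCF (plus optional map CSV)
#'
#' Minor-allele dosage is written as ALT dosage with synthetic REF/ALT
#' alleles A/B, which round-trips through [read_genotypes()] exactly.
#'
#' @param genotypes a [genotype_matrix()].
#' @param map a [marker_map()] covering the matrix.
#' @param path output `.vcf` path.
#' @param map_path optional CSV path for the map (written when non-NULL).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, map, path, map_path = NULL) {
  map <- check_map_covers(genotypes, map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(genotypes)),
                   collapse = "\t"), con)
  gt_str <- matrix("./.", nrow = ncol(genotypes), ncol = nrow(genotypes))
  g <- t(unclass(genotypes))
  gt_str[!is.na(g) & g == 0L] <- "0/0"
  gt_str[!is.na(g) & g == 1L] <- "0/1"
  gt_str[!is.na(g) & g == 2L] <- "1/1"
  pos <- map$pos_bp
  if (anyNA(pos)) pos[is.na(pos)] <- seq_len(sum(is.na(pos)))
  lines <- paste(map$chromosome, pos, map$marker_id, "A", "B", ".", ".",
                 ".", "GT",
                 apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  if (!is.null(map_path)) {
    utils::write.csv(map, map_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
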