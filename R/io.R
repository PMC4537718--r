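# Readers and writers for the tab-delimited bin-count, truth and result
# tables, BED6 export of DMR calls, and JSON (de)serialisation of the
# simulation configuration. Coordinates, when present, follow the BED
# convention (0-based, half-open).

COUNT_COLS <- c("x0", "y0", "x1", "y1")
OPT_COORD_COLS <- c("chrom", "start", "end", "strand")

#' Read and validate a bin-count table
#'
#' Expects a tab-delimited file with header columns `site_id`,
#' `bin_index`, `x0`, `y0`, `x1`, `y1`; optional `chrom`, `start`, `end`,
#' `strand` columns are carried through (`.` allowed). Within each site,
#' `bin_index` must be consecutive starting at 0; counts must be
#' non-negative integers (floats with a zero fraction are coerced).
#'
#' @param path Path to the TSV file.
#' @return A validated bin-count data frame.
#' @export
read_bin_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("site_id", "bin_index", COUNT_COLS)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("bin-count table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in c("bin_index", COUNT_COLS)) {
    v <- df[[nm]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("column '", nm, "' has a non-numeric value at row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    if (any(abs(v - round(v)) > 1e-6)) {
      bad <- which(abs(v - round(v)) > 1e-6)[1]
      stop("column '", nm, "' has a non-integer value at row ", bad,
           call. = FALSE)
    }
    df[[nm]] <- as.integer(round(v))
    if (nm != "bin_index" && any(df[[nm]] < 0)) {
      bad <- which(df[[nm]] < 0)[1]
      stop("negative count in column '", nm, "' at row ", bad,
           call. = FALSE)
    }
  }
  offset <- 0L
  for (s in split_by_site(df)) {
    L <- nrow(s)
    expected <- seq_len(L) - 1L
    if (!identical(s$bin_index, expected)) {
      bad <- which(s$bin_index != expected)[1]
      stop("site '", s$site_id[1], "' has non-consecutive bin_index at ",
           "position ", bad, " (row ", offset + bad, "): expected ",
           expected[bad], ", found ", s$bin_index[bad], call. = FALSE)
    }
    offset <- offset + L
  }
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write a bin-count table
#' @param counts A bin-count data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bin_table <- function(counts, path) {
  cols <- c("site_id", "bin_index",
            intersect(OPT_COORD_COLS, names(counts)), COUNT_COLS)
  write_tsv(counts[, cols], path)
}

#' Write per-bin strategy results
#' @param bins The `$bins` data frame from a strategy runner.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_results <- function(bins, path) {
  write_tsv(bins, path)
}

#' Write a ground-truth table
#' @param truth The `$truth` data frame from the simulator.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  write_tsv(truth, path)
}

#' Write DMR calls as BED6
#'
#' One line per DMR: `chrom`, `start`, `end`,
#' `name = site_id.dmr_<k>`, `score = round(1000 * mean posterior)`
#' clipped to \[0, 1000\], `strand` (`.` when absent). DMRs without
#' genomic coordinates cannot be exported.
#'
#' @param dmrs DMR data frame from [call_dmrs()] with coordinate columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  if (!all(c("chrom", "start", "end") %in% names(dmrs))) {
    stop("DMR calls carry no genomic coordinates; cannot write BED",
         call. = FALSE)
  }
  strand <- if ("strand" %in% names(dmrs)) as.character(dmrs$strand) else "."
  strand[is.na(strand) | strand == ""] <- "."
  bed <- data.frame(
    chrom = dmrs$chrom,
    start = dmrs$start,
    end = dmrs$end,
    name = sprintf("%s.dmr_%d", dmrs$site_id, dmrs$dmr_id),
    score = pmin(1000L, pmax(0L, as.integer(round(1000 * dmrs$mean_posterior)))),
    strand = strand,
    stringsAsFactors = FALSE)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Serialise a simulation configuration to JSON
#' @param cfg A [sim_config()].
#' @param path Optional output path; omitted returns the JSON string.
#' @return The JSON string (invisibly when written to a file).
#' @export
sim_config_to_json <- function(cfg, path = NULL) {
  x <- unclass(cfg)
  x$lib_sizes <- as.list(unclass(x$lib_sizes))
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a simulation configuration from JSON
#' @param path Path to a JSON file produced by [sim_config_to_json()]
#'   (fields may be omitted to keep defaults).
#' @return A [sim_config()].
#' @export
sim_config_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  args <- list()
  if (!is.null(x$site_lengths)) args$site_lengths <- x$site_lengths
  if (!is.null(x$lib_sizes)) {
    ls <- x$lib_sizes
    args$lib_sizes <- lib_sizes(ls$n0, ls$n1, ls$m0, ls$m1)
  }
  for (nm in c("lambda0", "de_log2fc_range", "dm_log2or_range",
               "pi_sim", "ip_scale")) {
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  }
  if (!is.null(x$A_sim)) args$A_sim <- matrix(unlist(x$A_sim), 2, 2)
  do.call(sim_config, args)
}
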