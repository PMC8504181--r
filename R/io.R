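#' @name cli_io
#' @title Validated table I/O
#'
#' @description
#' TSV is the canonical on-disk format (CSV accepted via `sep`), UTF-8,
#' `NA` for missing values, gzip-transparent reading. [read_table()]
#' validates a header against a declared schema and reports the offending
#' row and column on type errors; write followed by read is the identity on
#' the typed columns.
NULL

#' Read and validate a delimited table
#'
#' @param path input file (plain or gzip-compressed).
#' @param schema named character vector mapping required column names to
#'   types (`"character"`, `"integer"`, `"double"`, `"logical"`); `NULL`
#'   skips validation.
#' @param sep field separator (tab by default).
#' @param key optional column that must contain unique values.
#' @return data.frame with typed columns.
#' @export
read_table <- function(path, schema = NULL, sep = "\t", key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  if (anyDuplicated(names(df))) {
    stop("duplicate column(s) in ", path, ": ",
         paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
  }
  if (!is.null(schema)) {
    miss <- setdiff(names(schema), names(df))
    if (length(miss)) {
      stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
    }
    for (col in names(schema)) {
      df[[col]] <- coerce_column(df[[col]], schema[[col]], col, path)
    }
  }
  if (!is.null(key)) {
    dup <- df[[key]][duplicated(df[[key]])]
    if (length(dup)) {
      stop("duplicate ", key, " in ", path, ": ",
           paste(utils::head(unique(dup), 5L), collapse = ", "))
    }
  }
  df
}

coerce_column <- function(x, type, col, path) {
  was_na <- is.na(x)
  out <- switch(type,
    character = as.character(x),
    integer = suppressWarnings(as.integer(x)),
    double = suppressWarnings(as.numeric(x)),
    logical = parse_logical(x),
    stop("unknown schema type: ", type))
  bad <- which(is.na(out) & !was_na)
  if (length(bad)) {
    stop("column '", col, "' in ", path, ": cannot parse value '",
         x[bad[1L]], "' as ", type, " (row ", bad[1L], ")")
  }
  out
}

parse_logical <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("true", "t", "yes", "1")] <- TRUE
  out[lx %in% c("false", "f", "no", "0")] <- FALSE
  out
}

#' Write a table as TSV
#'
#' UTF-8, tab-separated, no quoting, `NA` for missing values, no row names.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene x sample count matrix
#'
#' First column must be `gene_id` (unique); remaining columns are samples
#' with nonnegative integer counts.
#'
#' @param path counts TSV.
#' @return integer matrix with gene ids as row names.
#' @export
read_counts_matrix <- function(path) {
  df <- read_table(path, key = "gene_id")
  if (names(df)[1L] != "gene_id") stop("first column must be gene_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  if (anyNA(m)) stop("missing count value in ", path)
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' Read a sample design sheet
#'
#' @param path TSV with columns `sample_id`, `genotype`, `treatment`,
#'   `chx`, `batch`.
#' @return validated data.frame.
#' @export
read_sample_design <- function(path) {
  df <- read_table(path, schema = c(sample_id = "character",
                                    genotype = "character",
                                    treatment = "character",
                                    chx = "logical",
                                    batch = "integer"),
                   key = "sample_id")
  validate_sample_design(df)
  df
}

#' Read a PSM table and its channel map into a reporter table
#'
#' @param psm_path tall TSV with columns `protein_id`, `peptide_id`,
#'   `psm_id`, `run_id`, `channel_id`, `intensity`.
#' @param channel_map_path TSV with columns `run_id`, `channel_id`,
#'   `condition`, `replicate`.
#' @return validated reporter table (see [validate_reporter_table()]).
#' @export
read_psm_table <- function(psm_path, channel_map_path) {
  psm <- read_table(psm_path, schema = c(protein_id = "character",
                                         peptide_id = "character",
                                         psm_id = "character",
                                         run_id = "character",
                                         channel_id = "character",
                                         intensity = "double"))
  map <- read_table(channel_map_path, schema = c(run_id = "character",
                                                 channel_id = "character",
                                                 condition = "character",
                                                 replicate = "integer"))
  rt <- merge(psm, map, by = c("run_id", "channel_id"), all.x = TRUE)
  if (anyNA(rt$condition)) {
    bad <- unique(paste(rt$run_id, rt$channel_id)[is.na(rt$condition)])
    stop("channel(s) missing from the channel map: ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  rt <- rt[, c("protein_id", "peptide_id", "psm_id", "run_id", "channel_id",
               "condition", "replicate", "intensity")]
  validate_reporter_table(rt)
  rt
}

#' Read a two-column annotation map
#'
#' @param path TSV whose first two columns are feature id and term id;
#'   repeated rows allowed.
#' @return data.frame with columns `id` and `term`.
#' @export
read_annotation <- function(path) {
  df <- read_table(path)
  if (ncol(df) < 2L) stop("annotation map needs two columns (id, term)")
  out <- df[, 1:2]
  names(out) <- c("id", "term")
  out
}
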