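# Typed containers and file I/O for the pipeline's data.
#
# Conventions, fixed across the package:
#   * beta matrices are samples x CpGs (cohorts are small, probe sets large);
#   * genomic coordinates are 0-based half-open (BED);
#   * missing betas are explicit NA, never 0 (0 is a valid beta);
#   * readers reject invalid values with typed errors rather than coercing.

#' Construct a beta-value matrix
#'
#' A `beta_matrix` is a numeric matrix of methylation fractions with samples
#' as rows and CpG probes as columns. Values must lie in \[0, 1\] or be `NA`.
#'
#' @param values Numeric matrix (samples x CpGs).
#' @param sample_ids,cpg_ids Unique identifiers; default to dimnames.
#' @return A numeric matrix of class `beta_matrix` with dimnames set.
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        cpg_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids) || is.null(cpg_ids)) {
    mc_abort("beta matrix requires sample and CpG identifiers",
             "methclock_format_error")
  }
  sample_ids <- as.character(sample_ids)
  cpg_ids <- as.character(cpg_ids)
  if (length(sample_ids) != nrow(values) || length(cpg_ids) != ncol(values)) {
    mc_abort("id lengths do not match matrix dimensions",
             "methclock_format_error")
  }
  if (anyDuplicated(sample_ids)) {
    mc_abort("duplicate sample ids in beta matrix", "methclock_format_error")
  }
  if (anyDuplicated(cpg_ids)) {
    mc_abort("duplicate CpG ids in beta matrix", "methclock_format_error")
  }
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(values))
    mc_abort(sprintf(
      "beta values must lie in [0,1]: value %g at sample '%s', CpG '%s'",
      values[bad[1]], sample_ids[i[1]], cpg_ids[i[2]]),
      "methclock_validation_error")
  }
  dimnames(values) <- list(sample_ids, cpg_ids)
  class(values) <- c("beta_matrix", class(values))
  values
}

#' Read a beta-value matrix from TSV
#'
#' Expects a header row of CpG ids and a first column of sample ids. Empty
#' cells and `NA` become missing values. With `transpose = TRUE` the file is
#' read as CpGs x samples and transposed on load.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @param transpose Logical; is the file CpGs x samples?
#' @return A [beta_matrix].
#' @export
read_beta_matrix <- function(path, sep = "\t", transpose = FALSE) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          na.strings = NULL, quote = "\"")
  if (ncol(df) < 2) {
    mc_abort("beta matrix file needs an id column plus >=1 value column",
             "methclock_format_error")
  }
  row_ids <- df[[1]]
  col_ids <- colnames(df)[-1]
  vals <- matrix(NA_real_, nrow = nrow(df), ncol = length(col_ids),
                 dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    raw <- df[[j + 1]]
    missing <- raw == "" | raw == "NA"
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(num) & !missing)
    if (length(bad)) {
      mc_abort(sprintf(
        "non-numeric beta value '%s' at row '%s', column '%s'",
        raw[bad[1]], row_ids[bad[1]], col_ids[j]),
        "methclock_parse_error")
    }
    num[missing] <- NA_real_
    vals[, j] <- num
  }
  if (transpose) vals <- t(vals)
  beta_matrix(vals)
}

#' Write a beta-value matrix to TSV
#'
#' @param betas A [beta_matrix].
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(betas, path, sep = "\t") {
  vals <- unclass(betas)
  cols <- lapply(seq_len(ncol(vals)), function(j) {
    v <- vals[, j]
    ifelse(is.na(v), "", sprintf("%.17g", v))
  })
  df <- data.frame(sample_id = rownames(vals), cols,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(vals))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

sample_table_required <- c("sample_id", "donor_age", "recipient_age", "pgd",
                           "batch", "entry_time", "event_time", "event")
sample_table_optional <- c("donor_sex", "recipient_sex", "donor_bmi",
                           "recipient_bmi", "donor_white", "recipient_white",
                           "cmv_group", "indication")

#' Construct a sample metadata table
#'
#' Validates and types per-sample cohort metadata: donor ("graft") and
#' recipient ages in years, severe primary graft dysfunction status,
#' processing batch, and the left-truncated survival triple
#' (`entry_time`, `event_time`, `event`; days post-transplant). Unknown
#' columns are preserved as extra covariates.
#'
#' @param df A data.frame with at least the required columns
#'   (`sample_id`, `donor_age`, `recipient_age`, `pgd`, `batch`,
#'   `entry_time`, `event_time`, `event`).
#' @return A data.frame of class `sample_table`.
#' @export
sample_table <- function(df) {
  missing_cols <- setdiff(sample_table_required, names(df))
  if (length(missing_cols)) {
    mc_abort(sprintf("sample table missing required column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "methclock_schema_error")
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    mc_abort("duplicate sample_id in sample table", "methclock_format_error")
  }
  for (col in c("donor_age", "recipient_age", "entry_time", "event_time")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$pgd <- parse_logical(df$pgd, "pgd")
  df$event <- parse_logical(df$event, "event")
  df$batch <- as.character(df$batch)
  if (any(df$donor_age <= 0 | df$recipient_age <= 0, na.rm = TRUE)) {
    mc_abort("ages must be positive", "methclock_validation_error")
  }
  if (any(df$entry_time <= 0, na.rm = TRUE)) {
    mc_abort("entry_time must be positive", "methclock_validation_error")
  }
  bad <- which(df$event_time < df$entry_time)
  if (length(bad)) {
    mc_abort(sprintf(
      "event_time precedes entry_time for sample '%s' (%g < %g)",
      df$sample_id[bad[1]], df$event_time[bad[1]], df$entry_time[bad[1]]),
      "methclock_validation_error")
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

parse_logical <- function(x, what) {
  if (is.logical(x)) return(x)
  x <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  if (any(is.na(out) & !(x %in% c("", "na")))) {
    mc_abort(sprintf("column '%s' is not interpretable as logical", what),
             "methclock_parse_error")
  }
  out
}

#' Read a sample sheet CSV
#'
#' @param path CSV path with the documented column dictionary; extra columns
#'   are carried through as covariates.
#' @return A [sample_table].
#' @export
read_sample_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sample_table(df)
}

#' Write a sample sheet CSV
#'
#' @param table A [sample_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Genes are de-duplicated within a set, order preserved.
#'
#' @param path GMT path.
#' @return Named list of character vectors, class `gene_set_collection`.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    mc_abort(sprintf("GMT line %d has fewer than 3 fields", short[1]),
             "methclock_format_error")
  }
  names_ <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(names_)) {
    mc_abort("duplicate gene-set names in GMT", "methclock_format_error")
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- names_
  gene_set_collection(sets)
}

#' Construct a gene-set collection
#'
#' @param sets Named list of character gene vectors.
#' @return Named list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)) ||
      any(!nzchar(names(sets)))) {
    mc_abort("gene sets require unique non-empty names",
             "methclock_format_error")
  }
  if (any(lengths(sets) == 0L)) {
    mc_abort("gene sets must be non-empty", "methclock_validation_error")
  }
  sets <- lapply(sets, function(g) unique(as.character(g)))
  class(sets) <- c("gene_set_collection", "list")
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set_collection].
#' @param path Output path.
#' @param description Per-set description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a CpG-to-promoter map
#'
#' Each entry links a CpG probe to a gene promoter interval. Coordinates are
#' 0-based half-open (BED convention); a CpG may map to zero or several
#' promoters.
#'
#' @param df Data.frame with columns `cpg_id`, `gene`, `chrom`, `start`,
#'   `end`, `strand`.
#' @return A data.frame of class `promoter_map`.
#' @export
promoter_map <- function(df) {
  need <- c("cpg_id", "gene", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    mc_abort(sprintf("promoter map missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             "methclock_schema_error")
  }
  df <- as.data.frame(df[need], stringsAsFactors = FALSE)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad)) {
    mc_abort(sprintf(
      "invalid promoter interval [%d, %d) for CpG '%s' (need 0 <= start < end)",
      df$start[bad[1]], df$end[bad[1]], df$cpg_id[bad[1]]),
      "methclock_coordinate_error")
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    mc_abort("strand must be '+', '-' or '.'", "methclock_format_error")
  }
  class(df) <- c("promoter_map", "data.frame")
  df
}

#' Read a BED-like promoter map
#'
#' Columns: chrom, start, end, name (gene symbol), score (CpG id), strand.
#' The score column carries the CpG probe id, a non-numeric dialect used by
#' this pipeline.
#'
#' @param path File path (tab-separated, no header).
#' @return A [promoter_map].
#' @export
read_promoter_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "gene",
                                        "cpg_id", "strand"))
  promoter_map(df)
}

#' Write a promoter map as BED6
#'
#' @param map A [promoter_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoter_map <- function(map, path) {
  bed <- data.frame(map$chrom, map$start, map$end, map$gene, map$cpg_id,
                    map$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct an epigenetic clock model
#'
#' A sparse linear predictor on the calibrated age-transform scale:
#' transformed age = `intercept` + sum over model CpGs of `weights * beta`.
#' `training_means` stores per-CpG mean betas from training for imputation of
#' probes absent at prediction time.
#'
#' @param cpg_ids Character CpG ids carrying nonzero weight.
#' @param weights Numeric weights, one per CpG.
#' @param intercept Intercept on the transformed-age scale.
#' @param adult_age Calibration constant of the age transform (years).
#' @param training_means Optional per-CpG training mean betas (named or in
#'   `cpg_ids` order).
#' @param training_meta Free-form provenance list.
#' @return A list of class `clock_model`.
#' @export
clock_model <- function(cpg_ids, weights, intercept, adult_age = 20,
                        training_means = NULL, training_meta = list()) {
  cpg_ids <- as.character(cpg_ids)
  weights <- as.numeric(weights)
  if (length(cpg_ids) != length(weights)) {
    mc_abort("clock model: weights and cpg_ids lengths differ",
             "methclock_schema_error")
  }
  if (anyDuplicated(cpg_ids)) {
    mc_abort("clock model: duplicate CpG ids", "methclock_schema_error")
  }
  if (!is_scalar_number(adult_age) || adult_age <= 0) {
    mc_abort("clock model: adult_age must be a positive number",
             "methclock_schema_error")
  }
  if (!is_scalar_number(intercept)) {
    mc_abort("clock model: intercept must be a finite number",
             "methclock_schema_error")
  }
  if (!is.null(training_means)) {
    training_means <- as.numeric(training_means)
    if (length(training_means) != length(cpg_ids)) {
      mc_abort("clock model: training_means length mismatch",
               "methclock_schema_error")
    }
    names(training_means) <- cpg_ids
  }
  structure(list(cpg_ids = cpg_ids, weights = stats::setNames(weights, cpg_ids),
                 intercept = intercept, adult_age = adult_age,
                 training_means = training_means,
                 training_meta = training_meta),
            class = "clock_model")
}

#' Serialize a clock model to JSON
#'
#' @param model A [clock_model].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_clock <- function(model, path) {
  payload <- list(cpg_ids = model$cpg_ids,
                  weights = unname(model$weights),
                  intercept = model$intercept,
                  adult_age = model$adult_age,
                  training_meta = model$training_meta)
  if (!is.null(model$training_means)) {
    payload$cpg_means <- unname(model$training_means)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a clock model from JSON
#'
#' @param path JSON path written by [serialize_clock] (or an externally
#'   supplied model with keys `cpg_ids`, `weights`, `intercept`, `adult_age`).
#' @return A [clock_model].
#' @export
load_clock <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("cpg_ids", "weights", "intercept", "adult_age")
  missing_keys <- setdiff(need, names(obj))
  if (length(missing_keys)) {
    mc_abort(sprintf("clock JSON missing key(s): %s",
                     paste(missing_keys, collapse = ", ")),
             "methclock_schema_error")
  }
  clock_model(obj$cpg_ids, obj$weights, obj$intercept, obj$adult_age,
              training_means = obj$cpg_means,
              training_meta = as.list(obj$training_meta %||% list()))
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> %d CpGs, intercept %.4f, adult_age %g\n",
              length(x$cpg_ids), x$intercept, x$adult_age))
  invisible(x)
}
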