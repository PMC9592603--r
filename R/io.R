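#' Read a nanoparticle property table
#'
#' Reads a CSV/TSV of per-nanoparticle descriptors and validates it.
#' Required columns: `np_id`, `coating`, `diameter_nm`, `size_type`
#' (`hydrodynamic` or `tem`), `gamma_lw`, `gamma_plus`, `gamma_minus`,
#' `psi0_mv`, `cell_line`.  Optional: `smiles`, `log_kow`, `k_exo_per_s`.
#'
#' Validation flags (attached as `warnings` and emitted as R warnings):
#' surface-energy components outside the plausible 0–100 mJ/m^2 range, and
#' mixing of hydrodynamic- and TEM-sized particles within one cell-line
#' group — exocytosis data measured with different sizing techniques must
#' not enter the same regression.
#'
#' @param path File path; the delimiter is `,` for `.csv` and tab otherwise.
#' @return Object of class `np_dataset`: `np_table` (data.frame),
#'   `k_exo` (data.frame or NULL), `provenance`, `warnings`.
#' @export
read_np_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = TRUE,
                           colClasses = "character")
  np_dataset(raw, provenance = path)
}

#' Construct and validate an NP dataset
#'
#' @param np_table data.frame with the columns of [read_np_table()].
#' @param k_exo Optional data.frame with `np_id`, `cell_line`,
#'   `k_exo_per_s` and optionally `method`.
#' @param provenance Label recording where the table came from.
#' @return Object of class `np_dataset`.
#' @export
np_dataset <- function(np_table, k_exo = NULL, provenance = "in-memory") {
  required <- c("np_id", "coating", "diameter_nm", "size_type", "gamma_lw",
                "gamma_plus", "gamma_minus", "psi0_mv", "cell_line")
  missing_cols <- setdiff(required, names(np_table))
  if (length(missing_cols))
    stop("NP table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  numeric_cols <- c("diameter_nm", "gamma_lw", "gamma_plus", "gamma_minus",
                    "psi0_mv")
  for (col in numeric_cols) {
    parsed <- suppressWarnings(as.numeric(np_table[[col]]))
    bad <- which(is.na(parsed) & !is.na(np_table[[col]]) &
                   nzchar(trimws(as.character(np_table[[col]]))))
    if (anyNA(parsed))
      stop("non-numeric value in column `", col, "` at row(s) ",
           paste(utils::head(which(is.na(parsed)), 5L), collapse = ", "),
           call. = FALSE)
    np_table[[col]] <- parsed
  }
  if ("log_kow" %in% names(np_table))
    np_table$log_kow <- suppressWarnings(as.numeric(np_table$log_kow))
  if ("k_exo_per_s" %in% names(np_table))
    np_table$k_exo_per_s <- suppressWarnings(as.numeric(np_table$k_exo_per_s))

  if (any(np_table$diameter_nm <= 0))
    stop("diameter_nm must be > 0", call. = FALSE)
  np_table$size_type <- tolower(np_table$size_type)
  bad_type <- setdiff(unique(np_table$size_type), c("hydrodynamic", "tem"))
  if (length(bad_type))
    stop("size_type must be 'hydrodynamic' or 'tem' (got: ",
         paste(bad_type, collapse = ", "), ")", call. = FALSE)
  if (any(np_table$gamma_lw < 0 | np_table$gamma_plus < 0 |
            np_table$gamma_minus < 0))
    stop("surface free-energy components must be non-negative", call. = FALSE)

  warns <- character()
  gam <- c(np_table$gamma_lw, np_table$gamma_plus, np_table$gamma_minus)
  if (any(gam > 100))
    warns <- c(warns,
               "surface-energy component(s) outside the plausible 0-100 mJ/m^2 range")
  dup <- stats::aggregate(np_id ~ cell_line, np_table,
                          function(x) any(duplicated(x)))
  if (any(dup$np_id))
    warns <- c(warns, paste0("duplicated np_id within cell_line group(s): ",
                             paste(dup$cell_line[dup$np_id], collapse = ", ")))
  mix <- stats::aggregate(size_type ~ cell_line, np_table,
                          function(x) length(unique(x)) > 1L)
  if (any(mix$size_type))
    warns <- c(warns,
               paste0("mixing hydrodynamic- and TEM-sized particles within ",
                      "cell_line group(s): ",
                      paste(mix$cell_line[mix$size_type], collapse = ", "),
                      " - do not fit these in one regression"))
  for (w in warns) warning(w, call. = FALSE)

  structure(list(np_table = np_table, k_exo = k_exo,
                 provenance = provenance, warnings = warns),
            class = "np_dataset")
}

#' @export
print.np_dataset <- function(x, ...) {
  cat(sprintf("NP dataset: %d particles, %d cell line(s) [%s]\n",
              nrow(x$np_table), length(unique(x$np_table$cell_line)),
              x$provenance))
  if (length(x$warnings)) cat("  flags:", length(x$warnings), "\n")
  invisible(x)
}

#' @export
as.data.frame.np_dataset <- function(x, ...) x$np_table

#' Write an NP dataset back to CSV
#'
#' @param dataset `np_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_np_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "np_dataset"))
  utils::write.csv(dataset$np_table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read exocytosis time series from CSV
#'
#' Expects columns `np_id`, `cell_line`, `time_h`, `amount_norm`; one series
#' per (np_id, cell_line) pair.
#'
#' @param path CSV path.
#' @return Named list of [exocytosis_series()] objects.
#' @export
read_exocytosis_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("np_id", "cell_line", "time_h", "amount_norm")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("time-series table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keys <- unique(tab[, c("np_id", "cell_line")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[tab$np_id == keys$np_id[i] & tab$cell_line == keys$cell_line[i], ]
    sub <- sub[order(sub$time_h), ]
    exocytosis_series(sub$time_h, sub$amount_norm,
                      cell_line = keys$cell_line[i], np_id = keys$np_id[i])
  })
  names(out) <- paste(keys$np_id, keys$cell_line, sep = "/")
  out
}

#' Store fitted cell-line models as JSON
#'
#' @param models List of [fit_cell_model()] results.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cell_models <- function(models, path) {
  if (inherits(models, "cell_line_model")) models <- list(models)
  payload <- lapply(models, function(m) {
    stopifnot(inherits(m, "cell_line_model"))
    m[c("cell_line", "beta", "ln_a", "beta_se", "ln_a_se", "r2", "p_value",
        "n", "residual_variance", "mean_dg", "ss_dg", "dg_range")]
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read cell-line models from a JSON store
#'
#' @param path JSON path written by [write_cell_models()].
#' @return Named list of `cell_line_model` objects.
#' @export
read_cell_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  out <- lapply(payload, function(m) {
    m$dg_range <- as.numeric(unlist(m$dg_range))
    m$n <- as.integer(m$n)
    structure(m, class = "cell_line_model")
  })
  names(out) <- vapply(out, function(m) m$cell_line, character(1))
  out
}
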