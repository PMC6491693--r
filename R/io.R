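# Delimited-text readers/writers shared by all modules.
#
# Covariance/correlation matrices: square delimited text, first row is the
# variable-name header (a leading row-name column is tolerated). Loading
# matrices: header row of factor names, first column of variable names.
# Delimiter (comma or tab) is auto-detected.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a matrix from delimited text
#'
#' @param path File path; comma- or tab-delimited, auto-detected.
#' @param kind `"covariance"` or `"correlation"` (square, header of variable
#'   names, symmetry enforced to 1e-6) or `"loadings"` (header of factor
#'   names, first column of variable names).
#' @return A named numeric matrix; for square kinds, symmetrised.
#' @export
read_matrix <- function(path, kind = c("covariance", "correlation", "loadings")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- detect_delim(path)
  raw <- tryCatch(
    read.table(path, header = TRUE, sep = delim, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) abort(sprintf("Cannot parse %s: %s", path,
                                      conditionMessage(e))))
  if (kind == "loadings") {
    vn <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    suppressWarnings(storage.mode(m) <- "double")
    rownames(m) <- vn
  } else {
    # tolerate an optional leading row-name column
    if (!is.numeric(raw[[1]]) && ncol(raw) == nrow(raw) + 1) {
      rn <- as.character(raw[[1]])
      raw <- raw[, -1, drop = FALSE]
      rownames(raw) <- rn
    }
    m <- as.matrix(raw)
    suppressWarnings(storage.mode(m) <- "double")
    if (nrow(m) != ncol(m)) {
      abort(sprintf("%s matrix in %s must be square (got %d x %d).",
                    kind, path, nrow(m), ncol(m)))
    }
    rownames(m) <- colnames(m)
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Non-numeric or missing cell at row %d, column '%s' of %s.",
                  bad[1, 1], colnames(m)[bad[1, 2]], path))
  }
  if (kind != "loadings") {
    if (nrow(m) != ncol(m)) {
      abort(sprintf("%s matrix in %s must be square (got %d x %d).",
                    kind, path, nrow(m), ncol(m)))
    }
    asym <- abs(m - t(m))
    if (max(asym) > 1e-6) {
      w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
      abort(sprintf(
        "Matrix in %s is asymmetric at ('%s','%s'): |%g - %g| > 1e-6.",
        path, rownames(m)[w[1]], colnames(m)[w[2]],
        m[w[1], w[2]], m[w[2], w[1]]))
    }
    m <- (m + t(m)) / 2
  }
  m
}

#' Write a report to delimited or structured text
#'
#' Delimited output renders numeric columns at 6 significant digits (tab
#' separated); structured output is JSON at full double precision, so a
#' round trip through [read_report()] reproduces the values exactly.
#'
#' @param results A data frame / tibble (any module's report).
#' @param path Output file path.
#' @param format `"delimited"` or `"structured"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("delimited", "structured")) {
  format <- match.arg(format)
  results <- as.data.frame(results)
  if (format == "delimited") {
    fmt <- results
    num <- vapply(fmt, is.numeric, logical(1))
    fmt[num] <- lapply(fmt[num], function(x) signif(x, 6))
    ok <- tryCatch({
      write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("Cannot write to %s.", path))
  } else {
    ok <- tryCatch({
      jsonlite::write_json(results, path, digits = NA, auto_unbox = TRUE,
                           dataframe = "columns", pretty = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) abort(sprintf("Cannot write to %s.", path))
  }
  invisible(path)
}

#' Read back a structured report
#'
#' @param path A file written by [write_report()] with
#'   `format = "structured"`.
#' @return A tibble.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble::as_tibble(as.data.frame(obj, stringsAsFactors = FALSE))
}

#' Write a model's matrices to delimited files
#'
#' Writes `lambda` (loadings layout), `phi` and `theta` (square layout)
#' next to each other with a common stem.
#'
#' @param model A [cfa_model()].
#' @param stem Path stem; files `<stem>_lambda.csv`, `<stem>_phi.csv`,
#'   `<stem>_theta.csv` are produced.
#' @return The three paths, invisibly.
#' @export
write_model <- function(model, stem) {
  stopifnot(inherits(model, "cfa_model"))
  paths <- paste0(stem, c("_lambda.csv", "_phi.csv", "_theta.csv"))
  lam <- data.frame(variable = rownames(model$lambda), model$lambda,
                    check.names = FALSE)
  write.table(lam, paths[1], sep = ",", quote = FALSE, row.names = FALSE)
  write.table(model$phi, paths[2], sep = ",", quote = FALSE, row.names = FALSE)
  write.table(model$theta, paths[3], sep = ",", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a model from delimited files
#'
#' Counterpart of [write_model()].
#'
#' @param stem The path stem used by [write_model()].
#' @return A [cfa_model()].
#' @export
read_model <- function(stem) {
  lam <- read_matrix(paste0(stem, "_lambda.csv"), "loadings")
  phi <- read_matrix(paste0(stem, "_phi.csv"), "covariance")
  theta <- read_matrix(paste0(stem, "_theta.csv"), "covariance")
  cfa_model(lam, phi, theta)
}
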