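## Spectral matrix IO. CSV is the first-class format (comma separated,
## period decimal, optional single header row); MATLAB MAT matrices (the
## corn benchmark's format) are read by delegating to the environment's
## Python + scipy.io, since no MAT reader is installed for R.

#' Read a spectral matrix
#'
#' @param path File path.
#' @param format `"csv"` or `"mat"`.
#' @param orientation `"rows"` if samples are in rows (default) or
#'   `"columns"` if samples are in columns; the result is always normalised
#'   to samples by channels.
#' @param y Reference property: a numeric vector, a column name/index of the
#'   CSV (extracted from the matrix), or for MAT files the name of the
#'   variable holding the property matrix together with `yColumn`.
#' @param yColumn For MAT property matrices: which column is the property
#'   (name not available; 1-based index).
#' @param variable MAT variable holding the spectra (e.g. `"m5spec"`).
#' @param header Does the CSV have a header row? Default: autodetect.
#' @return A [SpectralDataset-class]. The channel axis comes from numeric
#'   CSV header names when present, else the 0-based index.
#' @export
readSpectra <- function(path, format = c("csv", "mat"),
                        orientation = c("rows", "columns"),
                        y = NULL, yColumn = NULL, variable = NULL,
                        header = NA) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    first <- readLines(path, n = 1L)
    if (is.na(header))
      header <- anyNA(suppressWarnings(as.numeric(strsplit(first, ",")[[1]])))
    df <- read.csv(path, header = header, check.names = FALSE)
    bad <- !vapply(df, is.numeric, logical(1))
    ycol <- NULL
    if (!is.null(y) && length(y) == 1L && (is.character(y) || (is.numeric(y) && y <= ncol(df)))) {
      ycol <- if (is.character(y)) match(y, names(df)) else as.integer(y)
      if (is.na(ycol)) stop("y column '", y, "' not found in ", path)
      bad[ycol] <- FALSE
      yvec <- as.numeric(df[[ycol]])
    } else {
      yvec <- as.numeric(y)
    }
    if (any(bad))
      stop("non-numeric column(s) in ", path, ": ",
           paste(names(df)[bad], collapse = ", "))
    if (!is.null(ycol)) df <- df[, -ycol, drop = FALSE]
    M <- as.matrix(df)
    if (orientation == "columns") {
      M <- t(M)
      axis <- NULL               # channels were rows; no axis labels carried
    } else {
      axis <- suppressWarnings(as.numeric(colnames(M)))
    }
    if (is.null(axis) || anyNA(axis)) axis <- seq_len(ncol(M)) - 1
  } else {
    M <- readMatMatrix(path, variable)
    if (orientation == "columns") M <- t(M)
    axis <- seq_len(ncol(M)) - 1
    yvec <- if (is.character(y)) {
      ym <- readMatMatrix(path, y)
      if (is.null(yColumn)) stop("give 'yColumn' to pick the property column")
      as.numeric(ym[, yColumn])
    } else as.numeric(y)
  }
  if (length(yvec) == 0L) yvec <- rep(0, nrow(M))   # unsupervised read
  spectralDataset(M, yvec, axis = axis, metadata = list(source = path))
}

#' Read one numeric 2-D variable from a MATLAB MAT file
#'
#' Converts through the environment's `python` and scipy.io; only numeric
#' 2-D variables are supported. MAT containers with nested "dataset" objects
#' (as in the corn benchmark) have their `.data` field extracted.
#'
#' @param path MAT file path.
#' @param variable Variable name inside the file.
#' @return Numeric matrix.
#' @export
readMatMatrix <- function(path, variable) {
  if (is.null(variable)) stop("give the MAT 'variable' name to read")
  py <- Sys.which("python")
  if (py == "") stop("MAT reading needs the environment's python + scipy")
  tmp <- tempfile(fileext = ".csv")
  code <- paste(
    "import sys, numpy, scipy.io",
    "m = scipy.io.loadmat(sys.argv[1], squeeze_me=False)",
    "v = m.get(sys.argv[2])",
    "if v is None: sys.exit('MAT variable not found: ' + sys.argv[2])",
    "while hasattr(v, 'dtype') and v.dtype == object: v = v.item() if v.size == 1 else v[0]",
    "if hasattr(v, 'data'): v = v.data",
    "v = numpy.asarray(v, dtype=float)",
    "if v.ndim != 2: sys.exit('MAT variable is not a 2-D numeric matrix')",
    "numpy.savetxt(sys.argv[3], v, delimiter=',')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(code), shQuote(path),
                          shQuote(variable), shQuote(tmp)),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(tmp) || length(attr(status, "status")))
    stop("MAT conversion failed: ", paste(status, collapse = " "))
  as.matrix(read.csv(tmp, header = FALSE))
}

#' Write a spectral dataset as CSV
#'
#' Full-precision CSV round-trip: channels as header (axis values), one row
#' per sample, with the reference property in a trailing `y` column.
#'
#' @param dataset A [SpectralDataset-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSpectra <- function(dataset, path) {
  M <- dataset@X
  df <- as.data.frame(M)
  names(df) <- format(dataset@axis, digits = 15, trim = TRUE)
  df$y <- dataset@y
  # full precision so that write -> read reproduces values bit-exact
  out <- vapply(df, function(col) format(col, digits = 17, trim = TRUE),
                character(nrow(df)))
  if (nrow(df) == 1L) out <- matrix(out, nrow = 1L, dimnames = list(NULL, names(df)))
  write.table(rbind(names(df), out), path, sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  invisible(path)
}
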