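#' Delimited-table readers and writers for peak lists, titrations and SAXS
#'
#' All tabular inputs are comma- or whitespace-delimited text with a header
#' row; lines starting with `#` or `!` are comments. Numeric cells that fail
#' to parse raise an error naming the offending line.
#'
#' Documented headers:
#' * peak list: `resno, deltaH, deltaN, intensity, status`
#'   (`status` one of `observed`, `broadened_out`, `unassigned`; shift and
#'   intensity fields must be present iff observed)
#' * titration: `x, y[, sigma]` (x in molar for binding, mV for redox, pH
#'   units for activity curves)
#' * SAXS: `q, I[, sigma]` with q in inverse Angstrom, strictly positive
#'
#' @param path file path.
#' @return a typed tibble; titrations carry the model `kind` and SAXS tables
#'   the column units as attributes.
#' @name table_io
NULL

read_delim_checked <- function(path, numeric_cols, what) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*[#!]", raw) & nzchar(trimws(raw))
  line_no <- which(keep)
  raw <- raw[keep]
  if (length(raw) < 2L) abort(sprintf("%s '%s': no data rows", what, path))
  delim <- if (grepl(",", raw[1])) "," else "whitespace"
  split1 <- function(s) {
    if (delim == ",") trimws(strsplit(s, ",")[[1]]) else strsplit(trimws(s), "\\s+")[[1]]
  }
  hdr <- split1(raw[1])
  rows <- map(raw[-1], split1)
  bad_len <- which(lengths(rows) != length(hdr))
  if (length(bad_len)) {
    abort(sprintf("%s '%s': line %d has %d field(s), expected %d",
                  what, path, line_no[-1][bad_len[1]],
                  lengths(rows)[bad_len[1]], length(hdr)))
  }
  df <- as_tibble(setNames(map(seq_along(hdr), function(j) {
    vapply(rows, `[`, character(1), j)
  }), hdr))
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "", ".")))
    if (length(bad)) {
      abort(sprintf("%s '%s': non-numeric value '%s' in column '%s' at line %d",
                    what, path, df[[col]][bad[1]], col, line_no[-1][bad[1]]))
    }
    df[[col]] <- v
  }
  df
}

#' @rdname table_io
#' @export
read_peaklist <- function(path) {
  df <- read_delim_checked(path, c("resno", "deltaH", "deltaN", "intensity"),
                           "peak list")
  assert_cols(df, c("resno", "deltaH", "deltaN", "intensity"), "peak list")
  if (!"status" %in% names(df)) df$status <- "observed"
  df$resno <- as.integer(df$resno)
  validate_peaklist(df)
}

validate_peaklist <- function(df) {
  ok_status <- c("observed", "broadened_out", "unassigned")
  if (any(!df$status %in% ok_status)) {
    abort(sprintf("peak list: invalid status value(s): %s",
                  paste(setdiff(unique(df$status), ok_status), collapse = ", ")))
  }
  obs <- df$status == "observed"
  if (any(obs & (is.na(df$deltaH) | is.na(df$deltaN)))) {
    abort("peak list: observed rows must have deltaH and deltaN")
  }
  if (any(obs & (is.na(df$intensity) | df$intensity < 0))) {
    abort("peak list: observed rows must have intensity >= 0")
  }
  if (anyDuplicated(df$resno)) abort("peak list: duplicated residue numbers")
  as_tibble(df[, c("resno", "deltaH", "deltaN", "intensity", "status")])
}

#' @rdname table_io
#' @param peaks a peak-list tibble.
#' @export
write_peaklist <- function(peaks, path) {
  readr::write_csv(validate_peaklist(peaks), path)
  invisible(path)
}

#' @rdname table_io
#' @param kind titration model family: `"morrison"`, `"nernst"` or
#'   `"ph_activity"`.
#' @export
read_titration <- function(path, kind = c("morrison", "nernst", "ph_activity")) {
  kind <- match.arg(kind)
  df <- read_delim_checked(path, c("x", "y", "sigma"), "titration")
  assert_cols(df, c("x", "y"), "titration")
  as_titration(df, kind)
}

#' Construct a titration series
#'
#' @param df data frame with columns `x`, `y` and optionally `sigma`.
#' @param kind model family the series is intended for.
#' @return tibble sorted by `x` with attribute `kind`.
#' @export
as_titration <- function(df, kind = c("morrison", "nernst", "ph_activity")) {
  kind <- match.arg(kind)
  assert_cols(df, c("x", "y"), "titration")
  if (length(df$x) != length(df$y)) abort("titration: x and y lengths differ")
  if (is.unsorted(df$x, strictly = FALSE)) {
    warn("titration x values were not sorted; sorting")
    df <- df[order(df$x), , drop = FALSE]
  }
  if (anyDuplicated(df$x)) abort("titration: duplicated x values")
  out <- tibble(x = as.numeric(df$x), y = as.numeric(df$y))
  if ("sigma" %in% names(df)) out$sigma <- as.numeric(df$sigma)
  attr(out, "kind") <- kind
  out
}

#' @rdname table_io
#' @param series a titration tibble.
#' @export
write_titration <- function(series, path) {
  readr::write_csv(as_tibble(series), path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_saxs <- function(path) {
  df <- read_delim_checked(path, c("q", "I", "sigma"), "SAXS profile")
  assert_cols(df, c("q", "I"), "SAXS profile")
  as_saxs(df)
}

#' Construct a scattering profile
#' @param df data frame with columns `q` (1/Angstrom, > 0, strictly
#'   increasing), `I`, and optionally `sigma`.
#' @return a validated tibble.
#' @export
as_saxs <- function(df) {
  assert_cols(df, c("q", "I"), "SAXS profile")
  if (any(df$q <= 0)) abort("SAXS profile: q must be strictly positive")
  if (is.unsorted(df$q, strictly = TRUE)) abort("SAXS profile: q must be strictly increasing")
  if (any(!is.finite(df$I))) abort("SAXS profile: intensities must be finite")
  out <- tibble(q = as.numeric(df$q), I = as.numeric(df$I))
  if ("sigma" %in% names(df)) out$sigma <- as.numeric(df$sigma)
  out
}

#' @rdname table_io
#' @param profile a SAXS tibble.
#' @export
write_saxs <- function(profile, path) {
  readr::write_csv(as_tibble(profile), path)
  invisible(path)
}
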