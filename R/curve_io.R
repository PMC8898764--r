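#' Read a magnetometry curve from CSV
#'
#' The curve format is a plain CSV with a unit-bearing header naming the
#' columns — `T_K,chiT_cm3Kmol` for susceptibility or `H_T,M_muB` for
#' magnetization — an optional `sigma` column, and `#` comment lines
#' (which may carry `key = value` metadata such as `T_meas`).
#'
#' @param path Path to the CSV file.
#' @return A [magnetometry_curve()].
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' crv <- magnetometry_curve(seq(2, 30, 2), rep(1, 15), "susceptibility")
#' write_curve_csv(crv, tmp)
#' read_curve_csv(tmp)
#' @export
read_curve_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  is_comment <- grepl("^\\s*#", raw)
  meta <- raw[is_comment]
  body <- raw[!is_comment & nzchar(trimws(raw))]
  if (!length(body)) stop("no header line found in ", path, call. = FALSE)
  header <- strsplit(trimws(body[1L]), ",")[[1L]]
  kind <- if (identical(header[1:2], c("T_K", "chiT_cm3Kmol"))) {
    "susceptibility"
  } else if (identical(header[1:2], c("H_T", "M_muB"))) {
    "magnetization"
  } else {
    stop("unknown curve header '", body[1L],
         "'; expected 'T_K,chiT_cm3Kmol' or 'H_T,M_muB'", call. = FALSE)
  }
  rows <- body[-1L]
  parsed <- lapply(seq_along(rows), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(rows[i], ",")[[1L]]))
    if (length(f) != length(header) || any(is.na(f)))
      stop(sprintf("malformed row at data line %d of %s: '%s'",
                   i, path, rows[i]), call. = FALSE)
    f
  })
  m <- do.call(rbind, parsed)
  T_meas <- NULL
  tm <- regmatches(meta, regexec("T_meas\\s*=\\s*([0-9.eE+-]+)", meta))
  tm <- Filter(function(x) length(x) == 2L, tm)
  if (length(tm)) T_meas <- as.numeric(tm[[1L]][2L])
  sigma <- if ("sigma" %in% header) m[, match("sigma", header)] else NULL
  magnetometry_curve(m[, 1L], m[, 2L], kind = kind, T_meas = T_meas,
                     sigma = sigma)
}

#' Write a magnetometry curve to CSV
#'
#' Inverse of [read_curve_csv()]; numeric values are written with 12
#' significant digits so a write/read round trip is lossless at working
#' precision.
#'
#' @param curve A [magnetometry_curve()].
#' @param path Output path.
#' @param comments Optional character vector of comment lines (written
#'   with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path, comments = character()) {
  if (!inherits(curve, "magnetometry_curve"))
    stop("'curve' must be a magnetometry_curve", call. = FALSE)
  lines <- character()
  if (length(comments)) lines <- paste0("# ", comments)
  T_meas <- attr(curve, "T_meas")
  if (!is.null(T_meas)) lines <- c(lines, sprintf("# T_meas = %g", T_meas))
  cols <- names(curve)
  lines <- c(lines, paste(cols, collapse = ","))
  vals <- vapply(seq_len(nrow(curve)), function(i)
    paste(vapply(cols, function(cl) formatC(curve[[cl]][i], digits = 12,
                                            format = "g"), ""),
          collapse = ","), "")
  writeLines(c(lines, vals), path)
  invisible(path)
}
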