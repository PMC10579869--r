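#' Read a Grace/GROMACS XVG series
#'
#' Parses the Grace dialect GROMACS writes: \code{#} comment lines,
#' \code{@} metadata lines (title, axis labels, \code{s0 legend ...}), and
#' whitespace-separated numeric rows.  Column 1 becomes the time axis,
#' column 2 the primary values; further columns are retained as extra
#' series, with legends matched to the \code{@ s<n> legend} lines in order.
#' Unrecognised \code{@} lines are preserved verbatim and re-emitted by
#' \code{\link{writeXVG}}.
#'
#' @param path path to an existing XVG file.
#' @return a \linkS4class{LabeledSeries}.
#' @export
readXVG <- function(path) {
  if (!file.exists(path)) stop("XVG file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- ""; xlab <- ""; ylab <- ""
  legends <- character(); meta <- character()
  data_rows <- list(); data_lnos <- integer()
  grab <- function(line, pat) {
    m <- regmatches(line, regexec(pat, line))[[1]]
    if (length(m) >= 2) m[2] else NA_character_
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (grepl("^\\s*$", ln) || grepl("^\\s*#", ln)) next
    if (grepl("^\\s*@", ln)) {
      v <- grab(ln, "^\\s*@\\s*title\\s+\"(.*)\"")
      if (!is.na(v)) { title <- v; next }
      v <- grab(ln, "^\\s*@\\s*xaxis\\s+label\\s+\"(.*)\"")
      if (!is.na(v)) { xlab <- v; next }
      v <- grab(ln, "^\\s*@\\s*yaxis\\s+label\\s+\"(.*)\"")
      if (!is.na(v)) { ylab <- v; next }
      m <- regmatches(ln,
        regexec("^\\s*@\\s*s(\\d+)\\s+legend\\s+\"(.*)\"", ln))[[1]]
      if (length(m) == 3) {
        legends[as.integer(m[2]) + 1L] <- m[3]
        next
      }
      meta <- c(meta, sub("^\\s*", "", ln))
      next
    }
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals))
      stop("non-numeric token in data row at line ", i, " of ", path)
    data_rows[[length(data_rows) + 1L]] <- vals
    data_lnos <- c(data_lnos, i)
  }
  if (!length(data_rows))
    stop("malformed XVG (no numeric rows): ", path)
  ncol <- length(data_rows[[1]])
  bad <- which(vapply(data_rows, length, 1L) != ncol)
  if (length(bad))
    stop("ragged data row at line ", data_lnos[bad[1]], " of ", path)
  mat <- do.call(rbind, data_rows)
  if (ncol < 2) stop("XVG data must have at least two columns: ", path)
  legends <- legends[!is.na(legends)]
  extra <- list()
  if (ncol > 2) {
    extra <- lapply(seq.int(3, ncol), function(j) mat[, j])
    enames <- if (length(legends) >= ncol - 1) legends[seq.int(2, ncol - 1)]
              else paste0("column", seq.int(3, ncol))
    names(extra) <- enames
  }
  LabeledSeries(mat[, 1], mat[, 2], title = title, xLabel = xlab,
                yLabel = ylab, legend = legends, extra = extra, meta = meta)
}

#' Write a LabeledSeries as an XVG file
#'
#' Emits title/axis/legend metadata, any preserved opaque \code{@} lines,
#' then the numeric columns (time, value, extras).  \code{readXVG} on the
#' output reproduces the series exactly for all typed fields.
#'
#' @param series a \linkS4class{LabeledSeries}.
#' @param path output path.
#' @param digits significant digits for numeric output.
#' @return \code{path}, invisibly.
#' @export
writeXVG <- function(series, path, digits = 10) {
  stopifnot(is(series, "LabeledSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("@    title \"%s\"", series@title),
    sprintf("@    xaxis  label \"%s\"", series@xLabel),
    sprintf("@    yaxis  label \"%s\"", series@yLabel)), con)
  if (length(series@legend))
    writeLines(sprintf("@ s%d legend \"%s\"",
                       seq_along(series@legend) - 1L, series@legend), con)
  if (length(series@meta)) writeLines(series@meta, con)
  cols <- c(list(series@times, series@values), unname(series@extra))
  mat <- do.call(cbind, cols)
  writeLines(apply(mat, 1, function(r)
    paste(formatC(r, digits = digits, format = "g"), collapse = "  ")), con)
  invisible(path)
}
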