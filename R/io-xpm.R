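#' Read a GROMACS XPM character matrix
#'
#' Parses the GROMACS XPM dialect: a quoted header
#' \code{"ncols nrows ncolors chars_per_pixel"}, one quoted colour line per
#' code (its class name in the trailing \code{/* "..." */} comment), then
#' \code{nrows} quoted pixel rows, top row first.  Because the GROMACS
#' y-axis runs bottom-up, row 1 of the returned matrix corresponds to the
#' \emph{last} pixel row; this orientation is part of the contract.
#' Axis tick values are taken from \code{/* x-axis: ... */} and
#' \code{/* y-axis: ... */} comments when present.
#'
#' @param path path to an XPM file.
#' @return a \linkS4class{CharMatrix}.
#' @export
readXPM <- function(path) {
  if (!file.exists(path)) stop("XPM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  title <- ""
  xticks <- numeric(); yticks <- numeric()
  for (ln in lines) {
    m <- regmatches(ln, regexec("/\\*\\s*title:\\s*\"(.*)\"\\s*\\*/", ln))[[1]]
    if (length(m) == 2) title <- m[2]
    m <- regmatches(ln, regexec("/\\*\\s*x-axis:\\s*(.*?)\\*/", ln))[[1]]
    if (length(m) == 2)
      xticks <- c(xticks, as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]]))
    m <- regmatches(ln, regexec("/\\*\\s*y-axis:\\s*(.*?)\\*/", ln))[[1]]
    if (length(m) == 2)
      yticks <- c(yticks, as.numeric(strsplit(trimws(m[2]), "\\s+")[[1]]))
  }
  # pure comment lines may contain quotes (title, axis ticks): skip them
  quoted_at <- setdiff(grep("\"", lines), grep("^\\s*/\\*", lines))
  quoted <- character(); qcomment <- character()
  for (i in quoted_at) {
    m <- regmatches(lines[i], regexec("\"([^\"]*)\"", lines[i]))[[1]]
    if (length(m) < 2) next
    quoted <- c(quoted, m[2])
    cm <- regmatches(lines[i],
      regexec("/\\*\\s*\"(.*)\"\\s*\\*/", lines[i]))[[1]]
    qcomment <- c(qcomment, if (length(cm) == 2) cm[2] else NA_character_)
  }
  if (!length(quoted)) stop("malformed XPM (no quoted strings): ", path)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(quoted[1]),
                                              "\\s+")[[1]]))
  if (length(hdr) != 4 || anyNA(hdr))
    stop("malformed XPM header in ", path)
  ncols <- hdr[1]; nrows <- hdr[2]; ncolors <- hdr[3]; cpp <- hdr[4]
  if (cpp != 1) stop("only 1 character per pixel supported: ", path)
  if (length(quoted) < 1 + ncolors + nrows)
    stop("XPM truncated (expected ", 1 + ncolors + nrows,
         " quoted strings): ", path)
  codes <- character(ncolors); cols <- character(ncolors)
  legend <- character(ncolors)
  for (k in seq_len(ncolors)) {
    s <- quoted[1 + k]
    codes[k] <- substr(s, 1, 1)
    m <- regmatches(s, regexec("\\sc\\s+(\\S+)", s))[[1]]
    cols[k] <- if (length(m) == 2) m[2] else ""
    legend[k] <- if (!is.na(qcomment[1 + k])) qcomment[1 + k] else codes[k]
  }
  names(cols) <- codes; names(legend) <- codes
  pix <- quoted[seq.int(1 + ncolors + 1, 1 + ncolors + nrows)]
  badlen <- which(nchar(pix) != ncols)
  if (length(badlen))
    stop("pixel row ", badlen[1], " has length ", nchar(pix[badlen[1]]),
         ", expected ", ncols, " in ", path)
  # bottom-up: last pixel row becomes matrix row 1
  mat <- do.call(rbind, lapply(rev(pix), function(r)
    strsplit(r, "")[[1]]))
  undecl <- setdiff(unique(as.vector(mat)), codes)
  if (length(undecl))
    stop("undeclared pixel code(s) in ", path, ": ",
         paste(undecl, collapse = ", "))
  new("CharMatrix", codes = mat, rowLabels = yticks, colLabels = xticks,
      legend = legend, colors = cols, title = title)
}

#' Write a CharMatrix as a GROMACS-dialect XPM file
#'
#' Inverse of \code{\link{readXPM}}: matrix row 1 is written as the last
#' pixel row (bottom of the y-axis).
#'
#' @param mat a \linkS4class{CharMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeXPM <- function(mat, path) {
  stopifnot(is(mat, "CharMatrix"))
  m <- mat@codes
  codes <- names(mat@legend)
  cols <- mat@colors[codes]
  cols[is.na(cols) | cols == ""] <-
    grDevices::rainbow(sum(is.na(cols) | cols == ""))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("/* XPM */", con)
  writeLines(sprintf("/* title:   \"%s\" */", mat@title), con)
  if (length(mat@colLabels))
    writeLines(sprintf("/* x-axis:  %s */",
                       paste(mat@colLabels, collapse = " ")), con)
  if (length(mat@rowLabels))
    writeLines(sprintf("/* y-axis:  %s */",
                       paste(mat@rowLabels, collapse = " ")), con)
  writeLines("static char *trajkit_xpm[] = {", con)
  writeLines(sprintf("\"%d %d   %d 1\",", ncol(m), nrow(m),
                     length(codes)), con)
  writeLines(sprintf("\"%s  c %s \" /* \"%s\" */,", codes, cols,
                     mat@legend[codes]), con)
  rows <- apply(m, 1, paste, collapse = "")
  rows <- rev(rows)  # top pixel row first
  writeLines(c(sprintf("\"%s\",", rows[-length(rows)]),
               sprintf("\"%s\"", rows[length(rows)]), "};"), con)
  invisible(path)
}
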