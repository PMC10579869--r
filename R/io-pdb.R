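# Standard atomic masses (Da) and the atom-name -> element fallback used
# when PDB columns 77-78 are blank.
.ELEMENT_MASSES <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, MG = 24.305, K = 39.098, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971)

.massOf <- function(element, label = element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .ELEMENT_MASSES[key]
  if (anyNA(m))
    stop("unknown element, no mass available for atom(s): ",
         paste(unique(label[is.na(m)]), collapse = ", "))
  unname(m)
}

# PDB atom-name heuristic: strip digits, take the leading alphabetic
# token; two-letter elements recognised when the name starts in column 13.
.elementFromName <- function(name) {
  vapply(name, function(nm) {
    a <- gsub("[^A-Za-z]", "", nm)
    if (!nchar(a)) return(NA_character_)
    two <- toupper(substr(a, 1, 2))
    if (two %in% c("CL", "BR", "MG", "ZN", "FE", "MN", "CU", "SE") &&
        nchar(gsub("[0-9']", "", nm)) > 1)
      return(two)
    toupper(substr(a, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a multi-model PDB trajectory
#'
#' Frames are MODEL/ENDMDL blocks; a file without MODEL records is a
#' single implicit frame.  Coordinates come from the fixed columns 31-54
#' of ATOM/HETATM records (Angstrom); elements from columns 77-78, falling
#' back to the atom-name heuristic; masses from a standard element table.
#'
#' @param path path to a PDB file.
#' @return a \linkS4class{Trajectory}.
#' @export
readPDBTrajectory <- function(path) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  frames <- if (length(model_starts)) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) < length(model_starts))
      ends <- c(ends, length(lines))
    lapply(seq_along(model_starts), function(k) {
      idx <- seq.int(model_starts[k], ends[k])
      idx[is_atom[idx]]
    })
  } else list(which(is_atom))
  if (!length(frames[[1]])) stop("no ATOM/HETATM records in ", path)
  na <- length(frames[[1]])
  counts <- vapply(frames, length, 1L)
  if (any(counts != na))
    stop("structural inconsistency: frames have differing atom counts (",
         paste(unique(counts), collapse = ", "), ") in ", path)

  parse_frame <- function(idx) {
    ln <- lines[idx]
    cbind(as.numeric(substr(ln, 31, 38)),
          as.numeric(substr(ln, 39, 46)),
          as.numeric(substr(ln, 47, 54)))
  }
  xyz <- array(NA_real_, dim = c(length(frames), na, 3))
  for (k in seq_along(frames)) xyz[k, , ] <- parse_frame(frames[[k]])

  ln1 <- lines[frames[[1]]]
  name <- trimws(substr(ln1, 13, 16))
  element <- trimws(substr(ln1, 77, 78))
  element[element == ""] <- .elementFromName(name[element == ""])
  if (anyNA(element))
    stop("cannot infer element for atom(s): ",
         paste(name[is.na(element)], collapse = ", "))
  atoms <- data.frame(
    serial = as.integer(substr(ln1, 7, 11)),
    name = name,
    element = toupper(element),
    resid = as.integer(substr(ln1, 23, 26)),
    resname = trimws(substr(ln1, 18, 20)),
    chain = substr(ln1, 22, 22),
    stringsAsFactors = FALSE)
  atoms$mass <- .massOf(atoms$element, atoms$name)
  new("Trajectory", coords = xyz, atoms = atoms, times = numeric())
}

#' Write a Trajectory as a multi-model PDB file
#'
#' @param traj a \linkS4class{Trajectory}.
#' @param path output path.
#' @param frames frame indices to write (default all).
#' @return \code{path}, invisibly.
#' @export
writePDBTrajectory <- function(traj, path, frames = seq_len(nFrames(traj))) {
  stopifnot(is(traj, "Trajectory"))
  a <- traj@atoms
  con <- file(path, "w")
  on.exit(close(con))
  # PDB name convention: 1-letter elements start in column 14
  nm <- ifelse(nchar(a$name) < 4 & nchar(a$element) == 1,
               sprintf(" %-3s", a$name), sprintf("%-4s", a$name))
  for (k in frames) {
    writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %s %-3s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial, nm, a$resname, a$chain, a$resid,
      traj@coords[k, , 1], traj@coords[k, , 2], traj@coords[k, , 3],
      1, 0, a$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
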