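# DSSP 7-type -> 4-class reduction.  Bend (S) joins Coil by default, the
# universal simplification; set bendTo = "turn" to group it with turns.
.SS4_LEGEND <- c(H = "Helix", E = "Sheet", T = "Turn", C = "Coil")
.SS4_COLORS <- c(H = "#3333CC", E = "#CC3333", T = "#CCCC33", C = "#AAAAAA")

.ss7to4map <- function(bendTo = c("coil", "turn")) {
  bendTo <- match.arg(bendTo)
  c(H = "H", G = "H", I = "H",      # 3-10, alpha, pi helices
    E = "E", B = "E",               # strand, isolated bridge
    T = "T",                        # hydrogen-bonded turn
    S = if (bendTo == "coil") "C" else "T",
    C = "C", "~" = "C", " " = "C")  # coil spellings
}

#' Reduce a 7-type DSSP timeline to the four basic classes
#'
#' Surjectively maps the DSSP timeline codes onto helices (H, G, I),
#' beta-sheets (E, B), turns (T) and coils (S plus the coil spellings),
#' preserving the matrix shape and rewriting the legend to the four
#' classes.
#'
#' @param matrix7 a \linkS4class{CharMatrix} with codes in the 7-type
#'   alphabet.
#' @param bendTo where the bend code S goes: \code{"coil"} (default) or
#'   \code{"turn"}.
#' @return a \linkS4class{CharMatrix} over codes H, E, T, C.
#' @export
reclassifySS <- function(matrix7, bendTo = c("coil", "turn")) {
  stopifnot(is(matrix7, "CharMatrix"))
  map <- .ss7to4map(match.arg(bendTo))
  m <- matrix7@codes
  unknown <- setdiff(unique(as.vector(m)), names(map))
  if (length(unknown)) {
    cell <- which(matrix(as.vector(m) %in% unknown, nrow(m)),
                  arr.ind = TRUE)[1, ]
    stop("code outside the 7-type alphabet: \"",
         intersect(unique(as.vector(m)), unknown)[1],
         "\" at row ", cell[1], ", column ", cell[2])
  }
  out <- matrix(map[as.vector(m)], nrow(m), ncol(m))
  present <- intersect(names(.SS4_LEGEND), unique(as.vector(out)))
  new("CharMatrix", codes = out, rowLabels = matrix7@rowLabels,
      colLabels = matrix7@colLabels,
      legend = .SS4_LEGEND[present], colors = .SS4_COLORS[present],
      title = matrix7@title)
}

#' Per-class secondary-structure fractions over time
#'
#' For each class in the matrix legend, the fraction of residues assigned
#' to it in every frame; the fractions sum to 1 per frame.
#'
#' @param timeline a \linkS4class{CharMatrix} (7- or 4-class).
#' @return named list of \linkS4class{LabeledSeries}, one per class.
#' @export
ssFractionSeries <- function(timeline) {
  stopifnot(is(timeline, "CharMatrix"))
  m <- timeline@codes
  t <- if (length(timeline@colLabels) == ncol(m)) timeline@colLabels
       else seq_len(ncol(m))
  lapply(stats::setNames(names(timeline@legend),
                         make.unique(unname(timeline@legend))),
         function(code)
    LabeledSeries(t, colMeans(m == code),
                  title = paste0(timeline@legend[code], " fraction"),
                  xLabel = "Frame", yLabel = "Fraction",
                  legend = unname(timeline@legend[code])))
}

#' Per-frame class counts of a secondary-structure timeline
#'
#' @param timeline a \linkS4class{CharMatrix}.
#' @return class x frame integer matrix; columns sum to the residue count.
#' @export
ssCountMatrix <- function(timeline) {
  m <- timeline@codes
  out <- vapply(names(timeline@legend),
                function(code) colSums(m == code),
                numeric(ncol(m)))
  storage.mode(out) <- "integer"
  t(rbind(out))
}
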