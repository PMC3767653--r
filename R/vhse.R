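# VHSE descriptor constants and window encoding.
#
# VHSE (principal component score Vectors of Hydrophobic, Steric, and
# Electronic properties) assigns eight dimensionless scores to each of the
# 20 canonical amino acids: components 1-2 summarize hydrophobic
# properties, 3-4 steric properties, and 5-8 electronic properties. The
# scores are PCA scores of auto-scaled property panels, so each column is
# centered over the 20 residues up to two-decimal rounding. They are the
# method's fixed parameters and are embedded here as data.

.VHSE <- local({
  m <- matrix(c(
    #  VHSE1  VHSE2  VHSE3  VHSE4  VHSE5  VHSE6  VHSE7  VHSE8
       0.15, -1.11, -1.35, -0.92,  0.02, -0.91,  0.36, -0.48,  # A Ala
      -1.47,  1.45,  1.24,  1.27,  1.55,  1.47,  1.30,  0.83,  # R Arg
      -0.99,  0.00, -0.37,  0.69, -0.55,  0.85,  0.73, -0.80,  # N Asn
      -1.15,  0.67, -0.41, -0.01, -2.68,  1.31,  0.03,  0.56,  # D Asp
       0.18, -1.67, -0.46, -0.21,  0.00,  1.20, -1.61, -0.19,  # C Cys
      -0.96,  0.12,  0.18,  0.16,  0.09,  0.42, -0.20, -0.41,  # Q Gln
      -1.18,  0.40,  0.10,  0.36, -2.16, -0.17,  0.91,  0.02,  # E Glu
      -0.20, -1.53, -2.63,  2.28, -0.53, -1.18,  2.01, -1.34,  # G Gly
      -0.43, -0.25,  0.37,  0.19,  0.51,  1.28,  0.93,  0.65,  # H His
       1.27, -0.14,  0.30, -1.80,  0.30, -1.61, -0.16, -0.13,  # I Ile
       1.36,  0.07,  0.26, -0.80,  0.22, -1.37,  0.08, -0.62,  # L Leu
      -1.17,  0.70,  0.70,  0.80,  1.64,  0.67,  1.63,  0.13,  # K Lys
       1.01, -0.53,  0.43,  0.00,  0.23,  0.10, -0.86, -0.68,  # M Met
       1.52,  0.61,  0.96, -0.16,  0.25,  0.28, -1.33, -0.20,  # F Phe
       0.22, -0.17, -0.50,  0.05, -0.01, -1.34, -0.19,  3.56,  # P Pro
      -0.67, -0.86, -1.07, -0.41, -0.32,  0.27, -0.64,  0.11,  # S Ser
      -0.34, -0.51, -0.55, -1.06,  0.01, -0.01, -0.79,  0.39,  # T Thr
       1.50,  2.06,  1.79,  0.75,  0.75, -0.13, -1.06, -0.85,  # W Trp
       0.61,  1.60,  1.17,  0.73,  0.53,  0.25, -0.96, -0.52,  # Y Tyr
       0.76, -0.92,  0.17, -1.91,  0.22, -1.40, -0.24, -0.03), # V Val
    nrow = 20, byrow = TRUE,
    dimnames = list(
      c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
      paste0("VHSE", 1:8)))
  m
})

#' Canonical amino-acid one-letter codes
#'
#' @return character vector of the 20 canonical one-letter codes, in the
#'   row order of the descriptor table.
#' @export
canonicalResidues <- function() rownames(.VHSE)

#' The VHSE descriptor table
#'
#' Returns the 20 x 8 matrix of VHSE descriptor scores (rows: canonical
#' residues, columns: `VHSE1` ... `VHSE8`). Components 1-2 reflect
#' hydrophobic, 3-4 steric, and 5-8 electronic properties.
#'
#' @return numeric matrix with residue rownames.
#' @examples
#' vhseTable()["L", "VHSE1"]  # 1.36, leucine is strongly hydrophobic
#' @export
vhseTable <- function() .VHSE

#' Look up a single VHSE descriptor score
#'
#' @param residue one canonical one-letter amino-acid code.
#' @param component integer component number in 1..8.
#' @return the dimensionless descriptor score.
#' @examples
#' vhseLookup("A", 1)  # 0.15
#' vhseLookup("K", 1)  # -1.17
#' @export
vhseLookup <- function(residue, component) {
  if (!is.numeric(component) || length(component) != 1L ||
      is.na(component) || component != as.integer(component) ||
      component < 1 || component > 8)
    stop("'component' must be a single integer in 1..8", call. = FALSE)
  if (!is.character(residue) || length(residue) != 1L ||
      nchar(residue) != 1L)
    stop("'residue' must be a single one-letter code", call. = FALSE)
  if (!residue %in% rownames(.VHSE))
    stop(sprintf(
      "no VHSE descriptor available for residue '%s' (only the 20 canonical amino acids are defined)",
      residue), call. = FALSE)
  .VHSE[residue, component]
}

#' Validate a VHSE component selection
#'
#' The default selection `c(1, 3, 5)` retains the first principal
#' component of each property block (hydrophobic, steric, electronic),
#' the reduced variable set the prediction models are built on.
#'
#' @param selection integer vector of component numbers in 1..8, strictly
#'   increasing.
#' @return the selection as an integer vector.
#' @export
componentSelection <- function(selection = c(1L, 3L, 5L)) {
  sel <- as.integer(selection)
  if (length(sel) == 0L || anyNA(sel) || any(sel < 1L | sel > 8L))
    stop("'selection' must be non-empty component numbers in 1..8",
         call. = FALSE)
  if (any(diff(sel) <= 0L))
    stop("'selection' must be strictly increasing", call. = FALSE)
  sel
}

#' Position labels for a window
#'
#' Positions are named in Schechter-Berger style, counted outward from
#' the scissile bond: upstream `P_h ... P1` then downstream
#' `P1' ... P_h'`.
#'
#' @param halfWidth positive integer.
#' @return character vector of length `2 * halfWidth`.
#' @examples
#' positionLabels(2)  # "P2" "P1" "P1'" "P2'"
#' @export
positionLabels <- function(halfWidth) {
  halfWidth <- as.integer(halfWidth)
  if (length(halfWidth) != 1L || is.na(halfWidth) || halfWidth < 1L)
    stop("'halfWidth' must be a single positive integer", call. = FALSE)
  c(paste0("P", halfWidth:1), paste0("P", 1:halfWidth, "'"))
}

#' Encode a residue window as a VHSE descriptor vector
#'
#' The vector is position-major: the selected components (in ascending
#' index) of the first (most upstream) window residue come first, then
#' those of the second residue, and so on. A 28-residue window with the
#' default selection therefore encodes to 28 x 3 = 84 variables. The
#' names carry the (position, component) identity of each feature when
#' the window length is even (so a scissile bond sits at its center).
#'
#' @param window residue string over the canonical alphabet.
#' @param selection VHSE component numbers (see [componentSelection()]).
#' @return named numeric vector of length `nchar(window) * length(selection)`.
#' @examples
#' encodeWindow("LK", selection = 1)  # c(1.36, -1.17)
#' @export
encodeWindow <- function(window, selection = c(1L, 3L, 5L)) {
  sel <- componentSelection(selection)
  if (!is.character(window) || length(window) != 1L || nchar(window) < 1L)
    stop("'window' must be a single non-empty residue string",
         call. = FALSE)
  res <- strsplit(window, "", fixed = TRUE)[[1]]
  bad <- which(!res %in% rownames(.VHSE))
  if (length(bad))
    stop(sprintf(
      "no VHSE descriptor available for residue '%s' at window position %d",
      res[bad[1]], bad[1]), call. = FALSE)
  v <- as.vector(t(.VHSE[res, sel, drop = FALSE]))
  n <- length(res)
  if (n %% 2L == 0L) {
    pos <- positionLabels(n %/% 2L)
    names(v) <- paste0(rep(pos, each = length(sel)), "_VHSE",
                       rep(sel, times = n))
  } else {
    names(v) <- paste0("pos", rep(seq_len(n), each = length(sel)),
                       "_VHSE", rep(sel, times = n))
  }
  v
}

#' Export the VHSE descriptor table as TSV
#'
#' Writes a tab-separated audit copy with columns
#' `residue`, `VHSE1` ... `VHSE8`.
#'
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeVhseTable <- function(path) {
  df <- data.frame(residue = rownames(.VHSE), .VHSE,
                   check.names = FALSE, row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
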