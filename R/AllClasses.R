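#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' CleavageSampleSet: labeled residue windows around candidate scissile bonds
#'
#' Container for the cleavage / non-cleavage window samples produced by
#' [buildSampleSet()]. Each sample is a residue window of length
#' `2 * halfWidth` whose P1 residue (the residue immediately N-terminal to
#' the scissile bond) sits at 0-based window index `halfWidth - 1`.
#'
#' @slot samples a [S4Vectors::DataFrame] with columns `window` (residue
#'   string), `label` (`"cleavage"` or `"non_cleavage"`), `sourceId`,
#'   `peptide`, `matchOffset` (0-based start of the peptide in its source
#'   protein) and `siteIndex` (0-based index of the P1 residue in the
#'   source protein).
#' @slot halfWidth single positive integer; windows span `halfWidth`
#'   residues on each side of the scissile bond.
#' @slot dropStats named integer vector tallying dropped records by reason
#'   (e.g. `peptide_not_found`, `insufficient_context`,
#'   `non_canonical_residue`, `duplicate_window`, `label_conflict`).
#'
#' @seealso [buildSampleSet()], [trimSamples()], [sampleWindows()]
#' @export
setClass("CleavageSampleSet",
  representation(
    samples   = "DataFrame",
    halfWidth = "integer",
    dropStats = "integer"
  )
)

setValidity("CleavageSampleSet", function(object) {
  msg <- character()
  if (length(object@halfWidth) != 1L || is.na(object@halfWidth) ||
      object@halfWidth < 1L)
    msg <- c(msg, "halfWidth must be a single positive integer")
  need <- c("window", "label", "sourceId", "peptide", "matchOffset",
            "siteIndex")
  if (!all(need %in% colnames(object@samples)))
    msg <- c(msg, paste("samples must have columns:",
                        paste(need, collapse = ", ")))
  else {
    w <- object@samples$window
    if (length(w) && !all(nchar(w) == 2L * object@halfWidth))
      msg <- c(msg, "all windows must have length 2 * halfWidth")
    if (length(w) && !all(object@samples$label %in%
                          c("cleavage", "non_cleavage")))
      msg <- c(msg, "labels must be 'cleavage' or 'non_cleavage'")
    if (anyDuplicated(paste(w, object@samples$label)))
      msg <- c(msg, "duplicate (window, label) pairs are not allowed")
  }
  if (length(msg)) msg else TRUE
})

#' CleavageFeatures: scaled descriptor matrix ready for classification
#'
#' Feature matrix produced by [encodeSamples()] (raw descriptor space) or
#' [applyScaler()] (unit-interval space). Feature order is position-major:
#' all selected VHSE components of the most upstream position first,
#' positions running P_h ... P1, P1' ... P_h'.
#'
#' @slot x numeric matrix, one row per sample.
#' @slot labels integer vector of `+1` (cleavage) / `-1` (non-cleavage).
#' @slot indexMap [S4Vectors::DataFrame] mapping feature column index to
#'   `position` (label such as `"P3"` or `"P2'"`) and `component` (VHSE
#'   component number).
#' @slot scaled logical; `TRUE` once min-max scaling has been applied.
#'
#' @export
setClass("CleavageFeatures",
  representation(
    x        = "matrix",
    labels   = "integer",
    indexMap = "DataFrame",
    scaled   = "logical"
  )
)

setValidity("CleavageFeatures", function(object) {
  msg <- character()
  if (nrow(object@x) != length(object@labels))
    msg <- c(msg, "nrow(x) must equal length(labels)")
  if (length(object@labels) && !all(object@labels %in% c(-1L, 1L)))
    msg <- c(msg, "labels must be +1 or -1")
  if (nrow(object@indexMap) != ncol(object@x))
    msg <- c(msg, "indexMap must have one row per feature column")
  if (!all(c("position", "component") %in% colnames(object@indexMap)))
    msg <- c(msg, "indexMap needs columns 'position' and 'component'")
  if (isTRUE(object@scaled) && length(object@x) &&
      (min(object@x) < -1e-9 || max(object@x) > 1 + 1e-9))
    msg <- c(msg, "scaled features must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' ProteasomeSvm: a trained cleavage-site classifier
#'
#' Soft-margin SVM trained on scaled VHSE features by [trainSvm()].
#' For the linear kernel the explicit weight vector `w` and bias `b` are
#' materialized (`decision(x) = x . w + b` in scaled feature space); for
#' the RBF kernel the support vectors and dual coefficients are stored.
#'
#' @slot kernel `"linear"` or `"rbf"`.
#' @slot C positive cost parameter.
#' @slot gamma positive RBF width (`NA` for linear kernel).
#' @slot epsilon solver termination tolerance.
#' @slot w numeric weight vector (linear kernel; length 0 for RBF).
#' @slot b numeric intercept.
#' @slot supportVectors numeric matrix of support vectors (scaled space).
#' @slot coefs numeric vector of dual coefficients `alpha_i * y_i`.
#' @slot scaler per-feature min/max of the training set (see [fitScaler()]).
#' @slot indexMap feature index -> (position, component) map.
#' @slot halfWidth window half width the model was trained at.
#' @slot selection integer vector of VHSE component numbers used.
#'
#' @export
setClass("ProteasomeSvm",
  representation(
    kernel         = "character",
    C              = "numeric",
    gamma          = "numeric",
    epsilon        = "numeric",
    w              = "numeric",
    b              = "numeric",
    supportVectors = "matrix",
    coefs          = "numeric",
    scaler         = "list",
    indexMap       = "DataFrame",
    halfWidth      = "integer",
    selection      = "integer"
  )
)

setValidity("ProteasomeSvm", function(object) {
  msg <- character()
  if (!object@kernel %in% c("linear", "rbf"))
    msg <- c(msg, "kernel must be 'linear' or 'rbf'")
  if (object@C <= 0) msg <- c(msg, "C must be positive")
  if (object@kernel == "rbf" && (is.na(object@gamma) || object@gamma <= 0))
    msg <- c(msg, "gamma must be positive for the RBF kernel")
  if (object@kernel == "linear" &&
      length(object@w) != nrow(object@indexMap))
    msg <- c(msg, "linear weight vector length must equal feature count")
  if (length(msg)) msg else TRUE
})

#' PositionWeightProfile: per-position per-property weight coefficients
#'
#' The linear model's weight vector reshaped onto the
#' (position, VHSE component) grid by [positionWeights()]; the raw
#' material for cleavage-specificity interpretation.
#'
#' @slot weights numeric matrix; rows are positions P_h ... P1,
#'   P1' ... P_h' (in that order), columns the selected VHSE components
#'   (named `"VHSE1"` etc.).
#' @slot halfWidth window half width.
#' @slot selection integer VHSE component numbers (column order).
#' @slot scaler the model's training scaler, carried along so residue
#'   rankings can be computed in the same feature space the model saw.
#'
#' @export
setClass("PositionWeightProfile",
  representation(
    weights   = "matrix",
    halfWidth = "integer",
    selection = "integer",
    scaler    = "list"
  )
)

setValidity("PositionWeightProfile", function(object) {
  msg <- character()
  if (nrow(object@weights) != 2L * object@halfWidth)
    msg <- c(msg, "weights must have 2 * halfWidth rows")
  if (ncol(object@weights) != length(object@selection))
    msg <- c(msg, "weights must have one column per selected component")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CleavageSampleSet", function(object) {
  n <- nrow(object@samples)
  cat("CleavageSampleSet with", n, "samples (half width",
      object@halfWidth, ")\n")
  if (n) {
    cat("  cleavage:", sum(object@samples$label == "cleavage"),
        " non-cleavage:", sum(object@samples$label == "non_cleavage"),
        "\n")
  }
  if (length(object@dropStats) && sum(object@dropStats) > 0) {
    cat("  dropped:",
        paste(names(object@dropStats), object@dropStats,
              sep = "=", collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "CleavageFeatures", function(object) {
  cat("CleavageFeatures:", nrow(object@x), "samples x",
      ncol(object@x), "features",
      if (isTRUE(object@scaled)) "(scaled to [0,1])" else "(raw)", "\n")
  if (length(object@labels))
    cat("  labels: +1 x", sum(object@labels == 1L),
        ", -1 x", sum(object@labels == -1L), "\n")
  invisible(object)
})

setMethod("show", "ProteasomeSvm", function(object) {
  cat("ProteasomeSvm (", object@kernel, " kernel)\n", sep = "")
  cat("  C =", object@C,
      if (object@kernel == "rbf") paste(" gamma =", object@gamma) else "",
      "\n")
  cat("  features:", nrow(object@indexMap),
      " (half width", object@halfWidth, ", VHSE components",
      paste(object@selection, collapse = ","), ")\n")
  cat("  support vectors:", nrow(object@supportVectors), "\n")
  invisible(object)
})

setMethod("show", "PositionWeightProfile", function(object) {
  cat("PositionWeightProfile:", nrow(object@weights), "positions x",
      ncol(object@weights), "components\n")
  top <- which(object@weights == max(object@weights), arr.ind = TRUE)[1, ]
  cat("  largest weight", format(max(object@weights), digits = 4), "at (",
      rownames(object@weights)[top[1]], ",",
      colnames(object@weights)[top[2]], ")\n")
  invisible(object)
})

#' @export
setMethod("length", "CleavageSampleSet",
          function(x) nrow(x@samples))

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
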