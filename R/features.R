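# Feature construction: sample windows -> raw descriptor matrix -> [0,1]
# scaled matrix. The scaler is a per-feature min-max affine map fit on
# the training set; unseen values are clipped back into [0,1] and
# constant training features map to 0.

.indexMapFor <- function(halfWidth, selection) {
  pos <- positionLabels(halfWidth)
  S4Vectors::DataFrame(
    feature = paste0(rep(pos, each = length(selection)), "_VHSE",
                     rep(selection, times = length(pos))),
    position = rep(pos, each = length(selection)),
    component = rep(as.integer(selection), times = length(pos)))
}

#' Encode a sample set into a raw descriptor matrix
#'
#' Each window becomes one row of position-major VHSE descriptors; labels
#' are mapped to `+1` (cleavage) / `-1` (non-cleavage).
#'
#' @param sampleSet a [CleavageSampleSet-class].
#' @param selection VHSE component numbers (default `c(1, 3, 5)`).
#' @return a [CleavageFeatures-class] in raw (unscaled) descriptor space.
#' @export
encodeSamples <- function(sampleSet, selection = c(1L, 3L, 5L)) {
  stopifnot(methods::is(sampleSet, "CleavageSampleSet"))
  sel <- componentSelection(selection)
  h <- sampleSet@halfWidth
  imap <- .indexMapFor(h, sel)
  wins <- sampleWindows(sampleSet)
  x <- matrix(0, nrow = length(wins), ncol = nrow(imap),
              dimnames = list(NULL, imap$feature))
  for (i in seq_along(wins)) x[i, ] <- encodeWindow(wins[i], sel)
  labs <- ifelse(sampleLabels(sampleSet) == "cleavage", 1L, -1L)
  methods::new("CleavageFeatures", x = x, labels = as.integer(labs),
               indexMap = imap, scaled = FALSE)
}

#' Fit a per-feature min-max scaler
#'
#' Records the per-feature minimum and maximum of the training matrix;
#' [applyScaler()] maps training min to 0 and training max to 1.
#'
#' @param features a [CleavageFeatures-class] or numeric matrix.
#' @return an object of class `"vhseScaler"`: list with numeric vectors
#'   `min` and `max`.
#' @export
fitScaler <- function(features) {
  x <- if (methods::is(features, "CleavageFeatures")) features@x
       else as.matrix(features)
  if (nrow(x) < 1L) stop("need at least one row to fit a scaler",
                         call. = FALSE)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "vhseScaler")
}

#' Apply a min-max scaler
#'
#' Applies the affine map `(v - min) / (max - min)` per feature, clips
#' the result into `[0, 1]` (unseen values beyond the training range),
#' and maps constant training features to 0.
#'
#' @param scaler a `"vhseScaler"` from [fitScaler()].
#' @param features a [CleavageFeatures-class] or numeric matrix with the
#'   same feature dimension as the training set.
#' @return the same type as `features`, scaled.
#' @export
applyScaler <- function(scaler, features) {
  stopifnot(inherits(scaler, "vhseScaler"))
  isFM <- methods::is(features, "CleavageFeatures")
  x <- if (isFM) features@x else as.matrix(features)
  if (ncol(x) != length(scaler$min))
    stop(sprintf("feature dimension mismatch: scaler has %d, input %d",
                 length(scaler$min), ncol(x)), call. = FALSE)
  rng <- scaler$max - scaler$min
  out <- sweep(x, 2, scaler$min, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out[out < 0] <- 0
  out[out > 1] <- 1
  if (isFM)
    methods::new("CleavageFeatures", x = out, labels = features@labels,
                 indexMap = features@indexMap, scaled = TRUE)
  else out
}

#' Write / read a feature matrix as CSV
#'
#' The CSV header row holds the feature names (`"P10_VHSE1"` ...
#' `"P1'_VHSE5"` style) with a final `label` column of `+1`/`-1`.
#'
#' @param features a [CleavageFeatures-class].
#' @param path CSV path.
#' @return `path` (write) or a [CleavageFeatures-class] (read).
#' @export
writeFeatureCsv <- function(features, path) {
  stopifnot(methods::is(features, "CleavageFeatures"))
  df <- as.data.frame(features@x, check.names = FALSE)
  df$label <- features@labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCsv
#' @param scaled logical; mark the loaded matrix as already scaled.
#' @export
readFeatureCsv <- function(path, scaled = FALSE) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% colnames(df))
    stop("feature CSV must have a final 'label' column", call. = FALSE)
  labs <- as.integer(df$label)
  x <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
  imap <- .parseFeatureNames(colnames(x))
  methods::new("CleavageFeatures", x = x, labels = labs, indexMap = imap,
               scaled = scaled)
}

.parseFeatureNames <- function(nm) {
  m <- regmatches(nm, regexec("^(P\\d+'?)_VHSE(\\d)$", nm))
  ok <- lengths(m) == 3L
  if (!all(ok))
    stop("unparseable feature names in CSV header: ",
         paste(utils::head(nm[!ok], 3), collapse = ", "), call. = FALSE)
  S4Vectors::DataFrame(
    feature = nm,
    position = vapply(m, `[`, "", 2L),
    component = as.integer(vapply(m, `[`, "", 3L)))
}
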