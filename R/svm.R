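# Soft-margin SVM training, 10-fold cross-validated hyperparameter
# selection, prediction, and JSON persistence.
#
# The quadratic-programming solver is libsvm (via e1071); everything
# around it — scaling, fold construction, pooled CV metrics, the
# explicit linear weight vector w = sum_i alpha_i y_i x_i, and the
# portable model representation — lives here. Decision values are
# oriented so that positive means cleavage (+1).

.KERNELS <- c("linear", "rbf")

.checkKernel <- function(kernel) {
  if (!is.character(kernel) || length(kernel) != 1L ||
      !kernel %in% .KERNELS)
    stop("'kernel' must be one of: ", paste(.KERNELS, collapse = ", "),
         call. = FALSE)
  kernel
}

#' Train a cleavage-site SVM
#'
#' Fits a C-classification soft-margin SVM on scaled features. The
#' features must already be in `[0, 1]` (see [fitScaler()] /
#' [applyScaler()]); the scaler is attached to the model so new windows
#' can be mapped into the same space. For the linear kernel the explicit
#' weight vector and bias are materialized, which is what makes the model
#' interpretable position-by-position.
#'
#' @param features a scaled [CleavageFeatures-class] containing both
#'   classes.
#' @param kernel `"linear"` (default) or `"rbf"`.
#' @param C positive cost parameter (default 1).
#' @param gamma positive RBF width; required when `kernel = "rbf"`.
#' @param epsilon solver termination tolerance (default `1e-3`).
#' @param scaler the `"vhseScaler"` the features were scaled with; stored
#'   for deployment. If the features are synthetic/already scaled an
#'   identity scaler over `[0, 1]` is constructed.
#' @param halfWidth,selection window geometry; inferred from the feature
#'   index map when possible.
#' @return a [ProteasomeSvm-class].
#' @export
trainSvm <- function(features, kernel = "linear", C = 1, gamma = NULL,
                     epsilon = 1e-3, scaler = NULL, halfWidth = NULL,
                     selection = NULL) {
  stopifnot(methods::is(features, "CleavageFeatures"))
  .checkKernel(kernel)
  if (!is.numeric(C) || length(C) != 1L || is.na(C) || C <= 0)
    stop("'C' must be a single positive number", call. = FALSE)
  if (kernel == "rbf") {
    if (is.null(gamma) || !is.numeric(gamma) || gamma <= 0)
      stop("'gamma' must be a single positive number for the RBF kernel",
           call. = FALSE)
  } else gamma <- NA_real_
  x <- features@x
  y <- features@labels
  if (!all(is.finite(x)))
    stop("features contain non-finite values", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("training requires both cleavage and non-cleavage samples",
         call. = FALSE)

  fit <- e1071::svm(
    x = x, y = factor(y, levels = c(1L, -1L)),
    type = "C-classification", scale = FALSE,
    kernel = if (kernel == "linear") "linear" else "radial",
    cost = C, gamma = if (kernel == "rbf") gamma else 1 / ncol(x),
    tolerance = epsilon)

  sv <- as.matrix(fit$SV)
  co <- as.numeric(fit$coefs)
  rho <- as.numeric(fit$rho)
  # libsvm orients decision values toward the first training class it
  # sees; verify against the fitted labels and flip if needed so that
  # positive decision values always mean cleavage.
  dec <- as.numeric(attr(stats::predict(fit, x, decision.values = TRUE),
                         "decision.values"))
  pred <- as.integer(as.character(stats::predict(fit, x)))
  agree <- sum(sign(dec) == pred & dec != 0)
  flip <- if (agree < sum(dec != 0) / 2) -1 else 1
  co <- flip * co
  b <- -flip * rho

  w <- if (kernel == "linear") as.numeric(crossprod(sv, co)) else numeric()

  if (is.null(scaler))
    scaler <- structure(list(min = rep(0, ncol(x)),
                             max = rep(1, ncol(x))), class = "vhseScaler")
  imap <- features@indexMap
  if (is.null(halfWidth)) {
    up <- !grepl("'", imap$position, fixed = TRUE)
    halfWidth <- length(unique(imap$position[up]))
  }
  if (is.null(selection))
    selection <- sort(unique(imap$component))

  # name Class= explicitly: the C slot would otherwise partially match it
  methods::new(Class = "ProteasomeSvm",
               kernel = kernel, C = as.numeric(C),
               gamma = as.numeric(gamma), epsilon = as.numeric(epsilon),
               w = w, b = b, supportVectors = sv, coefs = co,
               scaler = unclass(scaler), indexMap = imap,
               halfWidth = as.integer(halfWidth),
               selection = as.integer(selection))
}

#' Decision values of a trained model on scaled feature rows
#'
#' `decision(x) = x . w + b` for the linear kernel, or the kernel
#' expansion over support vectors for RBF. Positive values predict
#' cleavage.
#'
#' @param model a [ProteasomeSvm-class].
#' @param x numeric matrix of scaled feature rows.
#' @return numeric vector of decision values.
#' @export
decisionValues <- function(model, x) {
  stopifnot(methods::is(model, "ProteasomeSvm"))
  x <- as.matrix(x)
  p <- nrow(model@indexMap)
  if (ncol(x) != p)
    stop(sprintf("feature dimension mismatch: model has %d, input %d",
                 p, ncol(x)), call. = FALSE)
  if (model@kernel == "linear")
    as.numeric(x %*% model@w + model@b)
  else {
    sv <- model@supportVectors
    sq <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
    K <- exp(-model@gamma * pmax(sq, 0))
    as.numeric(K %*% model@coefs + model@b)
  }
}

#' Predict cleavage for windows or feature rows
#'
#' Accepts residue windows (strings of length `2 * halfWidth`) or a raw
#' descriptor matrix. Windows are encoded with the model's component
#' selection and passed through its training scaler. Windows that cannot
#' be scored (wrong length, non-canonical residues) are flagged in the
#' `status` column with `NA` scores rather than dropped, so row order is
#' preserved.
#'
#' @param model a [ProteasomeSvm-class].
#' @param newdata character vector of windows, a numeric matrix of raw
#'   descriptor rows, or a [CleavageFeatures-class].
#' @return data.frame with columns `decision`, `label` (`+1`/`-1`) and
#'   `status` (`"ok"` or the reason the item was not scored).
#' @export
predictCleavage <- function(model, newdata) {
  stopifnot(methods::is(model, "ProteasomeSvm"))
  scaler <- structure(model@scaler, class = "vhseScaler")
  if (is.character(newdata)) {
    n <- length(newdata)
    dec <- rep(NA_real_, n)
    status <- rep("ok", n)
    xs <- matrix(NA_real_, n, nrow(model@indexMap))
    for (i in seq_len(n)) {
      if (nchar(newdata[i]) != 2L * model@halfWidth) {
        status[i] <- "wrong_length"
        next
      }
      v <- tryCatch(encodeWindow(newdata[i], model@selection),
                    error = function(e) NULL)
      if (is.null(v)) { status[i] <- "non_canonical_residue"; next }
      xs[i, ] <- v
    }
    ok <- status == "ok"
    if (any(ok))
      dec[ok] <- decisionValues(model,
                                applyScaler(scaler,
                                            xs[ok, , drop = FALSE]))
    lab <- ifelse(is.na(dec), NA_integer_, ifelse(dec > 0, 1L, -1L))
    return(data.frame(decision = dec, label = lab, status = status,
                      stringsAsFactors = FALSE))
  }
  x <- if (methods::is(newdata, "CleavageFeatures")) {
    if (isTRUE(newdata@scaled)) newdata@x
    else applyScaler(scaler, newdata@x)
  } else applyScaler(scaler, as.matrix(newdata))
  dec <- decisionValues(model, x)
  data.frame(decision = dec, label = ifelse(dec > 0, 1L, -1L),
             status = "ok", stringsAsFactors = FALSE)
}

# Stratified fold assignment: within each class, indices are shuffled
# once (seeded) and dealt round-robin, so fold sizes and class ratios are
# balanced to within one sample.
.stratifiedFolds <- function(y, folds, seed) {
  fold <- integer(length(y))
  rng <- .seededRng(seed)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[rng$sample(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation over a hyperparameter grid
#'
#' For every (C, gamma) setting, folds are held out in turn, the model is
#' trained on the remainder, and the held-out decision values are pooled
#' over all folds before computing Acc/Sen/Spe/MCC/AUC. The selected
#' setting maximizes pooled CV MCC; ties are broken by higher AUC, then
#' smaller C, then smaller gamma. Deterministic given the seed.
#'
#' @param features a scaled [CleavageFeatures-class].
#' @param kernel `"linear"` or `"rbf"`.
#' @param Cgrid numeric vector of cost values (default `2^seq(-5, 5, 2)`).
#' @param gammaGrid numeric vector of RBF widths (default
#'   `2^seq(-7, 3, 2)`; ignored for the linear kernel).
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold shuffle (default 20130909).
#' @param epsilon solver tolerance passed to [trainSvm()].
#' @return list with `table` (one row per setting with pooled metrics),
#'   `best` (the selected row), and `folds` (the fold assignment).
#' @export
crossValidate <- function(features, kernel = "linear",
                          Cgrid = 2^seq(-5, 5, 2),
                          gammaGrid = 2^seq(-7, 3, 2),
                          folds = 10L, seed = 20130909L,
                          epsilon = 1e-3) {
  stopifnot(methods::is(features, "CleavageFeatures"))
  .checkKernel(kernel)
  folds <- as.integer(folds)
  y <- features@labels
  if (folds < 2L) stop("'folds' must be at least 2", call. = FALSE)
  if (min(table(y)) < folds)
    stop(sprintf("need at least %d samples per class for %d-fold CV",
                 folds, folds), call. = FALSE)
  fold <- .stratifiedFolds(y, folds, seed)
  grid <- if (kernel == "linear")
    data.frame(C = sort(Cgrid), gamma = NA_real_)
  else
    expand.grid(C = sort(Cgrid), gamma = sort(gammaGrid))

  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    dec <- rep(NA_real_, length(y))
    for (f in seq_len(folds)) {
      tr <- fold != f
      sub <- methods::new("CleavageFeatures",
                          x = features@x[tr, , drop = FALSE],
                          labels = y[tr], indexMap = features@indexMap,
                          scaled = features@scaled)
      m <- trainSvm(sub, kernel = kernel, C = grid$C[g],
                    gamma = if (kernel == "rbf") grid$gamma[g] else NULL,
                    epsilon = epsilon)
      dec[!tr] <- decisionValues(m, features@x[!tr, , drop = FALSE])
    }
    pred <- ifelse(dec > 0, 1L, -1L)
    cc <- confusionCounts(y, pred)
    rows[[g]] <- data.frame(
      kernel = kernel, C = grid$C[g], gamma = grid$gamma[g],
      MCC = mccScore(cc), AUC = aucScore(y, dec),
      Acc = accuracy(cc), Sen = sensitivity(cc), Spe = specificity(cc))
  }
  tab <- do.call(rbind, rows)
  ord <- order(-tab$MCC, -tab$AUC, tab$C,
               if (kernel == "rbf") tab$gamma else seq_len(nrow(tab)))
  list(table = tab, best = tab[ord[1], , drop = FALSE], folds = fold)
}

#' Save / load a trained model as JSON
#'
#' The JSON document carries the kernel, hyperparameters, scaler,
#' support vectors and dual coefficients (plus the explicit `w`, `b` for
#' the linear kernel), the feature index map, window geometry, and an
#' optional provenance hash of the training data.
#'
#' @param model a [ProteasomeSvm-class].
#' @param path JSON file path.
#' @param provenance optional character tag (e.g. a training-file hash).
#' @return `path` (save) or a [ProteasomeSvm-class] (load).
#' @export
saveModel <- function(model, path, provenance = NULL) {
  stopifnot(methods::is(model, "ProteasomeSvm"))
  doc <- list(
    format = "procleave-svm-1",
    kernel = model@kernel, C = model@C,
    gamma = if (is.na(model@gamma)) NULL else model@gamma,
    epsilon = model@epsilon, w = model@w, b = model@b,
    support_vectors = model@supportVectors, coefs = model@coefs,
    scaler = model@scaler,
    index_map = as.data.frame(model@indexMap),
    half_width = model@halfWidth, selection = model@selection,
    provenance = provenance)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "procleave-svm-1"))
    stop("not a procleave model file: ", path, call. = FALSE)
  sv <- doc$support_vectors
  if (is.null(sv) || length(sv) == 0L)
    sv <- matrix(numeric(), 0L, length(doc$scaler$min))
  if (!is.matrix(sv)) sv <- matrix(sv, nrow = 1L)
  methods::new(Class = "ProteasomeSvm",
               kernel = doc$kernel, C = doc$C,
               gamma = if (length(doc$gamma) == 1L &&
                           is.numeric(doc$gamma[[1]]))
                 as.numeric(doc$gamma) else NA_real_,
               epsilon = doc$epsilon,
               w = if (is.null(doc$w)) numeric() else as.numeric(doc$w),
               b = doc$b, supportVectors = sv,
               coefs = as.numeric(doc$coefs),
               scaler = list(min = as.numeric(doc$scaler$min),
                             max = as.numeric(doc$scaler$max)),
               indexMap = S4Vectors::DataFrame(doc$index_map),
               halfWidth = as.integer(doc$half_width),
               selection = as.integer(doc$selection))
}
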