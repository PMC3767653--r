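# Interpretation of the linear model: reshaping the weight vector onto
# the (position, VHSE component) grid, ranking residues by their
# contribution at a position, scoring candidate P..|..P' contexts, and
# summarizing the upstream/downstream hydrophobicity contrast.

#' Per-position per-property weights of a linear model
#'
#' Reshapes the explicit weight vector of a linear-kernel
#' [ProteasomeSvm-class] through its feature index map into the
#' (position, component) grid. Flattening the grid row-major (positions
#' upstream to downstream, components in ascending index within each
#' position) reproduces the weight vector exactly.
#'
#' @param model a linear-kernel [ProteasomeSvm-class].
#' @return a [PositionWeightProfile-class].
#' @export
positionWeights <- function(model) {
  stopifnot(methods::is(model, "ProteasomeSvm"))
  if (model@kernel != "linear")
    stop("position weights require a linear-kernel model", call. = FALSE)
  pos <- positionLabels(model@halfWidth)
  sel <- model@selection
  w <- matrix(model@w, nrow = length(pos), ncol = length(sel),
              byrow = TRUE,
              dimnames = list(pos, paste0("VHSE", sel)))
  # sanity: the index map must agree with the position-major layout
  stopifnot(identical(as.character(model@indexMap$position),
                      rep(pos, each = length(sel))),
            identical(as.integer(model@indexMap$component),
                      rep(as.integer(sel), times = length(pos))))
  methods::new("PositionWeightProfile", weights = w,
               halfWidth = model@halfWidth,
               selection = as.integer(sel), scaler = model@scaler)
}

#' Flatten a weight profile back to a weight vector
#'
#' Inverse of [positionWeights()]; index order is position-major.
#'
#' @param profile a [PositionWeightProfile-class].
#' @return numeric vector.
#' @export
flattenProfile <- function(profile) {
  stopifnot(methods::is(profile, "PositionWeightProfile"))
  as.numeric(t(profile@weights))
}

#' Accessor: the weight matrix of a profile
#'
#' @param profile a [PositionWeightProfile-class].
#' @return numeric matrix (positions x components).
#' @export
profileWeights <- function(profile) profile@weights

.featureColumn <- function(profile, position, component) {
  pos <- rownames(profile@weights)
  j <- match(position, pos)
  k <- match(component, profile@selection)
  if (is.na(j)) stop("unknown position label: ", position, call. = FALSE)
  if (is.na(k)) stop("component ", component,
                     " is not in the profile's selection", call. = FALSE)
  (j - 1L) * length(profile@selection) + k
}

# Scale one VHSE constant with the model's training scaler for a given
# feature column; NULL scaler entries of zero range map to 0, matching
# applyScaler(). scaler = NULL means identity (raw descriptor space).
.scaledVhse <- function(value, scaler, column) {
  if (is.null(scaler)) return(value)
  lo <- scaler$min[column]
  hi <- scaler$max[column]
  if (hi <= lo) return(0)
  min(max((value - lo) / (hi - lo), 0), 1)
}

#' Rank residues by their cleavage contribution at a position
#'
#' Scores each canonical residue `a` at position `p` as
#' `score(a, p) = sum_k weight(p, k) * scaledVHSE_k(a)` over the
#' profile's selected components, where `scaledVHSE` passes the
#' descriptor constant through the model's own training scaler (so
#' rankings live in the feature space the model saw). Residues are ranked
#' descending; the top-`k` are the favored, the bottom-`k` the unfavored
#' residues at that position.
#'
#' @param profile a [PositionWeightProfile-class].
#' @param position position label (e.g. `"P1"`, `"P5'"`).
#' @param scaler `NULL` to use the profile's stored training scaler,
#'   `"identity"` to score in raw descriptor space, or a `"vhseScaler"`.
#' @param k number of residues in the favored / unfavored lists
#'   (default 4).
#' @return list with `position`, `ranking` (data.frame `residue`,
#'   `score`, sorted descending), `favored`, `unfavored`, and
#'   `degenerate` (`TRUE` when all scores are 0).
#' @export
residueScores <- function(profile, position, scaler = NULL, k = 4L) {
  stopifnot(methods::is(profile, "PositionWeightProfile"))
  sc <- if (is.null(scaler)) {
    if (length(profile@scaler)) profile@scaler else NULL
  } else if (identical(scaler, "identity")) NULL
  else { stopifnot(inherits(scaler, "vhseScaler")); unclass(scaler) }
  res <- canonicalResidues()
  scores <- vapply(res, function(a) {
    s <- 0
    for (comp in profile@selection) {
      col <- .featureColumn(profile, position, comp)
      s <- s + profile@weights[position, paste0("VHSE", comp)] *
        .scaledVhse(.VHSE[a, comp], sc, col)
    }
    s
  }, numeric(1))
  ord <- order(-scores, res)  # residue code breaks exact ties, stable
  ranking <- data.frame(residue = res[ord], score = scores[ord],
                        row.names = NULL)
  degenerate <- all(scores == 0)
  list(position = position, ranking = ranking,
       favored = ranking$residue[seq_len(min(k, nrow(ranking)))],
       unfavored = rev(ranking$residue)[seq_len(min(k, nrow(ranking)))],
       degenerate = degenerate)
}

#' Favorability score of a candidate cleavage context
#'
#' Sums [residueScores()] contributions over the supplied residues.
#' `upstream` runs outward from the bond (first element is P1, then P2,
#' ...); `downstream` likewise (P1', P2', ...). Either side may be
#' shorter than the profile's half width, or empty. Larger scores mean a
#' more cleavage-favorable context.
#'
#' @param profile a [PositionWeightProfile-class].
#' @param upstream,downstream character vectors of single residues.
#' @param scaler as in [residueScores()].
#' @return single numeric favorability score.
#' @examples
#' # with unit weight at (P1, VHSE1) and -1 at (P1', VHSE1), raw space:
#' # Leu|Lys scores 1.36 - (-1.17) = 2.53, a favorable combination
#' @export
siteScore <- function(profile, upstream = character(),
                      downstream = character(), scaler = NULL) {
  stopifnot(methods::is(profile, "PositionWeightProfile"))
  h <- profile@halfWidth
  if (length(upstream) > h || length(downstream) > h)
    stop("residue lists cannot exceed the profile's half width",
         call. = FALSE)
  sc <- if (is.null(scaler)) {
    if (length(profile@scaler)) profile@scaler else NULL
  } else if (identical(scaler, "identity")) NULL
  else { stopifnot(inherits(scaler, "vhseScaler")); unclass(scaler) }
  contrib <- function(a, position) {
    if (!a %in% canonicalResidues())
      stop(sprintf("no VHSE descriptor available for residue '%s'", a),
           call. = FALSE)
    s <- 0
    for (comp in profile@selection) {
      col <- .featureColumn(profile, position, comp)
      s <- s + profile@weights[position, paste0("VHSE", comp)] *
        .scaledVhse(.VHSE[a, comp], sc, col)
    }
    s
  }
  total <- 0
  for (i in seq_along(upstream))
    total <- total + contrib(upstream[i], paste0("P", i))
  for (i in seq_along(downstream))
    total <- total + contrib(downstream[i], paste0("P", i, "'"))
  total
}

#' Upstream/downstream hydrophobicity contrast of a profile
#'
#' Summarizes the hydrophobic (VHSE1) weight pattern flanking the
#' scissile bond: mean upstream VHSE1 weight minus mean downstream VHSE1
#' weight, with per-side counts of positive and negative weights. A
#' positive contrast says hydrophobic residues upstream and hydrophilic
#' residues downstream jointly favor cleavage.
#'
#' @param profile a [PositionWeightProfile-class] whose selection
#'   includes component 1.
#' @return list with `contrast`, `upstreamMean`, `downstreamMean`,
#'   `upstreamSigns` and `downstreamSigns` (each `c(positive, negative)`).
#' @export
hydrophobicContrast <- function(profile) {
  stopifnot(methods::is(profile, "PositionWeightProfile"))
  if (!1L %in% profile@selection)
    stop("profile does not include VHSE component 1 (hydrophobicity)",
         call. = FALSE)
  w1 <- profile@weights[, "VHSE1"]
  up <- w1[!grepl("'", names(w1), fixed = TRUE)]
  dn <- w1[grepl("'", names(w1), fixed = TRUE)]
  list(contrast = mean(up) - mean(dn),
       upstreamMean = mean(up), downstreamMean = mean(dn),
       upstreamSigns = c(positive = sum(up > 0), negative = sum(up < 0)),
       downstreamSigns = c(positive = sum(dn > 0), negative = sum(dn < 0)))
}

#' Convert a profile to raw-descriptor space
#'
#' Model weights live in the scaled `[0, 1]` feature space; dividing each
#' weight by its feature's training range re-expresses the profile per
#' raw descriptor unit, which makes magnitudes comparable across
#' features with different training spreads.
#'
#' @param profile a [PositionWeightProfile-class].
#' @return a new [PositionWeightProfile-class] in raw-descriptor space
#'   (its stored scaler is cleared to the identity).
#' @export
profileToRawSpace <- function(profile) {
  stopifnot(methods::is(profile, "PositionWeightProfile"))
  sc <- profile@scaler
  if (is.null(sc$min))
    stop("profile carries no scaler; already in raw space?",
         call. = FALSE)
  w <- profile@weights
  for (j in seq_len(nrow(w))) for (k in seq_along(profile@selection)) {
    col <- (j - 1L) * length(profile@selection) + k
    rng <- sc$max[col] - sc$min[col]
    w[j, k] <- if (rng > 0) w[j, k] / rng else 0
  }
  methods::new("PositionWeightProfile", weights = w,
               halfWidth = profile@halfWidth,
               selection = profile@selection, scaler = list())
}

#' Write a weight profile as TSV
#'
#' Rows are positions `P_h ... P_h'`, columns the selected VHSE
#' components; suitable for re-plotting specificity profiles.
#'
#' @param profile a [PositionWeightProfile-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  df <- data.frame(position = rownames(profile@weights),
                   profile@weights, check.names = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write favored/unfavored residue tables as TSV
#'
#' One row per requested position with comma-separated favored and
#' unfavored residues (columns `position`, `favored`, `unfavored`).
#'
#' @param profile a [PositionWeightProfile-class].
#' @param path output TSV path.
#' @param positions position labels to report (default: all).
#' @param k residues per list (default 4).
#' @return `path`, invisibly.
#' @export
writePreferences <- function(profile, path,
                             positions = rownames(profile@weights),
                             k = 4L) {
  rows <- lapply(positions, function(p) {
    rs <- residueScores(profile, p, k = k)
    data.frame(position = p,
               favored = paste(rs$favored, collapse = ","),
               unfavored = paste(rs$unfavored, collapse = ","))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
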