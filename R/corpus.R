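# Corpus construction: from source proteins + ligand/digest records to
# labeled cleavage / non-cleavage window samples.
#
# Each ligand (an MHC-I ligand or an in vitro digest product) is located
# in its source protein. Its C-terminal residue defines the P1 position
# of a cleavage site (the proteasome generates ligand C-termini), and its
# middle residue defines the P1 position of a presumed non-cleavage site.
# The +/- halfWidth residue span around each bond becomes a sample;
# records without full flanking context, with non-canonical residues, or
# duplicating an existing (window, label) pair are dropped with a tallied
# reason.

.DROP_REASONS <- c("peptide_not_found", "insufficient_context",
                   "non_canonical_residue", "duplicate_window",
                   "label_conflict")

.canonicalString <- function(s) {
  !grepl(paste0("[^", paste(rownames(.VHSE), collapse = ""), "]"), s)
}

#' Locate a peptide in its source protein
#'
#' Finds the first exact occurrence of `peptide` in `protein`. When the
#' peptide occurs more than once a warning is emitted and the first
#' occurrence is used (deterministic choice).
#'
#' @param protein,peptide residue strings.
#' @return 0-based start offset of the first occurrence, or `NA_integer_`
#'   when the peptide is absent.
#' @examples
#' locatePeptide("MAAALKSSA", "ALK")  # 3
#' @export
locatePeptide <- function(protein, peptide) {
  stopifnot(is.character(protein), length(protein) == 1L,
            is.character(peptide), length(peptide) == 1L,
            nchar(peptide) >= 1L)
  hits <- gregexpr(peptide, protein, fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(NA_integer_)
  if (length(hits) > 1L)
    warning(sprintf("peptide '%s' occurs %d times; using first occurrence",
                    peptide, length(hits)), call. = FALSE)
  as.integer(hits[1]) - 1L
}

#' Extract the residue window around a scissile bond
#'
#' The window spans `halfWidth` residues on each side of the bond that
#' follows the P1 residue: 0-based protein indices
#' `p1Index - halfWidth + 1` through `p1Index + halfWidth`. It is
#' returned only when the full span exists within the protein.
#'
#' @param protein residue string.
#' @param p1Index 0-based index of the P1 residue in `protein`.
#' @param halfWidth positive integer.
#' @return the window string, or `NA_character_` when the protein does
#'   not provide full context.
#' @export
extractWindow <- function(protein, p1Index, halfWidth) {
  stopifnot(is.character(protein), length(protein) == 1L)
  p1Index <- as.integer(p1Index)
  halfWidth <- as.integer(halfWidth)
  n <- nchar(protein)
  if (is.na(p1Index) || p1Index < 0L || p1Index >= n)
    stop("'p1Index' out of bounds for the protein", call. = FALSE)
  if (is.na(halfWidth) || halfWidth < 1L)
    stop("'halfWidth' must be a positive integer", call. = FALSE)
  lo <- p1Index - halfWidth + 1L
  hi <- p1Index + halfWidth
  if (lo < 0L || hi > n - 1L) return(NA_character_)
  substr(protein, lo + 1L, hi + 1L)
}

#' P1 index of a ligand's cleavage site
#'
#' The ligand C-terminus is the P1 residue of the cleavage that produced
#' it.
#'
#' @param matchOffset 0-based start of the ligand in its source protein.
#' @param peptideLength ligand length in residues.
#' @return 0-based P1 index in the source protein.
#' @export
cleavageSiteOf <- function(matchOffset, peptideLength) {
  as.integer(matchOffset) + as.integer(peptideLength) - 1L
}

#' P1 index of a ligand's presumed non-cleavage site
#'
#' The ligand's middle residue occupies P1; for even lengths the residue
#' just upstream of center is used (`ceiling(L / 2)`), which keeps the
#' non-cleavage bond strictly interior to the peptide.
#'
#' @inheritParams cleavageSiteOf
#' @return 0-based P1 index in the source protein.
#' @export
noncleavageSiteOf <- function(matchOffset, peptideLength) {
  as.integer(matchOffset) +
    as.integer(ceiling(as.integer(peptideLength) / 2)) - 1L
}

.emptySamples <- function() {
  S4Vectors::DataFrame(
    window = character(), label = character(), sourceId = character(),
    peptide = character(), matchOffset = integer(), siteIndex = integer())
}

#' Build a labeled sample set from proteins and ligand records
#'
#' Reproduces the corpus pretreatment: every locatable ligand contributes
#' one cleavage sample (window around its C-terminal bond) and one
#' non-cleavage sample (window around its middle residue), provided the
#' full `halfWidth` flank exists on both sides and the window is
#' canonical. Exact duplicate (window, label) pairs are collapsed; a
#' window carrying both labels keeps only its cleavage copy (positive
#' cleavage evidence outweighs the positional non-cleavage heuristic).
#' Drop reasons are tallied in the returned object's `dropStats`.
#'
#' @param proteins named character vector or [Biostrings::AAStringSet] of
#'   source protein sequences; names are the protein identifiers.
#' @param ligands data.frame with columns `peptide` and `source_id`.
#' @param halfWidth window half width (default 14, the widest span the
#'   corpus is built at; use [trimSamples()] for narrower spans).
#' @return a [CleavageSampleSet-class].
#' @export
buildSampleSet <- function(proteins, ligands, halfWidth = 14L) {
  halfWidth <- as.integer(halfWidth)
  if (length(halfWidth) != 1L || is.na(halfWidth) || halfWidth < 1L)
    stop("'halfWidth' must be a single positive integer", call. = FALSE)
  if (methods::is(proteins, "AAStringSet"))
    proteins <- as.character(proteins)
  if (is.null(names(proteins)) && length(proteins) > 0L)
    stop("'proteins' must be named by protein identifier", call. = FALSE)
  if (!is.data.frame(ligands) ||
      !all(c("peptide", "source_id") %in% colnames(ligands)))
    stop("'ligands' must have columns 'peptide' and 'source_id'",
         call. = FALSE)

  drops <- stats::setNames(integer(length(.DROP_REASONS)), .DROP_REASONS)
  rows <- vector("list", 2L * nrow(ligands))
  k <- 0L
  for (i in seq_len(nrow(ligands))) {
    pep <- as.character(ligands$peptide[i])
    sid <- as.character(ligands$source_id[i])
    prot <- if (sid %in% names(proteins)) proteins[[sid]] else NA_character_
    if (is.na(prot)) {
      drops["peptide_not_found"] <- drops["peptide_not_found"] + 2L
      next
    }
    off <- suppressWarnings(locatePeptide(prot, pep))
    if (is.na(off)) {
      drops["peptide_not_found"] <- drops["peptide_not_found"] + 2L
      next
    }
    sites <- c(cleavage = cleavageSiteOf(off, nchar(pep)),
               non_cleavage = noncleavageSiteOf(off, nchar(pep)))
    for (lab in names(sites)) {
      win <- extractWindow(prot, sites[[lab]], halfWidth)
      if (is.na(win)) {
        drops["insufficient_context"] <- drops["insufficient_context"] + 1L
        next
      }
      if (!.canonicalString(win)) {
        drops["non_canonical_residue"] <-
          drops["non_canonical_residue"] + 1L
        next
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        window = win, label = lab, sourceId = sid, peptide = pep,
        matchOffset = off, siteIndex = sites[[lab]],
        stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(methods::new("CleavageSampleSet", samples = .emptySamples(),
                        halfWidth = halfWidth, dropStats = drops))
  df <- do.call(rbind, rows[seq_len(k)])
  .dedupSamples(df, halfWidth, drops)
}

# Collapse duplicate (window, label) pairs, then resolve windows seen
# under both labels in favor of the cleavage copy.
.dedupSamples <- function(df, halfWidth, drops) {
  dup <- duplicated(paste(df$window, df$label))
  drops["duplicate_window"] <- drops["duplicate_window"] + sum(dup)
  df <- df[!dup, , drop = FALSE]
  conflict <- df$label == "non_cleavage" &
    df$window %in% df$window[df$label == "cleavage"]
  if (any(conflict)) {
    drops["label_conflict"] <- drops["label_conflict"] + sum(conflict)
    df <- df[!conflict, , drop = FALSE]
  }
  methods::new("CleavageSampleSet",
               samples = S4Vectors::DataFrame(df, row.names = NULL),
               halfWidth = halfWidth, dropStats = drops)
}

#' Trim a sample set to a narrower window span
#'
#' Windows are trimmed symmetrically about the scissile bond, so a
#' `+/-14` corpus yields the `+/-6 ... +/-12` corpora without revisiting
#' the source proteins. Trimming can create new duplicates or
#' label conflicts among the shorter windows; these are re-resolved under
#' the same rules as [buildSampleSet()].
#'
#' @param sampleSet a [CleavageSampleSet-class].
#' @param newHalfWidth target half width, at most the current one.
#' @return a new [CleavageSampleSet-class].
#' @export
trimSamples <- function(sampleSet, newHalfWidth) {
  stopifnot(methods::is(sampleSet, "CleavageSampleSet"))
  newHalfWidth <- as.integer(newHalfWidth)
  h <- sampleSet@halfWidth
  if (length(newHalfWidth) != 1L || is.na(newHalfWidth) ||
      newHalfWidth < 1L || newHalfWidth > h)
    stop("'newHalfWidth' must be in 1..halfWidth of the sample set",
         call. = FALSE)
  if (newHalfWidth == h) return(sampleSet)
  df <- as.data.frame(sampleSet@samples)
  drops <- sampleSet@dropStats
  if (nrow(df) == 0L)
    return(methods::new("CleavageSampleSet", samples = .emptySamples(),
                        halfWidth = newHalfWidth, dropStats = drops))
  cut <- h - newHalfWidth
  df$window <- substr(df$window, cut + 1L, cut + 2L * newHalfWidth)
  .dedupSamples(df, newHalfWidth, drops)
}

#' Accessors for CleavageSampleSet
#'
#' `sampleWindows()`, `sampleLabels()` and `sampleInfo()` return the
#' window strings, the labels (`"cleavage"`/`"non_cleavage"`), and the
#' full per-sample [S4Vectors::DataFrame]; `dropStats()` the tally of
#' dropped records by reason.
#'
#' @param x a [CleavageSampleSet-class].
#' @return see above.
#' @name sample-accessors
NULL

#' @rdname sample-accessors
#' @export
sampleWindows <- function(x) x@samples$window

#' @rdname sample-accessors
#' @export
sampleLabels <- function(x) x@samples$label

#' @rdname sample-accessors
#' @export
sampleInfo <- function(x) x@samples

#' @rdname sample-accessors
#' @export
dropStats <- function(x) x@dropStats

#' Read ligand records from TSV
#'
#' Expects a header line `peptide<TAB>source_id`.
#'
#' @param path TSV file path.
#' @return data.frame with columns `peptide`, `source_id`.
#' @export
readLigands <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("peptide", "source_id") %in% colnames(df)))
    stop("ligand TSV must have columns 'peptide' and 'source_id'",
         call. = FALSE)
  df
}

#' Read source proteins from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of protein sequences.
#' @export
readProteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  # FASTA headers may carry descriptions; the identifier is the first word
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a sample set (and its drop log) as TSV
#'
#' The samples TSV has header
#' `window<TAB>label<TAB>source_id<TAB>site_index_1based`; coordinates are
#' 1-based in this human-facing report. The optional drop log is a
#' `reason<TAB>count` TSV.
#'
#' @param sampleSet a [CleavageSampleSet-class].
#' @param path output TSV path.
#' @param dropLogPath optional path for the drop-reason tally.
#' @return `path`, invisibly.
#' @export
writeSamples <- function(sampleSet, path, dropLogPath = NULL) {
  stopifnot(methods::is(sampleSet, "CleavageSampleSet"))
  df <- as.data.frame(sampleSet@samples)
  out <- data.frame(window = df$window, label = df$label,
                    source_id = df$sourceId,
                    site_index_1based = df$siteIndex + 1L)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dropLogPath)) {
    dl <- data.frame(reason = names(sampleSet@dropStats),
                     count = as.integer(sampleSet@dropStats))
    utils::write.table(dl, dropLogPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a samples TSV back into a CleavageSampleSet
#'
#' Inverse of [writeSamples()] up to the provenance columns that the TSV
#' does not carry (`peptide`, `matchOffset` are set to placeholders).
#'
#' @param path samples TSV path.
#' @return a [CleavageSampleSet-class].
#' @export
readSamples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("window", "label", "source_id", "site_index_1based")
  if (!all(need %in% colnames(df)))
    stop("samples TSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("samples TSV is empty; cannot infer half width", call. = FALSE)
  len <- unique(nchar(df$window))
  if (length(len) != 1L || len %% 2L != 0L)
    stop("windows must share one even length", call. = FALSE)
  samples <- S4Vectors::DataFrame(
    window = df$window, label = df$label, sourceId = df$source_id,
    peptide = NA_character_, matchOffset = NA_integer_,
    siteIndex = as.integer(df$site_index_1based) - 1L)
  drops <- stats::setNames(integer(length(.DROP_REASONS)), .DROP_REASONS)
  methods::new("CleavageSampleSet", samples = samples,
               halfWidth = as.integer(len %/% 2L), dropStats = drops)
}
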