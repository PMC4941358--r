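#' Canonical dipeptide names
#'
#' The 400 ordered residue pairs in canonical order: alphabetical by
#' one-letter code, first residue major, second residue minor
#' (AA, AC, AD, ..., YY).
#'
#' @return Character vector of length 400.
#' @export
dipeptideNames <- function() {
  as.vector(t(outer(STANDARD_AA, STANDARD_AA, paste0)))
}

#' Canonical index of an ordered dipeptide
#'
#' Maps an ordered residue pair to its 0-based position u in the canonical
#' dipeptide ordering: \code{u = 20 * rank(first) + rank(second)} with
#' residues ranked alphabetically (A = 0, ..., Y = 19). The map is a
#' bijection onto [0, 399]; (A, A) -> 0, (A, C) -> 1, (Y, Y) -> 399.
#' Column positions in emitted feature matrices are this u (0-based), while
#' residue positions within a peptide are 1-based in all documentation.
#'
#' @param first,second One-letter codes of the first and second residue;
#'   vectorized.
#' @return Integer vector of 0-based indices.
#' @export
dipeptideIndex <- function(first, second) {
  i <- match(first, STANDARD_AA)
  j <- match(second, STANDARD_AA)
  if (anyNA(i) || anyNA(j))
    stop("non-standard residue: ",
         paste(unique(c(first[is.na(i)], second[is.na(j)])), collapse = ", "),
         call. = FALSE)
  as.integer(20L * (i - 1L) + (j - 1L))
}

.aaIndex <- function(chars) {
  i <- match(chars, STANDARD_AA)
  if (anyNA(i))
    stop("non-standard residue: ",
         paste(unique(chars[is.na(i)]), collapse = ", "), call. = FALSE)
  i
}

#' g-gap dipeptide composition of a peptide
#'
#' Encodes a peptide of length L as the 400-component frequency vector of
#' its g-gap dipeptides: for each position i in [1, L-g-1] the ordered pair
#' (R_i, R_{i+g+1}) — the two residues separated by g intervening residues —
#' increments its count n_u, and components are the normalized frequencies
#' d_u = n_u / (L - g - 1). With g = 0 this is the ordinary (proximate)
#' dipeptide composition. Components are non-negative and sum to 1.
#'
#' @param p A single peptide: character string, \code{AAString}, or an
#'   \code{AAStringSet} of length 1.
#' @param g Gap parameter, an integer in [0, 4].
#' @return Named numeric vector of length 400 (canonical dipeptide order).
#' @examples
#' ggapComposition("ACACA", g = 1)[c("AA", "CC")]  # 2/3, 1/3
#' @export
ggapComposition <- function(p, g) {
  g <- as.integer(g)
  if (length(g) != 1L || is.na(g) || g < 0L || g > 4L)
    stop("g must be an integer in [0, 4]", call. = FALSE)
  s <- as.character(p)
  if (length(s) != 1L) stop("p must be a single peptide", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  L <- length(chars)
  npairs <- L - g - 1L
  if (npairs < 1L)
    stop(sprintf("peptide too short for gap g: L = %d, g = %d (need L >= g + 2)",
                 L, g), call. = FALSE)
  i1 <- .aaIndex(chars[seq_len(npairs)])
  i2 <- .aaIndex(chars[seq_len(npairs) + g + 1L])
  u <- 20L * (i1 - 1L) + i2                    # 1-based canonical index
  d <- tabulate(u, nbins = 400L) / npairs
  names(d) <- dipeptideNames()
  d
}

#' Amino acid composition of a peptide
#'
#' The 20-component vector of normalized residue frequencies
#' f_i = count(residue i) / L, in the canonical alphabetical residue order.
#' All sequence-order information is discarded by this encoding.
#'
#' @param p A single peptide (character string or \code{AAString}).
#' @return Named numeric vector of length 20, summing to 1.
#' @export
aacComposition <- function(p) {
  s <- as.character(p)
  if (length(s) != 1L) stop("p must be a single peptide", call. = FALSE)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) < 1L) stop("empty peptide", call. = FALSE)
  f <- tabulate(.aaIndex(chars), nbins = 20L) / length(chars)
  names(f) <- STANDARD_AA
  f
}

#' Encode a peptide dataset as a feature matrix
#'
#' Applies \code{\link{ggapComposition}} or \code{\link{aacComposition}} to
#' every peptide of a \code{LabeledPeptides} object (or \code{AAStringSet}),
#' producing a \code{\link{PeptideFeatures}} matrix with one row per peptide
#' in dataset order. Peptides too short for the encoding (L < g + 2 under
#' g-gap) abort under \code{policy = "strict"} or are dropped with a warning
#' under \code{policy = "skip"}; dropped identifiers are recorded in the
#' result.
#'
#' @param x A \code{\link{LabeledPeptides}} or \code{AAStringSet}.
#' @param encoding \code{"ggap"} (default) or \code{"aac"}.
#' @param g Gap parameter for \code{"ggap"}.
#' @param policy \code{"strict"} or \code{"skip"}.
#' @return A \code{\link{PeptideFeatures}} object. When rows are dropped
#'   under \code{"skip"} and \code{x} is labeled, the corresponding labels
#'   are attached as attribute \code{"label"} of the result's matrix rows via
#'   \code{droppedLabels}; use \code{\link{encodedLabels}} to retrieve labels
#'   aligned with the returned rows.
#' @export
encodePeptides <- function(x, encoding = c("ggap", "aac"), g = 1L,
                           policy = c("strict", "skip")) {
  encoding <- match.arg(encoding)
  policy <- match.arg(policy)
  seqs <- if (is(x, "LabeledPeptides")) x@peptides else Biostrings::AAStringSet(x)
  if (length(seqs) == 0L) stop("no peptides to encode", call. = FALSE)
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs)) else names(seqs)
  g <- as.integer(g)
  if (encoding == "ggap") {
    minLen <- g + 2L
    short <- Biostrings::width(seqs) < minLen
  } else {
    short <- Biostrings::width(seqs) < 1L
  }
  if (any(short)) {
    msg <- sprintf("%d peptide(s) too short for encoding %s%s: %s",
                   sum(short), encoding,
                   if (encoding == "ggap") sprintf(" (g = %d)", g) else "",
                   paste(utils::head(ids[short], 10), collapse = ", "))
    if (policy == "strict") stop(msg, call. = FALSE)
    warning("dropped ", msg, call. = FALSE)
  }
  keep <- which(!short)
  if (length(keep) == 0L)
    stop("all peptides dropped during encoding", call. = FALSE)
  enc1 <- if (encoding == "ggap") function(s) ggapComposition(s, g) else
    aacComposition
  mat <- t(vapply(as.character(seqs)[keep], enc1,
                  numeric(if (encoding == "ggap") 400L else 20L)))
  rownames(mat) <- ids[keep]
  obj <- new("PeptideFeatures", values = mat, encoding = encoding,
             g = if (encoding == "ggap") g else NA_integer_,
             dropped = ids[short])
  if (is(x, "LabeledPeptides"))
    attr(obj, "label") <- factor(as.character(x@label[keep]),
                                 levels = .ACP_LEVELS)
  obj
}

#' Labels aligned with the rows of an encoded feature matrix
#'
#' @param features A \code{\link{PeptideFeatures}} built from a
#'   \code{LabeledPeptides} object.
#' @return Factor of class labels, one per feature-matrix row.
#' @export
encodedLabels <- function(features) {
  lab <- attr(features, "label")
  if (is.null(lab))
    stop("features were not encoded from a labeled dataset", call. = FALSE)
  lab
}

#' Write a feature matrix as TSV
#'
#' First column \code{id}, then one column per feature headed by its
#' dipeptide (or residue) name; values with 6 decimal places.
#'
#' @param features A \code{\link{PeptideFeatures}} object.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFeatureMatrix <- function(features, path) {
  v <- featureValues(features)
  df <- data.frame(id = rownames(v),
                   format(round(v, 6), nsmall = 6, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  writeTable(df, path)
}
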