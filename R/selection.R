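#' One-way ANOVA F-value per feature
#'
#' For each feature column, computes the classical one-way ANOVA
#' decomposition across the two classes: the between-group mean square
#' \deqn{MSB = \frac{1}{K-1} \sum_i m_i (\bar{x}_i - \bar{x})^2,}
#' the within-group mean square
#' \deqn{MSW = \frac{1}{M-K} \sum_i \sum_j (x_{ij} - \bar{x}_i)^2,}
#' and their ratio \eqn{F = MSB / MSW}, with degrees of freedom
#' \eqn{df_B = K - 1} and \eqn{df_W = M - K}. A large F marks a feature
#' whose class means differ far more than its within-class scatter; for
#' K = 2, F equals the square of the pooled-variance two-sample t
#' statistic.
#'
#' Degenerate features: MSW = 0 with MSB > 0 (a perfectly separating
#' feature) yields the \code{Inf} sentinel, ranked above every finite F;
#' a constant feature (both zero) yields F = 0.
#'
#' The \code{direction} column records the class polarity of each feature:
#' +1 when the positive-class mean exceeds the negative-class mean
#' (feature enriched in ACPs), -1 when smaller, 0 when equal.
#'
#' @param x Features: \code{\link{PeptideFeatures}} or numeric matrix
#'   (samples in rows).
#' @param label Class labels (taken from \code{x} when encoded from a
#'   labeled dataset).
#' @return An \code{\link{FScoreResults}} object.
#' @export
anovaFScores <- function(x, label = NULL) {
  if (is.null(label) && is(x, "PeptideFeatures")) label <- attr(x, "label")
  label <- .asLabel(label)
  X <- .featMat(x)
  pos <- label == "ACP"
  m1 <- sum(pos); m2 <- sum(!pos); M <- m1 + m2; K <- 2L
  if (m1 < 1L || m2 < 1L)
    stop("both groups must be non-empty", call. = FALSE)
  if (M - K < 1L)
    stop("need M >= 3 samples so that dfW >= 1", call. = FALSE)
  Xp <- X[pos, , drop = FALSE]; Xn <- X[!pos, , drop = FALSE]
  mp <- colMeans(Xp); mn <- colMeans(Xn)
  grand <- (m1 * mp + m2 * mn) / M
  dfB <- K - 1L; dfW <- M - K
  msb <- (m1 * (mp - grand)^2 + m2 * (mn - grand)^2) / dfB
  msw <- (colSums(sweep(Xp, 2, mp)^2) + colSums(sweep(Xn, 2, mn)^2)) / dfW
  F <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  dir <- sign(mp - mn)
  tab <- data.frame(feature = colnames(X) %||% as.character(seq_len(ncol(X))),
                    F = unname(F), MSB = unname(msb), MSW = unname(msw),
                    direction = as.integer(dir), stringsAsFactors = FALSE)
  new("FScoreResults", table = tab, dfB = dfB, dfW = dfW,
      encoding = if (is(x, "PeptideFeatures")) x@encoding else "raw",
      g = if (is(x, "PeptideFeatures")) x@g else NA_integer_)
}

#' Rank features by descending F-value
#'
#' Orders features from most to least class-relevant. \code{Inf} sentinels
#' (perfect separators) come first; ties break deterministically by
#' ascending canonical feature index, so the ranking is stable across
#' repeated runs on identical input.
#'
#' @param fscores An \code{\link{FScoreResults}} object (or numeric vector
#'   of F-values).
#' @return Integer permutation of \code{seq_len(nFeatures)}: 1-based column
#'   indices in descending-F order.
#' @export
rankFeatures <- function(fscores) {
  F <- if (is(fscores, "FScoreResults")) fscores@table$F else as.numeric(fscores)
  order(-F, seq_along(F))
}

#' Incremental feature selection over an F-ranked feature list
#'
#' Grows the feature set one feature at a time down the ranking: for each
#' prefix size tau = 1..Omega an RBF-SVM is trained and evaluated by
#' pooled stratified k-fold cross-validation under ONE fold partition,
#' fixed once from \code{seed}, so the curve varies only with tau. The
#' curve is computed for every tau (it may dip and recover, so no early
#' stopping); Theta is the smallest tau attaining the maximum accuracy.
#'
#' @param x Features (\code{PeptideFeatures} or matrix).
#' @param label Class labels (taken from \code{x} when labeled).
#' @param ranking Feature ranking from \code{\link{rankFeatures}}
#'   (computed from \code{\link{anovaFScores}} on the full data when
#'   omitted); must be a permutation of all feature columns.
#' @param k,seed,stratified Cross-validation settings (default 5-fold,
#'   stratified).
#' @param C,gamma SVM hyperparameters, fixed across all tau (no per-tau
#'   re-tuning).
#' @param folds Optional pre-built fold assignment, e.g. to share one
#'   partition across several encodings.
#' @param scale Min-max scale features per training fold (default TRUE).
#' @return An \code{\link{IFSRun}}.
#' @export
runIFS <- function(x, label = NULL, ranking = NULL, k = 5L, seed = 1L,
                   stratified = TRUE, C = 2, gamma = 0.125, folds = NULL,
                   scale = TRUE) {
  if (is.null(label) && is(x, "PeptideFeatures")) label <- attr(x, "label")
  label <- .asLabel(label)
  X <- .featMat(x)
  p <- ncol(X)
  if (is.null(ranking)) ranking <- rankFeatures(anovaFScores(X, label))
  ranking <- as.integer(ranking)
  if (!identical(sort(ranking), seq_len(p)))
    stop("ranking must be a permutation of all ", p, " feature columns",
         call. = FALSE)
  if (is.null(folds)) folds <- makeFolds(label, k, seed, stratified)
  curve <- matrix(NA_real_, nrow = p, ncol = 4,
                  dimnames = list(NULL, c("Sn", "Sp", "Acc", "MCC")))
  for (tau in seq_len(p)) {
    pred <- .cvPredict(X, label, ranking[seq_len(tau)], folds, C, gamma,
                       scale)
    curve[tau, ] <- computeMetrics(confusionCounts(label, pred))
  }
  curve <- data.frame(tau = seq_len(p), curve)
  peak <- max(curve$Acc)
  th <- which(curve$Acc >= peak - 1e-12)[1]      # ties -> smallest tau
  new("IFSRun", curve = curve, theta = as.integer(th), peakAcc = peak,
      ranking = ranking,
      g = if (is(x, "PeptideFeatures")) x@g else NA_integer_)
}

#' Select the best gap parameter by comparing IFS peaks
#'
#' Runs the full selection pipeline — g-gap encoding, ANOVA F ranking,
#' incremental feature selection — for each candidate g under the SAME
#' cross-validation fold partition, and returns the g whose IFS curve
#' peaks highest (ties resolve to the smaller g).
#'
#' @param ds A \code{\link{LabeledPeptides}} dataset.
#' @param gValues Candidate gaps (default 0:4).
#' @param k,seed,stratified Cross-validation settings shared by all runs.
#' @param C,gamma SVM hyperparameters.
#' @param policy Encoding policy for peptides too short for large gaps.
#' @param scale Min-max scale features per training fold (default TRUE).
#' @return A list with \code{g} (the winner), \code{best} (its
#'   \code{\link{IFSRun}}), and \code{runs} (named list of all IFS runs).
#' @export
selectBestG <- function(ds, gValues = 0:4, k = 5L, seed = 1L,
                        stratified = TRUE, C = 2, gamma = 0.125,
                        policy = c("strict", "skip"), scale = TRUE) {
  stopifnot(is(ds, "LabeledPeptides"))
  policy <- match.arg(policy)
  folds <- makeFolds(classLabels(ds), k, seed, stratified)
  runs <- list()
  for (g in gValues) {
    feats <- encodePeptides(ds, encoding = "ggap", g = g, policy = policy)
    lab <- encodedLabels(feats)
    # records too short for this g were dropped: restrict the shared
    # partition to the rows that were kept (positional, ids are not keys)
    keep <- Biostrings::width(peptides(ds)) >= g + 2L
    useFolds <- folds[keep]
    rank <- rankFeatures(anovaFScores(feats, lab))
    runs[[paste0("g", g)]] <- runIFS(feats, lab, ranking = rank, C = C,
                                     gamma = gamma, folds = useFolds,
                                     scale = scale)
  }
  peaks <- vapply(runs, function(r) r@peakAcc, numeric(1))
  best <- which(peaks >= max(peaks) - 1e-12)[1]  # ties -> smaller g
  list(g = gValues[best], best = runs[[best]], runs = runs)
}

#' Signed F-score matrix of the 400 g-gap dipeptides
#'
#' Arranges the per-dipeptide F-values as a 20 x 20 matrix — rows are the
#' first residue, columns the second, both alphabetical — with each entry
#' signed by the class polarity of the feature: positive when the
#' dipeptide is enriched in anticancer peptides, negative when enriched in
#' the negative class. This is the matrix behind the usual heat-map view
#' of which residue pairings carry the discrimination.
#'
#' @param fscores An \code{\link{FScoreResults}} built from a 400-feature
#'   g-gap matrix.
#' @return A 20 x 20 numeric matrix with residue-letter dimnames.
#' @export
signedFMatrix <- function(fscores) {
  stopifnot(is(fscores, "FScoreResults"))
  tab <- fscores@table
  if (nrow(tab) != 400L)
    stop("signed F matrix requires a 400-feature (g-gap) score table",
         call. = FALSE)
  m <- matrix(tab$direction * tab$F, nrow = 20, ncol = 20, byrow = TRUE,
              dimnames = list(STANDARD_AA, STANDARD_AA))
  m
}

#' Write selection artifacts as TSV
#'
#' \code{writeFScoreTable} writes columns feature, F, MSB, MSW, direction,
#' rank; \code{writeIFSCurve} writes tau, Sn, Sp, Acc, MCC;
#' \code{writeSignedMatrix} writes the 20 x 20 signed matrix with residue
#' headers.
#'
#' @param fscores An \code{\link{FScoreResults}}.
#' @param run An \code{\link{IFSRun}}.
#' @param m Matrix from \code{\link{signedFMatrix}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeFScoreTable <- function(fscores, path) {
  tab <- fscores@table
  rk <- rankFeatures(fscores)
  tab$rank <- integer(nrow(tab))
  tab$rank[rk] <- seq_len(nrow(tab))
  writeTable(tab, path)
}

#' @rdname writeFScoreTable
#' @export
writeIFSCurve <- function(run, path) {
  stopifnot(is(run, "IFSRun"))
  writeTable(run@curve, path)
}

#' @rdname writeFScoreTable
#' @export
writeSignedMatrix <- function(m, path) {
  df <- data.frame(residue = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTable(df, path)
}
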