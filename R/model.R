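.MODEL_VERSION <- "ggapACP-model-1"

.featMat <- function(x) {
  if (is(x, "PeptideFeatures")) return(featureValues(x))
  if (is.matrix(x)) return(x)
  stop("expected a PeptideFeatures object or a numeric matrix", call. = FALSE)
}

.asLabel <- function(label) {
  label <- factor(as.character(label), levels = .ACP_LEVELS)
  if (anyNA(label)) stop("labels must be \"ACP\" or \"non-ACP\"", call. = FALSE)
  label
}

# Decision values from an e1071 prediction, oriented so that positive values
# vote for the positive class ("ACP"). libsvm's sign convention depends on
# the order classes were seen in training, recorded in the column name.
.orientedDV <- function(pred) {
  dv <- attr(pred, "decision.values")
  voted <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  d <- as.numeric(dv[, 1])
  if (voted != "ACP") d <- -d
  d
}

.fitSVM <- function(X, label, C, gamma) {
  e1071::svm(x = X, y = label, kernel = "radial", cost = C, gamma = gamma,
             scale = FALSE, probability = FALSE)
}

# Per-feature min-max scaling to [-1, 1], fitted on training data only and
# re-applied verbatim at prediction (the standard libsvm svm-scale step).
# Features constant in training map to -1 everywhere.
.fitScaler <- function(X) {
  mn <- apply(X, 2, min)
  r <- apply(X, 2, max) - mn
  r[r == 0] <- 1
  list(min = mn, range = r)
}

.applyScaler <- function(X, s) {
  if (is.null(s) || length(s) == 0L) return(X)
  sweep(sweep(X, 2, s$min), 2, s$range, "/") * 2 - 1
}

.predictLabels <- function(fit, X) {
  if (nrow(X) == 0L)
    return(list(label = factor(character(), levels = .ACP_LEVELS),
                dv = numeric()))
  pred <- predict(fit, X, decision.values = TRUE)
  d <- .orientedDV(pred)
  # exact ties on the decision boundary resolve to the positive class
  list(label = factor(ifelse(d >= 0, "ACP", "non-ACP"), levels = .ACP_LEVELS),
       dv = d)
}

#' Build a cross-validation fold assignment
#'
#' Returns one fold id per sample. With \code{stratified = TRUE} (default)
#' each class is permuted separately and dealt round-robin across the k
#' folds, so fold class ratios track the dataset's. The permutation is fixed
#' by \code{seed} and does not disturb the caller's RNG state. With
#' \code{k >= M} every sample gets its own fold (the leave-one-out limit).
#'
#' @param label Class label factor/vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed fixing the partition.
#' @param stratified Stratify by class (default \code{TRUE}).
#' @return Integer vector of fold ids in [1, k].
#' @export
makeFolds <- function(label, k, seed = 1L, stratified = TRUE) {
  label <- .asLabel(label)
  M <- length(label)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k >= M) return(seq_len(M))
  withSeed(seed, {
    fold <- integer(M)
    if (stratified) {
      for (cl in levels(label)) {
        idx <- which(label == cl)
        fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(M)] <- rep_len(seq_len(k), M)
    }
    fold
  })
}

# Pooled cross-validated predictions under a fixed fold assignment. The
# feature scaler is refitted on each training fold (no leakage).
.cvPredict <- function(X, label, subset, foldid, C, gamma, scale = TRUE) {
  M <- nrow(X)
  out <- factor(rep(NA_character_, M), levels = .ACP_LEVELS)
  Xs <- X[, subset, drop = FALSE]
  for (f in unique(foldid)) {
    test <- foldid == f
    ytr <- label[!test]
    if (length(unique(ytr)) < 2L)
      stop("training fold lost a class; use stratified folds or smaller k",
           call. = FALSE)
    Xtr <- Xs[!test, , drop = FALSE]
    s <- if (scale) .fitScaler(Xtr) else NULL
    fit <- .fitSVM(.applyScaler(Xtr, s), droplevels(ytr), C, gamma)
    out[test] <- .predictLabels(fit,
                                .applyScaler(Xs[test, , drop = FALSE], s))$label
  }
  out
}

.resolveSubset <- function(subset, p) {
  if (is.null(subset)) subset <- seq_len(p)
  subset <- as.integer(subset)
  if (length(subset) == 0L || anyNA(subset) ||
      any(subset < 1L | subset > p))
    stop("subset must be non-empty 1-based indices within [1, ", p, "]",
         call. = FALSE)
  subset
}

#' Train an RBF-kernel SVM anticancer peptide classifier
#'
#' Fits a soft-margin support vector machine with radial basis kernel
#' \eqn{\exp(-\gamma \|x - y\|^2)} on the selected feature columns. By
#' default each feature is min-max scaled to [-1, 1] using ranges fitted on
#' the training data (the standard libsvm preprocessing step); the scaler is
#' stored in the model and re-applied verbatim at prediction. Composition
#' frequencies are so small in absolute terms that without this step the RBF
#' kernel at \code{gamma = 0.125} is nearly constant and the classifier
#' degenerates to majority voting. Training is deterministic given identical
#' inputs. Default hyperparameters are \code{C = 2}, \code{gamma = 0.125}.
#'
#' @param x A \code{\link{LabeledPeptides}} object (encoded internally), a
#'   \code{\link{PeptideFeatures}} object, or a numeric matrix.
#' @param label Class labels; taken from \code{x} when it is labeled.
#' @param subset 1-based feature column indices to train on
#'   (default: all columns).
#' @param encoding,g Encoding used when \code{x} is a
#'   \code{LabeledPeptides} object.
#' @param C,gamma SVM regularization and RBF kernel width (both > 0).
#' @param scale Min-max scale features to [-1, 1] on the training data
#'   (default \code{TRUE}).
#' @return An \code{\link{ACPModel}}.
#' @export
trainACP <- function(x, label = NULL, subset = NULL,
                     encoding = c("ggap", "aac"), g = 1L,
                     C = 2, gamma = 0.125, scale = TRUE) {
  stopifnot(C > 0, gamma > 0)
  trainSeqs <- character()
  if (is(x, "LabeledPeptides")) {
    encoding <- match.arg(encoding)
    trainSeqs <- as.character(x@peptides)
    feats <- encodePeptides(x, encoding = encoding, g = g)
    label <- encodedLabels(feats)
    X <- featureValues(feats)
    enc <- encoding; gg <- if (encoding == "ggap") as.integer(g) else NA_integer_
  } else {
    if (is.null(label) && is(x, "PeptideFeatures"))
      label <- attr(x, "label")
    if (is.null(label)) stop("label is required", call. = FALSE)
    X <- .featMat(x)
    enc <- if (is(x, "PeptideFeatures")) x@encoding else "raw"
    gg <- if (is(x, "PeptideFeatures")) x@g else NA_integer_
  }
  label <- .asLabel(label)
  if (length(unique(label)) < 2L)
    stop("training data must contain both classes", call. = FALSE)
  subset <- .resolveSubset(subset, ncol(X))
  Xs <- X[, subset, drop = FALSE]
  s <- if (scale) .fitScaler(Xs) else list()
  fit <- .fitSVM(.applyScaler(Xs, s), label, C, gamma)
  new("ACPModel", fit = fit, subset = subset, encoding = enc, g = gg,
      featureNames = colnames(X) %||% as.character(seq_len(ncol(X))),
      cost = C, gamma = gamma, scaling = s, trainSequences = trainSeqs,
      version = .MODEL_VERSION)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkEncodingMatch <- function(model, x) {
  if (is(x, "PeptideFeatures")) {
    if (x@encoding != model@encoding ||
        !identical(is.na(x@g), is.na(model@g)) ||
        (!is.na(x@g) && x@g != model@g))
      stop(sprintf("encoding mismatch: model expects %s (g = %s), got %s (g = %s)",
                   model@encoding, model@g, x@encoding, x@g), call. = FALSE)
  }
  X <- .featMat(x)
  if (ncol(X) != length(model@featureNames))
    stop(sprintf("dimension mismatch: model expects %d feature columns, got %d",
                 length(model@featureNames), ncol(X)), call. = FALSE)
  X
}

#' Predict class labels for peptides
#'
#' Applies a trained \code{\link{ACPModel}} to new data. Sequences are
#' encoded with the model's own encoding; pre-encoded matrices must match
#' the model's encoding and dimension exactly. The decision is the sign of
#' the fitted SVM decision function; exact ties resolve to the positive
#' class.
#'
#' @param model An \code{\link{ACPModel}}.
#' @param x Peptides to classify: character vector of sequences,
#'   \code{AAStringSet}, \code{\link{LabeledPeptides}},
#'   \code{\link{PeptideFeatures}}, or a numeric matrix over the full
#'   feature space.
#' @param policy Validation/encoding policy for raw sequences.
#' @return A data.frame with one row per input: \code{id},
#'   \code{decision_value}, \code{label} (\code{"ACP"}/\code{"non-ACP"}) and
#'   \code{verdict} (\code{"Anticancer peptide"} /
#'   \code{"non-Anticancer peptide"}).
#' @export
predictACP <- function(model, x, policy = c("strict", "skip")) {
  stopifnot(is(model, "ACPModel"))
  policy <- match.arg(policy)
  if (is.character(x) || is(x, "XStringSet") || is(x, "LabeledPeptides")) {
    seqs <- if (is(x, "LabeledPeptides")) x@peptides else Biostrings::AAStringSet(x)
    if (length(seqs) == 0L) stop("empty query set", call. = FALSE)
    x <- encodePeptides(seqs,
                        encoding = if (model@encoding == "aac") "aac" else "ggap",
                        g = if (is.na(model@g)) 1L else model@g,
                        policy = policy)
  }
  X <- .checkEncodingMatch(model, x)
  res <- .predictLabels(model@fit,
                        .applyScaler(X[, model@subset, drop = FALSE],
                                     model@scaling))
  data.frame(id = rownames(X) %||% as.character(seq_len(nrow(X))),
             decision_value = res$dv,
             label = as.character(res$label),
             verdict = ifelse(res$label == "ACP", "Anticancer peptide",
                              "non-Anticancer peptide"),
             stringsAsFactors = FALSE)
}

#' @describeIn predictACP S4 \code{predict} method delegating to
#'   \code{predictACP}.
#' @param object An \code{\link{ACPModel}}.
#' @param ... Passed on to \code{predictACP}.
#' @export
setMethod("predict", "ACPModel", function(object, ...) predictACP(object, ...))

#' Grid search for SVM hyperparameters
#'
#' Evaluates every (C, gamma) pair on the same fixed stratified k-fold
#' partition and returns the pair maximizing pooled cross-validated
#' accuracy. Ties resolve to the smaller C, then the smaller gamma. Default
#' grids are the usual powers of two, C in 2^-5..2^15 and gamma in
#' 2^-15..2^3.
#'
#' @param x Features (\code{PeptideFeatures} or matrix).
#' @param label Class labels.
#' @param Cgrid,gammaGrid Numeric grids (non-empty).
#' @param subset Feature subset (default all).
#' @param k,seed,stratified Cross-validation settings.
#' @param scale Min-max scale features per training fold (default TRUE).
#' @return A list with elements \code{C}, \code{gamma} and \code{Acc}.
#' @export
gridSearch <- function(x, label = NULL, Cgrid = 2^(-5:15),
                       gammaGrid = 2^(-15:3), subset = NULL, k = 5L,
                       seed = 1L, stratified = TRUE, scale = TRUE) {
  if (length(Cgrid) == 0L || length(gammaGrid) == 0L)
    stop("hyperparameter grids must be non-empty", call. = FALSE)
  if (is.null(label) && is(x, "PeptideFeatures")) label <- attr(x, "label")
  label <- .asLabel(label)
  X <- .featMat(x)
  subset <- .resolveSubset(subset, ncol(X))
  foldid <- makeFolds(label, k, seed, stratified)
  best <- NULL
  for (C in sort(Cgrid)) for (gamma in sort(gammaGrid)) {
    pred <- .cvPredict(X, label, subset, foldid, C, gamma, scale)
    acc <- computeMetrics(confusionCounts(label, pred))[["Acc"]]
    if (is.null(best) || acc > best$Acc + 1e-15)
      best <- list(C = C, gamma = gamma, Acc = acc)
  }
  best
}

.evaluationResult <- function(label, pred) {
  counts <- confusionCounts(label, pred)
  list(metrics = computeMetrics(counts), counts = counts, predictions = pred)
}

#' Jackknife (leave-one-out) evaluation
#'
#' For each of the M samples, trains on the other M - 1 (same feature
#' subset, same hyperparameters) and predicts the held-out one; the M
#' predictions are pooled into a single set of confusion counts from which
#' the four metrics are computed once. Fully deterministic: no partition,
#' no seed. The feature subset is fixed up front and not re-selected per
#' left-out sample (the usual presentation order: selection first, then
#' evaluation), which is a known source of mild optimism.
#'
#' @param x Features (\code{PeptideFeatures} or matrix).
#' @param label Class labels (taken from \code{x} if labeled).
#' @param subset Feature columns to use (default all).
#' @param C,gamma SVM hyperparameters.
#' @param scale Min-max scale features per training fold (default TRUE).
#' @return A list with \code{metrics}, \code{counts} and the pooled
#'   per-sample \code{predictions}.
#' @export
jackknifeEvaluate <- function(x, label = NULL, subset = NULL,
                              C = 2, gamma = 0.125, scale = TRUE) {
  if (is.null(label) && is(x, "PeptideFeatures")) label <- attr(x, "label")
  label <- .asLabel(label)
  X <- .featMat(x)
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  subset <- .resolveSubset(subset, ncol(X))
  pred <- .cvPredict(X, label, subset, seq_len(nrow(X)), C, gamma, scale)
  .evaluationResult(label, pred)
}

#' Stratified k-fold evaluation with pooled counts
#'
#' Partitions the samples into k folds fixed by \code{seed}, trains on each
#' complement and predicts each fold, then pools all M predictions into one
#' set of confusion counts before computing the four metrics (pooled
#' evaluation, not mean-of-folds). With \code{k >= M} this reduces exactly
#' to \code{\link{jackknifeEvaluate}}.
#'
#' @inheritParams jackknifeEvaluate
#' @param k Number of folds.
#' @param seed Seed fixing the partition.
#' @param stratified Stratify folds by class.
#' @param folds Optional pre-built fold assignment (overrides
#'   \code{k}/\code{seed}).
#' @return A list with \code{metrics}, \code{counts}, \code{predictions}
#'   and the \code{folds} used.
#' @export
kfoldEvaluate <- function(x, label = NULL, subset = NULL, k = 5L,
                          seed = 1L, stratified = TRUE, C = 2,
                          gamma = 0.125, folds = NULL, scale = TRUE) {
  if (is.null(label) && is(x, "PeptideFeatures")) label <- attr(x, "label")
  label <- .asLabel(label)
  X <- .featMat(x)
  subset <- .resolveSubset(subset, ncol(X))
  if (is.null(folds)) folds <- makeFolds(label, k, seed, stratified)
  pred <- .cvPredict(X, label, subset, folds, C, gamma, scale)
  out <- .evaluationResult(label, pred)
  out$folds <- folds
  out
}

#' Evaluate a trained model on an independent test set
#'
#' Encodes and classifies an independent labeled test set with a trained
#' model, returning metrics, counts and a per-peptide verdict table. The
#' test set is checked for exact-sequence overlap with the model's training
#' sequences; overlap triggers a warning (the evaluation still runs, but is
#' then a resubstitution for those records).
#'
#' @param model An \code{\link{ACPModel}}.
#' @param testDs A \code{\link{LabeledPeptides}} test set.
#' @param policy Encoding policy for peptides too short for the model's
#'   encoding.
#' @return A list with \code{metrics}, \code{counts} and the per-peptide
#'   \code{verdicts} data.frame (id, decision_value, label, verdict,
#'   truth).
#' @export
independentTest <- function(model, testDs, policy = c("strict", "skip")) {
  stopifnot(is(model, "ACPModel"), is(testDs, "LabeledPeptides"))
  policy <- match.arg(policy)
  if (length(testDs) == 0L) stop("empty test set", call. = FALSE)
  if (length(model@trainSequences)) {
    ov <- sum(as.character(testDs@peptides) %in% model@trainSequences)
    if (ov > 0)
      warning(ov, " test sequence(s) occur in the training set; ",
              "metrics are partly resubstitution", call. = FALSE)
  }
  feats <- encodePeptides(testDs,
                          encoding = if (model@encoding == "aac") "aac" else "ggap",
                          g = if (is.na(model@g)) 1L else model@g,
                          policy = policy)
  truth <- encodedLabels(feats)
  verdicts <- predictACP(model, feats)
  verdicts$truth <- as.character(truth)
  counts <- confusionCounts(truth, verdicts$label)
  list(metrics = computeMetrics(counts), counts = counts,
       verdicts = verdicts)
}

#' Persist / restore a trained model
#'
#' \code{saveACPModel} writes a versioned archive holding the SVM fit, the
#' feature-subset indices, the encoding contract and the hyperparameters.
#' \code{loadACPModel} restores it, verifying the archive version and the
#' feature-space dimension before returning a usable
#' \code{\link{ACPModel}}.
#'
#' @param model An \code{\link{ACPModel}}.
#' @param path Archive path.
#' @return \code{saveACPModel}: invisibly, \code{path};
#'   \code{loadACPModel}: an \code{\link{ACPModel}}.
#' @export
saveACPModel <- function(model, path) {
  stopifnot(is(model, "ACPModel"))
  saveRDS(list(version = model@version, encoding = model@encoding,
               g = model@g, subset = model@subset,
               featureNames = model@featureNames, C = model@cost,
               gamma = model@gamma, scaling = model@scaling,
               trainSequences = model@trainSequences, fit = model@fit),
          path)
  invisible(path)
}

#' @rdname saveACPModel
#' @export
loadACPModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, .MODEL_VERSION))
    stop("unsupported model archive version: ", obj$version, call. = FALSE)
  omega <- length(obj$featureNames)
  if ((obj$encoding == "ggap" && omega != 400L) ||
      (obj$encoding == "aac" && omega != 20L))
    stop("corrupt model archive: feature space dimension ", omega,
         " inconsistent with encoding ", obj$encoding, call. = FALSE)
  new("ACPModel", fit = obj$fit, subset = obj$subset,
      encoding = obj$encoding, g = obj$g, featureNames = obj$featureNames,
      cost = obj$C, gamma = obj$gamma, scaling = obj$scaling %||% list(),
      trainSequences = obj$trainSequences, version = obj$version)
}
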