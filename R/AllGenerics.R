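#' Accessors for package classes
#'
#' \code{peptides()} returns the underlying \code{AAStringSet};
#' \code{classLabels()} the label factor; \code{featureValues()} the numeric
#' feature matrix; \code{fScores()} the per-feature ANOVA table;
#' \code{ifsCurve()} the incremental-feature-selection curve and
#' \code{theta()} its optimal prefix size.
#'
#' @param x An object of the corresponding class.
#' @return See the individual descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("fScores", function(x) standardGeneric("fScores"))

#' @rdname accessors
#' @export
setGeneric("ifsCurve", function(x) standardGeneric("ifsCurve"))

#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))

#' @rdname accessors
#' @export
setMethod("peptides", "LabeledPeptides", function(x) x@peptides)

#' @rdname accessors
#' @export
setMethod("classLabels", "LabeledPeptides", function(x) x@label)

#' @rdname accessors
#' @export
setMethod("featureValues", "PeptideFeatures", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("fScores", "FScoreResults", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("ifsCurve", "IFSRun", function(x) x@curve)

#' @rdname accessors
#' @export
setMethod("theta", "IFSRun", function(x) x@theta)

#' @describeIn LabeledPeptides-class Number of peptides (\eqn{M}).
#' @param x A \code{LabeledPeptides} object.
#' @export
setMethod("length", "LabeledPeptides", function(x) length(x@peptides))

#' Subset a labeled peptide set
#'
#' @param x A \code{LabeledPeptides} object.
#' @param i Index vector.
#' @param j,...,drop Ignored.
#' @return A \code{LabeledPeptides} with the selected records.
#' @export
setMethod("[", "LabeledPeptides", function(x, i, j, ..., drop = FALSE) {
  new("LabeledPeptides", peptides = x@peptides[i],
      label = factor(as.character(x@label[i]), levels = .ACP_LEVELS))
})

setMethod("show", "LabeledPeptides", function(object) {
  tab <- table(object@label)
  cat("LabeledPeptides with", length(object@peptides), "peptides\n")
  cat("  positives (ACP):    ", tab[["ACP"]], "\n")
  cat("  negatives (non-ACP):", tab[["non-ACP"]], "\n")
  if (length(object@peptides)) {
    w <- Biostrings::width(object@peptides)
    cat("  length range:", min(w), "-", max(w), "residues\n")
  }
})

setMethod("show", "PeptideFeatures", function(object) {
  cat("PeptideFeatures:", nrow(object@values), "peptides x",
      ncol(object@values), "features\n")
  cat("  encoding:", object@encoding,
      if (object@encoding == "ggap") sprintf("(g = %d)", object@g) else "",
      "\n")
  if (length(object@dropped))
    cat("  dropped (too short):", length(object@dropped), "record(s)\n")
})

setMethod("show", "FScoreResults", function(object) {
  cat("FScoreResults over", nrow(object@table), "features",
      sprintf("(dfB = %d, dfW = %d)\n", object@dfB, object@dfW))
  top <- object@table[order(-object@table$F,
                            seq_len(nrow(object@table))), , drop = FALSE]
  cat("  top features by F:\n")
  print(utils::head(top, 5), row.names = FALSE)
})

setMethod("show", "IFSRun", function(object) {
  cat("IFSRun over", nrow(object@curve), "prefix sizes",
      if (!is.na(object@g)) sprintf("(g = %d)", object@g) else "", "\n")
  cat(sprintf("  peak Acc = %.4f at Theta = %d\n",
              object@peakAcc, object@theta))
})

setMethod("show", "ACPModel", function(object) {
  cat("ACPModel (RBF-SVM anticancer peptide classifier)\n")
  cat("  encoding:", object@encoding,
      if (object@encoding == "ggap") sprintf("(g = %d)", object@g) else "",
      "\n")
  cat("  features used:", length(object@subset), "of",
      length(object@featureNames), "\n")
  cat(sprintf("  C = %g, gamma = %g\n", object@cost, object@gamma))
  cat("  trained on", length(object@trainSequences), "peptides\n")
})

setMethod("show", "SynthSpec", function(object) {
  cat("SynthSpec:", object@nPos, "positives +", object@nNeg, "negatives\n")
  cat(sprintf("  lengths: %.0f%% in [%d, %d), rest in [%d, %d]\n",
              100 * object@shortFraction, object@minLen, object@shortMax,
              object@shortMax, object@maxLen))
  cat("  enriched residues:", paste(object@enrichedResidues, collapse = ""),
      sprintf("(factor %.2g, %s background)\n", object@enrichmentFactor,
              object@background))
  if (!is.na(object@plantedGap))
    cat(sprintf("  planted pair %s..%s at gap %d (prob %.2f)\n",
                object@plantedPair[1], object@plantedPair[2],
                object@plantedGap, object@plantProb))
  cat("  seed:", object@seed, "\n")
})
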