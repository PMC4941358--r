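#' @import methods
#' @importFrom Biostrings AAStringSet readBStringSet writeXStringSet width
#' @importClassesFrom Biostrings AAStringSet XStringSet
#' @importFrom stats predict runif
#' @importFrom e1071 svm
#' @importFrom utils head write.table read.table
NULL

#' The 20 standard amino acids, alphabetical by one-letter code
#'
#' Canonical residue ordering used throughout the package: alphabetical by
#' one-letter code (\code{ACDEFGHIKLMNPQRSTVWY}). All composition vectors and
#' dipeptide indices are defined relative to this ordering.
#'
#' @format A character vector of length 20.
#' @export
STANDARD_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.ACP_LEVELS <- c("ACP", "non-ACP")

#' LabeledPeptides: peptides with binary class labels
#'
#' A container for a two-class peptide dataset \eqn{S = S^+ \cup S^-}: an
#' \code{AAStringSet} of sequences in fixed order together with a parallel
#' factor of class labels (\code{"ACP"} = positive, \code{"non-ACP"} =
#' negative).
#'
#' @slot peptides An \code{\link[Biostrings]{AAStringSet}} of peptide
#'   sequences; names are record identifiers.
#' @slot label A factor with levels \code{c("ACP", "non-ACP")}, one label per
#'   peptide.
#'
#' @seealso \code{\link{loadLabeledPeptides}}, \code{\link{generatePeptides}}
#' @export
setClass("LabeledPeptides",
         slots = c(peptides = "AAStringSet", label = "factor"))

setValidity("LabeledPeptides", function(object) {
  msg <- character()
  if (length(object@peptides) != length(object@label))
    msg <- c(msg, "peptides and label must have the same length")
  if (!identical(levels(object@label), .ACP_LEVELS))
    msg <- c(msg, sprintf("label levels must be exactly c(\"%s\", \"%s\")",
                          .ACP_LEVELS[1], .ACP_LEVELS[2]))
  if (length(msg)) msg else TRUE
})

#' PeptideFeatures: a fixed-width composition feature matrix
#'
#' One row per peptide, one column per composition component. The encoding is
#' either \code{"aac"} (20 amino-acid frequencies) or \code{"ggap"} (400 g-gap
#' dipeptide frequencies); every row of an encodable peptide sums to 1.
#'
#' @slot values Numeric matrix, samples in rows, features in columns. Column
#'   names follow the canonical residue/dipeptide ordering.
#' @slot encoding \code{"aac"} or \code{"ggap"} (or \code{"raw"} for matrices
#'   supplied directly by the user).
#' @slot g Integer gap parameter for \code{"ggap"}; \code{NA} otherwise.
#' @slot dropped Identifiers of peptides dropped under the \code{"skip"}
#'   policy because they were too short for the encoding.
#'
#' @seealso \code{\link{encodePeptides}}
#' @export
setClass("PeptideFeatures",
         slots = c(values = "matrix", encoding = "character",
                   g = "integer", dropped = "character"))

setValidity("PeptideFeatures", function(object) {
  msg <- character()
  enc <- object@encoding
  if (length(enc) != 1L || !enc %in% c("aac", "ggap", "raw"))
    msg <- c(msg, "encoding must be one of \"aac\", \"ggap\", \"raw\"")
  else {
    p <- ncol(object@values)
    if (enc == "aac" && p != 20L)
      msg <- c(msg, "aac encoding requires 20 columns")
    if (enc == "ggap") {
      if (p != 400L) msg <- c(msg, "ggap encoding requires 400 columns")
      if (is.na(object@g) || object@g < 0L || object@g > 4L)
        msg <- c(msg, "g must be an integer in [0, 4] for ggap encoding")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FScoreResults: per-feature one-way ANOVA F statistics
#'
#' Holds, for each feature, the between-group mean square (MSB), the
#' within-group mean square (MSW), the F-value \eqn{F = MSB/MSW}, and the
#' direction of the class contrast (+1 when the positive-class mean exceeds
#' the negative-class mean, -1 when smaller, 0 when equal). Features with
#' MSW = 0 but MSB > 0 carry an \code{Inf} sentinel F (a perfectly separating
#' feature); constant features carry F = 0.
#'
#' @slot table A data.frame with columns \code{feature}, \code{F},
#'   \code{MSB}, \code{MSW}, \code{direction}.
#' @slot dfB,dfW Integer degrees of freedom (\eqn{K-1} and \eqn{M-K}).
#' @slot encoding,g Provenance of the feature matrix scored.
#'
#' @seealso \code{\link{anovaFScores}}, \code{\link{rankFeatures}},
#'   \code{\link{signedFMatrix}}
#' @export
setClass("FScoreResults",
         slots = c(table = "data.frame", dfB = "integer", dfW = "integer",
                   encoding = "character", g = "integer"))

#' IFSRun: an incremental feature selection curve and its peak
#'
#' For each prefix size tau of an F-ranked feature list, the pooled
#' cross-validated Sn/Sp/Acc/MCC of an RBF-SVM trained on that prefix. The
#' optimal prefix size Theta is the smallest tau attaining the maximum
#' accuracy on the curve.
#'
#' @slot curve data.frame with columns \code{tau}, \code{Sn}, \code{Sp},
#'   \code{Acc}, \code{MCC}.
#' @slot theta Integer: smallest tau at the accuracy peak.
#' @slot peakAcc Accuracy at the peak, in [0, 1].
#' @slot ranking Integer permutation: feature column indices in descending-F
#'   order; the tau-th curve row used \code{ranking[1:tau]}.
#' @slot g Gap parameter of the encoding scored (\code{NA} for non-ggap).
#'
#' @seealso \code{\link{runIFS}}, \code{\link{selectBestG}}
#' @export
setClass("IFSRun",
         slots = c(curve = "data.frame", theta = "integer",
                   peakAcc = "numeric", ranking = "integer", g = "integer"))

#' ACPModel: a trained RBF-SVM anticancer peptide classifier
#'
#' Wraps a fitted \code{e1071::svm} model together with everything needed to
#' apply it safely: the feature subset it was trained on, the encoding it
#' expects, the SVM hyperparameters, and the training sequences (used to warn
#' about train/test overlap in independent evaluations).
#'
#' @slot fit The fitted \code{e1071::svm} object.
#' @slot subset Integer 1-based feature column indices used in training.
#' @slot encoding,g Encoding contract for prediction inputs.
#' @slot featureNames Column names of the full feature space at training.
#' @slot cost,gamma SVM regularization parameter C and RBF kernel width.
#' @slot scaling Per-feature min-max scaling parameters fitted on the
#'   training data (empty list when trained with \code{scale = FALSE}).
#' @slot trainSequences Character vector of training sequences.
#' @slot version Archive format version string.
#'
#' @seealso \code{\link{trainACP}}, \code{\link{predictACP}},
#'   \code{\link{saveACPModel}}
#' @export
setClass("ACPModel",
         slots = c(fit = "ANY", subset = "integer", encoding = "character",
                   g = "integer", featureNames = "character",
                   cost = "numeric", gamma = "numeric", scaling = "list",
                   trainSequences = "character", version = "character"))

#' SynthSpec: parameters of the synthetic peptide generator
#'
#' Describes a two-class synthetic peptide dataset: class sizes, a length law
#' (a mixture putting \code{shortFraction} of the mass on short peptides, by
#' default 80\% below 30 residues on support [5, 50]), residue enrichment in
#' the positive class, and an optional planted residue-pair signal at a fixed
#' gap.
#'
#' @slot nPos,nNeg Class sizes (positives, negatives).
#' @slot shortFraction Fraction of peptide lengths drawn below
#'   \code{shortMax}; the rest are drawn on [\code{shortMax}, \code{maxLen}].
#' @slot minLen,shortMax,maxLen Length-law support parameters.
#' @slot enrichedResidues Residues over-represented in positives.
#' @slot enrichmentFactor Multiplicative sampling-weight bias (>= 1) applied
#'   to enriched residues in positives.
#' @slot background \code{"uniform"} or \code{"natural"} residue weights for
#'   the unbiased draw.
#' @slot plantedGap Optional gap g at which a fixed ordered residue pair is
#'   planted (\code{NA} = no planting); positives receive the pair in
#'   order, negatives reversed, keeping composition matched.
#' @slot plantedPair The ordered residue pair planted when
#'   \code{plantedGap} is set.
#' @slot plantProb Probability that a positive peptide receives one planted
#'   pair at a uniformly chosen eligible position.
#' @slot seed Integer RNG seed; generation is reproducible given the spec.
#'
#' @seealso \code{\link{synthSpec}}, \code{\link{generatePeptides}}
#' @export
setClass("SynthSpec",
         slots = c(nPos = "integer", nNeg = "integer",
                   shortFraction = "numeric", minLen = "integer",
                   shortMax = "integer", maxLen = "integer",
                   enrichedResidues = "character",
                   enrichmentFactor = "numeric", background = "character",
                   plantedGap = "integer", plantedPair = "character",
                   plantProb = "numeric", seed = "integer"))

setValidity("SynthSpec", function(object) {
  msg <- character()
  if (object@nPos < 1L || object@nNeg < 1L)
    msg <- c(msg, "class sizes must be >= 1")
  if (object@enrichmentFactor < 1)
    msg <- c(msg, "enrichmentFactor must be >= 1")
  if (object@shortFraction < 0 || object@shortFraction > 1)
    msg <- c(msg, "shortFraction must be in [0, 1]")
  if (!(object@minLen >= 1L && object@minLen < object@shortMax &&
        object@shortMax <= object@maxLen))
    msg <- c(msg, "need 1 <= minLen < shortMax <= maxLen")
  if (!all(object@enrichedResidues %in% STANDARD_AA))
    msg <- c(msg, "enrichedResidues must be standard amino acids")
  if (!object@background %in% c("uniform", "natural"))
    msg <- c(msg, "background must be \"uniform\" or \"natural\"")
  if (!is.na(object@plantedGap)) {
    if (object@plantedGap < 0L || object@plantedGap > 4L)
      msg <- c(msg, "plantedGap must be in [0, 4]")
    if (length(object@plantedPair) != 2L ||
        !all(object@plantedPair %in% STANDARD_AA))
      msg <- c(msg, "plantedPair must be two standard residues")
    if (object@plantProb < 0 || object@plantProb > 1)
      msg <- c(msg, "plantProb must be in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})
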