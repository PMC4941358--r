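# Residue background weights. "natural" uses rounded vertebrate-proteome
# abundances (percent); "uniform" is the exchangeable null.
.NATURAL_AA_FREQ <- c(A = 8.3, C = 1.4, D = 5.5, E = 6.8, F = 3.9, G = 7.1,
                      H = 2.3, I = 6.0, K = 5.8, L = 9.7, M = 2.4, N = 4.1,
                      P = 4.7, Q = 4.0, R = 5.5, S = 6.6, T = 5.3, V = 6.9,
                      W = 1.1, Y = 2.9)

#' Specify a synthetic two-class peptide dataset
#'
#' Builds a \code{\link{SynthSpec}} describing short peptides with
#' class-discriminating residue structure. Defaults emulate the observed
#' contrasts between anticancer and non-anticancer peptides: about 80\% of
#' lengths below 30 residues on support [5, 50], and the residues
#' C, E, F, G, I, K over-represented in the positive class. The
#' over-representation mechanism (a multiplicative sampling-weight bias,
#' default factor 5) is this package's own model of those contrasts, not a
#' biophysical simulation. Optionally a fixed ordered residue pair can be
#' planted at a chosen gap g in positives, creating a sequence-order signal
#' detectable only by g-gap encodings.
#'
#' @param nPos,nNeg Class sizes (default 138 and 206, the benchmark-style
#'   class balance).
#' @param shortFraction Fraction of lengths drawn below \code{shortMax}
#'   (default 0.8).
#' @param minLen,shortMax,maxLen Length-law support (defaults 5, 30, 50):
#'   lengths are uniform on [minLen, shortMax) with probability
#'   \code{shortFraction}, else uniform on [shortMax, maxLen].
#' @param enrichedResidues Residues over-represented in positives.
#' @param enrichmentFactor Weight multiplier (>= 1) for enriched residues
#'   in positives; 1 makes the classes exchangeable.
#' @param background \code{"uniform"} (default) or \code{"natural"}
#'   residue weights for unbiased draws.
#' @param plantedGap Optional gap at which \code{plantedPair} is planted
#'   (\code{NA} = none). Positives receive the pair in order, negatives
#'   the reversed pair at the same gap, so planted residue composition is
#'   identical across classes and the signal is purely order at that gap.
#' @param plantedPair Ordered residue pair to plant (default K..C).
#' @param plantProb Probability that a peptide receives one planted pair,
#'   at a uniformly chosen eligible position (default 0.9).
#' @param seed Integer seed; generation is fully reproducible.
#' @return A \code{\link{SynthSpec}}.
#' @export
synthSpec <- function(nPos = 138L, nNeg = 206L, shortFraction = 0.8,
                      minLen = 5L, shortMax = 30L, maxLen = 50L,
                      enrichedResidues = c("C", "E", "F", "G", "I", "K"),
                      enrichmentFactor = 5, background = "uniform",
                      plantedGap = NA_integer_, plantedPair = c("K", "C"),
                      plantProb = 0.9, seed = 1L) {
  new("SynthSpec", nPos = as.integer(nPos), nNeg = as.integer(nNeg),
      shortFraction = shortFraction, minLen = as.integer(minLen),
      shortMax = as.integer(shortMax), maxLen = as.integer(maxLen),
      enrichedResidues = enrichedResidues,
      enrichmentFactor = enrichmentFactor, background = background,
      plantedGap = as.integer(plantedGap), plantedPair = plantedPair,
      plantProb = plantProb, seed = as.integer(seed))
}

specAsList <- function(spec) {
  list(nPos = spec@nPos, nNeg = spec@nNeg,
       shortFraction = spec@shortFraction, minLen = spec@minLen,
       shortMax = spec@shortMax, maxLen = spec@maxLen,
       enrichedResidues = paste(spec@enrichedResidues, collapse = ""),
       enrichmentFactor = spec@enrichmentFactor,
       background = spec@background, plantedGap = spec@plantedGap,
       plantedPair = paste(spec@plantedPair, collapse = ""),
       plantProb = spec@plantProb, seed = spec@seed)
}

.drawLengths <- function(n, spec) {
  short <- stats::runif(n) < spec@shortFraction
  L <- integer(n)
  L[short] <- sample(spec@minLen:(spec@shortMax - 1L), sum(short),
                     replace = TRUE)
  L[!short] <- sample(spec@shortMax:spec@maxLen, sum(!short),
                      replace = TRUE)
  L
}

# Matched-control planting: one pair per peptide at a random eligible
# position — positives receive the pair in its stated orientation at the
# planted gap, negatives the REVERSED pair at the same gap. Both classes
# then carry identical planted residue composition, so the class signal
# lives purely in the residue order at that one gap; dense or one-sided
# planting would leak compositional signal into every encoding.
.drawPeptide <- function(L, weights, spec, positive) {
  chars <- sample(STANDARD_AA, L, replace = TRUE, prob = weights)
  g <- spec@plantedGap
  if (!is.na(g) && L >= g + 2L && stats::runif(1) < spec@plantProb) {
    pair <- if (positive) spec@plantedPair else rev(spec@plantedPair)
    i <- sample.int(L - g - 1L, 1L)
    chars[i] <- pair[1]
    chars[i + g + 1L] <- pair[2]
  }
  paste(chars, collapse = "")
}

#' Generate a labeled synthetic peptide dataset
#'
#' Draws peptides according to a \code{\link{SynthSpec}}: lengths i.i.d.
#' from the spec's mixture law; negative-class residues from the background
#' weights; positive-class residues from the background weights multiplied
#' by \code{enrichmentFactor} on the enriched residues (renormalized), with
#' optional planted residue pairs at the planted gap. Identical specs (same
#' seed) produce identical datasets; the caller's RNG state is untouched.
#'
#' @param spec A \code{\link{SynthSpec}}.
#' @return A \code{\link{LabeledPeptides}} dataset carrying \code{spec} as
#'   an attribute (recorded in FASTA sidecars by
#'   \code{\link{writeFastaPair}}).
#' @export
generatePeptides <- function(spec) {
  stopifnot(is(spec, "SynthSpec"))
  validObject(spec)
  base <- if (spec@background == "uniform") rep(1, 20) else
    unname(.NATURAL_AA_FREQ[STANDARD_AA])
  wNeg <- base / sum(base)
  wPos <- base
  wPos[STANDARD_AA %in% spec@enrichedResidues] <-
    wPos[STANDARD_AA %in% spec@enrichedResidues] * spec@enrichmentFactor
  wPos <- wPos / sum(wPos)
  withSeed(spec@seed, {
    Lp <- .drawLengths(spec@nPos, spec)
    Ln <- .drawLengths(spec@nNeg, spec)
    pos <- vapply(Lp, .drawPeptide, character(1), weights = wPos,
                  spec = spec, positive = TRUE)
    neg <- vapply(Ln, .drawPeptide, character(1), weights = wNeg,
                  spec = spec, positive = FALSE)
    names(pos) <- sprintf("synthACP_%03d", seq_along(pos))
    names(neg) <- sprintf("synthNeg_%03d", seq_along(neg))
    ds <- labeledPeptides(pos, neg)
    attr(ds, "spec") <- spec
    ds
  })
}

#' Length histogram of a peptide dataset
#'
#' Counts peptide lengths in bins of width 5 over [5, 50] (the last bin is
#' closed), plus open-ended underflow/overflow bins. Used to check the
#' generator's ~80\%-under-30-residues length law.
#'
#' @param ds A \code{\link{LabeledPeptides}} or \code{AAStringSet}.
#' @return Named integer vector of bin counts.
#' @export
lengthHistogram <- function(ds) {
  w <- if (is(ds, "LabeledPeptides")) Biostrings::width(peptides(ds)) else
    Biostrings::width(Biostrings::AAStringSet(ds))
  lower <- seq(5, 45, 5)
  labs <- c("<5", paste0("[", lower, ",", lower + 5, ")"), ">50")
  labs[10] <- "[45,50]"
  mid <- vapply(seq_along(lower), function(i) {
    if (i < length(lower)) sum(w >= lower[i] & w < lower[i] + 5)
    else sum(w >= 45 & w <= 50)
  }, integer(1))
  out <- c(sum(w < 5), mid, sum(w > 50))
  names(out) <- labs
  out
}
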