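#' Read peptide sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into an \code{AAStringSet}. Header text
#' after \code{">"} becomes the record identifier; sequence lines are
#' concatenated, whitespace-stripped and uppercased. Sequences are NOT
#' validated against the standard amino-acid alphabet here: validation is a
#' separate, policy-carrying step (\code{\link{validatePeptides}}), so that
#' records containing extended codes such as B, U, X or Z parse and can then
#' be rejected or skipped explicitly.
#'
#' @param path Path to a FASTA file.
#' @return An \code{\link[Biostrings]{AAStringSet}}, one element per record,
#'   in file order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "GLFD", "IVKK"), tf)
#' readPeptides(tf)
#' @export
readPeptides <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop("not a valid FASTA file (", conditionMessage(e), "): ",
                         path, call. = FALSE))
  if (length(raw) == 0L)
    stop("no records in FASTA file: ", path, call. = FALSE)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record(s) with empty sequence: ",
         paste(names(raw)[empty], collapse = ", "), call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Validate peptides against the 20 standard amino acids
#'
#' Checks every residue against \code{ACDEFGHIKLMNPQRSTVWY}. Codes such as
#' B, U, X and Z — and the gap/stop characters \code{"-"} and \code{"*"} —
#' are illegal. Under \code{policy = "strict"} any offending record aborts
#' the batch with an error naming the record, the residue and its (1-based)
#' position; under \code{policy = "skip"} offending records are dropped with
#' a warning and the remainder returned. Validation is idempotent.
#'
#' @param x An \code{AAStringSet} (e.g. from \code{\link{readPeptides}}).
#' @param policy \code{"strict"} (default) or \code{"skip"}.
#' @return The validated \code{AAStringSet} (possibly shorter under
#'   \code{"skip"}).
#' @export
validatePeptides <- function(x, policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  seqs <- as.character(x)
  ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  bad_at <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
  offenders <- which(bad_at > 0L)
  if (length(offenders) == 0L) return(x)
  details <- vapply(offenders, function(i) {
    sprintf("'%s': illegal residue '%s' at position %d", ids[i],
            substr(seqs[i], bad_at[i], bad_at[i]), bad_at[i])
  }, character(1))
  if (policy == "strict")
    stop("invalid peptide(s): ", paste(details, collapse = "; "),
         call. = FALSE)
  warning("dropped ", length(offenders), " invalid record(s): ",
          paste(details, collapse = "; "), call. = FALSE)
  x[-offenders]
}

#' Load a labeled two-class peptide dataset from paired FASTA files
#'
#' Reads a positive (ACP) and a negative (non-ACP) FASTA file, validates both
#' under the given policy, and assembles a \code{\link{LabeledPeptides}}
#' object with positives first. Duplicate identifiers across the two files
#' trigger a warning (identifiers are labels, not keys; records are kept).
#'
#' @param posPath FASTA file of positive (anticancer) peptides.
#' @param negPath FASTA file of negative peptides.
#' @param policy Validation policy, see \code{\link{validatePeptides}}.
#' @return A \code{\link{LabeledPeptides}} object.
#' @export
loadLabeledPeptides <- function(posPath, negPath,
                                policy = c("strict", "skip")) {
  policy <- match.arg(policy)
  pos <- validatePeptides(readPeptides(posPath), policy)
  neg <- validatePeptides(readPeptides(negPath), policy)
  if (length(pos) == 0L)
    stop("no positive peptides left after validation", call. = FALSE)
  if (length(neg) == 0L)
    stop("no negative peptides left after validation", call. = FALSE)
  dup <- intersect(names(pos), names(neg))
  if (length(dup))
    warning("duplicate identifier(s) across classes: ",
            paste(utils::head(dup, 10), collapse = ", "), call. = FALSE)
  all <- c(pos, neg)
  lab <- factor(rep(.ACP_LEVELS, c(length(pos), length(neg))),
                levels = .ACP_LEVELS)
  new("LabeledPeptides", peptides = all, label = lab)
}

#' Construct a LabeledPeptides object from in-memory sequences
#'
#' @param pos,neg Character vectors (or \code{AAStringSet}s) of positive and
#'   negative peptide sequences; names become identifiers.
#' @return A \code{\link{LabeledPeptides}} object.
#' @export
labeledPeptides <- function(pos, neg) {
  pos <- Biostrings::AAStringSet(pos)
  neg <- Biostrings::AAStringSet(neg)
  if (length(pos) == 0L || length(neg) == 0L)
    stop("both classes must be non-empty", call. = FALSE)
  if (is.null(names(pos))) names(pos) <- paste0("ACP_", seq_along(pos))
  if (is.null(names(neg))) names(neg) <- paste0("nonACP_", seq_along(neg))
  new("LabeledPeptides", peptides = c(pos, neg),
      label = factor(rep(.ACP_LEVELS, c(length(pos), length(neg))),
                     levels = .ACP_LEVELS))
}

#' Write a labeled dataset as a positive/negative FASTA pair
#'
#' Writes the positive and negative records of a \code{LabeledPeptides}
#' object to two FASTA files, optionally with a JSON provenance sidecar
#' (useful for regenerable synthetic fixtures; see
#' \code{\link{generatePeptides}}).
#'
#' @param ds A \code{\link{LabeledPeptides}} object.
#' @param posPath,negPath Output FASTA paths.
#' @param sidecar Optional path for a JSON sidecar; when \code{ds} carries a
#'   generator spec (attribute \code{"spec"}), the spec and seed are recorded.
#' @return Invisibly, a character vector of the files written.
#' @export
writeFastaPair <- function(ds, posPath, negPath, sidecar = NULL) {
  stopifnot(is(ds, "LabeledPeptides"))
  isPos <- ds@label == "ACP"
  Biostrings::writeXStringSet(ds@peptides[isPos], posPath, width = 60L)
  Biostrings::writeXStringSet(ds@peptides[!isPos], negPath, width = 60L)
  written <- c(posPath, negPath)
  if (!is.null(sidecar)) {
    spec <- attr(ds, "spec")
    meta <- list(nPos = sum(isPos), nNeg = sum(!isPos))
    if (!is.null(spec)) meta$spec <- specAsList(spec)
    jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, sidecar)
  }
  invisible(written)
}
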