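# Shared in-code fixtures: no data files, everything built at test time.

# Perfectly separable one-feature toy: positives at 1.0, negatives at 0.0.
toySeparable <- function(nPos = 10, nNeg = 10, extraNoise = 0) {
  p <- 1 + extraNoise
  X <- matrix(0, nrow = nPos + nNeg, ncol = p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  X[seq_len(nPos), 1] <- 1
  if (extraNoise > 0) {
    set.seed(42)
    X[, -1] <- matrix(runif((nPos + nNeg) * extraNoise), nPos + nNeg)
  }
  list(X = X, label = rep(c("ACP", "non-ACP"), c(nPos, nNeg)))
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(0)
  for (i in seq_along(seqs))
    lines <- c(lines, paste0(">", names(seqs)[i]), seqs[[i]])
  writeLines(lines, path)
  path
}

randomPeptide <- function(L) {
  paste(sample(ggapACP::STANDARD_AA, L, replace = TRUE), collapse = "")
}

# A small labeled dataset of valid random peptides (all long enough for any
# g in 0..4).
randomDataset <- function(nPos = 8, nNeg = 12, Lmin = 10, Lmax = 30,
                          seed = 1) {
  set.seed(seed)
  pos <- vapply(sample(Lmin:Lmax, nPos, TRUE), randomPeptide, character(1))
  neg <- vapply(sample(Lmin:Lmax, nNeg, TRUE), randomPeptide, character(1))
  names(pos) <- paste0("p", seq_len(nPos))
  names(neg) <- paste0("n", seq_len(nNeg))
  labeledPeptides(pos, neg)
}
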