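# Run code under a local RNG stream without disturbing the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Write a tab-separated table
#'
#' Writes a data.frame as UTF-8 TSV with a header row, no quoting and no row
#' names, in the row order given. An empty data.frame produces a header-only
#' file.
#'
#' @param rows A data.frame.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTable <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  utils::write.table(rows, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table written by \code{writeTable}
#'
#' @param path File path to a TSV with header row.
#' @return A data.frame.
#' @export
readTableTSV <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, comment.char = "",
                    check.names = FALSE, encoding = "UTF-8")
}
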