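# Tabular I/O with a versioned schema header comment on every output.

.SCHEMA_VERSION <- "tsv-schema/1"

#' Write a data.frame as TSV with a versioned schema header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param name Short schema name recorded in the header comment.
#' @export
write_tsv <- function(df, path, name = "table") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# pamuslink %s %s %s",
                     as.character(utils::packageVersion("pamuslink")),
                     .SCHEMA_VERSION, name), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (header comments are skipped)
#'
#' @param path Input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# Matrix variant: first column holds rownames.
.write_matrix_tsv <- function(m, path, name, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE, row.names = NULL)
  names(df)[1L] <- id_col
  write_tsv(df, path, name)
}

.read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
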