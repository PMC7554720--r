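# Subcellular proteome remodeling: group protein fold changes by annotated
# compartment and summarise location-wise shifts.

#' Default subcellular-location vocabulary mapping
#'
#' Reads the shipped mapping of UniProt-style location keywords to the
#' collapsed compartment vocabulary (plastid, mitochondrion, endoplasmic
#' reticulum, membrane, cytoplasm, nucleus). The file is an editable
#' extension point: two tab-separated columns, `pattern` (matched
#' case-insensitively as a substring of one location token) and
#' `compartment`. Earlier rows take precedence.
#'
#' @param path Optional path to a custom mapping file.
#' @return data.frame with columns `pattern`, `compartment`.
#' @export
compartment_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "compartment_map.tsv",
                        package = "pamuslink", mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Assign proteins to subcellular compartments from location strings
#'
#' Splits each UniProt-style "Subcellular location" string into tokens on
#' `,` and `;`, matches every token against the vocabulary mapping, and
#' either keeps the first-listed matching location (default) or all listed
#' compartments (`multi_assign = TRUE`). Strings with no recognised token
#' map to `"unannotated"`.
#'
#' @param location_strings Character vector of location annotations.
#' @param map Vocabulary mapping, see [compartment_map()].
#' @param multi_assign Return every listed compartment instead of the first.
#' @return With `multi_assign = FALSE`, a character vector (one label per
#'   input); otherwise a list of character vectors.
#' @examples
#' assign_compartment("Plastid, chloroplast thylakoid membrane")  # "plastid"
#' @export
assign_compartment <- function(location_strings, map = compartment_map(),
                               multi_assign = FALSE) {
  one <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return("unannotated")
    tokens <- trimws(strsplit(s, "[,;]")[[1L]])
    tokens <- tolower(tokens[nzchar(tokens)])
    hits <- character(0L)
    for (tok in tokens) {
      m <- which(vapply(tolower(map$pattern), grepl, logical(1L),
                        x = tok, fixed = TRUE))
      if (length(m)) hits <- c(hits, map$compartment[m[1L]])
    }
    if (!length(hits)) return("unannotated")
    if (multi_assign) unique(hits) else hits[1L]
  }
  res <- lapply(location_strings, one)
  if (multi_assign) res else unlist(res)
}

#' Compartment-wise distribution of protein log2 fold changes
#'
#' @param de_table `diff_expression` table for one contrast (columns
#'   `feature`, `l2fc`).
#' @param assignments Named character vector (feature -> compartment) or a
#'   named list for multi-assignment; every feature in `de_table` must be
#'   covered (possibly as `"unannotated"`).
#' @param contrast Optional contrast label copied into the summary.
#' @param min_size Compartments with fewer proteins are flagged
#'   `small = TRUE` (default 5).
#' @return A `compartment_summary` data.frame: `contrast`, `compartment`,
#'   `n`, `median_l2fc`, `iqr`, `small`.
#' @export
compartment_l2fc_distribution <- function(de_table, assignments,
                                          contrast = NULL, min_size = 5L) {
  stopifnot(all(c("feature", "l2fc") %in% names(de_table)))
  if (is.null(contrast))
    contrast <- if (!is.null(de_table$contrast)) de_table$contrast[1L] else NA
  missing_assign <- setdiff(de_table$feature, names(assignments))
  if (length(missing_assign))
    stop(length(missing_assign), " feature(s) without a compartment ",
         "assignment; map them to \"unannotated\" explicitly")
  if (is.list(assignments)) {
    expand <- assignments[de_table$feature]
    n_each <- lengths(expand)
    df <- data.frame(compartment = unlist(expand, use.names = FALSE),
                     l2fc = rep(de_table$l2fc, n_each))
  } else {
    df <- data.frame(compartment = unname(assignments[de_table$feature]),
                     l2fc = de_table$l2fc)
  }
  df <- df[is.finite(df$l2fc), , drop = FALSE]
  sp <- split(df$l2fc, df$compartment)
  out <- data.frame(
    contrast = contrast,
    compartment = names(sp),
    n = lengths(sp),
    median_l2fc = vapply(sp, stats::median, numeric(1L)),
    iqr = vapply(sp, stats::IQR, numeric(1L)),
    row.names = NULL)
  out$small <- out$n < min_size
  out <- out[order(-out$n), ]
  rownames(out) <- NULL
  class(out) <- c("compartment_summary", "data.frame")
  out
}
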