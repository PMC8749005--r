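# Delimited-matrix + JSON-sidecar serialization used across stages.

#' Write a numeric matrix as delimited text with a JSON sidecar
#'
#' @param mat numeric matrix (e.g. regions x time).
#' @param path output `.tsv` path; the sidecar goes to `<path>.json`.
#' @param meta named list of metadata (TR, session, seed, ...).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, meta = list()) {
  if (is.null(colnames(mat))) colnames(mat) <- paste0("V", seq_len(ncol(mat)))
  has_rn <- !is.null(rownames(mat))
  utils::write.table(mat, path, sep = "\t", quote = FALSE,
                     row.names = has_rn,
                     col.names = if (has_rn) NA else TRUE)
  meta$dim <- dim(mat)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path the `.tsv` path.
#' @return The matrix, with the sidecar (if present) in attribute
#'   `"meta"`.
#' @export
read_matrix_tsv <- function(path) {
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else NULL
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  # a leading empty field marks the row-name corner cell
  has_rn <- !nzchar(first[1])
  mat <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                     row.names = if (has_rn) 1 else NULL,
                                     check.names = FALSE))
  storage.mode(mat) <- "double"
  attr(mat, "meta") <- meta
  mat
}

#' Write an embedding as CSV plus JSON metadata
#'
#' CSV columns: the sample labels followed by `dim1..dimK`; the JSON
#' carries `t_selected`, `stress`, variance fractions, and parameters.
#'
#' @param embedding a `phate_embedding`.
#' @param path output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  df <- as.data.frame(embedding$coords)
  if (!is.null(embedding$labels)) df <- cbind(embedding$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(t_selected = embedding$t_selected, stress = embedding$stress,
         variance_fraction = embedding$variance_fraction,
         params = embedding$params, embedding_id = embedding$embedding_id),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a community lookup table
#'
#' Two-column tab-separated file mapping `region_id` to one of the four
#' network communities (`Sensory`, `Associative`, `Default`,
#' `Non-hub`). Every region must be mapped exactly once.
#'
#' @param path TSV path with header `region_id`, `community`.
#' @return data.frame with `region_id`, `community`.
#' @export
read_community_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "community") %in% names(tab))) {
    stopf("community table needs columns region_id and community")
  }
  if (anyDuplicated(tab$region_id)) {
    stopf("region(s) mapped more than once: %s",
          paste(utils::head(tab$region_id[duplicated(tab$region_id)], 5),
                collapse = ", "))
  }
  allowed <- c("Sensory", "Associative", "Default", "Non-hub")
  bad <- setdiff(unique(tab$community), allowed)
  if (length(bad)) {
    stopf("unknown community label(s): %s", paste(bad, collapse = ", "))
  }
  tab
}
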