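#' Pan-genome matrix container
#'
#' A family-by-genome matrix of gene copy counts. Rows are homolog families,
#' columns genomes; a presence/absence view is `pan > 0`.
#'
#' @param m Numeric/integer matrix with rownames (families) and colnames
#'   (genomes).
#' @return A `pan_matrix`.
#' @export
new_pan_matrix <- function(m) {
  m <- as.matrix(m)
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "pan matrix needs family rownames and genome colnames")
  storage.mode(m) <- "integer"
  assert_that(all(m >= 0), "copy counts must be non-negative")
  structure(m, class = c("pan_matrix", class(m)))
}

#' @export
print.pan_matrix <- function(x, ...) {
  cat(sprintf("<pan_matrix> %d families x %d genomes (%d presence cells)\n",
              nrow(x), ncol(x), sum(x > 0)))
  invisible(x)
}

#' Long-format view of a pan matrix
#'
#' @param x A `pan_matrix`.
#' @param ... Unused.
#' @return Tibble with columns family, genome, count.
#' @export
as_tibble.pan_matrix <- function(x, ...) {
  tibble(
    family = rep(rownames(x), times = ncol(x)),
    genome = rep(colnames(x), each = nrow(x)),
    count = as.integer(x)
  )
}

#' @rdname new_pan_matrix
#' @param path TSV path (first column `family`, then one column per genome).
#' @export
write_pan_matrix <- function(m, path) {
  df <- data.frame(family = rownames(m), as.data.frame(unclass(m)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname new_pan_matrix
#' @export
read_pan_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$family
  new_pan_matrix(m)
}

presence_view <- function(pan) {
  unclass(pan) > 0
}
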