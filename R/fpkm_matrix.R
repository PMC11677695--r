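#' FPKM expression matrix
#'
#' A validated transcript-by-tissue matrix of FPKM values (fragments per
#' kilobase of transcript per million mapped reads), the substrate of all
#' filter rules. One row per transcript, one column per tissue; all values
#' finite and non-negative; transcript ids and tissue labels unique.
#'
#' @param values a numeric matrix or data frame with transcript ids as row
#'   names and tissue labels as column names.
#' @return an object of class `fpkm_matrix` (a numeric matrix).
#' @export
#' @examples
#' m <- matrix(c(8, 1, 1, 1, 1, 0.5), nrow = 1,
#'             dimnames = list("TR000001", fpkm_tissues()))
#' fpkm_matrix(m)
fpkm_matrix <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_fmt("`values` must be a numeric matrix or data frame.",
              class = "semarkr_validation_error")
  }
  if (nrow(values) == 0) {
    dimnames(values) <- list(character(0), colnames(values))
  }
  ids <- rownames(values)
  tissues <- colnames(values)
  if ((is.null(ids) && nrow(values) > 0) || is.null(tissues)) {
    abort_fmt("FPKM matrix needs transcript row names and tissue column names.",
              class = "semarkr_validation_error")
  }
  if (anyDuplicated(ids)) {
    abort_fmt("duplicated transcript id(s): %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", "),
              class = "semarkr_validation_error")
  }
  if (anyDuplicated(tissues)) {
    abort_fmt("duplicated tissue label(s): %s",
              paste(unique(tissues[duplicated(tissues)]), collapse = ", "),
              class = "semarkr_validation_error")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- ids[which(rowSums(!is.finite(values)) > 0)]
    abort_fmt("missing or non-finite FPKM value(s) in row(s): %s",
              paste(utils::head(bad, 5), collapse = ", "),
              class = "semarkr_validation_error")
  }
  if (any(values < 0)) {
    bad <- ids[which(rowSums(values < 0) > 0)]
    abort_fmt("negative FPKM value(s) in row(s): %s",
              paste(utils::head(bad, 5), collapse = ", "),
              class = "semarkr_validation_error")
  }
  structure(values, class = c("fpkm_matrix", "matrix", "array"))
}

#' @export
print.fpkm_matrix <- function(x, ...) {
  cat(sprintf("<fpkm_matrix> %d transcripts x %d tissues (%s)\n",
              nrow(x), ncol(x), paste(colnames(x), collapse = ", ")))
  print(utils::head(unclass(x), 6), ...)
  if (nrow(x) > 6) cat(sprintf("... and %d more transcripts\n", nrow(x) - 6))
  invisible(x)
}

is_fpkm_matrix <- function(x) inherits(x, "fpkm_matrix")
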