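#' Summarize subset sizes and shares
#'
#' Computes, from a classification, the per-subset sizes, the total number of
#' hits counting a transcript once per subset it belongs to (the
#' "with-multiplicity" total used as the percentage denominator), per-subset
#' percentage shares of that total (rounded half-up), the organogenesis and
#' SE totals, and — over the four SE subsets — the number of transcripts
#' unique to exactly one SE subset.
#'
#' The with-multiplicity denominator, not the union size, is what reproduces
#' the published shares of the reference study design (e.g. 8687 of 16,748
#' hits = 51.87%).
#'
#' @param classification a `deg_classification` from [classify()].
#' @param config an [se_config()]; supplies `rounding_decimals`.
#' @return an object of class `subset_summary`: named numerics `sizes` and
#'   `percentages`, integers `total_hits`, `organogenesis_total`, `se_total`,
#'   and named integer `unique_counts` over the SE subsets present.
#' @export
#' @examples
#' cls <- classification_from_sizes(c(rl_specific = 2, early_se = 1))
#' summarize_subsets(cls)
summarize_subsets <- function(classification, config = se_config()) {
  stopifnot(inherits(classification, "deg_classification"))
  m <- classification$memberships
  if (length(m) == 0) {
    abort_fmt("classification has an empty subset vocabulary.",
              class = "semarkr_validation_error")
  }
  sizes <- lengths(m)
  total_hits <- sum(sizes)
  percentages <- if (total_hits == 0) {
    stats::setNames(numeric(0), character(0))
  } else {
    round_half_up(100 * sizes / total_hits, config$rounding_decimals)
  }
  org <- intersect(names(m), organogenesis_subsets())
  se <- intersect(names(m), se_subsets())
  unique_counts <- se_unique_counts(m, se)
  structure(
    list(
      sizes = sizes,
      total_hits = total_hits,
      percentages = percentages,
      organogenesis_total = sum(sizes[org]),
      se_total = sum(sizes[se]),
      unique_counts = unique_counts
    ),
    class = "subset_summary"
  )
}

se_unique_counts <- function(memberships, se_labels) {
  if (length(se_labels) == 0) return(stats::setNames(integer(0), character(0)))
  ids <- unique(unlist(memberships[se_labels], use.names = FALSE))
  counts <- stats::setNames(integer(length(se_labels)), se_labels)
  if (length(ids) == 0) return(counts)
  in_subset <- vapply(se_labels, function(s) ids %in% memberships[[s]],
                      logical(length(ids)))
  in_subset <- matrix(in_subset, nrow = length(ids),
                      dimnames = list(ids, se_labels))
  n_memberships <- rowSums(in_subset)
  for (s in se_labels) {
    counts[[s]] <- sum(in_subset[, s] & n_memberships == 1)
  }
  counts
}

#' @export
print.subset_summary <- function(x, ...) {
  cat(sprintf("<subset_summary> total hits (with multiplicity): %d\n",
              x$total_hits))
  cat(sprintf("  organogenesis total: %d   SE total: %d\n",
              x$organogenesis_total, x$se_total))
  for (s in names(x$sizes)) {
    pct <- if (length(x$percentages)) sprintf(" (%.2f%%)", x$percentages[[s]]) else ""
    uniq <- if (s %in% names(x$unique_counts))
      sprintf("  unique: %d", x$unique_counts[[s]]) else ""
    cat(sprintf("  %-12s %6d%s%s\n", s, x$sizes[[s]], pct, uniq))
  }
  invisible(x)
}

#' Build a classification directly from subset sizes
#'
#' Convenience constructor for summary arithmetic on published subset sizes:
#' creates a classification whose subsets are filled with disjoint
#' placeholder ids of the requested sizes. Totals and percentage shares
#' depend only on the sizes, so [summarize_subsets()] on the result
#' reproduces the arithmetic of any sizes-only report.
#'
#' @param sizes named integer vector, subset label -> size.
#' @return a `deg_classification`.
#' @export
classification_from_sizes <- function(sizes) {
  stopifnot(is.numeric(sizes), !is.null(names(sizes)), all(sizes >= 0))
  memberships <- list()
  offset <- 0L
  for (s in names(sizes)) {
    n <- as.integer(sizes[[s]])
    memberships[[s]] <- if (n > 0) sprintf("x%08d", offset + seq_len(n)) else character(0)
    offset <- offset + n
  }
  new_deg_classification(memberships,
                         unlist(memberships, use.names = FALSE))
}

#' Venn-region overlap table for the SE subsets
#'
#' For every non-empty combination of the subsets considered (by default the
#' four SE subsets present in the classification), counts the transcripts
#' belonging to exactly that combination. The regions partition the union:
#' each transcript is counted in exactly one region.
#'
#' @param classification a `deg_classification`.
#' @param subsets subset labels to cross; defaults to the SE subsets present.
#' @return a tibble with columns `combination` (labels joined by `+` in
#'   canonical subset order), `n_subsets` and `count`, sorted by `n_subsets`
#'   then combination.
#' @export
overlap_table <- function(classification, subsets = NULL) {
  stopifnot(inherits(classification, "deg_classification"))
  m <- classification$memberships
  if (is.null(subsets)) subsets <- intersect(names(m), se_subsets())
  missing <- setdiff(subsets, names(m))
  if (length(missing)) {
    abort_fmt("classification lacks subset(s): %s",
              paste(missing, collapse = ", "),
              class = "semarkr_validation_error")
  }
  ids <- unique(unlist(m[subsets], use.names = FALSE))
  if (length(ids) == 0) {
    return(tibble::tibble(combination = character(0),
                          n_subsets = integer(0), count = integer(0)))
  }
  sig <- vapply(ids, function(id) {
    inset <- subsets[vapply(subsets, function(s) id %in% m[[s]], logical(1))]
    paste(inset, collapse = "+")
  }, character(1))
  tab <- table(sig)
  out <- tibble::tibble(
    combination = names(tab),
    n_subsets = lengths(strsplit(names(tab), "+", fixed = TRUE)),
    count = as.integer(tab)
  )
  dplyr::arrange(out, .data$n_subsets, .data$combination)
}
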