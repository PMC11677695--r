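#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct against log10(copy number) for a serial
#' dilution series (the study design spans 1e9 down to 1e2 copies).
#' Amplification efficiency is `100 * (10^(-1/slope) - 1)`: a slope of
#' -3.3219 (= -1/log10(2)) means perfect doubling per cycle, 100%. The QC
#' flag requires a negative slope and efficiency within the optimal 90-110%
#' range.
#'
#' @param copies positive copy numbers of the dilution points.
#' @param ct observed Ct values, same length.
#' @param gene gene symbol the curve belongs to.
#' @return an object of class `standard_curve`: `gene`, `slope`, `intercept`
#'   (the Ct at one copy, log10 copies = 0), `r_squared`, `efficiency_pct`,
#'   `qc_pass`, `n_levels`.
#' @export
#' @examples
#' copies <- 10^(9:2)
#' ct <- 10 + 3.3219 * (9 - log10(copies))
#' fit_standard_curve(copies, ct, "RPL2")
fit_standard_curve <- function(copies, ct, gene = "gene") {
  stopifnot(is.numeric(copies), is.numeric(ct), length(copies) == length(ct))
  if (any(copies <= 0) || any(ct <= 0)) {
    abort_fmt("copies and ct must be positive.",
              class = "semarkr_validation_error")
  }
  if (length(unique(copies)) < 3) {
    abort_fmt("standard curve needs >= 3 distinct copy-number levels (got %d).",
              length(unique(copies)), class = "semarkr_validation_error")
  }
  x <- log10(copies)
  fit <- stats::lm(ct ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # computed directly: summary.lm() warns on the perfect fits that ideal
  # dilution series legitimately produce
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  r_squared <- 1 - ss_res / ss_tot
  efficiency_pct <- 100 * (10^(-1 / slope) - 1)
  qc_pass <- slope < 0 && efficiency_pct >= 90 && efficiency_pct <= 110
  structure(
    list(gene = gene, slope = slope, intercept = intercept,
         r_squared = r_squared, efficiency_pct = efficiency_pct,
         qc_pass = qc_pass, n_levels = length(unique(copies))),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> %s: slope %.4f, intercept %.2f, R^2 %.4f, efficiency %.2f%% [%s]\n",
    x$gene, x$slope, x$intercept, x$r_squared, x$efficiency_pct,
    if (x$qc_pass) "QC pass" else "QC FAIL"))
  invisible(x)
}

#' Impute undetected Ct values from standard-curve intercepts
#'
#' Replaces each undetected (out-of-detection-range) record's Ct with the
#' y-intercept of that gene's standard curve — the detection-floor Ct at a
#' single template copy. Detected records are untouched. The records that
#' were imputed are attached as the `"imputations"` attribute for audit.
#'
#' @param dataset a Ct tibble ([read_ct_long()] / [gen_ct()] columns).
#' @param curves a named list of [fit_standard_curve()] objects (or a single
#'   one), names matching gene symbols.
#' @return the dataset with undetected Cts filled in and `undetected` still
#'   flagging which records were imputed.
#' @export
impute_undetected <- function(dataset, curves) {
  if (inherits(curves, "standard_curve")) {
    curves <- stats::setNames(list(curves), curves$gene)
  }
  idx <- which(dataset$undetected)
  if (length(idx) == 0) return(dataset)
  audit <- list()
  for (i in idx) {
    g <- dataset$gene[i]
    curve <- curves[[g]]
    if (is.null(curve)) {
      abort_fmt("no standard curve for %s", g,
                class = "semarkr_validation_error")
    }
    dataset$ct[i] <- curve$intercept
    audit[[length(audit) + 1L]] <- tibble::tibble(
      tissue = dataset$tissue[i], gene = g,
      replicate = dataset$replicate[i], imputed_ct = curve$intercept)
  }
  attr(dataset, "imputations") <- dplyr::bind_rows(audit)
  inform_verbose("impute_undetected: %d record(s) imputed", length(idx))
  dataset
}

ct_lookup <- function(dataset, gene, tissue) {
  rows <- dataset[dataset$gene == gene & dataset$tissue == tissue, ]
  stats::setNames(rows$ct, rows$replicate)
}

#' Relative expression by the Livak 2^-ddCt method
#'
#' Per tissue and biological replicate: the reference Ct is the arithmetic
#' mean of the two reference-gene Cts (equivalently the geometric mean of
#' their quantities); dCt = target Ct - reference Ct; ddCt subtracts the
#' calibrator tissue's mean dCt; the replicate-level log2 fold change is
#' -ddCt. Replicates are paired by replicate index across target and
#' references. Per-tissue mean, standard error and replicate count are
#' reported; the calibrator's mean log2 fold change is 0 by construction.
#'
#' Efficiency is assumed 100% (pure Livak); standard curves serve QC and
#' undetected-Ct imputation only. Undetected records must be imputed first
#' ([impute_undetected()]).
#'
#' @param dataset a Ct tibble with no undetected records among the genes
#'   involved.
#' @param target target gene symbol.
#' @param references two reference gene symbols (default `RPL2`, `TBP1`).
#' @param calibrator calibrator tissue (default `"rl"`, rosette leaf).
#' @param tissues tissues to report; defaults to all tissues in the dataset,
#'   in [qpcr_tissues()] order.
#' @return a tibble `gene`, `tissue`, `log2_fc`, `se`, `n`, with the
#'   replicate-level log2 fold changes attached as attribute `"replicates"`.
#' @export
relative_expression <- function(dataset, target,
                                references = c("RPL2", "TBP1"),
                                calibrator = "rl", tissues = NULL) {
  stopifnot(length(references) == 2, length(target) == 1)
  if (is.null(tissues)) {
    present <- unique(dataset$tissue)
    canonical <- qpcr_tissues()
    tissues <- c(intersect(canonical, present), setdiff(present, canonical))
  }
  if (!calibrator %in% tissues || !calibrator %in% dataset$tissue) {
    abort_fmt("calibrator tissue '%s' absent from the dataset.", calibrator,
              class = "semarkr_validation_error")
  }
  genes <- c(target, references)
  involved <- dataset$gene %in% genes & dataset$tissue %in% tissues
  if (any(dataset$undetected[involved])) {
    abort_fmt(
      "undetected Ct records present for %s; run impute_undetected() first.",
      paste(unique(dataset$gene[involved & dataset$undetected]),
            collapse = ", "),
      class = "semarkr_validation_error")
  }

  delta_ct <- function(tissue) {
    tgt <- ct_lookup(dataset, target, tissue)
    if (length(tgt) == 0) {
      abort_fmt("no measurements of target '%s' in tissue '%s'.",
                target, tissue, class = "semarkr_validation_error")
    }
    r1 <- ct_lookup(dataset, references[1], tissue)
    r2 <- ct_lookup(dataset, references[2], tissue)
    reps <- names(tgt)
    if (!all(reps %in% names(r1)) || !all(reps %in% names(r2))) {
      abort_fmt("missing reference measurement (%s or %s) in tissue '%s'.",
                references[1], references[2], tissue,
                class = "semarkr_validation_error")
    }
    tgt - (r1[reps] + r2[reps]) / 2
  }

  cal_mean <- mean(delta_ct(calibrator))
  per_tissue <- lapply(tissues, function(tis) {
    lfc <- -(delta_ct(tis) - cal_mean)
    tibble::tibble(gene = target, tissue = tis,
                   replicate = as.integer(names(lfc)), log2_fc = unname(lfc))
  })
  reps <- dplyr::bind_rows(per_tissue)
  out <- dplyr::summarise(
    dplyr::group_by(reps, .data$gene, .data$tissue),
    mean_lfc = mean(.data$log2_fc),
    se = if (dplyr::n() > 1) stats::sd(.data$log2_fc) / sqrt(dplyr::n()) else NA_real_,
    n = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::rename(out, log2_fc = "mean_lfc")
  out <- out[match(tissues, out$tissue), ]
  attr(out, "replicates") <- reps
  out
}

#' One-way ANOVA with Tukey HSD and compact letter display
#'
#' Fits a one-way ANOVA across tissues, runs Tukey's honestly-significant-
#' difference all-pairs comparisons at level `alpha`, and summarises them as
#' a compact letter display by the insert-and-absorb algorithm over tissues
#' ordered by descending mean: tissues sharing a letter are not significantly
#' different.
#'
#' @param values named list, tissue -> numeric vector of replicate values
#'   (e.g. replicate-level log2 fold changes).
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter groups, one per tissue, with the
#'   Tukey p-value matrix attached as attribute `"p_values"`.
#' @export
#' @examples
#' anova_tukey(list(rl = c(-0.1, 0, 0.1), ec = c(9.9, 10, 10.1)))
anova_tukey <- function(values, alpha = 0.05) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (length(values) < 2) {
    abort_fmt("need >= 2 tissues for ANOVA.",
              class = "semarkr_validation_error")
  }
  if (any(lengths(values) < 2)) {
    abort_fmt("every tissue needs >= 2 replicates.",
              class = "semarkr_validation_error")
  }
  if (all(vapply(values, stats::var, numeric(1)) == 0)) {
    abort_fmt(paste("zero within-group variance in every tissue: Tukey HSD is",
                    "undefined; add replicate-level variation or compare",
                    "means directly."),
              class = "semarkr_degenerate_error")
  }
  tissues <- names(values)
  df <- data.frame(
    value = unlist(values, use.names = FALSE),
    tissue = factor(rep(tissues, lengths(values)), levels = tissues)
  )
  fit <- stats::aov(value ~ tissue, data = df)
  tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$tissue

  k <- length(tissues)
  p <- matrix(1, k, k, dimnames = list(tissues, tissues))
  pair_names <- rownames(tuk)
  for (i in seq_along(pair_names)) {
    ab <- strsplit(pair_names[i], "-", fixed = TRUE)[[1]]
    p[ab[1], ab[2]] <- p[ab[2], ab[1]] <- tuk[i, "p adj"]
  }

  means <- vapply(values, mean, numeric(1))
  ordered <- tissues[order(-means)]
  letters_vec <- cld_insert_absorb(p[ordered, ordered, drop = FALSE], alpha)
  out <- letters_vec[tissues]
  attr(out, "p_values") <- p
  out
}

# Insert-and-absorb compact letter display (Piepho-style) on a symmetric
# p-value matrix whose rows are already ordered by descending group mean.
cld_insert_absorb <- function(p, alpha) {
  groups <- rownames(p)
  k <- length(groups)
  # columns = letter classes, each a logical membership vector over groups
  cols <- list(rep(TRUE, k))
  sig_pairs <- which(p < alpha & upper.tri(p), arr.ind = TRUE)
  if (nrow(sig_pairs)) {
    for (idx in seq_len(nrow(sig_pairs))) {
      i <- sig_pairs[idx, 1]
      j <- sig_pairs[idx, 2]
      new_cols <- list()
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a), list(b))
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      # absorb: drop duplicates, then any column that is a subset of another
      new_cols <- unique(new_cols)
      is_subset <- vapply(seq_along(new_cols), function(a) {
        any(vapply(seq_along(new_cols), function(b) {
          a != b && all(new_cols[[a]] <= new_cols[[b]])
        }, logical(1)))
      }, logical(1))
      cols <- new_cols[!is_subset]
    }
  }
  # order letter columns by their highest-ranked member for stable labels
  first_member <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first_member)]
  out <- vapply(seq_len(k), function(g) {
    paste(letters[which(vapply(cols, `[`, logical(1), g))], collapse = "")
  }, character(1))
  stats::setNames(out, groups)
}

#' Full relative-expression table with significance letters
#'
#' Runs [relative_expression()] for each target gene, then [anova_tukey()]
#' on the replicate-level log2 fold changes across tissues, and additionally
#' flags each tissue's Tukey comparison against the calibrator.
#'
#' @param dataset a Ct tibble (undetected records already imputed).
#' @param targets character vector of target gene symbols.
#' @param references two reference gene symbols.
#' @param calibrator calibrator tissue label.
#' @param alpha significance level for the post hoc test.
#' @param tissues tissues to report (default: all present).
#' @return a tibble `gene`, `tissue`, `log2_fc`, `se`, `n`, `letters`,
#'   `sig_vs_calibrator`.
#' @export
relative_expression_table <- function(dataset, targets,
                                      references = c("RPL2", "TBP1"),
                                      calibrator = "rl", alpha = 0.05,
                                      tissues = NULL) {
  rows <- lapply(targets, function(g) {
    rel <- relative_expression(dataset, g, references, calibrator, tissues)
    reps <- attr(rel, "replicates")
    by_tissue <- split(reps$log2_fc, reps$tissue)[unique(reps$tissue)]
    lett <- anova_tukey(by_tissue, alpha)
    pmat <- attr(lett, "p_values")
    rel$letters <- unname(lett[rel$tissue])
    rel$sig_vs_calibrator <- pmat[rel$tissue, calibrator] < alpha
    rel
  })
  dplyr::bind_rows(rows)
}
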