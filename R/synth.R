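#' Generate a synthetic FPKM matrix with planted subset members
#'
#' Emulates a pooled bulk-RNA-seq FPKM table over the six sequenced tissues.
#' Background transcripts are drawn i.i.d. log-normal (median ~2 FPKM, the
#' right-skewed shape typical of bulk expression tables) and rejection-
#' sampled so that none satisfies any selection rule — clean negatives, not
#' probabilistic ones. Planted transcripts are constructed to satisfy their
#' target rule's inequalities with multiplicative slack of at least `margin`,
#' and to satisfy no other rule beyond those logically implied: with the
#' default conjunctive early-SE rule, `ec_induction` and `all_se` plants
#' necessarily also belong to `early_se`, and the recorded truth says so.
#'
#' @param n_background number of background transcripts.
#' @param n_per_subset named integer vector, subset label -> number of
#'   planted transcripts (labels from [all_subsets()]).
#' @param margin multiplicative slack > 1 on every planted inequality.
#' @param config an [se_config()]; supplies rule constants and the seed.
#' @param sigma log-normal sdlog of background FPKM values.
#' @return a list: `matrix` (an [fpkm_matrix()]) and `truth` (class
#'   `synthetic_truth`: `planted_memberships`, `seed`, `noise_params`).
#' @export
#' @examples
#' sim <- gen_fpkm(100, c(rl_specific = 5), config = se_config(seed = 7))
#' classify(sim$matrix)$memberships$rl_specific
gen_fpkm <- function(n_background, n_per_subset = integer(0), margin = 2,
                     config = se_config(), sigma = 1.5) {
  stopifnot(n_background >= 0, margin > 1, all(n_per_subset >= 0))
  bad <- setdiff(names(n_per_subset), all_subsets())
  if (length(bad)) {
    abort_fmt("unknown subset label(s) in n_per_subset: %s",
              paste(bad, collapse = ", "), class = "semarkr_validation_error")
  }
  set.seed(config$seed)
  rules <- builtin_rules(config)
  tissues <- config$fpkm_tissues
  fold <- config$fold_threshold
  minf <- max(config$min_fpkm, .Machine$double.eps)

  # below min_fpkm so no MinFpkm atom can fire on these tissues
  lows <- function(n, k) {
    matrix(stats::runif(n * k, 0.05, 0.5) * min(minf, 1), n, k)
  }

  plant <- function(subset, n) {
    vals <- matrix(0, n, length(tissues), dimnames = list(NULL, tissues))
    if (subset %in% organogenesis_subsets()) {
      target <- sub("_specific$", "", subset)
      others <- setdiff(tissues, target)
      vals[, others] <- lows(n, length(others))
      vals[, target] <- margin *
        pmax(minf, fold * apply(vals[, others, drop = FALSE], 1, max))
    } else if (subset == "ec_induction") {
      others <- c("rl", "rr", "abl", "cse", "gse")
      vals[, others] <- lows(n, length(others))
      comp <- c("rl", "rr", "abl", "cse")
      vals[, "ec"] <- margin *
        pmax(minf, fold * apply(vals[, comp, drop = FALSE], 1, max),
             vals[, "gse"])
    } else if (subset == "early_se") {
      # gse route: early_se without tripping ec_induction or late_se
      others <- setdiff(tissues, "gse")
      vals[, others] <- lows(n, length(others))
      vals[, "gse"] <- margin * pmax(minf, fold * vals[, "abl"])
    } else if (subset == "late_se") {
      others <- c("rl", "rr", "abl", "ec", "gse")
      vals[, others] <- lows(n, length(others))
      comp <- c("rl", "rr", "abl", "ec")
      vals[, "cse"] <- margin *
        pmax(minf, fold * apply(vals[, comp, drop = FALSE], 1, max),
             vals[, "gse"])
    } else if (subset == "all_se") {
      org <- c("rl", "rr", "abl")
      vals[, org] <- lows(n, length(org))
      level <- margin *
        pmax(minf, fold * apply(vals[, org, drop = FALSE], 1, max))
      # exactly equal embryogenic levels: the strict ec>gse / cse>gse
      # comparisons of ec_induction and late_se then fail deterministically
      vals[, c("ec", "gse", "cse")] <- level
    }
    vals
  }

  implied_memberships <- function(subset) {
    if (config$early_rule_mode == "conjunctive" &&
        subset %in% c("ec_induction", "all_se")) {
      c(subset, "early_se")
    } else {
      subset
    }
  }

  planted_rows <- list()
  planted_truth <- stats::setNames(
    rep(list(character(0)), length(all_subsets())), all_subsets())
  idx <- 0L
  for (s in names(n_per_subset)) {
    n <- as.integer(n_per_subset[[s]])
    if (n == 0) next
    vals <- plant(s, n)
    ids <- sprintf("TRP%06d", idx + seq_len(n))
    idx <- idx + n
    rownames(vals) <- ids
    planted_rows[[s]] <- vals
    for (lab in implied_memberships(s)) {
      planted_truth[[lab]] <- c(planted_truth[[lab]], ids)
    }
  }

  background <- matrix(numeric(0), 0, length(tissues),
                       dimnames = list(NULL, tissues))
  if (n_background > 0) {
    draw <- function(n) {
      matrix(stats::rlnorm(n * length(tissues), meanlog = log(2),
                           sdlog = sigma),
             n, length(tissues), dimnames = list(NULL, tissues))
    }
    background <- draw(n_background)
    for (iter in seq_len(100)) {
      rownames(background) <- sprintf("b%07d", seq_len(nrow(background)))
      cls <- classify(fpkm_matrix(background), rules)
      hit <- unique(unlist(cls$memberships, use.names = FALSE))
      if (length(hit) == 0) break
      redo <- rownames(background) %in% hit
      background[redo, ] <- draw(sum(redo))
      if (iter == 100) {
        abort_fmt("background rejection sampling did not converge.",
                  class = "semarkr_synth_error")
      }
    }
    rownames(background) <- sprintf("TRB%06d", seq_len(n_background))
  }

  values <- rbind(do.call(rbind, unname(planted_rows)), background)
  if (is.null(values)) values <- background
  m <- fpkm_matrix(values)
  truth <- structure(
    list(planted_memberships = lapply(planted_truth, sort),
         seed = config$seed,
         noise_params = list(fpkm_lognormal_sigma = sigma, margin = margin)),
    class = "synthetic_truth"
  )
  list(matrix = m, truth = truth)
}

#' Generate a synthetic RT-qPCR Ct dataset with planted fold changes
#'
#' Emulates the study's qPCR design: per tissue and biological replicate,
#' target Ct = `base_ct` - planted log2 fold change + Normal(0, `ct_sd`)
#' noise; reference-gene Cts = `ref_base_ct` + noise. Any Ct above the
#' detection ceiling is emitted as an undetected record (the behaviour of
#' transcripts dropping below RT-qPCR detection in some tissues). Reference
#' genes must carry a planted fold change of 0 everywhere.
#'
#' @param genes character vector of target gene symbols.
#' @param tissues tissue labels (default the nine-tissue qPCR panel).
#' @param n_reps biological replicates per (gene, tissue) (default 3).
#' @param truth_log2fc numeric matrix gene x tissue of planted log2 fold
#'   changes relative to the calibrator; rows for reference genes optional
#'   (assumed all-zero) but must be zero if present.
#' @param ct_sd replicate noise in cycles (default 0.2).
#' @param detection_limit_ct Ct ceiling above which a measurement is
#'   undetected (default 40 cycles).
#' @param seed integer RNG seed.
#' @param base_ct baseline target Ct at fold change 0 (default 25 cycles).
#' @param ref_base_ct baseline reference-gene Ct (default 20 cycles).
#' @param references the two reference gene symbols.
#' @return a list: `dataset` (a Ct tibble) and `truth` (class
#'   `synthetic_truth` carrying `planted_log2fc`, `seed`, `noise_params`).
#' @export
gen_ct <- function(genes, tissues = qpcr_tissues(), n_reps = 3,
                   truth_log2fc, ct_sd = 0.2, detection_limit_ct = 40,
                   seed = 1L, base_ct = 25, ref_base_ct = 20,
                   references = c("RPL2", "TBP1")) {
  stopifnot(n_reps >= 1, ct_sd >= 0, is.matrix(truth_log2fc))
  targets <- setdiff(genes, references)
  missing <- setdiff(targets, rownames(truth_log2fc))
  if (length(missing)) {
    abort_fmt("no planted fold changes for gene(s): %s",
              paste(missing, collapse = ", "),
              class = "semarkr_validation_error")
  }
  if (!all(tissues %in% colnames(truth_log2fc))) {
    abort_fmt("truth_log2fc lacks tissue column(s): %s",
              paste(setdiff(tissues, colnames(truth_log2fc)), collapse = ", "),
              class = "semarkr_validation_error")
  }
  planted_refs <- intersect(references, rownames(truth_log2fc))
  if (length(planted_refs) &&
      any(truth_log2fc[planted_refs, tissues] != 0)) {
    abort_fmt("reference gene(s) must have planted log2 fold change 0.",
              class = "semarkr_validation_error")
  }
  set.seed(seed)

  grid <- expand.grid(tissue = tissues, gene = c(targets, references),
                      replicate = seq_len(n_reps),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  is_ref <- grid$gene %in% references
  fc <- numeric(nrow(grid))
  fc[!is_ref] <- truth_log2fc[cbind(grid$gene[!is_ref], grid$tissue[!is_ref])]
  base <- ifelse(is_ref, ref_base_ct, base_ct)
  ct <- base - fc + stats::rnorm(nrow(grid), 0, ct_sd)
  undetected <- ct > detection_limit_ct
  ct[undetected] <- NA_real_

  dataset <- tibble::tibble(
    tissue = grid$tissue, gene = grid$gene,
    replicate = as.integer(grid$replicate),
    ct = ct, undetected = undetected
  )
  full_truth <- matrix(0, length(c(targets, references)), length(tissues),
                       dimnames = list(c(targets, references), tissues))
  full_truth[targets, ] <- truth_log2fc[targets, tissues]
  truth <- structure(
    list(planted_log2fc = full_truth, seed = seed,
         noise_params = list(ct_sd = ct_sd,
                             detection_limit_ct = detection_limit_ct,
                             base_ct = base_ct, ref_base_ct = ref_base_ct)),
    class = "synthetic_truth"
  )
  list(dataset = dataset, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> seed:", x$seed, "\n")
  if (!is.null(x$planted_memberships)) {
    cat("  planted members:",
        paste(sprintf("%s=%d", names(x$planted_memberships),
                      lengths(x$planted_memberships)), collapse = " "), "\n")
  }
  if (!is.null(x$planted_log2fc)) {
    cat(sprintf("  planted log2 fold changes: %d genes x %d tissues\n",
                nrow(x$planted_log2fc), ncol(x$planted_log2fc)))
  }
  invisible(x)
}

#' Write synthetic truth to JSON
#'
#' @param truth a `synthetic_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  if (!is.null(obj$planted_log2fc)) {
    obj$planted_log2fc <- list(
      genes = rownames(obj$planted_log2fc),
      tissues = colnames(obj$planted_log2fc),
      values = unname(apply(obj$planted_log2fc, 1, identity, simplify = FALSE))
    )
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
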