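#' Tissue vocabularies
#'
#' The sequenced tissue panel used for FPKM filtering (six tissues: rosette
#' leaf `rl`, rosette root `rr`, adventitious bud `abl`, embryogenic callus
#' `ec`, globular somatic embryo `gse`, cotyledonary somatic embryo `cse`)
#' and the extended RT-qPCR panel (adds field leaf `nl`, field root `nr`,
#' organogenic callus `oc`).
#'
#' @return character vector of tissue labels.
#' @export
fpkm_tissues <- function() c("rl", "rr", "abl", "ec", "gse", "cse")

#' @rdname fpkm_tissues
#' @export
qpcr_tissues <- function() c("rl", "rr", "nl", "nr", "oc", "abl", "ec", "gse", "cse")

#' Subset label vocabularies
#'
#' The seven differential-expression subsets: three tissue-specific
#' (organogenesis) subsets and four somatic-embryogenesis (SE) stage subsets.
#'
#' @return character vector of subset labels.
#' @export
organogenesis_subsets <- function() c("rl_specific", "rr_specific", "abl_specific")

#' @rdname organogenesis_subsets
#' @export
se_subsets <- function() c("ec_induction", "early_se", "late_se", "all_se")

#' @rdname organogenesis_subsets
#' @export
all_subsets <- function() c(organogenesis_subsets(), se_subsets())

#' Run configuration
#'
#' Bundles the analysis parameters: the fold-ratio threshold ("at least
#' `fold_threshold` times higher", default 8), the minimum FPKM required in a
#' target tissue (default 1), the significance level for post hoc tests, the
#' RNG seed used by the synthetic generators, the reading of the early-SE
#' rule, and the number of decimals for reported percentages.
#'
#' @param fold_threshold positive fold-ratio constant (default 8).
#' @param min_fpkm non-negative minimum FPKM in the target tissue (default 1).
#' @param alpha significance level in `[0, 1]` (default 0.05).
#' @param seed integer RNG seed for synthetic-data generation.
#' @param early_rule_mode `"conjunctive"` (default; the minimum-FPKM tissue
#'   and the tissue compared with `abl` must be the same embryogenic tissue)
#'   or `"literal_or"` (a plain disjunction of the four atomic conditions).
#' @param rounding_decimals decimals for reported percentages (default 2).
#' @param fpkm_tissues,qpcr_tissues tissue vocabularies; override only when
#'   reusing the filters on a different tissue panel.
#' @return an object of class `se_config` (a named list).
#' @export
#' @examples
#' se_config(fold_threshold = 3)
se_config <- function(fold_threshold = 8,
                      min_fpkm = 1,
                      alpha = 0.05,
                      seed = 1L,
                      early_rule_mode = c("conjunctive", "literal_or"),
                      rounding_decimals = 2L,
                      fpkm_tissues = c("rl", "rr", "abl", "ec", "gse", "cse"),
                      qpcr_tissues = c("rl", "rr", "nl", "nr", "oc",
                                       "abl", "ec", "gse", "cse")) {
  early_rule_mode <- match.arg(early_rule_mode)
  if (!is.numeric(fold_threshold) || length(fold_threshold) != 1 ||
      !is.finite(fold_threshold) || fold_threshold <= 0) {
    abort_fmt("`fold_threshold` must be a single positive number.",
              class = "semarkr_config_error")
  }
  if (!is.numeric(min_fpkm) || length(min_fpkm) != 1 ||
      !is.finite(min_fpkm) || min_fpkm < 0) {
    abort_fmt("`min_fpkm` must be a single non-negative number.",
              class = "semarkr_config_error")
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha < 0 || alpha > 1) {
    abort_fmt("`alpha` must lie in [0, 1].", class = "semarkr_config_error")
  }
  if (anyDuplicated(fpkm_tissues) || anyDuplicated(qpcr_tissues)) {
    abort_fmt("tissue vocabularies must not contain duplicates.",
              class = "semarkr_config_error")
  }
  structure(
    list(
      fold_threshold = as.numeric(fold_threshold),
      min_fpkm = as.numeric(min_fpkm),
      alpha = as.numeric(alpha),
      seed = as.integer(seed),
      early_rule_mode = early_rule_mode,
      rounding_decimals = as.integer(rounding_decimals),
      fpkm_tissues = fpkm_tissues,
      qpcr_tissues = qpcr_tissues
    ),
    class = "se_config"
  )
}

#' @export
print.se_config <- function(x, ...) {
  cat("<se_config>\n")
  cat("  fold_threshold:", x$fold_threshold,
      " min_fpkm:", x$min_fpkm,
      " alpha:", x$alpha, "\n")
  cat("  early_rule_mode:", x$early_rule_mode,
      " seed:", x$seed, "\n")
  cat("  fpkm tissues:", paste(x$fpkm_tissues, collapse = ", "), "\n")
  cat("  qpcr tissues:", paste(x$qpcr_tissues, collapse = ", "), "\n")
  invisible(x)
}

#' Read a run configuration from YAML
#'
#' Reads a YAML file whose top-level keys are [se_config()] arguments; keys
#' not present keep their defaults.
#'
#' @param path path to a YAML file.
#' @return an `se_config` object.
#' @export
read_se_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) {
    abort_fmt("config file '%s' must contain a YAML mapping.", path,
              class = "semarkr_config_error")
  }
  known <- names(formals(se_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    abort_fmt("unknown config key(s): %s", paste(bad, collapse = ", "),
              class = "semarkr_config_error")
  }
  do.call(se_config, vals)
}
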