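#' Atomic filter conditions
#'
#' The three atoms the subset rules are built from: a minimum FPKM in a
#' target tissue, a non-strict fold-ratio requirement ("at least `fold` times
#' higher", implemented multiplicatively as `target >= fold * comparator` so
#' zero-FPKM comparators need no special case), and a strict comparison
#' between two tissues.
#'
#' @param tissue,target,comparator tissue labels.
#' @param threshold minimum FPKM (non-negative).
#' @param fold positive fold constant.
#' @return a list describing the atom, class `se_atom`.
#' @export
atom_min_fpkm <- function(tissue, threshold) {
  stopifnot(is.character(tissue), length(tissue) == 1, threshold >= 0)
  structure(list(type = "min_fpkm", tissue = tissue, threshold = threshold),
            class = "se_atom")
}

#' @rdname atom_min_fpkm
#' @export
atom_fold_at_least <- function(target, comparator, fold) {
  stopifnot(is.character(target), is.character(comparator), fold > 0)
  structure(list(type = "fold_at_least", target = target,
                 comparator = comparator, fold = fold),
            class = "se_atom")
}

#' @rdname atom_min_fpkm
#' @export
atom_strictly_greater <- function(target, comparator) {
  structure(list(type = "strictly_greater", target = target,
                 comparator = comparator),
            class = "se_atom")
}

#' Construct a subset rule
#'
#' A rule is a disjunction over clauses, each clause a conjunction of atoms.
#' All seven built-in rules have a single clause except the early-SE rule,
#' whose conjunctive reading is a disjunction over the two embryogenic
#' tissues `ec` and `gse`.
#'
#' @param name subset label.
#' @param clauses a list of clauses; each clause is a list of atoms.
#' @return an object of class `subset_rule`.
#' @export
subset_rule <- function(name, clauses) {
  stopifnot(is.character(name), length(name) == 1, is.list(clauses),
            length(clauses) >= 1)
  for (cl in clauses) {
    stopifnot(is.list(cl), length(cl) >= 1)
    for (a in cl) {
      if (!inherits(a, "se_atom")) {
        abort_fmt("rule '%s': clauses must contain `se_atom` objects.", name,
                  class = "semarkr_rule_error")
      }
      if (a$type == "fold_at_least" && a$fold <= 0) {
        abort_fmt("rule '%s': fold must be positive.", name,
                  class = "semarkr_rule_error")
      }
    }
  }
  structure(list(name = name, clauses = clauses), class = "subset_rule")
}

rule_tissues <- function(rule) {
  unique(unlist(lapply(rule$clauses, function(cl) {
    unlist(lapply(cl, function(a) {
      switch(a$type,
             min_fpkm = a$tissue,
             fold_at_least = c(a$target, a$comparator),
             strictly_greater = c(a$target, a$comparator))
    }))
  })))
}

#' The seven built-in selection rules
#'
#' Builds the declarative filter definitions used to classify transcripts
#' into the seven subsets. With the defaults (`fold_threshold = 8`,
#' `min_fpkm = 1`):
#'
#' * `rl_specific`, `rr_specific`, `abl_specific`: FPKM >= 1 in the target
#'   tissue and at least 8x higher than in each of the other five tissues.
#' * `ec_induction`: FPKM >= 1 in `ec`, strictly higher in `ec` than `gse`,
#'   and at least 8x higher in `ec` than in `rl`, `rr`, `abl` and `cse`.
#' * `early_se` (conjunctive reading, the default): some embryogenic tissue
#'   `t` in `{ec, gse}` has FPKM >= 1 **and** at least 8x the `abl` level.
#'   With `early_rule_mode = "literal_or"` the rule is instead the plain
#'   disjunction of the four atomic conditions.
#' * `late_se`: FPKM >= 1 in `cse`, strictly higher in `cse` than `gse`, and
#'   at least 8x higher in `cse` than in `rl`, `rr`, `abl` and `ec`.
#' * `all_se`: FPKM >= 1 in each of `ec`, `gse`, `cse`, and each embryogenic
#'   tissue at least 8x each organogenic tissue (`rl`, `rr`, `abl`).
#'
#' Boundary equality passes every fold atom ("at least"); the `ec > gse` and
#' `cse > gse` comparisons are strict.
#'
#' @param config an [se_config()].
#' @return a named list of seven [subset_rule()] objects.
#' @export
#' @examples
#' rules <- builtin_rules()
#' names(rules)
builtin_rules <- function(config = se_config()) {
  fold <- config$fold_threshold
  minf <- config$min_fpkm
  six <- config$fpkm_tissues
  stopifnot(all(c("rl", "rr", "abl", "ec", "gse", "cse") %in% six))

  tissue_specific <- function(target) {
    others <- setdiff(six, target)
    subset_rule(paste0(target, "_specific"), list(c(
      list(atom_min_fpkm(target, minf)),
      lapply(others, function(o) atom_fold_at_least(target, o, fold))
    )))
  }

  ec_rule <- subset_rule("ec_induction", list(c(
    list(atom_min_fpkm("ec", minf), atom_strictly_greater("ec", "gse")),
    lapply(c("rl", "rr", "abl", "cse"),
           function(o) atom_fold_at_least("ec", o, fold))
  )))

  early_rule <- if (config$early_rule_mode == "conjunctive") {
    subset_rule("early_se", list(
      list(atom_min_fpkm("ec", minf), atom_fold_at_least("ec", "abl", fold)),
      list(atom_min_fpkm("gse", minf), atom_fold_at_least("gse", "abl", fold))
    ))
  } else {
    subset_rule("early_se", list(
      list(atom_min_fpkm("ec", minf)),
      list(atom_min_fpkm("gse", minf)),
      list(atom_fold_at_least("ec", "abl", fold)),
      list(atom_fold_at_least("gse", "abl", fold))
    ))
  }

  late_rule <- subset_rule("late_se", list(c(
    list(atom_min_fpkm("cse", minf), atom_strictly_greater("cse", "gse")),
    lapply(c("rl", "rr", "abl", "ec"),
           function(o) atom_fold_at_least("cse", o, fold))
  )))

  emb <- c("ec", "gse", "cse")
  org <- c("rl", "rr", "abl")
  all_rule <- subset_rule("all_se", list(c(
    lapply(emb, function(t) atom_min_fpkm(t, minf)),
    unlist(lapply(emb, function(e) {
      lapply(org, function(o) atom_fold_at_least(e, o, fold))
    }), recursive = FALSE)
  )))

  rules <- list(tissue_specific("rl"), tissue_specific("rr"),
                tissue_specific("abl"), ec_rule, early_rule, late_rule,
                all_rule)
  stats::setNames(rules, vapply(rules, `[[`, character(1), "name"))
}

eval_atom <- function(atom, values) {
  switch(atom$type,
    min_fpkm = values[, atom$tissue] >= atom$threshold,
    fold_at_least = values[, atom$target] >= atom$fold * values[, atom$comparator],
    strictly_greater = values[, atom$target] > values[, atom$comparator],
    abort_fmt("unknown atom type '%s'.", atom$type, class = "semarkr_rule_error")
  )
}

check_rule_tissues <- function(rules, matrix) {
  need <- unique(unlist(lapply(rules, rule_tissues)))
  missing <- setdiff(need, colnames(matrix))
  if (length(missing)) {
    abort_fmt("matrix lacks tissue column(s) required by the rules: %s",
              paste(missing, collapse = ", "),
              class = "semarkr_config_error")
  }
}

new_deg_classification <- function(memberships, universe) {
  structure(
    list(memberships = memberships, universe = universe,
         universe_size = length(universe)),
    class = "deg_classification"
  )
}

#' Classify transcripts into subsets
#'
#' Evaluates every rule on every transcript of an FPKM matrix. A transcript
#' may belong to several SE subsets (overlap is expected); the three
#' tissue-specific subsets are provably pairwise disjoint for
#' `fold_threshold >= 2` and `min_fpkm > 0`. Memberships are reported sorted
#' by transcript id.
#'
#' `classify_bruteforce()` is a deliberately naive per-transcript, per-atom
#' reference implementation with an identical contract, kept as an
#' independent cross-check of the vectorised `classify()`.
#'
#' @param matrix an [fpkm_matrix()].
#' @param rules a list of [subset_rule()]s, e.g. [builtin_rules()].
#' @return an object of class `deg_classification`: a named list
#'   `memberships` (subset label -> sorted character vector of transcript
#'   ids), the evaluated `universe` of ids, and `universe_size`.
#' @export
#' @examples
#' m <- fpkm_matrix(matrix(c(8, 1, 1, 1, 1, 0.5), nrow = 1,
#'                         dimnames = list("TR000001", fpkm_tissues())))
#' classify(m, builtin_rules())$memberships$rl_specific
classify <- function(matrix, rules = builtin_rules()) {
  stopifnot(is_fpkm_matrix(matrix))
  check_rule_tissues(rules, matrix)
  values <- unclass(matrix)
  ids <- rownames(values) %||% character(0)
  memberships <- lapply(rules, function(rule) {
    hit <- rep(FALSE, nrow(values))
    for (cl in rule$clauses) {
      clause_ok <- rep(TRUE, nrow(values))
      for (a in cl) clause_ok <- clause_ok & eval_atom(a, values)
      hit <- hit | clause_ok
    }
    sort(ids[hit])
  })
  names(memberships) <- vapply(rules, `[[`, character(1), "name")
  inform_verbose("classify: %s",
                 paste(sprintf("%s=%d", names(memberships),
                               lengths(memberships)), collapse = " "))
  new_deg_classification(memberships, rownames(values) %||% character(0))
}

#' @rdname classify
#' @export
classify_bruteforce <- function(matrix, rules = builtin_rules()) {
  stopifnot(is_fpkm_matrix(matrix))
  check_rule_tissues(rules, matrix)
  values <- unclass(matrix)
  names <- vapply(rules, `[[`, character(1), "name")
  memberships <- stats::setNames(
    rep(list(character(0)), length(rules)), names)
  if (nrow(values) > 0) {
    for (i in seq_len(nrow(values))) {
      row <- values[i, , drop = TRUE]
      for (r in seq_along(rules)) {
        rule_ok <- FALSE
        for (cl in rules[[r]]$clauses) {
          clause_ok <- TRUE
          for (a in cl) {
            ok <- switch(a$type,
              min_fpkm = row[[a$tissue]] >= a$threshold,
              fold_at_least = row[[a$target]] >= a$fold * row[[a$comparator]],
              strictly_greater = row[[a$target]] > row[[a$comparator]])
            if (!ok) {
              clause_ok <- FALSE
              break
            }
          }
          if (clause_ok) {
            rule_ok <- TRUE
            break
          }
        }
        if (rule_ok) {
          memberships[[names[r]]] <- c(memberships[[names[r]]],
                                       rownames(values)[i])
        }
      }
    }
  }
  memberships <- lapply(memberships, sort)
  new_deg_classification(memberships, rownames(values) %||% character(0))
}

#' @export
print.deg_classification <- function(x, ...) {
  cat(sprintf("<deg_classification> %d transcripts evaluated\n",
              x$universe_size))
  for (s in names(x$memberships)) {
    cat(sprintf("  %-12s %d\n", s, length(x$memberships[[s]])))
  }
  invisible(x)
}

#' Write per-subset FPKM tables and a membership report
#'
#' Writes one TSV per subset (transcript id plus its FPKM values) and a JSON
#' membership report, mirroring the package's standard outputs for a filter
#' run.
#'
#' @param classification a `deg_classification`.
#' @param matrix the [fpkm_matrix()] that was classified.
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_classification <- function(classification, matrix, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in names(classification$memberships)) {
    ids <- classification$memberships[[s]]
    p <- file.path(out_dir, paste0(s, ".tsv"))
    write_fpkm_table(fpkm_matrix(unclass(matrix)[ids, , drop = FALSE]), p)
    paths[[s]] <- p
  }
  report <- list(universe_size = classification$universe_size,
                 sizes = as.list(lengths(classification$memberships)),
                 memberships = classification$memberships)
  jp <- file.path(out_dir, "membership.json")
  jsonlite::write_json(report, jp, auto_unbox = TRUE, pretty = TRUE)
  paths$membership <- jp
  invisible(paths)
}
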