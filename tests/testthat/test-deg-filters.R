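test_that("builtin_rules builds seven parameterized rules", {
  rules <- builtin_rules()
  expect_named(rules, all_subsets())
  # fold and min-FPKM constants flow from the config
  atoms <- unlist(rules$rl_specific$clauses[[1]], recursive = FALSE)
  folds <- vapply(Filter(function(a) a$type == "fold_at_least",
                         rules$rl_specific$clauses[[1]]),
                  `[[`, numeric(1), "fold")
  expect_equal(unique(folds), 8)
  mins <- Filter(function(a) a$type == "min_fpkm",
                 rules$rl_specific$clauses[[1]])
  expect_equal(mins[[1]]$threshold, 1)

  rules3 <- builtin_rules(se_config(fold_threshold = 3))
  folds3 <- vapply(Filter(function(a) a$type == "fold_at_least",
                          rules3$rl_specific$clauses[[1]]),
                   `[[`, numeric(1), "fold")
  expect_equal(unique(folds3), 3)

  # early rule switches from two conjunctive clauses to four literal atoms
  expect_length(rules$early_se$clauses, 2)
  lit <- builtin_rules(se_config(early_rule_mode = "literal_or"))
  expect_length(lit$early_se$clauses, 4)
  expect_true(all(lengths(lit$early_se$clauses) == 1))
})

test_that("classify matches hand-evaluated rule atoms on boundary rows", {
  member_of <- function(m) {
    cls <- classify(m, builtin_rules())
    names(Filter(length, cls$memberships))
  }
  # exactly 8x is "at least" and passes
  expect_equal(
    member_of(fpkm_row("a", rl = 8, rr = 1, abl = 1, ec = 1, gse = 1,
                       cse = 0.5)),
    "rl_specific")
  # below the minimum FPKM nothing fires
  expect_equal(
    member_of(fpkm_row("b", rl = 0.9, rr = 0, abl = 0, ec = 0, gse = 0,
                       cse = 0)),
    character(0))
  # SE subsets overlap by design
  expect_equal(
    member_of(fpkm_row("c", rl = 1, rr = 1, abl = 1, ec = 10, gse = 2,
                       cse = 1)),
    c("ec_induction", "early_se"))
  # equal embryogenic levels: all_se + early_se, strict > excludes the rest
  expect_equal(
    member_of(fpkm_row("d", rl = 1, rr = 1, abl = 1, ec = 8, gse = 8,
                       cse = 8)),
    c("early_se", "all_se"))
})

test_that("literal_or early rule admits any transcript detected in ec or gse", {
  m <- fpkm_row("x", rl = 50, rr = 50, abl = 50, ec = 1, gse = 0.1,
                cse = 0.1)
  conj <- classify(m, builtin_rules(se_config()))
  lit <- classify(m, builtin_rules(se_config(early_rule_mode = "literal_or")))
  expect_false("x" %in% conj$memberships$early_se)
  expect_true("x" %in% lit$memberships$early_se)
})

test_that("classify errors when a rule tissue is missing from the matrix", {
  m <- structure(matrix(1, 1, 5, dimnames = list("t1", six[-6])),
                 class = c("fpkm_matrix", "matrix", "array"))
  expect_error(classify(m, builtin_rules()), "cse",
               class = "semarkr_config_error")
})

test_that("classify agrees with the brute-force oracle on random matrices", {
  for (seed in c(7, 8)) {
    m <- random_fpkm(600, seed = seed)
    fast <- classify(m, builtin_rules())
    slow <- classify_bruteforce(m, builtin_rules())
    expect_identical(fast$memberships, slow$memberships)
    expect_identical(fast$universe_size, slow$universe_size)
  }
  # degenerate inputs
  empty <- fpkm_matrix(matrix(numeric(0), 0, 6,
                              dimnames = list(NULL, six)))
  expect_identical(classify(empty)$memberships,
                   classify_bruteforce(empty)$memberships)
  expect_equal(classify(empty)$universe_size, 0)
  zeros <- fpkm_rows(matrix(0, 5, 6, dimnames = list(paste0("z", 1:5), six)))
  expect_true(all(lengths(classify(zeros)$memberships) == 0))
})

test_that("disjointness and subset theorems hold on generated data", {
  m <- random_fpkm(2000, seed = 99)
  cls <- classify(m, builtin_rules())
  ms <- cls$memberships
  # tissue-specific subsets pairwise disjoint
  expect_length(intersect(ms$rl_specific, ms$rr_specific), 0)
  expect_length(intersect(ms$rl_specific, ms$abl_specific), 0)
  expect_length(intersect(ms$rr_specific, ms$abl_specific), 0)
  # ec induction and late SE are mutually exclusive
  expect_length(intersect(ms$ec_induction, ms$late_se), 0)
  # all-SE members are always early-SE members under the conjunctive rule
  expect_true(all(ms$all_se %in% ms$early_se))
})

test_that("raising the fold threshold never adds a member (monotonicity)", {
  m <- random_fpkm(800, seed = 12)
  lo <- classify(m, builtin_rules(se_config(fold_threshold = 4)))
  hi <- classify(m, builtin_rules(se_config(fold_threshold = 8)))
  for (s in all_subsets()) {
    expect_true(all(hi$memberships[[s]] %in% lo$memberships[[s]]))
  }
})

test_that("scaling a transcript up preserves satisfied fold atoms", {
  # fold-ratio atoms are scale-invariant; min-FPKM can only flip fail->pass
  m <- random_fpkm(300, seed = 21)
  before <- classify(m, builtin_rules())
  scaled <- fpkm_matrix(unclass(m) * 3)
  after <- classify(scaled, builtin_rules())
  # membership requires min-FPKM already passed, so scaling up keeps members
  for (s in all_subsets()) {
    expect_true(all(before$memberships[[s]] %in% after$memberships[[s]]))
  }
})

test_that("write_classification emits one TSV per subset plus a JSON report", {
  m <- random_fpkm(50, seed = 31)
  cls <- classify(m)
  out <- withr::local_tempdir()
  paths <- write_classification(cls, m, out)
  expect_true(all(file.exists(unlist(paths))))
  report <- jsonlite::read_json(file.path(out, "membership.json"),
                                simplifyVector = TRUE)
  expect_equal(report$universe_size, 50)
  expect_equal(unlist(report$sizes), lengths(cls$memberships))
})
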