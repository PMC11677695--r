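test_that("standard curves recover slope, intercept and efficiency", {
  copies <- 10^(9:2)
  ct <- 10 + 3.3219 * (9 - log10(copies))
  sc <- fit_standard_curve(copies, ct, "RPL2")
  expect_equal(sc$slope, -3.3219, tolerance = 1e-10)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_equal(sc$efficiency_pct, 100, tolerance = 0.01)
  expect_true(sc$qc_pass)
  # efficiency formula invariant holds bit-exactly
  expect_identical(sc$efficiency_pct, 100 * (10^(-1 / sc$slope) - 1))

  # closed-form efficiencies just outside the optimal band fail QC
  sc36 <- fit_standard_curve(copies, 5 + 3.6 * (9 - log10(copies)))
  expect_equal(sc36$efficiency_pct, 100 * (10^(1 / 3.6) - 1),
               tolerance = 1e-12)
  expect_equal(sc36$efficiency_pct, 89.57, tolerance = 0.005)
  expect_false(sc36$qc_pass)
  sc31 <- fit_standard_curve(copies, 5 + 3.1 * (9 - log10(copies)))
  expect_equal(sc31$efficiency_pct, 100 * (10^(1 / 3.1) - 1),
               tolerance = 1e-12)
  expect_false(sc31$qc_pass)

  expect_error(fit_standard_curve(c(10, 100), c(30, 27)),
               class = "semarkr_validation_error")
  # rising curve: flagged invalid, efficiency still reported
  bad <- fit_standard_curve(copies, 10 - 0.5 * (9 - log10(copies)))
  expect_false(bad$qc_pass)
  expect_true(is.finite(bad$efficiency_pct))
})

test_that("undetected Cts are imputed from the curve intercept", {
  ds <- tibble::tibble(
    tissue = c("ec", "nr"), gene = "CeNA1", replicate = c(1L, 2L),
    ct = c(17.2, NA), undetected = c(FALSE, TRUE))
  curve <- fit_standard_curve(10^(9:2), 41.2 - 3.4 * log10(10^(9:2)),
                              "CeNA1")
  out <- impute_undetected(ds, list(CeNA1 = curve))
  expect_equal(out$ct[2], 41.2, tolerance = 1e-9)
  expect_equal(out$ct[1], 17.2) # detected record untouched
  expect_equal(nrow(attr(out, "imputations")), 1)

  # identity on fully detected data
  clean <- ds[1, ]
  expect_identical(impute_undetected(clean, list(CeNA1 = curve)), clean)

  # missing curve names the gene
  expect_error(impute_undetected(ds, list(OTHER = curve)),
               "no standard curve for CeNA1",
               class = "semarkr_validation_error")
})

test_that("Livak math reproduces hand-worked delta-delta-Ct values", {
  # worked example: rl target 24 refs (20, 22); ec target 14 refs (19, 23)
  ds <- ct_fixture(list(rl = c(24, 20, 22), ec = c(14, 19, 23)))
  rel <- relative_expression(ds, "T")
  expect_equal(rel$log2_fc[rel$tissue == "rl"], 0)
  expect_equal(rel$log2_fc[rel$tissue == "ec"], 10) # RQ = 1024
  # one-cycle-lower target with identical references doubles expression
  ds2 <- ct_fixture(list(rl = c(24, 20, 22), ec = c(23, 20, 22)))
  expect_equal(relative_expression(ds2, "T")$log2_fc[2], 1)
})

test_that("delta-Ct is invariant to plate-wide Ct shifts within a tissue", {
  set.seed(41)
  base <- ct_fixture(list(rl = c(24, 20, 22), ec = c(18, 19, 21),
                          cse = c(26, 20, 21)), n_reps = 3)
  shifted <- base
  # add a constant to target AND references of one tissue simultaneously
  shifted$ct[shifted$tissue == "ec"] <- shifted$ct[shifted$tissue == "ec"] + 1.7
  expect_equal(relative_expression(shifted, "T")$log2_fc,
               relative_expression(base, "T")$log2_fc)
})

test_that("relative expression validates references and calibrator", {
  ds <- ct_fixture(list(rl = c(24, 20, 22), ec = c(14, 19, 23)))
  expect_error(relative_expression(ds, "T", calibrator = "oc"),
               class = "semarkr_validation_error")
  no_ref <- ds[ds$gene != "TBP1", ]
  expect_error(relative_expression(no_ref, "T"),
               class = "semarkr_validation_error")
  und <- ds
  und$undetected[1] <- TRUE
  expect_error(relative_expression(und, "T"), "impute_undetected",
               class = "semarkr_validation_error")
})

test_that("Tukey letters separate clearly distinct groups and only those", {
  # three well-separated groups earn three distinct letters
  lt <- anova_tukey(list(rl = c(-0.1, 0, 0.1), gse = c(4.9, 5, 5.1),
                         ec = c(9.9, 10, 10.1)))
  expect_equal(unname(lt), c("c", "b", "a"),
               ignore_attr = TRUE) # descending-mean lettering
  # identical groups share a single letter
  same <- anova_tukey(list(a = c(1, 1.1, 0.9), b = c(1.05, 0.95, 1),
                           c = c(0.98, 1.02, 1)))
  expect_true(all(same == "a"))
  # two separated groups
  two <- anova_tukey(list(a = c(0, 0.1, -0.1), b = c(5, 5.1, 4.9)))
  expect_equal(unname(two[c("a", "b")]), c("b", "a"))

  expect_error(anova_tukey(list(a = c(1, 1))),
               class = "semarkr_validation_error")
  expect_error(anova_tukey(list(a = c(1, 1), b = c(2, 2))),
               class = "semarkr_degenerate_error")
})

test_that("letter sharing is equivalent to non-significance (property)", {
  set.seed(61)
  for (i in 1:25) {
    k <- sample(3:6, 1)
    vals <- stats::setNames(
      lapply(seq_len(k), function(j) rnorm(3, mean = sample(0:3, 1),
                                           sd = 0.4)),
      paste0("t", seq_len(k)))
    lt <- anova_tukey(vals)
    p <- attr(lt, "p_values")
    for (a in names(vals)) {
      for (b in setdiff(names(vals), a)) {
        share <- length(intersect(strsplit(lt[[a]], "")[[1]],
                                  strsplit(lt[[b]], "")[[1]])) > 0
        expect_equal(share, p[a, b] >= 0.05)
      }
    }
  }
})

test_that("the full expression table carries letters and calibrator flags", {
  set.seed(71)
  tr <- matrix(c(0, 8, -3), 1, 3,
               dimnames = list("G1", c("rl", "ec", "cse")))
  sim <- gen_ct("G1", tissues = c("rl", "ec", "cse"), truth_log2fc = tr,
                ct_sd = 0.1, seed = 71)
  tab <- relative_expression_table(sim$dataset, "G1")
  expect_setequal(names(tab),
                  c("gene", "tissue", "log2_fc", "se", "n", "letters",
                    "sig_vs_calibrator"))
  expect_equal(tab$n, rep(3L, 3))
  expect_false(tab$sig_vs_calibrator[tab$tissue == "rl"])
  expect_true(tab$sig_vs_calibrator[tab$tissue == "ec"])
  expect_true(tab$letters[tab$tissue == "ec"] !=
                tab$letters[tab$tissue == "rl"])
})
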