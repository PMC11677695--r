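test_that("coverage percentages complement to 100 and reject empty subsets", {
  recs <- annotation_record("t1")
  cov <- coverage_stats(c("t1", "t2", "t3", "t4"), recs, "swissprot")
  expect_equal(cov$annotated_pct, 25.00)
  expect_equal(cov$na_pct, 75.00)
  expect_equal(cov$annotated_pct + cov$na_pct, 100)
  expect_error(coverage_stats(character(0), recs, "swissprot"),
               class = "semarkr_validation_error")

  # complement property across uneven splits
  for (n_ann in c(1, 3, 7)) {
    members <- sprintf("m%d", 1:9)
    r <- annotation_record(members[seq_len(n_ann)])
    cc <- coverage_stats(members, r, "swissprot")
    expect_equal(cc$annotated_pct + cc$na_pct, 100, tolerance = 0.011)
  }
})

test_that("species tally keeps one best hit per transcript", {
  recs <- dplyr::bind_rows(
    annotation_record("t1", species = "spA", e_value = 1e-30,
                      hit_accession = "A1"),
    annotation_record("t1", species = "spB", e_value = 1e-10,
                      hit_accession = "B1"),
    annotation_record("t2", species = "spA"),
    annotation_record("t3", species = "spB"))
  tally <- species_tally(recs, "swissprot")
  expect_equal(tally$species, c("spA", "spB"))
  expect_equal(tally$count, c(2L, 1L))
  # counts sum to the number of annotated transcripts
  expect_equal(sum(tally$count), 3)

  # tie on e-value broken by lexicographic accession
  tie <- dplyr::bind_rows(
    annotation_record("t1", species = "late", e_value = 1e-20,
                      hit_accession = "ZZZ"),
    annotation_record("t1", species = "first", e_value = 1e-20,
                      hit_accession = "AAA"))
  expect_equal(species_tally(tie, "swissprot")$species, "first")

  expect_equal(nrow(species_tally(recs[0, ], "swissprot")), 0)
  expect_equal(nrow(species_tally(recs, "ncbi_nt")), 0)
})

test_that("go_top_terms counts distinct members, excludes roots, breaks ties", {
  go <- tibble::tibble(
    transcript_id = c("g1", "g2", "g1", "g1", "g2"),
    go_id = c("GO:0006952", "GO:0006952", "GO:0006952", "GO:0008150",
              "GO:0005634"),
    go_name = c("defense response", "defense response", "defense response",
                "biological_process", "nucleus"),
    category = c(rep("biological_process", 4), "cellular_component"))
  top <- go_top_terms(c("g1", "g2"), go, "biological_process")
  expect_equal(top$go_id, "GO:0006952")
  expect_equal(top$gene_count, 2L) # duplicate (g1, term) rows count once
  # root terms never appear
  expect_false("GO:0008150" %in% top$go_id)
  # asking for more terms than exist returns the full ranking
  expect_equal(nrow(go_top_terms(c("g1", "g2"), go, "biological_process",
                                 n = 50)),
               1)
  # deterministic tie-break by GO id
  go2 <- tibble::tibble(
    transcript_id = c("g1", "g1"),
    go_id = c("GO:0000002", "GO:0000001"),
    go_name = c("b", "a"), category = "molecular_function")
  expect_equal(go_top_terms("g1", go2, "molecular_function")$go_id,
               c("GO:0000001", "GO:0000002"))
})

test_that("candidate selection follows the E-value threshold and priority", {
  m <- fpkm_rows(matrix(c(1, 1, 1, 10, 2, 1,
                          1, 1, 1, 12, 2, 1,
                          1, 1, 1, 16, 2, 1),
                        3, 6, byrow = TRUE,
                        dimnames = list(c("tA", "tB", "tC"), six)))
  cls <- classify(m)
  expect_true(all(c("tA", "tB", "tC") %in% cls$memberships$ec_induction))
  recs <- dplyr::bind_rows(
    annotation_record("tA", "swissprot", e_value = 1.03e-46,
                      hit_accession = "SP_A"),
    annotation_record("tA", "ncbi_nt", e_value = 1e-60,
                      hit_accession = "NT_A"),
    # Swiss-Prot hit fails the threshold; nt hit passes and is chosen
    annotation_record("tB", "swissprot", e_value = 1e-10,
                      hit_accession = "SP_B"),
    annotation_record("tB", "ncbi_nt", e_value = 1e-20,
                      hit_accession = "NT_B"))

  cand <- select_candidates(cls, m, recs)
  a <- cand[cand$transcript_id == "tA" & cand$subset == "ec_induction", ]
  expect_equal(a$database, "swissprot") # priority despite better nt e-value
  expect_equal(a$e_value, 1.03e-46)
  b <- cand[cand$transcript_id == "tB" & cand$subset == "ec_induction", ]
  expect_equal(b$database, "ncbi_nt")
  expect_false("tC" %in% cand$transcript_id) # no record, flag off

  # unannotated candidates only on request (the novel-transcript route)
  cand2 <- select_candidates(cls, m, recs, include_unannotated = TRUE)
  c2 <- cand2[cand2$transcript_id == "tC" & cand2$subset == "ec_induction", ]
  expect_equal(nrow(c2), 1)
  expect_true(is.na(c2$database))
  expect_equal(c2$ec, 16) # FPKM profile travels with the candidate

  # invariant: no chosen annotation at or above the threshold
  expect_true(all(is.na(cand2$e_value) | cand2$e_value < 1e-15))
})
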