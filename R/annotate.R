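#' GO ontology root terms
#'
#' The three Gene Ontology root terms, excluded by default from top-term
#' rankings because they carry no information beyond the category itself.
#'
#' @return character vector of GO accessions.
#' @export
go_root_terms <- function() {
  c(biological_process = "GO:0008150",
    molecular_function = "GO:0003674",
    cellular_component = "GO:0005575")
}

#' Annotation coverage of a subset
#'
#' For a gene subset and one database, counts the members with at least one
#' hit record (annotated) versus those without (NA, not available), with
#' percentages of the subset size rounded half-up to two decimals.
#'
#' @param subset_members character vector of transcript ids (non-empty).
#' @param records an annotation tibble ([read_annotation_table()] columns).
#' @param database `"swissprot"` or `"ncbi_nt"`.
#' @return a one-row tibble: `database`, `subset_size`, `annotated_count`,
#'   `na_count`, `annotated_pct`, `na_pct`.
#' @export
#' @examples
#' recs <- tibble::tibble(transcript_id = "t1", database = "swissprot",
#'                        hit_accession = "P1", description = "d",
#'                        species = "s", e_value = 1e-30, length_bp = 100L)
#' coverage_stats(c("t1", "t2", "t3", "t4"), recs, "swissprot")
coverage_stats <- function(subset_members, records, database) {
  database <- match.arg(database, c("swissprot", "ncbi_nt"))
  subset_members <- unique(subset_members)
  n <- length(subset_members)
  if (n == 0) {
    abort_fmt("empty subset: coverage percentages are undefined.",
              class = "semarkr_validation_error")
  }
  hits <- unique(records$transcript_id[records$database == database])
  annotated <- sum(subset_members %in% hits)
  tibble::tibble(
    database = database,
    subset_size = n,
    annotated_count = annotated,
    na_count = n - annotated,
    annotated_pct = round_half_up(100 * annotated / n, 2),
    na_pct = round_half_up(100 * (n - annotated) / n, 2)
  )
}

best_hits <- function(records, database) {
  recs <- dplyr::filter(records, .data$database == !!database)
  if (nrow(recs) == 0) return(recs)
  recs <- dplyr::arrange(recs, .data$transcript_id, .data$e_value,
                         .data$hit_accession)
  dplyr::slice_head(dplyr::group_by(recs, .data$transcript_id), n = 1) |>
    dplyr::ungroup()
}

#' Tally annotated transcripts by species
#'
#' Keeps one best hit per transcript within the chosen database (lowest
#' E-value, ties broken by lexicographic accession), tallies by species, and
#' returns the top `top_n` species sorted by count descending then species
#' name ascending.
#'
#' @param records an annotation tibble.
#' @param database `"swissprot"` or `"ncbi_nt"`.
#' @param top_n number of species to keep (default 30).
#' @return a tibble with columns `species`, `count`.
#' @export
species_tally <- function(records, database, top_n = 30) {
  database <- match.arg(database, c("swissprot", "ncbi_nt"))
  best <- best_hits(records, database)
  if (nrow(best) == 0) {
    return(tibble::tibble(species = character(0), count = integer(0)))
  }
  dplyr::count(best, .data$species, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$species) |>
    dplyr::slice_head(n = top_n)
}

#' Top GO terms for a set of transcripts
#'
#' Counts distinct member transcripts per GO term within one category,
#' excluding the root-term blocklist, and returns the `n` most represented
#' terms (ties broken by GO id ascending). The intended members are the
#' transcripts unique to a single SE subset, per the study design.
#'
#' @param subset_unique_members character vector of transcript ids.
#' @param annotations a GO tibble ([read_go_table()] columns).
#' @param category one of `"biological_process"`, `"cellular_component"`,
#'   `"molecular_function"`.
#' @param n number of terms to return (default 10).
#' @param blocklist GO ids never reported; defaults to [go_root_terms()].
#' @return a tibble with columns `go_id`, `go_name`, `gene_count`.
#' @export
go_top_terms <- function(subset_unique_members, annotations, category,
                         n = 10, blocklist = go_root_terms()) {
  category <- match.arg(category, c("biological_process",
                                    "cellular_component",
                                    "molecular_function"))
  stopifnot(n >= 1)
  ann <- dplyr::filter(
    annotations,
    .data$category == !!category,
    .data$transcript_id %in% subset_unique_members,
    !(.data$go_id %in% blocklist)
  )
  if (nrow(ann) == 0) {
    return(tibble::tibble(go_id = character(0), go_name = character(0),
                          gene_count = integer(0)))
  }
  dplyr::distinct(ann, .data$transcript_id, .data$go_id, .data$go_name) |>
    dplyr::count(.data$go_id, .data$go_name, name = "gene_count") |>
    dplyr::arrange(dplyr::desc(.data$gene_count), .data$go_id) |>
    dplyr::slice_head(n = n)
}

#' Select annotated candidate genes from the SE subsets
#'
#' For each SE-subset member, chooses its annotation by the study's priority
#' rule: a Swiss-Prot hit with E-value strictly below `e_threshold` if one
#' exists (best hit by E-value, ties by accession), otherwise an NCBI-nt hit
#' below the threshold, otherwise the transcript is dropped — unless
#' `include_unannotated = TRUE`, in which case it is emitted with empty
#' annotation fields (the route by which unannotated transcripts such as
#' novel genes enter the candidate list). Each candidate row carries its SE
#' subset label and its FPKM profile across the six sequenced tissues.
#'
#' @param classification a `deg_classification`.
#' @param matrix the [fpkm_matrix()] the classification came from.
#' @param records an annotation tibble.
#' @param e_threshold strict E-value cutoff (default `1e-15`).
#' @param include_unannotated emit members with no qualifying record?
#' @return a tibble with one row per (transcript, SE subset) membership:
#'   `transcript_id`, `subset`, `database`, `hit_accession`, `description`,
#'   `species`, `e_value`, `length_bp`, and one FPKM column per tissue.
#' @export
select_candidates <- function(classification, matrix, records,
                              e_threshold = 1e-15,
                              include_unannotated = FALSE) {
  stopifnot(inherits(classification, "deg_classification"),
            is_fpkm_matrix(matrix), e_threshold > 0)
  se <- intersect(names(classification$memberships), se_subsets())
  pass <- dplyr::filter(records, .data$e_value < e_threshold)
  best_sp <- best_hits(pass, "swissprot")
  best_nt <- best_hits(pass, "ncbi_nt")

  rows <- list()
  for (s in se) {
    for (id in classification$memberships[[s]]) {
      rec <- dplyr::filter(best_sp, .data$transcript_id == id)
      if (nrow(rec) == 0) rec <- dplyr::filter(best_nt, .data$transcript_id == id)
      if (nrow(rec) == 0) {
        if (!include_unannotated) next
        rec <- tibble::tibble(transcript_id = id, database = NA_character_,
                              hit_accession = NA_character_,
                              description = NA_character_,
                              species = NA_character_,
                              e_value = NA_real_, length_bp = NA_integer_)
      }
      rows[[length(rows) + 1L]] <- dplyr::mutate(rec, subset = s)
    }
  }
  if (length(rows) == 0) {
    empty_fpkm <- stats::setNames(
      rep(list(numeric(0)), ncol(matrix)), colnames(matrix))
    return(tibble::tibble(transcript_id = character(0), subset = character(0),
                          database = character(0),
                          hit_accession = character(0),
                          description = character(0), species = character(0),
                          e_value = numeric(0), length_bp = integer(0),
                          !!!empty_fpkm))
  }
  out <- dplyr::bind_rows(rows)
  prof <- tibble::as_tibble(unclass(matrix)[out$transcript_id, , drop = FALSE])
  out <- dplyr::bind_cols(
    dplyr::select(out, "transcript_id", "subset", "database", "hit_accession",
                  "description", "species", "e_value", "length_bp"),
    prof
  )
  dplyr::arrange(out, .data$subset, .data$transcript_id)
}
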