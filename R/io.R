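sniff_delim <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_table_checked <- function(path, delim) {
  # parse problems (ragged rows etc.) surface as NA cells, which the typed
  # validators below reject with a named error; readr's own warning is noise
  suppressWarnings(
    readr::read_delim(path, delim = delim,
                      col_types = readr::cols(.default = "c"),
                      progress = FALSE, show_col_types = FALSE)
  )
}

#' Read a transcript-by-tissue FPKM table
#'
#' Reads a tab- or comma-separated table (sniffed from the file extension)
#' with a first column of transcript ids and one column per tissue, and
#' validates it into an [fpkm_matrix()]. The header must name every tissue in
#' `config$fpkm_tissues`; extra or misspelled columns, duplicated transcript
#' ids, missing cells and negative values are rejected, never coerced.
#'
#' @param path path to a TSV/CSV file.
#' @param config an [se_config()]; supplies the expected tissue vocabulary.
#' @return an `fpkm_matrix` with tissues in vocabulary order.
#' @export
read_fpkm_table <- function(path, config = se_config()) {
  tab <- read_table_checked(path, sniff_delim(path))
  if (ncol(tab) < 2) {
    abort_fmt("'%s': expected a transcript id column plus tissue columns.",
              path, class = "semarkr_format_error")
  }
  tissues <- config$fpkm_tissues
  have <- names(tab)[-1]
  missing <- setdiff(tissues, have)
  extra <- setdiff(have, tissues)
  if (length(missing) || length(extra)) {
    abort_fmt(
      "'%s': malformed header; missing column(s): %s; unexpected column(s): %s",
      path,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none",
      class = "semarkr_format_error"
    )
  }
  ids <- tab[[1]]
  if (anyNA(ids)) {
    abort_fmt("'%s': missing transcript id(s).", path,
              class = "semarkr_validation_error")
  }
  vals <- matrix(NA_real_, nrow(tab), length(tissues),
                 dimnames = list(ids, tissues))
  for (t in tissues) {
    col <- tab[[t]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col))
    if (length(bad)) {
      abort_fmt("'%s': non-numeric FPKM value '%s' for transcript '%s' (column %s).",
                path, col[bad[1]], ids[bad[1]], t,
                class = "semarkr_validation_error")
    }
    nacell <- which(is.na(col))
    if (length(nacell)) {
      abort_fmt("'%s': missing FPKM cell for transcript '%s' (column %s).",
                path, ids[nacell[1]], t, class = "semarkr_validation_error")
    }
    vals[, t] <- num
  }
  m <- fpkm_matrix(vals)
  inform_verbose("read_fpkm_table: %d transcripts x %d tissues from '%s'",
                 nrow(m), ncol(m), path)
  m
}

#' Write an FPKM table
#'
#' Writes an [fpkm_matrix()] as a tab-separated table (the package's canonical
#' dialect) whose numeric fields round-trip bit-exactly through
#' [read_fpkm_table()].
#'
#' @param x an `fpkm_matrix`.
#' @param path output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_fpkm_table <- function(x, path) {
  stopifnot(is_fpkm_matrix(x))
  out <- data.frame(transcript_id = rownames(x), stringsAsFactors = FALSE)
  for (t in colnames(x)) out[[t]] <- sprintf("%.17g", x[, t])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format RT-qPCR Ct table
#'
#' Reads a long table with columns `tissue`, `gene`, `replicate`, `ct`, where
#' `ct` is a positive cycle-threshold value or the token `ND` (not detected).
#' Tissue labels outside the nine-tissue qPCR vocabulary and non-numeric Ct
#' values other than `ND` are errors.
#'
#' @param path path to a TSV/CSV file.
#' @param config an [se_config()]; supplies the qPCR tissue vocabulary.
#' @return a tibble with columns `tissue`, `gene`, `replicate` (integer),
#'   `ct` (double, `NA` when undetected) and `undetected` (logical).
#' @export
read_ct_long <- function(path, config = se_config()) {
  tab <- read_table_checked(path, sniff_delim(path))
  need <- c("tissue", "gene", "replicate", "ct")
  if (!all(need %in% names(tab))) {
    abort_fmt("'%s': malformed header; need columns %s.", path,
              paste(need, collapse = ", "), class = "semarkr_format_error")
  }
  bad_tissue <- setdiff(unique(tab$tissue), config$qpcr_tissues)
  if (length(bad_tissue)) {
    abort_fmt("'%s': unknown tissue label(s): %s", path,
              paste(bad_tissue, collapse = ", "),
              class = "semarkr_validation_error")
  }
  rep_num <- suppressWarnings(as.integer(tab$replicate))
  if (anyNA(rep_num) || any(rep_num < 1)) {
    abort_fmt("'%s': `replicate` must be a positive integer.", path,
              class = "semarkr_validation_error")
  }
  undetected <- tab$ct == "ND"
  ct <- suppressWarnings(as.numeric(tab$ct))
  bad_ct <- which(!undetected & (is.na(ct) | ct <= 0))
  if (length(bad_ct)) {
    abort_fmt("'%s': invalid ct value '%s' (row %d); expected a positive number or 'ND'.",
              path, tab$ct[bad_ct[1]], bad_ct[1],
              class = "semarkr_validation_error")
  }
  ct[undetected] <- NA_real_
  out <- tibble::tibble(
    tissue = tab$tissue,
    gene = tab$gene,
    replicate = rep_num,
    ct = ct,
    undetected = undetected
  )
  dup <- duplicated(out[c("tissue", "gene", "replicate")])
  if (any(dup)) {
    abort_fmt("'%s': duplicated (tissue, gene, replicate) record(s), first at row %d.",
              path, which(dup)[1], class = "semarkr_validation_error")
  }
  inform_verbose("read_ct_long: %d records (%d undetected) from '%s'",
                 nrow(out), sum(out$undetected), path)
  out
}

#' Write a long-format Ct table
#'
#' Inverse of [read_ct_long()]; undetected records are written as `ND` and
#' detected Ct values round-trip bit-exactly.
#'
#' @param dataset a Ct tibble as returned by [read_ct_long()] or [gen_ct()].
#' @param path output path (`.tsv`).
#' @return `path`, invisibly.
#' @export
write_ct_long <- function(dataset, path) {
  ct_chr <- ifelse(dataset$undetected, "ND", sprintf("%.17g", dataset$ct))
  out <- data.frame(tissue = dataset$tissue, gene = dataset$gene,
                    replicate = dataset$replicate, ct = ct_chr,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read database annotation and GO tables
#'
#' `read_annotation_table()` reads a minimal tabular export of BLAST-style
#' database hits: columns `transcript_id`, `database` (`swissprot` or
#' `ncbi_nt`), `hit_accession`, `description`, `species`, `e_value`,
#' `length_bp`. `read_go_table()` reads Gene Ontology assignments: columns
#' `transcript_id`, `go_id` (`GO:` + 7 digits), `go_name`, `category`
#' (`biological_process`, `cellular_component` or `molecular_function`).
#'
#' @param path path to a TSV/CSV file.
#' @return a tibble with typed, validated columns.
#' @export
read_annotation_table <- function(path) {
  tab <- read_table_checked(path, sniff_delim(path))
  need <- c("transcript_id", "database", "hit_accession", "description",
            "species", "e_value", "length_bp")
  if (!all(need %in% names(tab))) {
    abort_fmt("'%s': malformed header; need columns %s.", path,
              paste(need, collapse = ", "), class = "semarkr_format_error")
  }
  bad_db <- setdiff(unique(tab$database), c("swissprot", "ncbi_nt"))
  if (length(bad_db)) {
    abort_fmt("'%s': unknown database label(s): %s", path,
              paste(bad_db, collapse = ", "),
              class = "semarkr_validation_error")
  }
  e_value <- suppressWarnings(as.numeric(tab$e_value))
  if (anyNA(e_value) || any(e_value < 0)) {
    abort_fmt("'%s': `e_value` must be a non-negative number.", path,
              class = "semarkr_validation_error")
  }
  length_bp <- suppressWarnings(as.integer(tab$length_bp))
  if (anyNA(length_bp) || any(length_bp < 1)) {
    abort_fmt("'%s': `length_bp` must be a positive integer.", path,
              class = "semarkr_validation_error")
  }
  tibble::tibble(
    transcript_id = tab$transcript_id,
    database = tab$database,
    hit_accession = tab$hit_accession,
    description = tab$description,
    species = tab$species,
    e_value = e_value,
    length_bp = length_bp
  )
}

#' @rdname read_annotation_table
#' @export
read_go_table <- function(path) {
  tab <- read_table_checked(path, sniff_delim(path))
  need <- c("transcript_id", "go_id", "go_name", "category")
  if (!all(need %in% names(tab))) {
    abort_fmt("'%s': malformed header; need columns %s.", path,
              paste(need, collapse = ", "), class = "semarkr_format_error")
  }
  bad_go <- !grepl("^GO:[0-9]{7}$", tab$go_id)
  if (any(bad_go)) {
    abort_fmt("'%s': malformed GO id '%s' (row %d).", path,
              tab$go_id[which(bad_go)[1]], which(bad_go)[1],
              class = "semarkr_validation_error")
  }
  cats <- c("biological_process", "cellular_component", "molecular_function")
  bad_cat <- setdiff(unique(tab$category), cats)
  if (length(bad_cat)) {
    abort_fmt("'%s': unknown GO category label(s): %s", path,
              paste(bad_cat, collapse = ", "),
              class = "semarkr_validation_error")
  }
  tibble::tibble(
    transcript_id = tab$transcript_id,
    go_id = tab$go_id,
    go_name = tab$go_name,
    category = tab$category
  )
}
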