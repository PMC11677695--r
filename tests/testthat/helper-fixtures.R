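# Shared in-code fixtures and independent oracles.

six <- semarkr::fpkm_tissues()

# one-row fpkm matrix from named values
fpkm_row <- function(id, ...) {
  vals <- c(...)
  stopifnot(setequal(names(vals), six))
  semarkr::fpkm_matrix(matrix(vals[six], nrow = 1,
                              dimnames = list(id, six)))
}

fpkm_rows <- function(mat) {
  semarkr::fpkm_matrix(mat[, six, drop = FALSE])
}

# random FPKM matrix skewed enough that some rows satisfy rules
random_fpkm <- function(n, sdlog = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rlnorm(n * 6, meanlog = log(2), sdlog = sdlog), n, 6,
              dimnames = list(sprintf("r%05d", seq_len(n)), six))
  semarkr::fpkm_matrix(m)
}

annotation_record <- function(transcript_id, database = "swissprot",
                              hit_accession = "ACC1", description = "desc",
                              species = "Arabidopsis thaliana",
                              e_value = 1e-30, length_bp = 300L) {
  tibble::tibble(transcript_id = transcript_id, database = database,
                 hit_accession = hit_accession, description = description,
                 species = species, e_value = e_value,
                 length_bp = as.integer(length_bp))
}

# minimal paired target/reference Ct dataset builder:
# cts is a named list tissue -> c(target, ref1, ref2); n_reps replicates
ct_fixture <- function(cts, gene = "T", refs = c("RPL2", "TBP1"),
                       n_reps = 2) {
  rows <- list()
  for (tis in names(cts)) {
    for (rep in seq_len(n_reps)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        tissue = tis, gene = c(gene, refs), replicate = as.integer(rep),
        ct = cts[[tis]], undetected = FALSE)
    }
  }
  dplyr::bind_rows(rows)
}

# long expression table -> gene x tissue matrix (test-side, independent
# of the package's internal pivot)
rel_table_matrix_for_test <- function(tab) {
  genes <- unique(tab$gene)
  tissues <- unique(tab$tissue)
  m <- matrix(NA_real_, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  for (i in seq_len(nrow(tab))) {
    m[tab$gene[i], tab$tissue[i]] <- tab$log2_fc[i]
  }
  m
}

# brute-force complete-linkage agglomeration: returns the cophenetic
# distance matrix, computed with an exhaustive pairwise scan at each step
bf_complete_cophenetic <- function(d) {
  m <- as.matrix(d)
  labels <- rownames(m)
  clusters <- as.list(labels)
  coph <- matrix(0, length(labels), length(labels),
                 dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    best_h <- Inf
    best <- c(NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(m[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# planted 4-group tissue expression table over the nine-tissue panel
planted_tissue_table <- function(n_genes = 15, sep = 6, noise_sd = 0.2,
                                 seed = 11) {
  set.seed(seed)
  groups <- list(c("ec", "oc"), c("gse", "cse", "abl"),
                 c("rl", "rr"), c("nl", "nr"))
  tissues <- unlist(groups)
  centers <- matrix(stats::rnorm(n_genes * length(groups), sd = sep),
                    n_genes, length(groups))
  rows <- list()
  for (g in seq_len(n_genes)) {
    for (k in seq_along(groups)) {
      for (tis in groups[[k]]) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          gene = sprintf("g%02d", g), tissue = tis,
          log2_fc = centers[g, k] + stats::rnorm(1, sd = noise_sd))
      }
    }
  }
  list(table = dplyr::bind_rows(rows),
       partition = rep(seq_along(groups), lengths(groups)) |>
         stats::setNames(tissues))
}
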