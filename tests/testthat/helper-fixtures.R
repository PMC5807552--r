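# small library + effect-model fixtures used across test files

tiny_library <- function(n_ub = 10, n_atg = 2, shrnas_per_gene = 4,
                         guide_length = 10, seed = 42) {
  simulate_library(n_ubiquitin = n_ub, n_autophagy = n_atg,
                   total_shrnas = (n_ub + n_atg) * shrnas_per_gene,
                   guide_length = guide_length, seed = seed)
}

# count matrix with explicit values and rep{i}_{high,low} columns
manual_counts <- function(values, shrna_ids, sample_ids) {
  count_matrix(matrix(as.integer(values), length(shrna_ids),
                      length(sample_ids),
                      dimnames = list(shrna_ids, sample_ids)))
}

# brute-force reimplementation of the scoring pipeline: literal arithmetic,
# no vectorization; independent oracle for screen_score
oracle_score <- function(counts, gene_map, pseudocount, threshold = 3,
                         min_scoring = 3) {
  ids <- rownames(counts)
  samples <- colnames(counts)
  rpm <- matrix(NA_real_, nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  for (j in seq_along(samples)) {
    tot <- 0
    for (i in seq_along(ids)) tot <- tot + counts[i, j]
    for (i in seq_along(ids))
      rpm[i, j] <- (counts[i, j] + pseudocount) / tot * 1e6
  }
  reps <- sort(unique(as.integer(sub("^rep(\\d+)_.*$", "\\1", samples))))
  scores <- NULL
  for (i in seq_along(ids)) {
    prod_fc <- 1
    fcs <- numeric(0)
    for (r in reps) {
      fc <- rpm[i, paste0("rep", r, "_high")] /
        rpm[i, paste0("rep", r, "_low")]
      fcs <- c(fcs, fc)
      prod_fc <- prod_fc * fc
    }
    g <- prod_fc^(1 / length(reps))
    row <- data.frame(shrna_id = ids[i],
                      gene = gene_map$gene[gene_map$shrna_id == ids[i]],
                      geomean = g, scoring = g >= threshold)
    for (r in seq_along(reps)) row[[paste0("fc_rep", reps[r])]] <- fcs[r]
    scores <- rbind(scores, row)
  }
  genes <- unique(gene_map$gene[match(ids, gene_map$shrna_id)])
  hits <- NULL
  for (g in genes) {
    sub <- scores[scores$gene == g & scores$scoring, , drop = FALSE]
    if (nrow(sub) >= min_scoring) {
      avg <- 0
      for (v in sub$geomean) avg <- avg + v
      hits <- rbind(hits, data.frame(gene = g, n_scoring = nrow(sub),
                                     avg_geomean = avg / nrow(sub)))
    }
  }
  if (is.null(hits))
    hits <- data.frame(gene = character(0), n_scoring = integer(0),
                       avg_geomean = numeric(0))
  hits <- hits[order(-hits$n_scoring, -hits$avg_geomean, hits$gene), ,
               drop = FALSE]
  hits$rank <- seq_len(nrow(hits))
  rownames(hits) <- NULL
  list(scores = scores, hits = hits)
}

# the nine printed rows of the screen's published hit list, used as a
# worked example for filtering and sort order
published_hits <- function() {
  data.frame(
    gene = c("Atg7", "Atg16l1", "Birc6", "Rb1cc1", "Tsg101", "Atg12",
             "Sqstm1", "Nedd8", "Atg9a"),
    n_scoring = c(5L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L),
    avg_geomean = c(21.60, 7.59, 3.18, 14.33, 7.15, 4.91, 3.77, 3.05, 3.03),
    stringsAsFactors = FALSE)
}
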