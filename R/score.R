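#' Reads-per-million normalization of guide counts
#'
#' Depth-normalizes each sample: `rpm = (count + pseudocount) / raw_total *
#' 1e6`, where `raw_total` is the sample's raw column sum (the pseudocount
#' enters the numerator only, so with pseudocount 0 every nonzero column
#' sums to exactly one million). The default pseudocount is 0.5 when any
#' count is zero -- so that fold changes stay finite -- and 0 otherwise.
#'
#' @param counts A [count_matrix()] (or plain integer matrix with dimnames).
#' @param pseudocount Non-negative pseudocount; `NULL` (default) selects 0.5
#'   if any count is zero, else 0.
#' @return Numeric matrix of the same shape, class `normalized_matrix`, with
#'   the pseudocount used stored in attribute `pseudocount`.
#' @examples
#' m <- count_matrix(matrix(c(10L, 90L), 2, 1,
#'                          dimnames = list(c("a", "b"), "rep1_high")))
#' normalize_rpm(m, pseudocount = 0)
#' @export
normalize_rpm <- function(counts, pseudocount = NULL) {
  m <- unclass(counts)
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  stopifnot(is.matrix(m), all(m >= 0))
  if (is.null(pseudocount)) pseudocount <- if (any(m == 0)) 0.5 else 0
  stopifnot(pseudocount >= 0)
  totals <- colSums(m)
  if (any(totals == 0))
    stop("all-zero column(s): ",
         paste(colnames(m)[totals == 0], collapse = ", "),
         if (pseudocount == 0) " (pseudocount 0)" else "")
  out <- sweep(m + pseudocount, 2, totals, "/") * 1e6
  structure(out, class = "normalized_matrix", pseudocount = pseudocount)
}

#' Per-shRNA fold enrichment and replicate geometric mean
#'
#' For every shRNA, the fold change in each replicate is the normalized
#' (RPM) abundance in the "GFP high" sorted population divided by the
#' abundance in the "GFP low" population; the per-shRNA score is the
#' geometric mean of the replicate fold changes, and an shRNA scores when
#' that geometric mean shows at least `threshold`-fold enrichment
#' (inclusive). Columns are paired by the `rep{i}_high` / `rep{i}_low`
#' naming convention; a replicate missing either gate is an error.
#'
#' The geometric mean is computed in log space, `exp(mean(log(FC_r)))`,
#' which equals `(prod(FC_r))^(1/R)`.
#'
#' @param norm A `normalized_matrix` from [normalize_rpm()].
#' @param library An `shrna_library`, or a data.frame with columns
#'   `shrna_id` and `gene`, mapping each row to its gene.
#' @param threshold Scoring threshold on the geometric mean (default 3,
#'   i.e. at least three-fold enrichment).
#' @return data.frame with one row per shRNA: `shrna_id`, `gene`, one
#'   `fc_rep{i}` column per replicate, `geomean`, and logical `scoring`.
#' @export
score_shrnas <- function(norm, library, threshold = 3) {
  gene_map <- if (inherits(library, "shrna_library")) library$shrnas else library
  stopifnot(all(c("shrna_id", "gene") %in% colnames(gene_map)))
  if (!all(rownames(norm) %in% gene_map$shrna_id))
    stop("normalized matrix contains shRNAs with no gene mapping")

  cn <- colnames(norm)
  reps <- sort(unique(as.integer(sub("^rep(\\d+)_(high|low)$", "\\1",
                                     grep("^rep\\d+_(high|low)$", cn,
                                          value = TRUE)))))
  if (length(reps) == 0)
    stop("no rep{i}_high / rep{i}_low column pairs found")
  for (r in reps) {
    miss <- setdiff(sprintf("rep%d_%s", r, c("high", "low")), cn)
    if (length(miss) > 0)
      stop("replicate ", r, " is missing column(s): ",
           paste(miss, collapse = ", "))
  }
  fc <- vapply(reps, function(r)
    norm[, sprintf("rep%d_high", r)] / norm[, sprintf("rep%d_low", r)],
    numeric(nrow(norm)))
  fc <- matrix(fc, nrow = nrow(norm),
               dimnames = list(rownames(norm), sprintf("fc_rep%d", reps)))
  if (any(!is.finite(fc) | fc <= 0))
    stop("non-positive or non-finite fold change; use a pseudocount > 0")
  geomean <- exp(rowMeans(log(fc)))
  out <- data.frame(shrna_id = rownames(norm),
                    gene = gene_map$gene[match(rownames(norm),
                                               gene_map$shrna_id)],
                    fc, geomean = geomean,
                    scoring = geomean >= threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Gene-level hit calling from shRNA scores
#'
#' A gene is a hit when at least `min_scoring` of its shRNAs score (their
#' replicate geometric-mean fold enrichment met the scoring threshold). The
#' reported `avg_geomean` is the arithmetic mean of the geometric means of
#' the scoring shRNAs only. The returned table is ranked with
#' [rank_hits()].
#'
#' @param scores data.frame from [score_shrnas()].
#' @param min_scoring Minimum number of scoring shRNAs for a gene to be
#'   reported (default 3, inclusive).
#' @return data.frame of class `hit_table`: `gene`, `n_scoring`,
#'   `avg_geomean`, `rank`, sorted by the ranking rule.
#' @examples
#' s <- data.frame(shrna_id = letters[1:4], gene = "g1",
#'                 geomean = c(3.5, 3.0, 2.9, 4.0),
#'                 scoring = c(3.5, 3.0, 2.9, 4.0) >= 3)
#' call_hits(s)  # n_scoring 3, avg_geomean mean(3.5, 3.0, 4.0)
#' @export
call_hits <- function(scores, min_scoring = 3) {
  stopifnot(all(c("gene", "geomean", "scoring") %in% colnames(scores)))
  sc <- scores[scores$scoring, , drop = FALSE]
  n_scoring <- table(factor(sc$gene, levels = unique(scores$gene)))
  avg <- tapply(sc$geomean, factor(sc$gene, levels = unique(scores$gene)),
                mean)
  hits <- data.frame(gene = names(n_scoring),
                     n_scoring = as.integer(n_scoring),
                     avg_geomean = as.numeric(avg),
                     row.names = NULL, stringsAsFactors = FALSE)
  hits <- hits[hits$n_scoring >= min_scoring, , drop = FALSE]
  rank_hits(hits)
}

#' Rank a gene hit table
#'
#' Stable sort by number of scoring shRNAs (descending), then average
#' geometric mean (descending), then gene name (ascending) as a
#' deterministic tie-break; adds a `rank` column.
#'
#' @param hits data.frame with columns `gene`, `n_scoring`, `avg_geomean`.
#' @return The sorted data.frame, class `hit_table`, with `rank` 1..n.
#' @export
rank_hits <- function(hits) {
  stopifnot(all(c("gene", "n_scoring", "avg_geomean") %in% colnames(hits)))
  ord <- order(-hits$n_scoring, -hits$avg_geomean, hits$gene)
  out <- hits[ord, c("gene", "n_scoring", "avg_geomean"), drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' @export
print.hit_table <- function(x, ...) {
  cat(sprintf("gene hit table: %d gene(s)\n", nrow(x)))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}
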