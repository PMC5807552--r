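#' Simulate an shRNA library manifest
#'
#' Builds the ground-truth scaffold of a pooled screen: a set of target genes
#' (ubiquitin-pathway regulators plus known autophagy regulators used as
#' positive controls), shRNAs allocated to genes as evenly as possible, unique
#' guide sequences, and per-sample demultiplexing barcodes. Defaults match a
#' 710-gene / 4,184-shRNA library screened in duplicate with high/low sorted
#' gates.
#'
#' shRNAs are split over genes by an as-even-as-possible integer allocation:
#' every gene gets `floor(total_shrnas / n_genes)` guides and the remainder is
#' assigned one extra guide per gene in deterministic gene order.
#'
#' @param n_ubiquitin Number of ubiquitin-regulator genes.
#' @param n_autophagy Number of autophagy-control genes.
#' @param total_shrnas Total number of shRNAs across all genes.
#' @param guide_length Guide sequence length in nucleotides (>= 8).
#' @param sample_ids Character vector of sample names to assign barcodes to;
#'   the downstream scoring convention is `rep{i}_high` / `rep{i}_low`.
#' @param barcode_length Sample barcode length in nucleotides.
#' @param seed Integer seed; fixed seed gives a bit-identical manifest.
#' @return An object of class `shrna_library`: a list with `genes`
#'   (data.frame: `gene`, `class`), `shrnas` (data.frame: `shrna_id`, `gene`,
#'   `guide`) and `barcodes` (named character vector, sample id -> barcode).
#' @examples
#' lib <- simulate_library(n_ubiquitin = 4, n_autophagy = 2,
#'                         total_shrnas = 20, guide_length = 10, seed = 1)
#' nrow(lib$shrnas)
#' @export
simulate_library <- function(n_ubiquitin = 680, n_autophagy = 30,
                             total_shrnas = 4184, guide_length = 22,
                             sample_ids = c("rep1_high", "rep1_low",
                                            "rep2_high", "rep2_low"),
                             barcode_length = 6, seed = 1) {
  n_genes <- n_ubiquitin + n_autophagy
  stopifnot(n_ubiquitin >= 0, n_autophagy >= 0, n_genes >= 1,
            total_shrnas >= n_genes, guide_length >= 8, barcode_length >= 1,
            length(sample_ids) >= 1, !anyDuplicated(sample_ids))
  if (guide_length * log(4) < log(total_shrnas))
    stop("cannot draw ", total_shrnas, " unique guides of length ",
         guide_length, ": 4^", guide_length, " sequences exist")
  if (barcode_length * log(4) < log(length(sample_ids)))
    stop("barcode_length too short for ", length(sample_ids), " samples")

  set.seed(seed)
  gene <- c(if (n_ubiquitin > 0) sprintf("Ubr%04d", seq_len(n_ubiquitin)),
            if (n_autophagy > 0) sprintf("Atgc%03d", seq_len(n_autophagy)))
  class <- rep(c("ubiquitin_regulator", "autophagy_control"),
               c(n_ubiquitin, n_autophagy))
  genes <- data.frame(gene = gene, class = class, stringsAsFactors = FALSE)

  base <- total_shrnas %/% n_genes
  per_gene <- rep(base, n_genes)
  extra <- total_shrnas %% n_genes
  if (extra > 0) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L

  shrna_gene <- rep(gene, per_gene)
  within_idx <- unlist(lapply(per_gene, seq_len), use.names = FALSE)
  shrna_id <- sprintf("%s.sh%d", shrna_gene, within_idx)
  guides <- random_unique_seqs(total_shrnas, guide_length)
  shrnas <- data.frame(shrna_id = shrna_id, gene = shrna_gene,
                       guide = guides, stringsAsFactors = FALSE)

  barcodes <- random_unique_seqs(length(sample_ids), barcode_length)
  names(barcodes) <- sample_ids

  lib <- structure(list(genes = genes, shrnas = shrnas, barcodes = barcodes),
                   class = "shrna_library")
  validate_library(lib)
  lib
}

# unique random fixed-length nucleotide strings; redraws on collision
random_unique_seqs <- function(n, len) {
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    draw <- vapply(seq_len(need + ceiling(need / 4)), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), character(1))
    out <- unique(c(out, draw))
  }
  out[seq_len(n)]
}

validate_library <- function(lib) {
  stopifnot(inherits(lib, "shrna_library"))
  with(lib, {
    if (anyDuplicated(shrnas$shrna_id)) stop("duplicate shrna_id in library")
    if (anyDuplicated(shrnas$guide)) stop("duplicate guide sequence in library")
    if (anyDuplicated(barcodes)) stop("duplicate sample barcode")
    if (length(unique(nchar(barcodes))) > 1) stop("barcodes of unequal length")
    if (length(unique(nchar(shrnas$guide))) > 1) stop("guides of unequal length")
    if (!all(shrnas$gene %in% genes$gene))
      stop("shRNA maps to a gene absent from the gene table")
  })
  invisible(lib)
}

#' @export
print.shrna_library <- function(x, ...) {
  cat(sprintf("shRNA library: %d genes (%d ubiquitin_regulator, %d autophagy_control), %d shRNAs\n",
              nrow(x$genes), sum(x$genes$class == "ubiquitin_regulator"),
              sum(x$genes$class == "autophagy_control"), nrow(x$shrnas)))
  cat(sprintf("guide length %d nt; %d sample barcodes (%s)\n",
              nchar(x$shrnas$guide[1]), length(x$barcodes),
              paste(names(x$barcodes), collapse = ", ")))
  invisible(x)
}

#' Write / read an shRNA library manifest as TSV
#'
#' The manifest is a tab-separated table with columns `shrna_id`, `gene`,
#' `class`, `guide`; sample barcodes are stored in `# barcode` header comment
#' lines so that a single file round-trips the whole design.
#'
#' @param lib An `shrna_library` object.
#' @param path File path.
#' @return `write_library` returns `path` invisibly; `read_library` returns
#'   the reconstructed `shrna_library`.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# barcode\t%s\t%s", names(lib$barcodes), lib$barcodes),
             con)
  cls <- lib$genes$class[match(lib$shrnas$gene, lib$genes$gene)]
  tab <- data.frame(shrna_id = lib$shrnas$shrna_id, gene = lib$shrnas$gene,
                    class = cls, guide = lib$shrnas$guide)
  writeLines(paste(colnames(tab), collapse = "\t"), con)
  writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lines <- readLines(path)
  bc_lines <- grep("^# barcode\t", lines, value = TRUE)
  parts <- strsplit(bc_lines, "\t", fixed = TRUE)
  barcodes <- vapply(parts, `[`, character(1), 3)
  names(barcodes) <- vapply(parts, `[`, character(1), 2)
  body <- lines[!startsWith(lines, "#")]
  tab <- read.delim(text = body, stringsAsFactors = FALSE)
  genes <- unique(tab[, c("gene", "class")])
  rownames(genes) <- NULL
  lib <- structure(list(
    genes = genes,
    shrnas = data.frame(shrna_id = tab$shrna_id, gene = tab$gene,
                        guide = tab$guide, stringsAsFactors = FALSE),
    barcodes = barcodes), class = "shrna_library")
  validate_library(lib)
  lib
}
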