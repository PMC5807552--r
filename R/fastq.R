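#' Write simulated screen reads as FASTQ
#'
#' Emulates the guide-strand amplicon sequencing of a sorted screen: every
#' read is the sample barcode immediately followed by the shRNA guide
#' sequence, error-free, with constant Phred+33 quality ("I" = Q40). The
#' number of reads per (sample, shRNA) equals the corresponding count cell,
#' so re-counting the output with [count_guides()] reproduces the input
#' matrix exactly.
#'
#' @param counts A [count_matrix()] whose rows are shRNAs of `library` and
#'   whose columns are samples with barcodes in `library$barcodes`.
#' @param library An `shrna_library`.
#' @param path Output FASTQ path (a `.gz` suffix writes gzip).
#' @return The total number of reads written, invisibly.
#' @export
simulate_fastq <- function(counts, library, path) {
  validate_library(library)
  stopifnot(inherits(counts, "count_matrix"))
  unknown <- setdiff(rownames(counts), library$shrnas$shrna_id)
  if (length(unknown) > 0)
    stop("counts reference shRNAs absent from library: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  missing_bc <- setdiff(colnames(counts), names(library$barcodes))
  if (length(missing_bc) > 0)
    stop("no barcode for sample(s): ", paste(missing_bc, collapse = ", "))

  guide <- library$shrnas$guide[match(rownames(counts),
                                      library$shrnas$shrna_id)]
  seqs <- character(0)
  for (s in colnames(counts)) {
    nz <- which(counts[, s] > 0)
    if (length(nz) == 0) next
    seqs <- c(seqs, rep(paste0(library$barcodes[[s]], guide[nz]),
                        counts[nz, s]))
  }
  x <- Biostrings::DNAStringSet(seqs)
  if (length(x) > 0) names(x) <- sprintf("read_%d", seq_along(x))
  qual <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual,
                              compress = endsWith(path, ".gz"))
  invisible(length(x))
}

#' Count barcoded guide reads into an shRNA-by-sample matrix
#'
#' Demultiplexes each read by exact barcode match at `barcode_offset`, then
#' assigns it to an shRNA by exact guide match at `guide_offset` (1-based
#' positions within the read). No mismatch rescue is attempted: a read whose
#' barcode matches no sample increments the pool-wide `no_barcode_match`
#' tally, and a barcode-matched read whose guide matches nothing (including
#' reads too short to contain a full guide) increments that sample's
#' `no_guide_match` tally. The returned matrix covers the full library,
#' zero-filled.
#'
#' @param fastq Path to a FASTQ file (plain or gzip).
#' @param library An `shrna_library` providing barcodes and guide sequences.
#' @param barcode_offset 1-based read position where the barcode starts.
#' @param guide_offset 1-based read position where the guide starts; default
#'   immediately after the barcode.
#' @return A [count_matrix()] over all library shRNAs and samples.
#' @export
count_guides <- function(fastq, library, barcode_offset = 1,
                         guide_offset = barcode_offset +
                           nchar(library$barcodes[[1]])) {
  validate_library(library)
  stopifnot(barcode_offset >= 1, guide_offset >= 1)
  validate_fastq_structure(fastq)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq",
                                                     use.names = FALSE))
  barcodes <- library$barcodes
  guides <- library$shrnas$guide
  ids <- library$shrnas$shrna_id
  samples <- names(barcodes)
  bc_len <- nchar(barcodes[[1]])
  g_len <- nchar(guides[1])

  bc <- substr(reads, barcode_offset, barcode_offset + bc_len - 1L)
  sample_idx <- match(bc, barcodes)
  no_barcode <- sum(is.na(sample_idx))
  gd <- substr(reads, guide_offset, guide_offset + g_len - 1L)
  shrna_idx <- match(gd, guides)

  ok <- !is.na(sample_idx) & !is.na(shrna_idx)
  tab <- table(factor(ids[shrna_idx[ok]], levels = ids),
               factor(samples[sample_idx[ok]], levels = samples))
  m <- matrix(as.integer(tab), nrow = length(ids),
              dimnames = list(ids, samples))
  ngm <- tabulate(sample_idx[!is.na(sample_idx) & is.na(shrna_idx)],
                  nbins = length(samples))
  count_matrix(m, no_guide_match = stats::setNames(as.integer(ngm), samples),
               no_barcode_match = no_barcode)
}

# structural FASTQ check so malformed records fail with a record index
# (4-line records: '@' header, sequence, '+' separator, quality)
validate_fastq_structure <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  if (length(lines) %% 4 != 0)
    stop(sprintf("truncated FASTQ record %d in %s",
                 length(lines) %/% 4 + 1L, path))
  if (length(lines) == 0) return(invisible(TRUE))
  hdr <- lines[seq(1, length(lines), by = 4)]
  sep <- lines[seq(3, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(sep, "+"))
  if (length(bad) > 0)
    stop(sprintf("malformed FASTQ record %d in %s", bad[1], path))
  invisible(TRUE)
}
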