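#' Construct an shRNA-by-sample count matrix
#'
#' A `count_matrix` is an integer matrix with shRNA ids as row names and
#' sample ids as column names, carrying two demultiplexing tallies:
#' `no_guide_match` (per sample: reads whose barcode matched but whose guide
#' did not) and `no_barcode_match` (a single pool-wide tally -- a read whose
#' barcode matches no sample cannot be attributed to one). Per sample,
#' `colSums(x) + no_guide_match` equals the number of barcode-matched reads,
#' and adding `no_barcode_match` over all samples gives the total read count.
#'
#' @param counts Integer matrix (shRNA x sample) with dimnames.
#' @param no_guide_match Named integer vector per sample (default all zero).
#' @param no_barcode_match Single integer (default 0).
#' @return An object of class `count_matrix` (an integer matrix with
#'   attributes).
#' @export
count_matrix <- function(counts, no_guide_match = NULL, no_barcode_match = 0L) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (anyDuplicated(rownames(counts))) stop("duplicate shRNA row ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  if (is.null(no_guide_match)) {
    no_guide_match <- stats::setNames(integer(ncol(counts)), colnames(counts))
  }
  stopifnot(identical(sort(names(no_guide_match)), sort(colnames(counts))))
  attr(counts, "no_guide_match") <- no_guide_match[colnames(counts)]
  attr(counts, "no_barcode_match") <- as.integer(no_barcode_match)
  class(counts) <- c("count_matrix", class(counts))
  counts
}

#' Unassigned-read tallies of a count matrix
#'
#' @param x A `count_matrix`.
#' @return A list with `no_guide_match` (named integer per sample) and
#'   `no_barcode_match` (integer).
#' @export
unassigned_reads <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  list(no_guide_match = attr(x, "no_guide_match"),
       no_barcode_match = attr(x, "no_barcode_match"))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count matrix: %d shRNAs x %d samples, %s assigned reads\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  ua <- unassigned_reads(x)
  cat(sprintf("unassigned: %d no-guide-match, %d no-barcode-match\n",
              sum(ua$no_guide_match), ua$no_barcode_match))
  invisible(x)
}

#' Write / read a count matrix as TSV
#'
#' Layout: `# no_barcode_match <n>` and one `# no_guide_match <sample> <n>`
#' comment line per sample, then a header row `shrna_id` plus sample columns,
#' then one row per shRNA. Zero rows are preserved; `read_counts` errors on
#' duplicated shRNA ids or non-integer cells, naming the offender.
#'
#' @param x A `count_matrix`.
#' @param path File path.
#' @return `write_counts` returns `path` invisibly; `read_counts` the
#'   reconstructed `count_matrix`.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "count_matrix"))
  ua <- unassigned_reads(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# no_barcode_match\t%d", ua$no_barcode_match), con)
  writeLines(sprintf("# no_guide_match\t%s\t%d",
                     names(ua$no_guide_match), ua$no_guide_match), con)
  writeLines(paste(c("shrna_id", colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], x[i, ]), collapse = "\t"), character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  nbm <- 0L
  ngm_names <- character(0); ngm <- integer(0)
  for (ln in lines[is_comment]) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (parts[1] == "# no_barcode_match") nbm <- as.integer(parts[2])
    if (parts[1] == "# no_guide_match") {
      ngm_names <- c(ngm_names, parts[2])
      ngm <- c(ngm, as.integer(parts[3]))
    }
  }
  tab <- read.delim(text = lines[!is_comment], stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
  if (anyDuplicated(tab$shrna_id))
    stop("duplicated shRNA row id: ",
         tab$shrna_id[duplicated(tab$shrna_id)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m),
                                 dimnames = list(tab$shrna_id, colnames(m))))
  bad <- which(is.na(num) | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-integer count at shRNA '%s', sample '%s': '%s'",
                 rownames(num)[bad[1, 1]], colnames(num)[bad[1, 2]],
                 m[bad[1, , drop = FALSE]]))
  count_matrix(num, no_guide_match = stats::setNames(ngm, ngm_names),
               no_barcode_match = nbm)
}
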