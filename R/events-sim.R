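#' Simulate per-cell reporter fluorescence event tables
#'
#' Generates flow-cytometry-style event tables for tandem-reporter cells.
#' mCherry is pH-insensitive and drawn from its basal log-normal in every
#' condition. GFP is drawn from the basal log-normal for cells in
#' non-induced conditions and for flux-blocked cells; flux-competent cells
#' in an autophagy-inducing condition have their GFP multiplied by
#' `quench_factor` (quenching in the acidic autolysosome).
#'
#' @param n_events Cells per condition per replicate.
#' @param conditions Condition labels; each row is tagged with one.
#' @param induced Subset of `conditions` in which autophagy is induced
#'   (starvation or drug); GFP quenching applies only there.
#' @param flux_block Probability that a cell fails to complete flux (its
#'   GFP stays basal) in an induced condition, in `[0, 1]`.
#' @param quench_factor Multiplicative GFP reduction for flux-competent
#'   induced cells, in `(0, 1]`.
#' @param gfp_meanlog,gfp_sdlog Basal GFP log-normal parameters.
#' @param mcherry_meanlog,mcherry_sdlog mCherry log-normal parameters.
#' @param cell_line Cell-line label for the metadata column.
#' @param replicates Number of biological replicates.
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @return data.frame with columns `mcherry`, `gfp`, `condition`,
#'   `cell_line`, `replicate` -- one row per cell.
#' @examples
#' ev <- simulate_events(n_events = 500, flux_block = 0,
#'                       quench_factor = 0.2, seed = 7)
#' aggregate(gfp ~ condition, ev, mean)
#' @export
simulate_events <- function(n_events = 10000,
                            conditions = c("FM", "Starv"),
                            induced = setdiff(conditions, "FM"),
                            flux_block = 0, quench_factor = 0.2,
                            gfp_meanlog = log(1000), gfp_sdlog = 0.4,
                            mcherry_meanlog = log(800), mcherry_sdlog = 0.3,
                            cell_line = "reporter", replicates = 3,
                            seed = 1) {
  stopifnot(n_events > 0, length(conditions) >= 1,
            all(induced %in% conditions),
            flux_block >= 0, flux_block <= 1,
            quench_factor > 0, quench_factor <= 1, replicates >= 1)
  set.seed(seed)
  out <- vector("list", length(conditions) * replicates)
  k <- 0
  for (rep_i in seq_len(replicates)) {
    for (cond in conditions) {
      mch <- rlnorm(n_events, mcherry_meanlog, mcherry_sdlog)
      gfp <- rlnorm(n_events, gfp_meanlog, gfp_sdlog)
      if (cond %in% induced) {
        blocked <- rbinom(n_events, 1L, flux_block) == 1L
        gfp[!blocked] <- gfp[!blocked] * quench_factor
      }
      k <- k + 1
      out[[k]] <- data.frame(mcherry = mch, gfp = gfp, condition = cond,
                             cell_line = cell_line, replicate = rep_i,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Write / read an event table as CSV
#'
#' Column layout: `mcherry`, `gfp`, `condition`, `cell_line`, `replicate`.
#'
#' @param events Event data.frame as produced by [simulate_events()].
#' @param path File path.
#' @return `write_events` returns `path` invisibly; `read_events` the
#'   data.frame.
#' @export
write_events <- function(events, path) {
  stopifnot(all(c("mcherry", "gfp", "condition", "cell_line", "replicate")
                %in% colnames(events)))
  write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
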