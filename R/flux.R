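#' Summarize autophagic flux as percent of control fluorescence
#'
#' For every cell line, replicate and condition, the mean of the raw
#' (linear) fluorescence of the chosen channel is computed; within each
#' cell line and replicate the control condition is set to 100% and every
#' condition is expressed as `100 * mean / control_mean` (the remaining
#' fluorescence after autophagy induction). Percentages are then averaged
#' across replicates with a sample SD (n - 1 denominator).
#'
#' @param events Event data.frame with columns `mcherry`, `gfp`,
#'   `condition`, `cell_line`, `replicate`.
#' @param control_condition Condition set to 100% (full medium or vehicle).
#' @param channel `"gfp"` or `"mcherry"`.
#' @return Object of class `flux_summary`: list with `per_replicate`
#'   (cell_line, replicate, condition, mean_signal, percent) and `summary`
#'   (cell_line, condition, percent_mean, percent_sd, n_replicates).
#' @examples
#' ev <- simulate_events(n_events = 300, flux_block = 0, seed = 2)
#' summarize_flux(ev, control_condition = "FM")$summary
#' @export
summarize_flux <- function(events, control_condition = "FM",
                           channel = c("gfp", "mcherry")) {
  channel <- match.arg(channel)
  need <- c("mcherry", "gfp", "condition", "cell_line", "replicate")
  stopifnot(all(need %in% colnames(events)), nrow(events) > 0)
  if (any(events[[channel]] < 0)) stop("negative fluorescence values")
  missing_ctrl <- setdiff(unique(events$cell_line),
                          unique(events$cell_line[events$condition ==
                                                    control_condition]))
  if (length(missing_ctrl) > 0)
    stop("no '", control_condition, "' control events for cell line(s): ",
         paste(missing_ctrl, collapse = ", "))

  agg <- aggregate(events[[channel]],
                   by = list(cell_line = events$cell_line,
                             replicate = events$replicate,
                             condition = events$condition),
                   FUN = mean)
  names(agg)[4] <- "mean_signal"
  ctrl <- agg[agg$condition == control_condition, ]
  key <- paste(agg$cell_line, agg$replicate)
  ctrl_mean <- ctrl$mean_signal[match(key, paste(ctrl$cell_line,
                                                 ctrl$replicate))]
  if (anyNA(ctrl_mean))
    stop("control condition missing for some cell line x replicate")
  agg$percent <- 100 * agg$mean_signal / ctrl_mean

  smry <- aggregate(agg$percent,
                    by = list(cell_line = agg$cell_line,
                              condition = agg$condition),
                    FUN = function(v) c(mean(v), sd(v), length(v)))
  smry <- data.frame(cell_line = smry$cell_line, condition = smry$condition,
                     percent_mean = smry$x[, 1], percent_sd = smry$x[, 2],
                     n_replicates = as.integer(smry$x[, 3]),
                     stringsAsFactors = FALSE)
  ord <- order(agg$cell_line, agg$replicate, agg$condition)
  structure(list(per_replicate = agg[ord, ], summary = smry,
                 channel = channel, control_condition = control_condition),
            class = "flux_summary")
}

#' @export
print.flux_summary <- function(x, ...) {
  cat(sprintf("autophagic flux summary (%s, control = %s, 100%%):\n",
              x$channel, x$control_condition))
  print.data.frame(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Construct a gate specification
#'
#' @param channel Channel name (e.g. `"gfp"`).
#' @param lower,upper Gate bounds (either may be infinite); membership is
#'   inclusive-lower / exclusive-upper.
#' @param label Gate label (e.g. `"GFP low"`).
#' @return A list of class `gate_spec`.
#' @export
gate_spec <- function(channel, lower, upper, label) {
  stopifnot(lower < upper)
  structure(list(channel = channel, lower = lower, upper = upper,
                 label = label), class = "gate_spec")
}

#' Derive GFP-low / GFP-high sort gates from control populations
#'
#' The low gate captures cells with functional flux (quenched reporter): its
#' upper bound is the `(1 - alpha)` quantile of the negative-control
#' (starved, flux-competent) population. The high gate captures blocked
#' cells: its lower bound is the `alpha` quantile of the positive-control
#' (flux-blocked) population. If the two bounds cross, the controls are not
#' separable at this `alpha` and an error is raised.
#'
#' @param neg_control,pos_control Event data.frames (or numeric vectors of
#'   channel values) for the flux-competent and flux-blocked controls.
#' @param channel Channel column to gate on.
#' @param alpha Tail fraction of each control left outside its gate.
#' @return list with `low` and `high` [gate_spec()] objects.
#' @export
derive_gates <- function(neg_control, pos_control, channel = "gfp",
                         alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  vals <- function(x) if (is.numeric(x)) x else x[[channel]]
  neg <- vals(neg_control); pos <- vals(pos_control)
  stopifnot(length(neg) > 0, length(pos) > 0)
  low_upper <- quantile(neg, 1 - alpha, names = FALSE)
  high_lower <- quantile(pos, alpha, names = FALSE)
  if (low_upper >= high_lower)
    stop(sprintf("controls not separable at alpha = %g", alpha))
  list(low = gate_spec(channel, -Inf, low_upper, "GFP low"),
       high = gate_spec(channel, high_lower, Inf, "GFP high"))
}

#' Percentage of events falling in each gate
#'
#' Membership is inclusive of the lower bound and exclusive of the upper
#' bound; for disjoint gates the percentages sum to at most 100.
#'
#' @param events Event data.frame.
#' @param gates A single [gate_spec()] or a list of them.
#' @return Named numeric vector of percentages (names = gate labels).
#' @examples
#' ev <- simulate_events(n_events = 200, seed = 3)
#' g <- gate_spec("gfp", 0, Inf, "all")
#' gate_percentages(ev, g)  # 100
#' @export
gate_percentages <- function(events, gates) {
  if (inherits(gates, "gate_spec")) gates <- list(gates)
  stopifnot(nrow(events) > 0, all(vapply(gates, inherits, logical(1),
                                         "gate_spec")))
  out <- vapply(gates, function(g) {
    v <- events[[g$channel]]
    100 * sum(v >= g$lower & v < g$upper) / length(v)
  }, numeric(1))
  names(out) <- vapply(gates, `[[`, character(1), "label")
  out
}
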