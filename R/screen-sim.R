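#' Ground-truth effect model for a simulated screen
#'
#' Encodes which genes block autophagic flux when knocked down and how well
#' each shRNA knocks its gene down. A cell carrying shRNA `s` targeting gene
#' `g` blocks flux with probability `gene_effect[g] * shrna_efficacy[s]`;
#' flux-competent cells quench their GFP by the multiplicative
#' `quench_factor` upon starvation (EGFP is pH-sensitive and loses signal in
#' the acidic autolysosome, mCherry does not).
#'
#' @param library An `shrna_library`.
#' @param regulators Character vector of gene names that are true flux
#'   regulators (receive `effect`); all other genes get effect 0.
#' @param effect Flux-block strength in `[0, 1]` for regulator genes.
#'   Alternatively pass `gene_effect` directly.
#' @param efficacy Per-shRNA knockdown efficacy in `[0, 1]`; a scalar
#'   (recycled), or a named vector over `library$shrnas$shrna_id`.
#' @param quench_factor Multiplicative GFP reduction upon successful
#'   autolysosome formation, in `(0, 1]`.
#' @param gene_effect Optional named numeric vector over all genes,
#'   overriding `regulators`/`effect`.
#' @return Object of class `true_effect_model`: list with `gene_effect`
#'   (named over genes), `shrna_efficacy` (named over shRNAs), and
#'   `quench_factor`.
#' @export
true_effect_model <- function(library, regulators = character(0),
                              effect = 1, efficacy = 1,
                              quench_factor = 0.2, gene_effect = NULL) {
  validate_library(library)
  genes <- library$genes$gene
  if (is.null(gene_effect)) {
    if (!all(regulators %in% genes))
      stop("unknown regulator gene(s): ",
           paste(setdiff(regulators, genes), collapse = ", "))
    gene_effect <- stats::setNames(numeric(length(genes)), genes)
    gene_effect[regulators] <- effect
  } else {
    stopifnot(identical(sort(names(gene_effect)), sort(genes)))
    gene_effect <- gene_effect[genes]
  }
  ids <- library$shrnas$shrna_id
  if (is.null(names(efficacy))) {
    shrna_efficacy <- stats::setNames(rep_len(efficacy, length(ids)), ids)
  } else {
    stopifnot(identical(sort(names(efficacy)), sort(ids)))
    shrna_efficacy <- efficacy[ids]
  }
  stopifnot(all(gene_effect >= 0 & gene_effect <= 1),
            all(shrna_efficacy >= 0 & shrna_efficacy <= 1),
            quench_factor > 0, quench_factor <= 1)
  structure(list(gene_effect = gene_effect, shrna_efficacy = shrna_efficacy,
                 quench_factor = quench_factor), class = "true_effect_model")
}

#' Configuration of the sort-and-sequence screen simulator
#'
#' Defaults are the screen's own conditions: 1,000 cells per shRNA coverage,
#' 8.5% single-copy transduction efficiency, two replicates, sort gates at
#' the outer deciles of the pooled starved GFP distribution, and exactly
#' multinomial sequencing counts (no overdispersion).
#'
#' @param coverage Cells instantiated per shRNA per replicate.
#' @param transduction_efficiency Fraction of seeded cells transduced
#'   (planning quantity; the simulated pool is already the transduced,
#'   selected population).
#' @param sequencing_depth Reads per sorted sample; `NULL` means 100 reads
#'   per shRNA, resolved when the library size is known.
#' @param n_replicates Number of independent screen replicates.
#' @param gate_low,gate_high Percentiles (0-100) of the pooled starved GFP
#'   distribution bounding the "GFP low" (below `gate_low`) and "GFP high"
#'   (above `gate_high`) sort gates.
#' @param overdispersion Dirichlet concentration multiplier for sequencing
#'   counts; 0 disables it (pure multinomial). When positive, pool
#'   proportions `p` are perturbed as `Dirichlet(overdispersion * p)` before
#'   the multinomial draw (smaller values = noisier counts).
#' @param gfp_meanlog,gfp_sdlog Log-normal parameters of basal (unquenched)
#'   per-cell GFP fluorescence.
#' @param mcherry_meanlog,mcherry_sdlog Log-normal parameters of per-cell
#'   mCherry fluorescence (pH-insensitive).
#' @param seed Integer seed; fixed seed gives bit-identical counts.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(coverage = 1000,
                              transduction_efficiency = 0.085,
                              sequencing_depth = NULL,
                              n_replicates = 2,
                              gate_low = 10, gate_high = 90,
                              overdispersion = 0,
                              gfp_meanlog = log(1000), gfp_sdlog = 0.4,
                              mcherry_meanlog = log(800), mcherry_sdlog = 0.3,
                              seed = 1) {
  stopifnot(coverage >= 1,
            transduction_efficiency > 0, transduction_efficiency <= 1,
            is.null(sequencing_depth) || sequencing_depth >= 0,
            n_replicates >= 1,
            gate_low >= 0, gate_high <= 100, gate_low < gate_high,
            overdispersion >= 0, gfp_sdlog > 0, mcherry_sdlog > 0)
  structure(list(coverage = coverage,
                 transduction_efficiency = transduction_efficiency,
                 sequencing_depth = sequencing_depth,
                 n_replicates = n_replicates,
                 gate_low = gate_low, gate_high = gate_high,
                 overdispersion = overdispersion,
                 gfp_meanlog = gfp_meanlog, gfp_sdlog = gfp_sdlog,
                 mcherry_meanlog = mcherry_meanlog,
                 mcherry_sdlog = mcherry_sdlog,
                 seed = seed), class = "screen_sim_config")
}

#' Simulate sorted-population sequencing counts for a pooled reporter screen
#'
#' Emulates the screen architecture: a starved pool of reporter cells, each
#' carrying a single shRNA, is sorted on GFP into a "GFP high" gate (flux
#' blocked -- unquenched reporter) and a "GFP low" gate (functional flux --
#' quenched reporter), and each sorted population is sequenced.
#'
#' Per replicate: `coverage` cells are instantiated per shRNA; each cell
#' blocks flux with probability `gene_effect * shrna_efficacy`; starved GFP
#' is drawn from the basal log-normal for blocked cells and from the basal
#' times `quench_factor` for flux-competent cells. Cells above the
#' `gate_high` percentile of the pooled GFP distribution form the high pool,
#' cells below the `gate_low` percentile the low pool. Sequencing counts per
#' pool are multinomial over the pool's shRNA composition at
#' `sequencing_depth` reads (Dirichlet-perturbed first if
#' `overdispersion > 0`), so each column sums exactly to the depth.
#'
#' @param library An `shrna_library`.
#' @param effects A `true_effect_model` over the same shRNA set.
#' @param cfg A `screen_sim_config`.
#' @return A list with `counts` (a [count_matrix()] with columns
#'   `rep{i}_high` / `rep{i}_low`) and `ground_truth` (data.frame: `gene`,
#'   `class`, `effect`).
#' @export
simulate_screen_counts <- function(library, effects,
                                   cfg = screen_sim_config()) {
  validate_library(library)
  stopifnot(inherits(effects, "true_effect_model"),
            inherits(cfg, "screen_sim_config"))
  ids <- library$shrnas$shrna_id
  if (!identical(sort(names(effects$shrna_efficacy)), sort(ids)))
    stop("effect model and library cover different shRNA sets")
  n <- length(ids)
  depth <- if (is.null(cfg$sequencing_depth)) 100L * n else cfg$sequencing_depth
  p_block <- effects$gene_effect[library$shrnas$gene] *
    effects$shrna_efficacy[ids]

  set.seed(cfg$seed)
  cols <- list()
  for (r in seq_len(cfg$n_replicates)) {
    shrna_of_cell <- rep(seq_len(n), each = cfg$coverage)
    n_cells <- length(shrna_of_cell)
    blocked <- rbinom(n_cells, 1L, p_block[shrna_of_cell]) == 1L
    gfp <- rlnorm(n_cells, cfg$gfp_meanlog, cfg$gfp_sdlog)
    gfp[!blocked] <- gfp[!blocked] * effects$quench_factor
    qlo <- quantile(gfp, cfg$gate_low / 100, names = FALSE)
    qhi <- quantile(gfp, cfg$gate_high / 100, names = FALSE)
    for (gate in c("high", "low")) {
      in_pool <- if (gate == "high") gfp > qhi else gfp < qlo
      pool <- shrna_of_cell[in_pool]
      if (depth > 0 && length(pool) == 0)
        stop(sprintf("empty %s pool in replicate %d at requested depth %d",
                     gate, r, depth))
      if (depth == 0) {
        cnt <- integer(n)
      } else {
        p <- tabulate(pool, nbins = n) / length(pool)
        if (cfg$overdispersion > 0) {
          a <- rgamma(n, shape = cfg$overdispersion * p, rate = 1)
          p <- if (sum(a) > 0) a / sum(a) else p
        }
        cnt <- as.integer(rmultinom(1, depth, p))
      }
      cols[[sprintf("rep%d_%s", r, gate)]] <- cnt
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- ids
  gt <- data.frame(gene = library$genes$gene, class = library$genes$class,
                   effect = unname(effects$gene_effect[library$genes$gene]),
                   stringsAsFactors = FALSE)
  list(counts = count_matrix(m), ground_truth = gt)
}
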