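# Stochastic model of a markerless transposon library and the two-round,
# inducer-coupled FACS gene-trap enrichment.
#
# Each simulated cell independently acquires at most one insertion. Inserted
# cells land in the target gene, an expressed off-target locus, or a silent
# locus in proportion to the genome model's TA-site counts; a per-site
# productive probability (coorientation 1/2 x phase match 1/3 for a single
# variant) and an in-frame-fluorescence probability decide whether the
# insertion can fluoresce at all. Target-locus fluorescence is inducer
# dependent (the gene trap); expressed off-target loci fluoresce regardless
# of inducer. Fluorescence values are drawn per sort from two log-normal
# components (dark autofluorescence vs bright expressing) and gated at a
# threshold in arbitrary units.

#' Build and validate an enrichment simulation configuration
#'
#' Defaults describe a rare-transposition library in a bacterial genome with
#' 260,000 TA sites of which 70 fall in the ~1-kb target gene and half sit in
#' expressed genes; under these defaults the bright fraction of the library is
#' about 1:5,000 cells.
#'
#' @param n_cells Library size per round.
#' @param p_transposition Probability a cell carries an insertion.
#' @param total_ta_sites,target_ta_sites Genome model TA-site counts.
#' @param frac_expressed Fraction of non-target TA sites inside expressed
#'   genes.
#' @param p_productive Per-site probability an insertion is cooriented and in
#'   the compatible phase (default 1/2 x 1/3).
#' @param p_inframe_fluorescent Probability a productive insertion folds into
#'   a fluorescent fusion.
#' @param p_dropout Per-round probability a fluorescence-capable cell is dark
#'   for reasons other than induction.
#' @param dark_meanlog,dark_sdlog,bright_meanlog,bright_sdlog Log-normal
#'   parameters (arbitrary fluorescence units) of the dark and bright
#'   components.
#' @param gate_threshold Gate value in the same arbitrary units.
#' @param seed Optional integer seed; fixes the whole protocol.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 20000L,
                       p_transposition = 0.003,
                       total_ta_sites = 260000L,
                       target_ta_sites = 70L,
                       frac_expressed = 0.5,
                       p_productive = 1 / 6,
                       p_inframe_fluorescent = 0.8,
                       p_dropout = 0,
                       dark_meanlog = log(100), dark_sdlog = 0.4,
                       bright_meanlog = log(10000), bright_sdlog = 0.6,
                       gate_threshold = 1000,
                       seed = NULL) {
  cfg <- list(
    n_cells = as.integer(n_cells), p_transposition = p_transposition,
    total_ta_sites = as.integer(total_ta_sites),
    target_ta_sites = as.integer(target_ta_sites),
    frac_expressed = frac_expressed, p_productive = p_productive,
    p_inframe_fluorescent = p_inframe_fluorescent, p_dropout = p_dropout,
    dark_meanlog = dark_meanlog, dark_sdlog = dark_sdlog,
    bright_meanlog = bright_meanlog, bright_sdlog = bright_sdlog,
    gate_threshold = gate_threshold, seed = seed
  )
  probs <- c("p_transposition", "frac_expressed", "p_productive",
             "p_inframe_fluorescent", "p_dropout")
  for (p in probs) {
    if (!is.numeric(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop("config error: ", p, " must be a probability in [0, 1]",
           call. = FALSE)
    }
  }
  if (cfg$n_cells < 1L) stop("config error: n_cells must be >= 1",
                             call. = FALSE)
  if (cfg$target_ta_sites > cfg$total_ta_sites) {
    stop("config error: target_ta_sites exceeds total_ta_sites",
         call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a transposon mutant library
#'
#' @param config A [sim_config()]. When `config$seed` is set the result is
#'   deterministic.
#' @return A data.frame of class `library_population` with columns
#'   `has_insertion`, `locus` (`target`, `off_target_expressed`, `silent`,
#'   `none`), `productive`, `fluorescent_capable`, `inducer_dependent`.
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_library_(config))
}

simulate_library_ <- function(config) {
  n <- config$n_cells
  has_insertion <- runif(n) < config$p_transposition
  p_target <- config$target_ta_sites / config$total_ta_sites
  u <- runif(n)
  locus <- rep("none", n)
  locus[has_insertion] <- ifelse(
    u[has_insertion] < p_target, "target",
    ifelse(u[has_insertion] < p_target +
             (1 - p_target) * config$frac_expressed,
           "off_target_expressed", "silent")
  )
  expressed <- locus %in% c("target", "off_target_expressed")
  productive <- expressed & runif(n) < config$p_productive
  fluorescent_capable <- productive &
    runif(n) < config$p_inframe_fluorescent
  pop <- data.frame(
    has_insertion = has_insertion,
    locus = locus,
    productive = productive,
    fluorescent_capable = fluorescent_capable,
    inducer_dependent = locus == "target",
    stringsAsFactors = FALSE
  )
  class(pop) <- c("library_population", class(pop))
  pop
}

# Draw one fluorescence value per cell for the current inducer state.
draw_fluorescence <- function(pop, config, inducer) {
  n <- nrow(pop)
  lit <- pop$fluorescent_capable &
    (inducer | !pop$inducer_dependent) &
    (config$p_dropout == 0 | runif(n) >= config$p_dropout)
  val <- rlnorm(n, config$dark_meanlog, config$dark_sdlog)
  if (any(lit)) {
    val[lit] <- rlnorm(sum(lit), config$bright_meanlog, config$bright_sdlog)
  }
  val
}

#' Gate a population on fluorescence
#'
#' Fluorescence is redrawn for the current inducer state, then cells are kept
#' according to the gate direction. The above-gate and below-gate
#' subpopulations at the same threshold partition the population.
#'
#' @param pop A `library_population`.
#' @param config The [sim_config()].
#' @param direction Keep cells `"above"` or `"below"` the threshold.
#' @param inducer Whether the inducer is present for this sort.
#' @param threshold Gate value (default `config$gate_threshold`).
#' @return The gated subpopulation with a `fluorescence` column.
#' @export
apply_gate <- function(pop, config, direction = c("above", "below"),
                       inducer = TRUE, threshold = config$gate_threshold) {
  direction <- match.arg(direction)
  fl <- draw_fluorescence(pop, config, inducer)
  keep <- if (direction == "above") fl > threshold else fl <= threshold
  out <- pop[keep, , drop = FALSE]
  out$fluorescence <- fl[keep]
  out
}

target_fraction <- function(pop) {
  if (nrow(pop) == 0L) return(0)
  mean(pop$locus == "target")
}

#' Run the gene-trap enrichment protocol
#'
#' Round 1 sorts the induced library for cells above the gate; the kept cells
#' are regrown (multinomial resampling back to `n_cells`, which models both
#' repropagation and sibling expansion); round 2 sorts the uninduced culture
#' for cells below the gate. With `rounds = 1` only the first sort is
#' performed.
#'
#' @param config A [sim_config()].
#' @param rounds 1 or 2.
#' @return An object of class `trap_result`: list with `per_round`
#'   (data.frame: `round`, `inducer`, `direction`, `n_before`, `n_kept`,
#'   `fluorescent_fraction`, `target_fraction`), `initial_target_fraction`,
#'   `final_target_fraction` and `enrichment_factor`. An empty intermediate
#'   population yields zero fractions with a warning.
#' @export
run_trap_protocol <- function(config, rounds = 2L) {
  stopifnot(inherits(config, "sim_config"), rounds %in% 1:2)
  with_seed(config$seed, {
    pop <- simulate_library_(config)
    init_tf <- target_fraction(pop)
    per_round <- list()
    note <- function(round, inducer, direction, before, kept) {
      per_round[[length(per_round) + 1L]] <<- data.frame(
        round = round, inducer = inducer, direction = direction,
        n_before = nrow(before), n_kept = nrow(kept),
        fluorescent_fraction = if (nrow(before)) nrow(kept) / nrow(before)
          else 0,
        target_fraction = target_fraction(kept),
        stringsAsFactors = FALSE
      )
    }
    r1 <- apply_gate(pop, config, "above", inducer = TRUE)
    note(1L, TRUE, "above", pop, r1)
    final <- r1
    if (rounds == 2L) {
      if (nrow(r1) == 0L) {
        warning("round 1 gate kept no cells; protocol result is empty",
                call. = FALSE)
        r2 <- r1
        note(2L, FALSE, "below", r1, r2)
      } else {
        regrown <- r1[sample.int(nrow(r1), config$n_cells, replace = TRUE), ,
                      drop = FALSE]
        r2 <- apply_gate(regrown, config, "below", inducer = FALSE)
        note(2L, FALSE, "below", regrown, r2)
      }
      final <- r2
    }
    per_round <- do.call(rbind, per_round)
    # fluorescent_fraction of a below-gate sort is the fraction *removed*
    per_round$fluorescent_fraction[per_round$direction == "below"] <-
      1 - per_round$fluorescent_fraction[per_round$direction == "below"]
    final_tf <- target_fraction(final)
    structure(list(
      per_round = per_round,
      initial_target_fraction = init_tf,
      final_target_fraction = final_tf,
      enrichment_factor = if (init_tf > 0) final_tf / init_tf else NA_real_,
      final_population = final
    ), class = "trap_result")
  })
}

#' @export
print.trap_result <- function(x, ...) {
  cat(sprintf(
    "<trap_result> target fraction %.3g -> %.3g (enrichment %.3g)\n",
    x$initial_target_fraction, x$final_target_fraction, x$enrichment_factor
  ))
  print(x$per_round)
  invisible(x)
}

#' Export a trap result as TSV
#'
#' @param result A `trap_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trap_tsv <- function(result, path) {
  write.table(result$per_round, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
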