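#' Simulation configuration
#'
#' Controls the stochastic simulation: seeding, steady-state burn-in, the
#' measurement window, and replication.
#'
#' Burn-in discards events until `burn_in_terminations` terminations have
#' occurred or simulated time exceeds \eqn{20\,n/\bar\lambda} (whichever
#' first; the time cap covers initiation-starved genes that rarely
#' terminate). Measurement then runs until `measure_terminations` further
#' terminations or until `max_time` of total simulated time, in which case
#' the result is flagged low-confidence rather than returned silently.
#'
#' Each replicate draws from an independent random stream derived from
#' `seed` and the replicate index alone, so replicate k's trajectory does
#' not depend on how many replicates are run, and paired designs can reuse
#' the same streams (`common_random_numbers`).
#'
#' @param seed Integer root seed.
#' @param burn_in_terminations Terminations discarded as burn-in (default 200).
#' @param measure_terminations Terminations required in the measurement
#'   window (default 2000).
#' @param max_time Cap on total simulated seconds per replicate.
#' @param replicates Number of independent replicate runs.
#' @param common_random_numbers Reuse per-replicate streams across paired
#'   baseline/perturbed runs (default `TRUE`; see [sensitivity()]).
#' @param collect_occupancy Record the per-codon occupancy profile (adds
#'   O(s) work per event; off by default in bulk sweeps).
#' @param check_exclusion Assert the hard-core exclusion invariant after
#'   every event (debugging aid).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, burn_in_terminations = 200L,
                       measure_terminations = 2000L, max_time = 1e7,
                       replicates = 4L, common_random_numbers = TRUE,
                       collect_occupancy = FALSE, check_exclusion = FALSE) {
  stopifnot(burn_in_terminations >= 1, measure_terminations >= 1,
            max_time > 0, replicates >= 1)
  structure(
    list(seed = as.integer(seed),
         burn_in_terminations = as.integer(burn_in_terminations),
         measure_terminations = as.integer(measure_terminations),
         max_time = as.numeric(max_time),
         replicates = as.integer(replicates),
         common_random_numbers = isTRUE(common_random_numbers),
         collect_occupancy = isTRUE(collect_occupancy),
         check_exclusion = isTRUE(check_exclusion)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d, burn-in %d terms, measure %d terms, ",
                     "max_time %.3g s, %d replicate(s)\n"),
              x$seed, x$burn_in_terminations, x$measure_terminations,
              x$max_time, x$replicates))
  invisible(x)
}

# one replicate; rep_index keys the random stream together with the root seed
run_one <- function(gene, config, rep_index, collect_occupancy = NULL) {
  occ <- if (is.null(collect_occupancy)) config$collect_occupancy
         else collect_occupancy
  burn_cap <- 20 * length(gene$rates) / mean(gene$rates)
  .tasep_run_cpp(gene$rates, gene$init_rate, gene$footprint,
                 config$seed, rep_index,
                 config$burn_in_terminations, burn_cap,
                 config$measure_terminations, config$max_time,
                 occ, config$check_exclusion)
}

#' Simulate translation of one gene
#'
#' Exact event-driven stochastic simulation of translation elongation as an
#' open-boundary TASEP with extended particles: ribosomes of footprint
#' \eqn{s} codons move 5' to 3' over the \eqn{n} sense codons, never
#' overlapping or overtaking. A ribosome decoding codon \eqn{i} covers
#' codons \eqn{[i, i+s-1]}; it advances at rate \eqn{\lambda_i} when the
#' codon it would newly cover is free, and the ribosome at codon \eqn{n}
#' terminates at rate \eqn{\lambda_n}. Initiation places a ribosome at
#' codon 1 at rate \eqn{\lambda_0} whenever the first \eqn{s} codons are
#' clear. All waiting times are exponential, so the dynamics form a
#' continuous-time Markov chain simulated without approximation.
#'
#' The translation rate TR is the number of terminations per second of
#' measured (post-burn-in) simulated time, averaged over replicates.
#'
#' @param gene A [gene_model()].
#' @param config A [sim_config()].
#' @return An object of class `sim_result`: a list with `tr_mean`, `tr_sd`,
#'   `tr_ci95` (half-width, t-based across replicates), `mean_ribosomes`,
#'   `occupancy` (per-codon fraction of time covered, if collected),
#'   `n_initiations`/`n_terminations` (measurement-window totals),
#'   `measure_time`, `low_confidence`, and the per-replicate table
#'   `replicates`.
#' @examples
#' g <- gene_model("uniform", rates = rep(1, 60), init_rate = 0.05)
#' simulate_tasep(g, sim_config(seed = 1, replicates = 2,
#'                              measure_terminations = 200))
#' @export
simulate_tasep <- function(gene, config = sim_config()) {
  stopifnot(inherits(gene, "gene_model"), inherits(config, "sim_config"))
  R <- config$replicates
  runs <- lapply(seq_len(R), function(k) run_one(gene, config, k))
  summarize_runs(gene, config, runs)
}

summarize_runs <- function(gene, config, runs) {
  R <- length(runs)
  tr <- vapply(runs, `[[`, 0, "tr")
  mr <- vapply(runs, `[[`, 0, "mean_ribosomes")
  lowconf <- vapply(runs, `[[`, TRUE, "low_confidence")
  tr_sd <- if (R > 1) sd(tr) else NA_real_
  ci <- if (R > 1) qt(0.975, R - 1) * tr_sd / sqrt(R) else NA_real_
  occupancy <- NULL
  if (config$collect_occupancy) {
    occ_mat <- vapply(runs, `[[`, numeric(length(gene$rates)), "occupancy")
    occupancy <- rowMeans(occ_mat)
  }
  rep_tab <- data.frame(
    replicate = seq_len(R), tr = tr, mean_ribosomes = mr,
    n_terminations = vapply(runs, `[[`, 0, "n_terminations"),
    measure_time = vapply(runs, `[[`, 0, "measure_time"),
    init_total = vapply(runs, `[[`, 0, "init_total"),
    term_total = vapply(runs, `[[`, 0, "term_total"),
    bound_at_end = vapply(runs, `[[`, 0, "bound_at_end"),
    low_confidence = lowconf)
  structure(
    list(gene_id = gene$gene_id, tr_mean = mean(tr), tr_sd = tr_sd,
         tr_ci95 = ci, mean_ribosomes = mean(mr), occupancy = occupancy,
         n_initiations = sum(vapply(runs, `[[`, 0, "n_initiations")),
         n_terminations = sum(vapply(runs, `[[`, 0, "n_terminations")),
         measure_time = sum(vapply(runs, `[[`, 0, "measure_time")),
         low_confidence = any(lowconf), replicates = rep_tab),
    class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result '%s'>\n", x$gene_id))
  cat(sprintf("  TR = %.5g /s (sd %.3g, 95%% CI half-width %.3g, %d replicates)\n",
              x$tr_mean, x$tr_sd, x$tr_ci95, nrow(x$replicates)))
  cat(sprintf("  mean bound ribosomes = %.4g; %d terminations over %.4g s\n",
              x$mean_ribosomes, as.integer(x$n_terminations), x$measure_time))
  if (x$low_confidence)
    cat("  WARNING: low confidence (max_time reached before the termination quota)\n")
  invisible(x)
}

#' Time-averaged number of bound ribosomes
#'
#' Replicate-averaged, time-weighted mean number of ribosomes bound to the
#' mRNA over the measurement window. This is the quantity calibrated
#' against polysome-profiling density measurements (see
#' [calibrate_initiation_rate()]); its expectation is nondecreasing in the
#' initiation rate.
#'
#' @inheritParams simulate_tasep
#' @return Numeric scalar.
#' @export
estimate_mean_ribosomes <- function(gene, config = sim_config()) {
  simulate_tasep(gene, config)$mean_ribosomes
}
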