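# Synthetic-data generators: uniform test genes, codon decoding-rate tables,
# random gene cohorts, forward-simulated density targets and correlated
# protein-abundance values. These stand in for the experimental inputs of a
# real study (polysome densities, ribosome-profiling decoding rates, protein
# abundance) and are labelled synthetic throughout.

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Uniform-rate synthetic gene
#'
#' The canonical synthetic gene for controlled experiments: `n` codons
#' (default 500, a typical ORF length), all decoding rates equal (default
#' 1 codon/s) so that \eqn{\xi} equals the initiation rate, footprint 9.
#'
#' @param n ORF length in codons.
#' @param rate Common decoding rate.
#' @param lambda0 Initiation rate.
#' @param s Ribosome footprint.
#' @param gene_id Identifier (default `"synthetic_uniform"`).
#' @return A [gene_model()] without codon sequence.
#' @examples
#' xi(make_uniform_gene(lambda0 = 0.1)) # 0.1
#' @export
make_uniform_gene <- function(n = 500L, rate = 1.0, lambda0 = 0.1, s = 9L,
                              gene_id = "synthetic_uniform") {
  gene_model(gene_id, rep(rate, n), lambda0, s)
}

#' Synthetic codon decoding-rate table
#'
#' Draws a typical decoding rate for each of the 61 sense codons from a
#' log-normal distribution. The defaults give rates mostly between ~2 and
#' ~15 codons/s, the physiological range of codon decoding speeds.
#' Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @param log_mean,log_sd Parameters of the log-normal (natural log scale).
#' @return Named numeric vector of length 61 (codon -> rate, codons/s).
#' @examples
#' tdr <- make_tdr_table(seed = 1)
#' range(tdr)
#' @export
make_tdr_table <- function(seed = 1L, log_mean = log(6), log_sd = 0.35) {
  codons <- sense_codons()
  rates <- with_seed(seed, rlnorm(length(codons), log_mean, log_sd))
  setNames(rates, codons)
}

#' Specification of a synthetic gene cohort
#'
#' Bundles the generative parameters for [sample_cohort()]: the number of
#' genes, a log-normal ORF-length distribution (truncated to
#' `length_range`, emulating ORFs of ~50-4000 codons), the codon
#' decoding-rate table, codon-usage sampling weights, a log-normal
#' initiation-rate distribution, and the protein-abundance model (a
#' Gaussian copula linking abundance positively to initiation rate and
#' negatively to length).
#'
#' Default initiation rates put most genes in the low-\eqn{\xi} regime
#' (median \eqn{\xi \approx 0.05}), as observed for baseline conditions.
#'
#' @param n_genes Number of genes.
#' @param length_meanlog,length_sdlog Log-normal ORF-length parameters.
#' @param length_range Truncation bounds in codons (min must be >= `s`).
#' @param tdr_table Codon -> rate table (default [make_tdr_table()] with
#'   this spec's seed).
#' @param codon_usage Named sampling weights over the 61 sense codons
#'   (default uniform); normalized to sum to 1.
#' @param lambda0_meanlog,lambda0_sdlog Log-normal initiation-rate
#'   parameters.
#' @param pa_rho_lambda0 Target copula correlation of protein abundance
#'   with initiation rate (positive).
#' @param pa_rho_length Target copula correlation with ORF length
#'   (negative).
#' @param pa_meanlog,pa_sdlog Log-normal marginal of protein abundance.
#' @param s Ribosome footprint.
#' @param seed Integer root seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_genes = 100L, length_meanlog = log(400),
                        length_sdlog = 0.6, length_range = c(50L, 4000L),
                        tdr_table = NULL, codon_usage = NULL,
                        lambda0_meanlog = log(0.3), lambda0_sdlog = 0.7,
                        pa_rho_lambda0 = 0.5, pa_rho_length = -0.3,
                        pa_meanlog = log(1e4), pa_sdlog = 1.2,
                        s = 9L, seed = 1L) {
  if (is.null(tdr_table)) tdr_table <- make_tdr_table(seed)
  stopifnot(all(tdr_table > 0), length(tdr_table) == 61L,
            length_range[1] >= s, n_genes >= 1)
  if (is.null(codon_usage)) {
    codon_usage <- setNames(rep(1 / 61, 61), sense_codons())
  }
  codon_usage <- codon_usage / sum(codon_usage)
  if (pa_rho_lambda0^2 + pa_rho_length^2 >= 1) {
    stop("pa copula correlations too large (rho1^2 + rho2^2 must be < 1)")
  }
  structure(list(n_genes = as.integer(n_genes),
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 length_range = as.integer(length_range),
                 tdr_table = tdr_table, codon_usage = codon_usage,
                 lambda0_meanlog = lambda0_meanlog,
                 lambda0_sdlog = lambda0_sdlog,
                 pa_rho_lambda0 = pa_rho_lambda0,
                 pa_rho_length = pa_rho_length,
                 pa_meanlog = pa_meanlog, pa_sdlog = pa_sdlog,
                 s = as.integer(s), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Sample a synthetic gene cohort
#'
#' Draws `n_genes` genes according to a [cohort_spec()]: ORF lengths from
#' the truncated log-normal, codon sequences starting with ATG and
#' continuing with sense codons sampled by the usage weights, per-codon
#' rates looked up in the decoding-rate table, and initiation rates from
#' the log-normal. Byte-identical output for a fixed spec (including its
#' seed).
#'
#' @param spec A [cohort_spec()].
#' @return Named list of [gene_model()]s (names = gene ids `g001`, ...).
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  codons_pool <- names(spec$codon_usage)
  with_seed(spec$seed, {
    lens <- round(rlnorm(spec$n_genes, spec$length_meanlog, spec$length_sdlog))
    lens <- pmin(pmax(lens, spec$length_range[1]), spec$length_range[2])
    lambda0 <- rlnorm(spec$n_genes, spec$lambda0_meanlog, spec$lambda0_sdlog)
    ids <- sprintf("g%03d", seq_len(spec$n_genes))
    genes <- lapply(seq_len(spec$n_genes), function(i) {
      body <- sample(codons_pool, lens[i] - 1L, replace = TRUE,
                     prob = spec$codon_usage)
      codons <- c("ATG", body)
      gene_model(ids[i], unname(spec$tdr_table[codons]), lambda0[i],
                 spec$s, codons)
    })
    setNames(genes, ids)
  })
}

#' Forward-simulated ribosome-density targets
#'
#' Simulates each gene at its (known) initiation rate and records the
#' resulting mean bound-ribosome count as that gene's density target,
#' emulating a polysome-profiling measurement with known ground truth.
#' The true initiation rates are returned separately (`truth`) so
#' calibration tests can score recovery without the targets file leaking
#' them.
#'
#' @param genes Named list of [gene_model()]s.
#' @param config A [sim_config()].
#' @return List with data frames `targets` (`gene_id`,
#'   `target_ribosomes`) and `truth` (`gene_id`, `lambda0`).
#' @export
forward_density_targets <- function(genes, config = sim_config()) {
  rows <- lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id,
               target_ribosomes = estimate_mean_ribosomes(g, config))
  })
  truth <- data.frame(
    gene_id = vapply(genes, `[[`, "", "gene_id"),
    lambda0 = vapply(genes, `[[`, 0, "init_rate"), row.names = NULL)
  list(targets = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = truth)
}

#' Sample protein-abundance values correlated with initiation rate
#'
#' Draws log-normal protein abundances via a Gaussian copula: the latent
#' normal is a weighted sum of the normal scores of the genes' initiation
#' rates (positive weight) and ORF lengths (negative weight) plus
#' independent noise, so the realized Spearman correlations approximate
#' the spec's `pa_rho_lambda0` and `pa_rho_length`.
#'
#' @param genes Named list of [gene_model()]s.
#' @param spec The [cohort_spec()] carrying the abundance model.
#' @param seed Seed offset (default: spec seed + 1, so abundance noise is
#'   independent of cohort sampling).
#' @return Data frame `gene_id`, `protein_abundance` (linear scale, > 0).
#' @export
sample_protein_abundance <- function(genes, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  ng <- length(genes)
  lam <- vapply(genes, `[[`, 0, "init_rate")
  len <- vapply(genes, function(g) length(g$rates), 0)
  zscore <- function(v) qnorm((rank(v, ties.method = "average") - 0.5) / ng)
  r1 <- spec$pa_rho_lambda0
  r2 <- spec$pa_rho_length
  z <- with_seed(seed, {
    eps <- rnorm(ng)
    r1 * zscore(lam) + r2 * zscore(len) + sqrt(1 - r1^2 - r2^2) * eps
  })
  pa <- exp(spec$pa_meanlog + spec$pa_sdlog * z)
  data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
             protein_abundance = unname(pa), row.names = NULL)
}
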