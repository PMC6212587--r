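#' Classify a gene's initiation regime from xi
#'
#' Three regimes of start-region sensitivity as a function of
#' \eqn{\xi = \lambda_0/\langle\lambda_i\rangle}: in regime 1 (low
#' \eqn{\xi}) sensitivity grows with initiation rate, peaking near the
#' upper boundary; in regime 2 it decays as internal codons take over as
#' the bottleneck; in regime 3 the first codons are insensitive regardless
#' of initiation rate. The default boundaries (0.1, 0.5) describe a
#' uniform-rate gene and are tunable for other rate compositions. The tie
#' at the lower boundary is assigned to regime 1, the tie at the upper
#' boundary to regime 3.
#'
#' @param xi Numeric vector of \eqn{\xi} values.
#' @param boundaries Length-2 numeric, the regime boundaries.
#' @return Integer vector in \{1, 2, 3\}.
#' @examples
#' classify_regime(c(0.05, 0.1, 0.3, 0.5, 2))
#' @export
classify_regime <- function(xi, boundaries = c(0.1, 0.5)) {
  stopifnot(length(boundaries) == 2L, boundaries[1] < boundaries[2],
            all(xi > 0))
  ifelse(xi <= boundaries[1], 1L, ifelse(xi < boundaries[2], 2L, 3L))
}

#' Spearman rank correlation with two-sided p-value
#'
#' Thin wrapper around [stats::cor.test()] (`method = "spearman"`, ties
#' mid-ranked, two-sided). A constant input has no rank ordering: the
#' result is then `rho = NaN` with `defined = FALSE` rather than an error.
#'
#' @param x,y Numeric vectors of equal length.
#' @return List: `rho`, `p_value`, `n`, `defined`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NaN, p_value = NaN, n = length(x), defined = FALSE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Least-squares fit of sensitivity (percent) on log10(xi)
#'
#' Fits `sensitivity_percent ~ log10(xi)` by ordinary least squares over the
#' genes whose \eqn{\xi} falls inside `xi_range`, mirroring the per-regime
#' log-linear summaries of start-region sensitivity.
#'
#' @param xi Numeric vector of \eqn{\xi} values.
#' @param sens_percent Sensitivities in percent (signed).
#' @param xi_range Length-2 numeric interval (inclusive).
#' @return List: `slope`, `intercept`, `n`, plus the `lm` fit.
#' @export
loglinear_fit <- function(xi, sens_percent, xi_range = range(xi)) {
  stopifnot(length(xi) == length(sens_percent), length(xi_range) == 2L)
  keep <- xi >= xi_range[1] & xi <= xi_range[2] & complete.cases(xi, sens_percent)
  if (sum(keep) < 3L) stop("fewer than 3 points inside xi_range")
  lx <- log10(xi[keep])
  fit <- lm(sens_percent[keep] ~ lx)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       n = sum(keep), fit = fit)
}

#' Protein-abundance / sensitivity correlation within ORF-length bins
#'
#' Divides genes into `n_bins` bins of (near-)equal gene count by ORF
#' length and computes the Spearman correlation between protein abundance
#' and the chosen sensitivity inside each bin, removing the confounding of
#' both quantities with length. Significance markers at three configurable
#' p-value thresholds are included for plotting.
#'
#' @param records Data frame with columns `length_codons`,
#'   `protein_abundance`, and the sensitivity column named by `sens_col`.
#' @param sens_col Name of the sensitivity column (default
#'   `"start_sensitivity"`).
#' @param n_bins Number of equal-count length bins (default 10).
#' @param thresholds Three descending p-value thresholds for the
#'   significance marker (default 0.05, 0.01, 0.001).
#' @return Data frame: `bin`, `mean_length`, `rho`, `p_value`, `n`,
#'   `signif_level` (0-3: number of thresholds passed).
#' @export
length_binned_pa_correlation <- function(records,
                                         sens_col = "start_sensitivity",
                                         n_bins = 10L,
                                         thresholds = c(0.05, 0.01, 0.001)) {
  stopifnot(all(c("length_codons", "protein_abundance", sens_col) %in%
                  names(records)), length(thresholds) == 3L)
  records <- records[complete.cases(records[c("length_codons",
                                              "protein_abundance", sens_col)]), ]
  ord <- order(records$length_codons)
  records <- records[ord, ]
  ng <- nrow(records)
  if (ng < n_bins * 3L) stop("too few genes for ", n_bins, " bins")
  bin <- ceiling(seq_len(ng) / (ng / n_bins))
  bin[bin > n_bins] <- n_bins
  out <- lapply(seq_len(n_bins), function(b) {
    sub <- records[bin == b, ]
    sc <- spearman_corr(sub$protein_abundance, sub[[sens_col]])
    data.frame(bin = b, mean_length = mean(sub$length_codons), rho = sc$rho,
               p_value = sc$p_value, n = nrow(sub),
               signif_level = if (is.nan(sc$p_value)) 0L
                              else sum(sc$p_value < thresholds))
  })
  do.call(rbind, out)
}

#' Sweep of sensitivity over perturbation magnitudes
#'
#' Computes the mean start-region (or overall) sensitivity of a gene set at
#' each perturbation magnitude in `p_values`, and returns a table that
#' supports linear interpolation to unmeasured magnitudes via
#' [interpolate_sweep()].
#'
#' @param genes List of [gene_model()]s.
#' @param p_values Numeric vector of signed perturbation fractions (or
#'   percent strings). Defaults to the canonical sweep
#'   \{-90%, -50%, -30%, -10%, +10%, +30%, +50%, +100%\}.
#' @param alpha Initiation multiplier.
#' @param positions Positions to average over (default 1:9, the start
#'   region).
#' @param config A [sim_config()].
#' @return Data frame of class `magnitude_sweep`: `p`, `mean_sensitivity`,
#'   `se` (over genes, or over positions for a single gene).
#' @export
magnitude_sweep <- function(genes,
                            p_values = c(-0.9, -0.5, -0.3, -0.1,
                                         0.1, 0.3, 0.5, 1),
                            alpha = 1, positions = 1:9,
                            config = sim_config()) {
  if (inherits(genes, "gene_model")) genes <- list(genes)
  p_values <- vapply(p_values, parse_percent, 0)
  rows <- lapply(p_values, function(p) {
    per_gene <- vapply(genes, function(g) {
      prof <- sensitivity_profile(g, p, alpha, positions, config)
      mean(prof$values)
    }, 0)
    data.frame(p = p, mean_sensitivity = mean(per_gene),
               se = if (length(per_gene) > 1)
                 sd(per_gene) / sqrt(length(per_gene)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("magnitude_sweep", "data.frame")
  out
}

#' Interpolate a magnitude sweep at unmeasured perturbation values
#'
#' Linear interpolation of mean sensitivity between measured perturbation
#' magnitudes (no extrapolation outside the measured range).
#'
#' @param sweep A [magnitude_sweep()] result.
#' @param p New perturbation magnitudes (fractions or percent strings).
#' @return Numeric vector of interpolated sensitivities.
#' @export
interpolate_sweep <- function(sweep, p) {
  p <- vapply(p, parse_percent, 0)
  if (any(p < min(sweep$p) | p > max(sweep$p))) {
    stop("interpolation only within the measured magnitude range")
  }
  approx(sweep$p, sweep$mean_sensitivity, xout = p)$y
}

#' Stratify genes by codon presence in positional windows
#'
#' For a codon type C, builds the four gene strata used to control
#' start-region effects in codon-type-global perturbations. With
#' \eqn{\Gamma(C; I_{yes}, I_{no})} the set of genes carrying C somewhere
#' in the positions \eqn{I_{yes}} but nowhere in \eqn{I_{no}}:
#' \itemize{
#'   \item group 1: \eqn{\Gamma(C; \{2..9\}, \emptyset)} — C in the start
#'     region;
#'   \item group 2: \eqn{\Gamma(C; \{10..18\}, \{2..9\})};
#'   \item group 3: \eqn{\Gamma(C; \{19..27\}, \{2..18\})};
#'   \item group 1c: \eqn{\Gamma(C; \{10..n\}, \{2..9\})} — C only beyond
#'     the start region.
#' }
#' Position 1 (the start codon) is always ignored. Groups 1/2, 2/3 and
#' 1/1c are disjoint by construction.
#'
#' @param genes Named list of [gene_model()]s carrying codon sequences.
#' @param codon_type Codon triplet C.
#' @return An object of class `gamma_groups`: list with `codon_type` and
#'   gene-id character vectors `gamma1`, `gamma2`, `gamma3`, `gamma1c`.
#' @examples
#' g1 <- gene_model("a", rates = rep(1, 30), init_rate = .1,
#'                  codons = c("ATG", "AAA", "AAA", "CGA", rep("AAA", 26)))
#' build_gamma_groups(list(a = g1), "CGA")
#' @export
build_gamma_groups <- function(genes, codon_type) {
  codon_type <- toupper(codon_type)
  has_in <- function(g, window) {
    if (is.null(g$codons)) stop("gene '", g$gene_id, "' carries no sequence")
    window <- window[window >= 2L & window <= length(g$codons)]
    any(g$codons[window] == codon_type)
  }
  ids <- vapply(genes, `[[`, "", "gene_id")
  in1 <- vapply(genes, has_in, TRUE, window = 2:9)
  in2 <- vapply(genes, has_in, TRUE, window = 10:18)
  in3 <- vapply(genes, has_in, TRUE, window = 19:27)
  in_rest <- vapply(genes, function(g) has_in(g, 10:length(g$codons)), TRUE)
  structure(list(codon_type = codon_type,
                 gamma1 = ids[in1],
                 gamma2 = ids[in2 & !in1],
                 gamma3 = ids[in3 & !in1 & !in2],
                 gamma1c = ids[in_rest & !in1]),
            class = "gamma_groups")
}

#' @export
print.gamma_groups <- function(x, ...) {
  cat(sprintf("<gamma_groups '%s'> |G1| = %d, |G2| = %d, |G3| = %d, |G1c| = %d\n",
              x$codon_type, length(x$gamma1), length(x$gamma2),
              length(x$gamma3), length(x$gamma1c)))
  invisible(x)
}

#' Group-wise sensitivity versus codon decoding rate
#'
#' For each codon type and each gene stratum ([build_gamma_groups()]),
#' averages a per-gene sensitivity over the stratum's members and pairs it
#' with the codon's decoding rate, producing the table underlying
#' "sensitivity vs. decoding rate per group" analyses.
#'
#' @param genes Named list of [gene_model()]s with sequences.
#' @param tdr_table Named numeric vector codon -> rate (see
#'   [make_tdr_table()]).
#' @param sensitivities Named list (by codon type) of named numeric vectors
#'   (by gene id) of sensitivities to that codon's global perturbation.
#' @param codon_types Codons to include (default: all in `sensitivities`).
#' @return Data frame: `codon`, `rate`, `group`, `mean_sensitivity`, `n`.
#' @export
group_sensitivity_vs_rate <- function(genes, tdr_table, sensitivities,
                                      codon_types = names(sensitivities)) {
  rows <- list()
  for (codon in codon_types) {
    groups <- build_gamma_groups(genes, codon)
    sens <- sensitivities[[codon]]
    for (grp in c("gamma1", "gamma2", "gamma3", "gamma1c")) {
      members <- intersect(groups[[grp]], names(sens))
      rows[[length(rows) + 1L]] <- data.frame(
        codon = codon, rate = unname(tdr_table[codon]), group = grp,
        mean_sensitivity = if (length(members)) mean(sens[members]) else NA_real_,
        n = length(members))
    }
  }
  do.call(rbind, rows)
}

#' Start-region sensitivity across an initiation-rate grid
#'
#' Scans \eqn{\xi} over a grid for a uniform-rate gene (for which
#' \eqn{\xi = \lambda_0}) and returns the start-region sensitivity (mean
#' of positions `1..s`) at each grid point with its standard error. This
#' is the regime map of start-region sensitivity: rising in magnitude
#' through regime 1, peaking near \eqn{\xi \approx 0.1}, decaying through
#' regime 2 and vanishing in regime 3.
#'
#' @param xi_grid Numeric vector of \eqn{\xi} values to scan.
#' @param p Perturbation fraction (or percent string; default -50%).
#' @param n,rate,s Uniform-gene parameters (see [make_uniform_gene()]).
#' @param config A [sim_config()].
#' @return Data frame: `xi`, `start_sensitivity`, `se`.
#' @export
regime_scan <- function(xi_grid = c(0.02, 0.05, 0.08, 0.1, 0.12, 0.15,
                                    0.2, 0.3),
                        p = -0.5, n = 500L, rate = 1.0, s = 9L,
                        config = sim_config()) {
  p <- parse_percent(p)
  rows <- lapply(xi_grid, function(x) {
    g <- make_uniform_gene(n = n, rate = rate, lambda0 = x * rate, s = s)
    prof <- sensitivity_profile(g, p, alpha = 1, positions = seq_len(s),
                                config = config)
    data.frame(xi = x, start_sensitivity = mean(prof$values),
               se = sqrt(sum(prof$se^2)) / s)
  })
  do.call(rbind, rows)
}
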