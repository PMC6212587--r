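#' Specify a perturbation of translation rates
#'
#' A perturbation multiplies the decoding rate of targeted codons by
#' \eqn{(1 + p)} and the initiation rate by \eqn{\alpha}. Three kinds are
#' supported: `single_codon` (one position), `prolonged` (a contiguous
#' block of `block_length` positions starting at `position`), and
#' `global_codon` (every occurrence of a codon type along the ORF, the
#' start codon excepted — modelling, e.g., a change in the abundance of one
#' tRNA species).
#'
#' `p` is a signed fraction: `p = -0.5` halves the targeted rates,
#' `p = 1` doubles them. Percent strings are accepted (`"-50%"`).
#'
#' @param kind `"single_codon"`, `"prolonged"` or `"global_codon"`.
#' @param p Signed fraction > -1, or a percent string.
#' @param position 1-based codon index of the (first) perturbed codon.
#' @param block_length Block length \eqn{L_p} in codons (prolonged only;
#'   `single_codon` is the `block_length = 1` special case).
#' @param codon_type Codon triplet, e.g. `"CTG"` (global_codon only).
#' @param alpha Initiation-rate multiplier \eqn{\alpha > 0} (default 1).
#' @return An object of class `perturbation`.
#' @examples
#' perturbation("single_codon", p = "-50%", position = 3)
#' perturbation("global_codon", p = -0.5, codon_type = "CTG", alpha = 5)
#' @export
perturbation <- function(kind = c("single_codon", "prolonged", "global_codon"),
                         p, position = NULL, block_length = 1L,
                         codon_type = NULL, alpha = 1) {
  kind <- match.arg(kind)
  p <- parse_percent(p)
  if (!is.finite(p) || p <= -1) stop("p must be a finite fraction > -1")
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  block_length <- as.integer(block_length)
  if (kind == "single_codon") block_length <- 1L
  if (kind %in% c("single_codon", "prolonged")) {
    if (is.null(position)) stop("position required for ", kind)
    position <- as.integer(position)
    if (position < 1L) stop("position must be >= 1")
    if (block_length < 1L) stop("block_length must be >= 1")
  }
  if (kind == "global_codon") {
    if (is.null(codon_type)) stop("codon_type required for global_codon")
    codon_type <- toupper(codon_type)
    if (!codon_type %in% sense_codons()) stop("unknown sense codon: ", codon_type)
  }
  structure(list(kind = kind, p = p, position = position,
                 block_length = block_length, codon_type = codon_type,
                 alpha = as.numeric(alpha)),
            class = "perturbation")
}

parse_percent <- function(p) {
  if (is.character(p)) {
    p <- as.numeric(sub("%$", "", p)) / 100
  }
  as.numeric(p)
}

#' @export
print.perturbation <- function(x, ...) {
  where <- switch(x$kind,
    single_codon = sprintf("position %d", x$position),
    prolonged = sprintf("positions %d..%d", x$position,
                        x$position + x$block_length - 1L),
    global_codon = sprintf("every %s (start codon excluded)", x$codon_type))
  cat(sprintf("<perturbation> %s: p = %+.0f%% at %s, alpha = %g\n",
              x$kind, 100 * x$p, where, x$alpha))
  invisible(x)
}

#' Apply a perturbation to a gene model
#'
#' Returns a new [gene_model()] with \eqn{\lambda_0' = \alpha \lambda_0}
#' and \eqn{\lambda_i' = (1 + p)\lambda_i} at the targeted positions; the
#' input gene is unmodified. Global codon-type perturbations require the
#' gene to carry its codon sequence and never touch position 1.
#'
#' @param gene A [gene_model()].
#' @param pert A [perturbation()].
#' @return A new `gene_model`. The attribute `"n_targeted"` records how
#'   many positions were rescaled (0 is possible for `global_codon` when
#'   the codon does not occur).
#' @export
apply_perturbation <- function(gene, pert) {
  stopifnot(inherits(gene, "gene_model"), inherits(pert, "perturbation"))
  n <- length(gene$rates)
  targets <- switch(pert$kind,
    single_codon = ,
    prolonged = {
      last <- pert$position + pert$block_length - 1L
      if (last > n) {
        stop(sprintf("perturbed block %d..%d exceeds gene length %d",
                     pert$position, last, n))
      }
      pert$position:last
    },
    global_codon = {
      if (is.null(gene$codons)) {
        stop("global_codon perturbation requires the gene's codon sequence")
      }
      setdiff(which(gene$codons == pert$codon_type), 1L)
    })
  rates <- gene$rates
  rates[targets] <- rates[targets] * (1 + pert$p)
  out <- gene_model(gene$gene_id, rates, pert$alpha * gene$init_rate,
                    gene$footprint, gene$codons)
  attr(out, "n_targeted") <- length(targets)
  out
}

# baseline gene for the sensitivity statistic: alpha applied, no rate change
alpha_baseline <- function(gene, alpha) {
  if (alpha == 1) return(gene)
  gene_model(gene$gene_id, gene$rates, alpha * gene$init_rate,
             gene$footprint, gene$codons)
}

# paired replicate TRs for an arbitrary pair of genes under one config
paired_trs <- function(gene_a, gene_b, config) {
  R <- config$replicates
  ks <- seq_len(R)
  tra <- vapply(ks, function(k)
    run_one(gene_a, config, k, collect_occupancy = FALSE)$tr, 0)
  kb <- if (config$common_random_numbers) ks else ks + R
  trb <- vapply(kb, function(k)
    run_one(gene_b, config, k, collect_occupancy = FALSE)$tr, 0)
  list(base = tra, pert = trb)
}

sens_from_pairs <- function(tr_base, tr_pert) {
  R <- length(tr_base)
  mb <- mean(tr_base)
  d <- tr_pert - tr_base
  value <- mean(d) / mb
  se <- if (R > 1) sd(d) / sqrt(R) / mb else NA_real_
  ci <- if (R > 1) qt(0.975, R - 1) * se else NA_real_
  c(value = value, se = se, ci = ci)
}

#' Translation-rate sensitivity to a perturbation
#'
#' The relative change in steady-state translation rate caused by a
#' perturbation:
#' \deqn{\mathrm{sensitivity} = \frac{\langle TR(\theta(\lambda_0,
#' \lambda))\rangle - \langle TR(\lambda_0, \lambda)\rangle}{\langle
#' TR(\lambda_0, \lambda)\rangle}}
#' estimated from paired replicate simulations. When
#' `config$common_random_numbers` is `TRUE` (default), replicate k of the
#' baseline and perturbed runs share a random stream, which cancels most of
#' the between-replicate noise that would otherwise mask small effects.
#'
#' When `alpha != 1` both the baseline and the perturbed gene carry the
#' scaled initiation rate \eqn{\alpha\lambda_0}, so the statistic isolates
#' the rate perturbation `p` at that initiation level.
#'
#' @param gene A [gene_model()].
#' @param pert A [perturbation()].
#' @param config A [sim_config()]; `replicates` should be >= 2 for a CI.
#' @return Named numeric vector: `value` (signed fraction), `se`, `ci`
#'   (95% half-width).
#' @export
sensitivity <- function(gene, pert, config = sim_config()) {
  stopifnot(inherits(gene, "gene_model"), inherits(pert, "perturbation"))
  base <- alpha_baseline(gene, pert$alpha)
  perturbed <- apply_perturbation(gene, pert)
  trs <- paired_trs(base, perturbed, config)
  out <- sens_from_pairs(trs$base, trs$pert)
  if (pert$kind == "global_codon" && attr(perturbed, "n_targeted") == 0L) {
    out[] <- c(0, 0, 0)
    attr(out, "applied") <- FALSE
  }
  out
}

new_sensitivity_profile <- function(gene, p, alpha, positions, values, se, ci,
                                    block_length = 1L) {
  structure(list(gene_id = gene$gene_id, p = p, alpha = alpha,
                 block_length = as.integer(block_length),
                 positions = as.integer(positions),
                 values = as.numeric(values), se = as.numeric(se),
                 ci = as.numeric(ci)),
            class = "sensitivity_profile")
}

#' Positional sensitivity profile of a gene
#'
#' Computes the sensitivity SP(i, p, alpha) of the translation rate to a
#' single-codon perturbation at each requested position i. The baseline
#' replicate runs (at initiation rate \eqn{\alpha\lambda_0}) are simulated
#' once and shared across all positions, with common random streams pairing
#' each perturbed run to its baseline.
#'
#' @param gene A [gene_model()].
#' @param p Signed perturbation fraction (or percent string).
#' @param alpha Initiation multiplier (default 1).
#' @param positions Integer vector of codon positions (default all).
#' @param config A [sim_config()].
#' @return An object of class `sensitivity_profile`: positions, `values`
#'   (signed fractions), per-position `se` and 95% `ci` half-widths.
#' @examples
#' \donttest{
#' g <- make_uniform_gene(n = 200, lambda0 = 0.05)
#' sp <- sensitivity_profile(g, p = "-50%", positions = 1:12,
#'                           config = sim_config(seed = 1, replicates = 10,
#'                                               measure_terminations = 500))
#' print(sp)
#' }
#' @export
sensitivity_profile <- function(gene, p, alpha = 1, positions = NULL,
                                config = sim_config()) {
  stopifnot(inherits(gene, "gene_model"))
  p <- parse_percent(p)
  n <- length(gene$rates)
  if (is.null(positions)) positions <- seq_len(n)
  positions <- as.integer(positions)
  stopifnot(all(positions >= 1L), all(positions <= n))

  base <- alpha_baseline(gene, alpha)
  R <- config$replicates
  tr_base <- vapply(seq_len(R), function(k)
    run_one(base, config, k, collect_occupancy = FALSE)$tr, 0)

  res <- vapply(positions, function(i) {
    pert <- perturbation("single_codon", p, position = i, alpha = alpha)
    perturbed <- apply_perturbation(gene, pert)
    ks <- if (config$common_random_numbers) seq_len(R) else seq_len(R) + R
    tr_pert <- vapply(ks, function(k)
      run_one(perturbed, config, k, collect_occupancy = FALSE)$tr, 0)
    sens_from_pairs(tr_base, tr_pert)
  }, c(value = 0, se = 0, ci = 0))

  new_sensitivity_profile(gene, p, alpha, positions,
                          res["value", ], res["se", ], res["ci", ])
}

#' Sensitivity profile for prolonged (multi-codon) perturbations
#'
#' Like [sensitivity_profile()] but each perturbation rescales a contiguous
#' block of `block_length` codons; the position axis indexes the first
#' codon of the block.
#'
#' @inheritParams sensitivity_profile
#' @param block_length Block length \eqn{L_p} in codons.
#' @param positions Block start positions (default: all starts that fit).
#' @return A `sensitivity_profile` with `block_length` set.
#' @export
prolonged_profile <- function(gene, block_length, p, alpha = 1,
                              positions = NULL, config = sim_config()) {
  stopifnot(inherits(gene, "gene_model"))
  p <- parse_percent(p)
  block_length <- as.integer(block_length)
  n <- length(gene$rates)
  if (is.null(positions)) positions <- seq_len(n - block_length + 1L)
  positions <- as.integer(positions)
  stopifnot(all(positions >= 1L), all(positions + block_length - 1L <= n))

  base <- alpha_baseline(gene, alpha)
  R <- config$replicates
  tr_base <- vapply(seq_len(R), function(k)
    run_one(base, config, k, collect_occupancy = FALSE)$tr, 0)

  res <- vapply(positions, function(i) {
    pert <- perturbation("prolonged", p, position = i,
                         block_length = block_length, alpha = alpha)
    perturbed <- apply_perturbation(gene, pert)
    ks <- if (config$common_random_numbers) seq_len(R) else seq_len(R) + R
    tr_pert <- vapply(ks, function(k)
      run_one(perturbed, config, k, collect_occupancy = FALSE)$tr, 0)
    sens_from_pairs(tr_base, tr_pert)
  }, c(value = 0, se = 0, ci = 0))

  new_sensitivity_profile(gene, p, alpha, positions,
                          res["value", ], res["se", ], res["ci", ],
                          block_length = block_length)
}

#' Sensitivity to a codon-type-global perturbation
#'
#' Rescales the decoding rate of every occurrence of `codon_type` along the
#' ORF (the start codon excepted) and returns the resulting translation-rate
#' sensitivity. If the codon does not occur in the gene the sensitivity is
#' 0 by definition and the result carries `applied = FALSE`.
#'
#' @inheritParams sensitivity_profile
#' @param codon_type Codon triplet, e.g. `"CTG"`.
#' @return As [sensitivity()].
#' @export
global_codon_sensitivity <- function(gene, codon_type, p, alpha = 1,
                                     config = sim_config()) {
  pert <- perturbation("global_codon", parse_percent(p),
                       codon_type = codon_type, alpha = alpha)
  sensitivity(gene, pert, config)
}

#' @export
print.sensitivity_profile <- function(x, ...) {
  what <- if (x$block_length > 1L)
    sprintf("prolonged blocks of %d codons", x$block_length)
  else "single codons"
  cat(sprintf("<sensitivity_profile '%s'> p = %+.0f%%, alpha = %g, %s\n",
              x$gene_id, 100 * x$p, x$alpha, what))
  cat(sprintf("  %d positions (%d..%d); start-region mean %s\n",
              length(x$positions), min(x$positions), max(x$positions),
              tryCatch(sprintf("%+.3f%%", 100 * start_region_sensitivity(x)),
                       error = function(e) "n/a")))
  invisible(x)
}

#' @export
as.data.frame.sensitivity_profile <- function(x, ...) {
  data.frame(gene_id = x$gene_id, position = x$positions, p = x$p,
             alpha = x$alpha, block_length = x$block_length,
             sensitivity = x$values, se = x$se, ci = x$ci)
}

#' Moving-average smoothing of a profile for display
#'
#' Returns a copy of the profile whose values (and error bands) are
#' smoothed with a centred moving average (default window 5, shrunk at the
#' edges). Smoothing is a presentation device only: summary statistics such
#' as [start_region_sensitivity()] always operate on raw stored values.
#'
#' @param profile A `sensitivity_profile`.
#' @param window Odd window width in positions.
#' @return A smoothed `sensitivity_profile` (attribute `"smoothed"` set).
#' @export
smooth_profile <- function(profile, window = 5L) {
  stopifnot(inherits(profile, "sensitivity_profile"), window %% 2 == 1)
  h <- (window - 1L) %/% 2L
  m <- length(profile$values)
  sm <- function(v) vapply(seq_len(m), function(j) {
    idx <- max(1L, j - h):min(m, j + h)
    mean(v[idx])
  }, 0)
  out <- profile
  out$values <- sm(profile$values)
  out$se <- sm(profile$se)
  out$ci <- sm(profile$ci)
  attr(out, "smoothed") <- window
  out
}

#' Start-region sensitivity
#'
#' Mean sensitivity over the first `s` codons (default 9, the ribosome
#' footprint) — the region where a delayed ribosome also blocks initiation,
#' and therefore the dominant contribution at baseline initiation rates.
#'
#' @param profile A `sensitivity_profile` covering positions `1:s`.
#' @param s Number of leading codons to average (default 9).
#' @return Numeric scalar (signed fraction).
#' @export
start_region_sensitivity <- function(profile, s = 9L) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  idx <- match(seq_len(s), profile$positions)
  if (anyNA(idx)) stop("profile does not cover positions 1..", s)
  mean(profile$values[idx])
}

#' Overall sensitivity
#'
#' Mean sensitivity over all positions in the profile (over codons
#' \eqn{1..n} when the profile covers the whole ORF).
#'
#' @param profile A `sensitivity_profile`.
#' @return Numeric scalar (signed fraction).
#' @export
overall_sensitivity <- function(profile) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  mean(profile$values)
}

#' Leading block of elevated sensitivity
#'
#' Identifies the contiguous leading block of positions whose sensitivity
#' magnitude is elevated relative to the immediately following positions,
#' and locates the steep transition that terminates it. With footprint
#' \eqn{s} and low initiation rate the expected block length is exactly
#' \eqn{s}: a ribosome delayed anywhere in codons \eqn{1..s} also blocks
#' initiation, and that coupling ends abruptly at \eqn{s + 1}. (A weaker
#' secondary elevation over the next footprint block is real but an order
#' of magnitude smaller, so the block boundary is a change point, not a
#' significance frontier.)
#'
#' The boundary is placed at the largest drop in sensitivity magnitude
#' between consecutive tested positions. The block is then validated
#' against the downstream reference stretch: its mean magnitude in excess
#' of the reference mean must exceed `z` combined standard errors, and
#' must exceed the post-block mean's excess by the same criterion;
#' otherwise there is no detectable block and 0 is returned.
#'
#' @param profile A `sensitivity_profile` covering position 1 up to at
#'   least the reference positions, with per-position standard errors.
#' @param reference_positions Positions defining the downstream reference
#'   level (default 19:30, beyond the second footprint block).
#' @param z Significance threshold in combined standard errors (default
#'   `qnorm(0.999)`).
#' @return Integer block length; attribute `"excess"` carries each tested
#'   position's magnitude excess over the reference mean.
#' @export
leading_sensitive_block <- function(profile, reference_positions = 19:30,
                                    z = qnorm(0.999)) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  ridx <- match(reference_positions, profile$positions)
  if (anyNA(ridx)) stop("profile does not cover the reference positions")
  test_pos <- profile$positions[profile$positions < min(reference_positions)]
  test_pos <- sort(test_pos)
  if (test_pos[1] != 1L) stop("profile must start at position 1")
  tidx <- match(test_pos, profile$positions)
  ref_mean <- mean(abs(profile$values[ridx]))
  ref_se <- sqrt(sum(profile$se[ridx]^2)) / length(ridx)
  mag <- abs(profile$values[tidx])
  excess <- mag - ref_mean
  # change point: largest drop in magnitude between consecutive positions
  drops <- mag[-length(mag)] - mag[-1]
  cut <- which.max(drops)
  block <- seq_len(cut)
  after <- setdiff(seq_along(test_pos), block)
  mean_se <- function(idx) sqrt(sum(profile$se[tidx][idx]^2)) / length(idx)
  block_mean <- mean(excess[block])
  after_mean <- mean(excess[after])
  ok_ref <- block_mean > z * sqrt(mean_se(block)^2 + ref_se^2)
  ok_after <- (block_mean - after_mean) >
    z * sqrt(mean_se(block)^2 + mean_se(after)^2)
  run <- if (ok_ref && ok_after) length(block) else 0L
  structure(as.integer(run), excess = setNames(excess, test_pos))
}

#' Length of the fully-elevated leading plateau of a profile
#'
#' For prolonged perturbations the sensitivity profile starts with a flat
#' plateau of maximal magnitude — the block start positions for which the
#' whole perturbed block lies inside the initiation-coupled first
#' \eqn{s} codons, i.e. the first \eqn{s + 1 - L_p} positions — and then
#' declines gradually as the block increasingly sticks out. This
#' sequential detector returns the plateau length: positions are scanned
#' from the start and the plateau ends just before the first position
#' whose magnitude falls significantly below the running plateau mean
#' (one-sided, `z` combined standard errors).
#'
#' @param profile A `sensitivity_profile` starting at position 1.
#' @param z One-sided significance threshold in combined standard errors.
#' @return Integer plateau length (>= 1).
#' @export
sensitive_plateau_length <- function(profile, z = qnorm(0.9995)) {
  stopifnot(inherits(profile, "sensitivity_profile"))
  ord <- order(profile$positions)
  pos <- profile$positions[ord]
  if (pos[1] != 1L) stop("profile must start at position 1")
  mag <- abs(profile$values[ord])
  se <- profile$se[ord]
  for (i in 2:length(pos)) {
    run <- seq_len(i - 1L)
    plateau_mean <- mean(mag[run])
    plateau_se <- sqrt(sum(se[run]^2)) / length(run)
    if ((plateau_mean - mag[i]) > z * sqrt(plateau_se^2 + se[i]^2)) {
      return(i - 1L)
    }
  }
  length(pos)
}
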