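#' Density target for initiation-rate calibration
#'
#' One gene's target mean bound-ribosome count (as measured by polysome
#' profiling) together with the relative tolerance at which calibration is
#' declared converged (default 2%).
#'
#' @param gene_id Character scalar.
#' @param target_ribosomes Positive target mean ribosome count.
#' @param rel_tolerance Relative error bound, in (0, 0.2].
#' @return An object of class `density_target`.
#' @export
density_target <- function(gene_id, target_ribosomes, rel_tolerance = 0.02) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (!is.finite(target_ribosomes) || target_ribosomes <= 0) {
    stop("target_ribosomes must be > 0")
  }
  if (!(rel_tolerance > 0 && rel_tolerance <= 0.2)) {
    stop("rel_tolerance must be in (0, 0.2]")
  }
  structure(list(gene_id = gene_id,
                 target_ribosomes = as.numeric(target_ribosomes),
                 rel_tolerance = as.numeric(rel_tolerance)),
            class = "density_target")
}

#' Calibrate a gene's initiation rate against a ribosome-density target
#'
#' Estimates the effective initiation rate \eqn{\lambda_0} of a gene by
#' tuning it until the simulated mean bound-ribosome count matches the
#' experimental target within the target's relative tolerance. The
#' objective (expected mean ribosome count as a function of
#' \eqn{\lambda_0}) is monotone but evaluated with noise, so the search is
#' a bracket expansion (doubling/halving from the initial guess
#' \eqn{\bar\lambda/10}) followed by bisection, with every evaluation
#' averaged over at least 8 replicates sharing common random streams so
#' successive evaluations are directly comparable.
#'
#' The target must be achievable: a pilot run at a saturating initiation
#' rate checks that the requested count lies below the jam-density ceiling,
#' and `target_ribosomes` may never exceed the packing bound \eqn{n/s}.
#'
#' @param rates Per-codon decoding-rate vector (or a [gene_model()], whose
#'   rates and footprint are used).
#' @param target A [density_target()].
#' @param config A [sim_config()]; `replicates` is raised to 8 if lower.
#' @param footprint Ribosome footprint, used when `rates` is a bare vector.
#' @param max_iter Iteration cap for the bracket + bisection search.
#' @return A list of class `calibration`: `lambda0`, `achieved`,
#'   `iterations`, `converged`, `target`.
#' @examples
#' \donttest{
#' g <- gene_model("toy", rates = rep(1, 100), init_rate = 0.05)
#' tgt <- density_target("toy", target_ribosomes = 2)
#' calibrate_initiation_rate(g$rates, tgt,
#'                           sim_config(seed = 1, measure_terminations = 500))
#' }
#' @export
calibrate_initiation_rate <- function(rates, target, config = sim_config(),
                                      footprint = 9L, max_iter = 60L) {
  if (inherits(rates, "gene_model")) {
    footprint <- rates$footprint
    rates <- rates$rates
  }
  stopifnot(inherits(target, "density_target"), inherits(config, "sim_config"))
  n <- length(rates)
  s <- as.integer(footprint)
  if (target$target_ribosomes > n / s) {
    stop(sprintf(
      "infeasible target: %.3g ribosomes exceeds the packing bound n/s = %.3g",
      target$target_ribosomes, n / s))
  }
  if (config$replicates < 8L) config$replicates <- 8L

  objective <- function(lambda0) {
    g <- gene_model(target$gene_id, rates, lambda0, s)
    estimate_mean_ribosomes(g, config) # same config => common random streams
  }

  # feasibility pilot: saturation density at a very large initiation rate
  sat <- objective(100 * mean(rates))
  if (target$target_ribosomes >= sat) {
    stop(sprintf(paste0("infeasible target: %.4g ribosomes is at or above the ",
                        "saturation value %.4g for this gene"),
         target$target_ribosomes, sat))
  }

  lam <- mean(rates) / 10
  m <- objective(lam)
  iter <- 1L
  tol_ok <- function(m) abs(m - target$target_ribosomes) /
    target$target_ribosomes <= target$rel_tolerance

  if (tol_ok(m)) {
    return(structure(list(lambda0 = lam, achieved = m, iterations = iter,
                          converged = TRUE, target = target),
                     class = "calibration"))
  }

  # bracket the target by doubling or halving
  if (m < target$target_ribosomes) {
    lo <- lam; m_lo <- m
    hi <- lam
    repeat {
      hi <- hi * 2
      m_hi <- objective(hi); iter <- iter + 1L
      if (tol_ok(m_hi)) {
        return(structure(list(lambda0 = hi, achieved = m_hi, iterations = iter,
                              converged = TRUE, target = target),
                         class = "calibration"))
      }
      if (m_hi >= target$target_ribosomes) break
      lo <- hi; m_lo <- m_hi
      if (iter >= max_iter) {
        stop(sprintf(paste0("calibration failed to bracket the target in %d ",
                            "iterations; best lambda0 %.4g gave %.4g ",
                            "(target %.4g)"), iter, hi, m_hi,
                     target$target_ribosomes))
      }
    }
  } else {
    hi <- lam; m_hi <- m
    lo <- lam
    repeat {
      lo <- lo / 2
      m_lo <- objective(lo); iter <- iter + 1L
      if (tol_ok(m_lo)) {
        return(structure(list(lambda0 = lo, achieved = m_lo, iterations = iter,
                              converged = TRUE, target = target),
                         class = "calibration"))
      }
      if (m_lo <= target$target_ribosomes) break
      hi <- lo; m_hi <- m_lo
      if (iter >= max_iter) {
        stop(sprintf(paste0("calibration failed to bracket the target in %d ",
                            "iterations; best lambda0 %.4g gave %.4g ",
                            "(target %.4g)"), iter, lo, m_lo,
                     target$target_ribosomes))
      }
    }
  }

  # bisection on the replicate-averaged objective
  best <- list(lambda0 = lo, achieved = m_lo)
  while (iter < max_iter) {
    mid <- sqrt(lo * hi) # geometric: lambda0 spans orders of magnitude
    m_mid <- objective(mid); iter <- iter + 1L
    if (abs(m_mid - target$target_ribosomes) <
        abs(best$achieved - target$target_ribosomes)) {
      best <- list(lambda0 = mid, achieved = m_mid)
    }
    if (tol_ok(m_mid)) {
      return(structure(list(lambda0 = mid, achieved = m_mid, iterations = iter,
                            converged = TRUE, target = target),
                       class = "calibration"))
    }
    if (m_mid < target$target_ribosomes) lo <- mid else hi <- mid
  }
  stop(sprintf(paste0("calibration did not converge within %d iterations; ",
                      "best lambda0 %.4g achieved %.4g (target %.4g, ",
                      "tolerance %.3g)"), max_iter, best$lambda0,
               best$achieved, target$target_ribosomes, target$rel_tolerance))
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf(paste0("<calibration '%s'> lambda0 = %.5g /s, achieved %.4g ",
                     "ribosomes (target %.4g, rel. err %.2g%%), %d iterations\n"),
              x$target$gene_id, x$lambda0, x$achieved,
              x$target$target_ribosomes,
              100 * abs(x$achieved - x$target$target_ribosomes) /
                x$target$target_ribosomes, x$iterations))
  invisible(x)
}

#' Calibrate a cohort of genes from a density-target table
#'
#' Vectorized driver over [calibrate_initiation_rate()]: genes that fail
#' (infeasible target or non-convergence) are recorded with `converged =
#' FALSE` and the error message, and the run continues.
#'
#' @param genes Named list of [gene_model()]s (initiation rates ignored).
#' @param targets Data frame with columns `gene_id`, `target_ribosomes`
#'   (e.g. from [read_density_targets()]).
#' @param config A [sim_config()].
#' @param rel_tolerance Relative tolerance passed to [density_target()].
#' @return Data frame: `gene_id`, `lambda0`, `achieved`, `iterations`,
#'   `converged`, `message`.
#' @export
calibrate_cohort <- function(genes, targets, config = sim_config(),
                             rel_tolerance = 0.02) {
  stopifnot(all(c("gene_id", "target_ribosomes") %in% names(targets)))
  rows <- lapply(seq_len(nrow(targets)), function(r) {
    gid <- targets$gene_id[r]
    g <- genes[[gid]]
    if (is.null(g)) {
      return(data.frame(gene_id = gid, lambda0 = NA_real_,
                        achieved = NA_real_, iterations = 0L,
                        converged = FALSE, message = "gene not found"))
    }
    tgt <- density_target(gid, targets$target_ribosomes[r], rel_tolerance)
    res <- tryCatch(calibrate_initiation_rate(g, tgt, config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      data.frame(gene_id = gid, lambda0 = NA_real_, achieved = NA_real_,
                 iterations = 0L, converged = FALSE,
                 message = conditionMessage(res))
    } else {
      data.frame(gene_id = gid, lambda0 = res$lambda0, achieved = res$achieved,
                 iterations = res$iterations, converged = res$converged,
                 message = "")
    }
  })
  do.call(rbind, rows)
}
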