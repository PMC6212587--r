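#' Construct a gene model for translation simulation
#'
#' A gene model bundles everything the simulator needs for one mRNA: the
#' per-codon decoding-rate vector \eqn{\lambda_1, \ldots, \lambda_n}
#' (codons/second), the effective initiation rate \eqn{\lambda_0}
#' (events/second), the ribosome footprint \eqn{s} in codons, and optionally
#' the codon sequence itself (needed for codon-type perturbations and
#' codon-order permutation).
#'
#' The stop codon is not part of the lattice: `rates` (and `codons`, if
#' given) cover the \eqn{n} sense codons only, with the start codon at
#' position 1.
#'
#' @param gene_id Character scalar identifier.
#' @param rates Numeric vector of positive per-codon decoding rates, length
#'   \eqn{n \ge s}.
#' @param init_rate Positive initiation rate \eqn{\lambda_0}.
#' @param footprint Ribosome size \eqn{s} in codons (default 9).
#' @param codons Optional character vector of codon triplets (DNA alphabet,
#'   length \eqn{n}, sense codons only).
#' @return An object of class `gene_model`.
#' @examples
#' g <- gene_model("toy", rates = rep(1, 100), init_rate = 0.05)
#' g
#' @export
gene_model <- function(gene_id, rates, init_rate, footprint = 9L,
                       codons = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  rates <- as.numeric(rates)
  n <- length(rates)
  footprint <- as.integer(footprint)
  if (footprint < 1L) stop("footprint must be >= 1")
  if (n < footprint) {
    stop(sprintf("gene '%s' has %d codons, shorter than the footprint (%d)",
                 gene_id, n, footprint))
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    stop("all decoding rates must be finite and > 0")
  }
  if (!is.finite(init_rate) || init_rate <= 0) {
    stop("init_rate must be finite and > 0")
  }
  if (!is.null(codons)) {
    codons <- toupper(as.character(codons))
    if (length(codons) != n) stop("codons must have one entry per rate")
    bad <- setdiff(unique(codons), sense_codons())
    if (length(bad)) {
      stop("codons contains non-sense codons: ", paste(bad, collapse = ", "))
    }
  }
  structure(
    list(gene_id = gene_id, rates = rates, init_rate = as.numeric(init_rate),
         footprint = footprint, codons = codons),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model '%s'>  n = %d codons, s = %d\n",
              x$gene_id, length(x$rates), x$footprint))
  cat(sprintf("  lambda0 = %.4g /s, mean decoding rate = %.4g codons/s, xi = %.4g\n",
              x$init_rate, mean(x$rates), xi(x)))
  if (!is.null(x$codons)) {
    cat(sprintf("  sequence: %s ... %s\n",
                paste(x$codons[seq_len(min(3, length(x$codons)))], collapse = " "),
                x$codons[length(x$codons)]))
  }
  invisible(x)
}

#' @export
length.gene_model <- function(x) length(x$rates)

#' Initiation-to-elongation rate ratio
#'
#' \eqn{\xi = \lambda_0 / \langle\lambda_i\rangle}: the gene's initiation
#' rate divided by the arithmetic mean of its decoding rates. This
#' dimensionless ratio determines which sensitivity regime the gene occupies
#' (see [classify_regime()]). For a uniform gene with unit decoding rates,
#' \eqn{\xi = \lambda_0}.
#'
#' @param gene A [gene_model()].
#' @return Numeric scalar.
#' @export
xi <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  gene$init_rate / mean(gene$rates)
}

#' Bottleneck factor of a gene
#'
#' The ratio between the initiation rate and the minimum effective
#' elongation rate over all windows of \eqn{s} consecutive codons. The
#' effective rate of a window is its traversal rate
#' \eqn{s / \sum_{j \in w} 1/\lambda_j} (the harmonic-mean form: the number
#' of codons divided by the expected time to decode them all). A value near
#' or above 1 means some stretch of codons is as limiting as initiation
#' itself. `method = "min"` instead uses the slowest single rate in each
#' window, an alternative reading of "effective elongation rate".
#'
#' @param gene A [gene_model()].
#' @param method `"harmonic"` (default) or `"min"`.
#' @return Numeric scalar.
#' @examples
#' g <- gene_model("toy", rates = rep(1, 50), init_rate = 0.1)
#' bottleneck_factor(g) # 0.1: uniform gene, window rate 1
#' @export
bottleneck_factor <- function(gene, method = c("harmonic", "min")) {
  stopifnot(inherits(gene, "gene_model"))
  method <- match.arg(method)
  s <- gene$footprint
  n <- length(gene$rates)
  if (method == "harmonic") {
    inv <- 1 / gene$rates
    csum <- c(0, cumsum(inv))
    win_time <- csum[(s + 1):(n + 1)] - csum[1:(n - s + 1)]
    win_rate <- s / win_time
  } else {
    win_rate <- vapply(seq_len(n - s + 1),
                       function(i) min(gene$rates[i:(i + s - 1)]), 0)
  }
  gene$init_rate / min(win_rate)
}
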