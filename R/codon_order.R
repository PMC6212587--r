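#' Codon-order permutation variants of a gene
#'
#' Generates randomized variants of a gene in which the codons at positions
#' \eqn{2..n} are uniformly permuted (the start codon stays fixed). Each
#' variant has exactly the original codon multiset — hence the same
#' protein composition in the amino-acid-multiset sense, the same codon
#' usage, the same length, the same mean decoding rate and the same
#' \eqn{\xi} — but all location-specific structure (e.g. slow codons near
#' the 5' end) is erased. Rate vectors are re-derived from the decoding
#' rate table so sequence and rates stay consistent.
#'
#' `mode = "synonymous"` restricts the shuffle to positions encoding the
#' same amino acid, preserving the protein sequence exactly while still
#' relocating synonymous codon choices.
#'
#' @param gene A [gene_model()] carrying its codon sequence.
#' @param tdr_table Named numeric vector codon -> decoding rate.
#' @param n_variants Number of variants (default 10).
#' @param seed Integer seed (variants are reproducible given the seed).
#' @param mode `"full"` (permute all of 2..n) or `"synonymous"`.
#' @return An object of class `variant_set`: list with `gene_id`, `seed`,
#'   `mode` and `variants`, a list of `gene_model`s named `v1..vK`.
#' @export
permute_codons <- function(gene, tdr_table, n_variants = 10L, seed = 1L,
                           mode = c("full", "synonymous")) {
  stopifnot(inherits(gene, "gene_model"))
  mode <- match.arg(mode)
  if (is.null(gene$codons)) stop("gene carries no codon sequence")
  miss <- setdiff(unique(gene$codons), names(tdr_table))
  if (length(miss)) stop("tdr_table lacks codons: ", paste(miss, collapse = ","))
  n <- length(gene$codons)
  variants <- with_seed(seed, lapply(seq_len(n_variants), function(k) {
    codons <- gene$codons
    if (mode == "full") {
      idx <- 2:n
      codons[idx] <- codons[idx][sample.int(length(idx))]
    } else {
      aa <- codon_to_aa(codons)
      for (a in unique(aa[-1])) {
        idx <- setdiff(which(aa == a), 1L)
        if (length(idx) > 1L) codons[idx] <- codons[idx][sample.int(length(idx))]
      }
    }
    gene_model(sprintf("%s_v%d", gene$gene_id, k),
               unname(tdr_table[codons]), gene$init_rate, gene$footprint,
               codons)
  }))
  structure(list(gene_id = gene$gene_id, seed = as.integer(seed), mode = mode,
                 variants = setNames(variants,
                                     paste0("v", seq_len(n_variants)))),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set '%s'> %d %s-permutation variants (seed %d)\n",
              x$gene_id, length(x$variants), x$mode, x$seed))
  invisible(x)
}

#' Region-averaged original sensitivity O_g
#'
#' Mean of the original gene's sensitivity profile over codons `a..b`
#' (inclusive count \eqn{b - a + 1}; at `a == b` this is the
#' single-position value).
#'
#' @param profile The original gene's `sensitivity_profile`.
#' @param a,b Region bounds, \eqn{a \le b}.
#' @return Numeric scalar.
#' @export
region_mean_original <- function(profile, a, b) {
  stopifnot(inherits(profile, "sensitivity_profile"), a <= b)
  idx <- match(a:b, profile$positions)
  if (anyNA(idx)) stop("profile does not cover positions ", a, "..", b)
  mean(profile$values[idx])
}

#' Region-averaged variant sensitivity M_g
#'
#' Averages the sensitivity profiles of a gene's permutation variants into
#' a single profile and then averages it over codons `a..b`.
#'
#' @param profiles List of `sensitivity_profile`s, one per variant.
#' @param a,b Region bounds, \eqn{a \le b}.
#' @return Numeric scalar.
#' @export
region_mean_variants <- function(profiles, a, b) {
  mean(vapply(profiles, region_mean_original, 0, a = a, b = b))
}

#' Bonferroni threshold on the -log10 p-value scale
#'
#' The family of region tests covers all \eqn{1 \le a \le b \le}
#' `max_codon`, i.e. \eqn{T = \mathrm{max\_codon}(\mathrm{max\_codon}+1)/2}
#' cells; a family-wise cutoff of `cutoff` therefore requires a per-cell
#' p-value below `cutoff / T`, i.e. \eqn{\Pi \ge -\log_{10}(cutoff/T)}.
#'
#' @param max_codon Largest region bound (default 200, giving T = 20100).
#' @param cutoff Family-wise error cutoff (default 0.01).
#' @param n_tests Override the test count T if the family differs.
#' @return Numeric threshold on the \eqn{\Pi} scale.
#' @examples
#' bonferroni_pi_threshold() # ~6.303
#' @export
bonferroni_pi_threshold <- function(max_codon = 200L, cutoff = 0.01,
                                    n_tests = NULL) {
  if (is.null(n_tests)) n_tests <- max_codon * (max_codon + 1) / 2
  -log10(cutoff / n_tests)
}

#' Codon-order significance matrix
#'
#' For every region \eqn{a \le b \le} `max_codon`, tests whether the set
#' \eqn{\Delta = \{O_g - M_g\}} of per-gene differences between
#' original and variant-averaged region sensitivities has mean zero
#' (one-sample two-sided t-test), and records
#' \eqn{\Pi_{a,b} = -\log_{10} p} along with the direction of the effect
#' (+1: originals more sensitive in signed value, -1: variants). Cells
#' with fewer than 3 finite differences are left undefined (`NA`).
#'
#' The per-cell means/variances are computed vectorially from cumulative
#' sums over positions; a spot check against [stats::t.test()] is part of
#' the package's test suite.
#'
#' @param original Numeric matrix, genes x positions: each gene's original
#'   sensitivity profile over positions `1..max_codon` (or more).
#' @param variant_mean Numeric matrix, genes x positions: the across-variant
#'   mean profile of each gene, same shape.
#' @param max_codon Largest region bound (default 200, capped at the
#'   matrix width).
#' @param cutoff Family-wise Bonferroni cutoff (default 0.01).
#' @return An object of class `pi_matrix`: long data frame `cells` with
#'   columns `a`, `b`, `pi`, `direction`, `n`, `significant`, plus
#'   `threshold` and `max_codon`.
#' @export
pi_matrix <- function(original, variant_mean, max_codon = 200L,
                      cutoff = 0.01) {
  stopifnot(is.matrix(original), is.matrix(variant_mean),
            all(dim(original) == dim(variant_mean)))
  max_codon <- min(as.integer(max_codon), ncol(original))
  delta <- original[, seq_len(max_codon), drop = FALSE] -
    variant_mean[, seq_len(max_codon), drop = FALSE]
  G <- nrow(delta)
  # cumulative sums across positions -> region means for all (a, b) cells
  U <- upper.tri(diag(max_codon), diag = TRUE) * 1
  cs <- cbind(0, delta %*% U)
  ab <- which(upper.tri(diag(max_codon), diag = TRUE), arr.ind = TRUE)
  a <- ab[, "row"]; b <- ab[, "col"]
  width <- b - a + 1
  # per-gene region means: G x cells
  rm_mat <- (cs[, b + 1, drop = FALSE] - cs[, a, drop = FALSE]) /
    rep(width, each = G)
  n_ok <- colSums(is.finite(rm_mat))
  mu <- colMeans(rm_mat)
  s2 <- colSums(sweep(rm_mat, 2L, mu)^2) / (n_ok - 1)
  tstat <- mu / sqrt(s2 / n_ok)
  pval <- 2 * pt(-abs(tstat), df = n_ok - 1)
  pi_val <- -log10(pval)
  undef <- n_ok < 3L | !is.finite(tstat)
  pi_val[undef] <- NA_real_
  threshold <- bonferroni_pi_threshold(max_codon, cutoff)
  cells <- data.frame(a = a, b = b, pi = pi_val,
                      direction = sign(mu), n = n_ok,
                      significant = !is.na(pi_val) & pi_val >= threshold)
  structure(list(cells = cells, threshold = threshold,
                 max_codon = max_codon, cutoff = cutoff),
            class = "pi_matrix")
}

#' @export
print.pi_matrix <- function(x, ...) {
  nsig <- sum(x$cells$significant, na.rm = TRUE)
  cat(sprintf(paste0("<pi_matrix> %d cells (a <= b <= %d), Bonferroni ",
                     "threshold Pi >= %.3f (cutoff %.3g)\n"),
              nrow(x$cells), x$max_codon, x$threshold, x$cutoff))
  cat(sprintf("  %d significant cell(s)\n", nsig))
  invisible(x)
}

#' @export
as.matrix.pi_matrix <- function(x, ...) {
  m <- matrix(NA_real_, x$max_codon, x$max_codon)
  m[cbind(x$cells$a, x$cells$b)] <- x$cells$pi
  m
}
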