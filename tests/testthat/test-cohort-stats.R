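test_that("regime classification uses the documented boundaries and ties", {
  expect_identical(classify_regime(c(0.05, 0.1, 0.3, 0.5, 2)),
                   c(1L, 1L, 2L, 3L, 3L))
  expect_identical(classify_regime(0.2, boundaries = c(0.25, 0.6)), 1L)
  expect_error(classify_regime(-1), "xi > 0")
})

test_that("spearman correlation handles perfect ranks and degenerate input", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_corr(x, x)$rho, 1)
  expect_equal(spearman_corr(x, -x)$rho, -1)
  flat <- spearman_corr(x, rep(2, 6))
  expect_true(is.nan(flat$rho))
  expect_false(flat$defined)
})

test_that("log-linear fit recovers an exact synthetic line in range", {
  xi <- c(0.01, 0.02, 0.05, 0.08, 0.1, 0.2, 0.5)
  sens <- -3.4 * log10(xi) - 7.5
  fit <- loglinear_fit(xi, sens, xi_range = c(0.01, 0.1))
  expect_equal(fit$slope, -3.4, tolerance = 1e-10)
  expect_equal(fit$intercept, -7.5, tolerance = 1e-10)
  expect_equal(fit$n, 5L)
  expect_error(loglinear_fit(xi[1:2], sens[1:2]), "fewer than 3")
})

test_that("length-binned abundance correlations use equal-count bins", {
  set.seed(9)
  ng <- 200
  len <- round(exp(rnorm(ng, log(400), 0.5)))
  sens <- -0.03 + 0.002 * scale(log(len))[, 1] + rnorm(ng, 0, 0.001)
  pa <- exp(3 + 2 * sens / 0.03 + rnorm(ng, 0, 0.2)) # PA tracks sensitivity
  rec <- data.frame(length_codons = len, protein_abundance = pa,
                    start_sensitivity = sens)
  tab <- length_binned_pa_correlation(rec, n_bins = 10)
  expect_equal(nrow(tab), 10L)
  expect_equal(sum(tab$n), ng)
  expect_true(all(tab$n == 20))
  expect_true(all(tab$rho > 0)) # built-in positive association per bin
  expect_true(all(tab$signif_level %in% 0:3))
})

test_that("magnitude sweep is monotone in p and interpolates linearly", {
  g <- uniform_gene(100, lambda0 = 0.1)
  cfg <- fast_cfg(seed = 41, replicates = 8, terms = 800)
  sw <- magnitude_sweep(g, p_values = c(-0.5, -0.3, -0.1), config = cfg)
  expect_equal(sw$p, c(-0.5, -0.3, -0.1))
  expect_true(all(diff(sw$mean_sensitivity) > 0)) # less negative as p rises
  # interpolated -30% from the endpoints agrees with the measured -30%
  interp <- interpolate_sweep(sw[c(1, 3), ], -0.3)
  prof_se <- 0.004 # conservative per-point noise bound at this depth
  expect_lt(abs(interp - sw$mean_sensitivity[2]), 4 * prof_se)
  expect_error(interpolate_sweep(sw, -0.9), "within the measured")
})

test_that("gamma groups reproduce the worked CGA example", {
  mk <- function(id, pos_cga, n = 40) {
    codons <- c("ATG", rep("AAA", n - 1))
    codons[pos_cga] <- "CGA"
    gene_model(id, rep(1, n), 0.1, codons = codons)
  }
  genes <- list(a = mk("a", 5),        # CGA within 2..9  -> group 1
                b = mk("b", 12),       # only at 12       -> groups 2 and 1c
                c = mk("c", 22),       # only at 19..27   -> groups 3 and 1c
                d = mk("d", integer(0)), # no CGA         -> no group
                e = mk("e", c(3, 12))) # start region wins -> group 1 only
  gg <- build_gamma_groups(genes, "CGA")
  expect_setequal(gg$gamma1, c("a", "e"))
  expect_setequal(gg$gamma2, "b")
  expect_setequal(gg$gamma3, "c")
  expect_setequal(gg$gamma1c, c("b", "c"))
})

test_that("gamma groups are disjoint and partition carriers", {
  genes <- toy_cohort(n_genes = 30, seed = 7)
  for (codon in c("CGA", "GGG", "TTT")) {
    gg <- build_gamma_groups(genes, codon)
    expect_length(intersect(gg$gamma1, gg$gamma2), 0)
    expect_length(intersect(gg$gamma2, gg$gamma3), 0)
    expect_length(intersect(gg$gamma1, gg$gamma1c), 0)
    carriers <- names(Filter(function(g)
      any(g$codons[-1] == codon), genes))
    expect_setequal(union(gg$gamma1, gg$gamma1c), carriers)
  }
})

test_that("group sensitivity table pairs strata with codon rates", {
  genes <- toy_cohort(n_genes = 12, seed = 11)
  tdr <- make_tdr_table(123)
  sens <- list(CGA = setNames(runif(12, -0.05, 0), names(genes)))
  tab <- group_sensitivity_vs_rate(genes, tdr, sens)
  expect_equal(nrow(tab), 4L)
  expect_equal(unique(tab$rate), unname(tdr["CGA"]))
  g1 <- build_gamma_groups(genes, "CGA")$gamma1
  expect_equal(tab$mean_sensitivity[tab$group == "gamma1"],
               mean(sens$CGA[g1]))
})
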