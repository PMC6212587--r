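test_that("permutation variants preserve composition, usage, and xi", {
  tdr <- make_tdr_table(19) # the table the cohort's rates come from
  genes <- toy_cohort(n_genes = 3, seed = 19)
  g <- genes[[1]]
  vs <- permute_codons(g, tdr, n_variants = 10, seed = 2)
  expect_length(vs$variants, 10L)
  for (v in vs$variants) {
    expect_identical(v$codons[1], "ATG")
    expect_identical(sort(v$codons[-1]), sort(g$codons[-1]))
    expect_equal(mean(v$rates), mean(g$rates))
    expect_equal(xi(v), xi(g))
    expect_equal(v$rates, unname(tdr[v$codons])) # rates re-derived
  }
  # reproducible given seed, different otherwise
  vs2 <- permute_codons(g, tdr, n_variants = 10, seed = 2)
  expect_identical(lapply(vs$variants, `[[`, "codons"),
                   lapply(vs2$variants, `[[`, "codons"))
  vs3 <- permute_codons(g, tdr, n_variants = 10, seed = 3)
  expect_false(identical(vs$variants$v1$codons, vs3$variants$v1$codons))
})

test_that("degenerate and synonymous permutation modes behave", {
  tdr <- make_tdr_table(5)
  mono <- gene_model("mono", rep(unname(tdr["AAA"]), 20), 0.1,
                     codons = c("ATG", rep("AAA", 19)))
  vs <- permute_codons(mono, tdr, n_variants = 3, seed = 1)
  for (v in vs$variants) expect_identical(v$codons, mono$codons)

  g <- toy_cohort(n_genes = 1, seed = 23)[[1]]
  syn <- permute_codons(g, tdr, n_variants = 5, seed = 4,
                        mode = "synonymous")
  aa0 <- ribopert:::codon_to_aa(g$codons)
  for (v in syn$variants) {
    expect_identical(ribopert:::codon_to_aa(v$codons), aa0) # protein intact
    expect_identical(sort(v$codons), sort(g$codons))
  }
  expect_error(permute_codons(uniform_gene(30), tdr), "no codon sequence")
})

test_that("region means use inclusive counts and average variants", {
  g <- uniform_gene(30, lambda0 = 0.1)
  prof <- ribopert:::new_sensitivity_profile(
    g, -0.5, 1, 1:30, values = seq(-0.30, -0.01, by = 0.01),
    se = rep(0.001, 30), ci = rep(0.002, 30))
  expect_equal(region_mean_original(prof, 1, 10), mean(prof$values[1:10]))
  expect_equal(region_mean_original(prof, 7, 7), prof$values[7])
  prof2 <- prof
  prof2$values <- prof$values + 0.02
  expect_equal(region_mean_variants(list(prof, prof2), 1, 10),
               mean(prof$values[1:10]) + 0.01)
  expect_error(region_mean_original(prof, 25, 35), "does not cover")
})

test_that("Bonferroni threshold counts the triangular test family", {
  expect_equal(bonferroni_pi_threshold(200, 0.01), -log10(0.01 / 20100))
  expect_equal(bonferroni_pi_threshold(200, 0.01), 6.303, tolerance = 1e-3)
  expect_equal(bonferroni_pi_threshold(1, 0.01), 2)
  expect_equal(bonferroni_pi_threshold(cutoff = 0.01, n_tests = 25000),
               -log10(0.01 / 25000))
})

test_that("pi matrix flags a planted shift and matches t.test cell-wise", {
  set.seed(31)
  G <- 100; m <- 12
  vmean <- matrix(rnorm(G * m, 0, 0.1), G, m)
  orig <- vmean + 1 # Delta ~ N(1, 0) planted effect
  orig <- orig + matrix(rnorm(G * m, 0, 0.1), G, m)
  pm <- pi_matrix(orig, vmean, max_codon = m)
  expect_s3_class(pm, "pi_matrix")
  expect_equal(nrow(pm$cells), m * (m + 1) / 2)
  expect_true(all(pm$cells$significant))
  expect_true(all(pm$cells$direction == 1))
  expect_true(all(pm$cells$pi > 50)) # t ~ 100 on n=100 genes

  # spot-check one cell against stats::t.test
  a <- 3; b <- 7
  delta_cell <- rowMeans(orig[, a:b] - vmean[, a:b])
  tt <- t.test(delta_cell)
  cell <- pm$cells[pm$cells$a == a & pm$cells$b == b, ]
  expect_equal(cell$pi, -log10(tt$p.value), tolerance = 1e-8)

  # near-null data: p near 1, nothing significant
  null_pm <- pi_matrix(vmean, vmean + matrix(rnorm(G * m, 0, 1e-6), G, m),
                       max_codon = m)
  expect_false(any(null_pm$cells$significant))

  # fewer than 3 genes -> undefined cells
  tiny <- pi_matrix(orig[1:2, ], vmean[1:2, ], max_codon = m)
  expect_true(all(is.na(tiny$cells$pi)))
})

test_that("family-wise error of the thresholded matrix is controlled", {
  # originals and "variants" drawn from the same ensemble: with a 1%
  # Bonferroni cutoff, cohorts showing any significant cell must be rare
  set.seed(77)
  flagged <- 0L
  for (cohort in 1:20) {
    G <- 15; m <- 15
    orig <- matrix(rnorm(G * m, -0.02, 0.01), G, m)
    vmean <- matrix(rnorm(G * m, -0.02, 0.01 / sqrt(10)), G, m)
    pm <- pi_matrix(orig, vmean, max_codon = m)
    flagged <- flagged + any(pm$cells$significant)
  }
  expect_lte(flagged, 1L)
})

test_that("relocating slow codons away from the start is detected", {
  # cohort with deliberately slow codons at positions 10..40; at high
  # initiation (alpha = 10) originals are more sensitive there than
  # codon-order variants, so negative-direction cells must reach the
  # Bonferroni threshold within the probed window
  codons <- ribopert:::sense_codons()
  slow <- setdiff(codons[1:10], "ATG")
  fast <- setdiff(codons, c(slow, "ATG"))
  tdr <- setNames(rep(6, 61), codons)
  tdr[slow] <- 1.5
  ng <- 8; mc <- 20; len <- 150
  cfg <- fast_cfg(seed = 23, replicates = 8, terms = 1000)
  orig <- matrix(NA_real_, ng, mc)
  vmean <- matrix(NA_real_, ng, mc)
  set.seed(77)
  for (gi in seq_len(ng)) {
    body <- sample(fast, len - 1, replace = TRUE)
    body[9:39] <- sample(slow, 31, replace = TRUE) # codons 10..40 slow
    cods <- c("ATG", body)
    g <- gene_model(sprintf("g%d", gi), unname(tdr[cods]),
                    0.05 * mean(tdr[cods]), codons = cods)
    orig[gi, ] <- sensitivity_profile(g, -0.5, alpha = 10, positions = 1:mc,
                                      config = cfg)$values
    vs <- permute_codons(g, tdr, n_variants = 4, seed = 1000 + gi)
    vp <- vapply(vs$variants, function(v)
      sensitivity_profile(v, -0.5, alpha = 10, positions = 1:mc,
                          config = cfg)$values, numeric(mc))
    vmean[gi, ] <- rowMeans(vp)
  }
  pm <- pi_matrix(orig, vmean, max_codon = mc)
  sig <- pm$cells[pm$cells$significant, ]
  expect_gt(nrow(sig), 0)
  expect_true(all(sig$direction == -1)) # originals more (negatively) sensitive
  expect_true(any(sig$b >= 10)) # significant cells overlap the slow region
})
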