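test_that("perturbations rescale exactly the targeted rates", {
  g <- uniform_gene(50, lambda0 = 0.1)
  p3 <- apply_perturbation(g, perturbation("single_codon", -0.5, position = 3))
  expect_equal(p3$rates[3], 0.5)
  expect_equal(p3$rates[-3], rep(1, 49))
  expect_equal(p3$init_rate, 0.1)
  expect_equal(g$rates[3], 1) # input untouched

  # identity
  id <- apply_perturbation(g, perturbation("single_codon", 0, position = 1))
  expect_equal(id$rates, g$rates)
  expect_equal(id$init_rate, g$init_rate)

  # prolonged block
  blk <- apply_perturbation(g, perturbation("prolonged", 1, position = 10,
                                            block_length = 4))
  expect_equal(which(blk$rates == 2), 10:13)

  expect_error(apply_perturbation(
    g, perturbation("prolonged", -0.5, position = 49, block_length = 5)),
    "exceeds gene length")
})

test_that("percent strings parse and invalid magnitudes are rejected", {
  expect_equal(perturbation("single_codon", "-50%", position = 1)$p, -0.5)
  expect_equal(perturbation("single_codon", "+100%", position = 1)$p, 1)
  expect_error(perturbation("single_codon", -1, position = 1), "p must be")
  expect_error(perturbation("single_codon", -0.5, position = 0), "position")
  expect_error(perturbation("global_codon", -0.5, codon_type = "TAA"),
               "unknown sense codon")
})

test_that("global codon perturbation hits every occurrence except the start", {
  codons <- c("ATG", "CTG", "AAA", "CTG", "AAA", "CTG", rep("AAA", 24))
  g <- gene_model("g", rep(1, 30), 0.2, codons = codons)
  gp <- apply_perturbation(g, perturbation("global_codon", -0.5,
                                           codon_type = "CTG", alpha = 5))
  expect_equal(gp$init_rate, 1.0) # 5 * 0.2
  expect_equal(which(gp$rates == 0.5), c(2L, 4L, 6L))
  expect_equal(attr(gp, "n_targeted"), 3L)
  # internal ATG occurrences would be eligible, position 1 never is
  g2 <- gene_model("g2", rep(1, 30), 0.2,
                   codons = c("ATG", "ATG", rep("AAA", 28)))
  gp2 <- apply_perturbation(g2, perturbation("global_codon", -0.5,
                                             codon_type = "ATG"))
  expect_equal(which(gp2$rates == 0.5), 2L)
  expect_error(apply_perturbation(
    uniform_gene(30), perturbation("global_codon", -0.5, codon_type = "CTG")),
    "codon sequence")
})

test_that("a null perturbation has exactly zero sensitivity under CRN", {
  g <- uniform_gene(80, lambda0 = 0.1)
  s0 <- sensitivity(g, perturbation("single_codon", 0, position = 5),
                    fast_cfg(seed = 3, replicates = 4))
  expect_identical(unname(s0["value"]), 0) # identical paired trajectories
})

test_that("codon absent from the gene yields zero sensitivity with a flag", {
  g <- gene_model("g", rep(1, 30), 0.1, codons = c("ATG", rep("AAA", 29)))
  s <- global_codon_sensitivity(g, "CTG", -0.5, config = fast_cfg(seed = 1))
  expect_identical(unname(s["value"]), 0)
  expect_false(attr(s, "applied"))
})

test_that("start-region sensitivity in regime 1 is negative and localized", {
  g <- uniform_gene(200, lambda0 = 0.1)
  cfg <- fast_cfg(seed = 17, replicates = 10, terms = 1000)
  near <- sensitivity(g, perturbation("single_codon", -0.5, position = 1), cfg)
  far <- sensitivity(g, perturbation("single_codon", -0.5, position = 50), cfg)
  expect_lt(near["value"] + 2 * near["se"], 0)
  expect_gt(abs(near["value"]), abs(far["value"]))
})

test_that("profiles share baselines, and summaries use raw values", {
  g <- uniform_gene(100, lambda0 = 0.1)
  sp <- sensitivity_profile(g, "-50%", positions = 1:12,
                            config = fast_cfg(seed = 21, replicates = 6))
  expect_s3_class(sp, "sensitivity_profile")
  expect_length(sp$values, 12L)
  expect_true(all(is.finite(sp$values)))
  df <- as.data.frame(sp)
  expect_equal(df$position, 1:12)
  expect_equal(start_region_sensitivity(sp), mean(sp$values[1:9]))
  expect_equal(overall_sensitivity(sp), mean(sp$values))
  expect_error(start_region_sensitivity(
    sensitivity_profile(g, -0.5, positions = 3:12,
                        config = fast_cfg(seed = 1, replicates = 2,
                                          terms = 100))),
    "does not cover")

  sm <- smooth_profile(sp, window = 5)
  expect_equal(sm$values[6], mean(sp$values[4:8])) # centred moving average
  expect_equal(sm$values[1], mean(sp$values[1:3])) # shrunk at the edge
  expect_identical(sp$values, as.data.frame(sp)$sensitivity) # raw untouched
})

test_that("prolonged profiles index by block start and grow with length", {
  g <- uniform_gene(100, lambda0 = 0.05)
  cfg <- fast_cfg(seed = 29, replicates = 8, terms = 800)
  p1 <- prolonged_profile(g, 1, -0.5, positions = 1, config = cfg)
  p2 <- prolonged_profile(g, 2, -0.5, positions = 1, config = cfg)
  p5 <- prolonged_profile(g, 5, -0.5, positions = 1, config = cfg)
  mags <- abs(c(p1$values, p2$values, p5$values))
  expect_identical(order(mags), 1:3) # |sensitivity| nondecreasing in L_p
  expect_equal(p5$block_length, 5L)
  expect_error(prolonged_profile(g, 5, -0.5, positions = 98, config = cfg),
               "positions")
})
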