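# Composite-diplotype mapping, haplotype frequency estimation and the
# phase-ambiguity mixture.

test_that("unambiguous genotypes map to a unique composite diplotype", {
  # risk [11]: homozygous major-major carries two copies, 22/22 none
  expect_equal(map_to_composite(c(0, 0), "[11]")$status, "HH")
  expect_equal(map_to_composite(c(2, 2), "[11]")$status, "HbarHbar")
  # one copy of [11] in 11/12 ([11][12]) and in 12/11 ([11][21])
  expect_equal(map_to_composite(c(0, 1), "[11]")$status, "HHbar")
  expect_equal(map_to_composite(c(1, 0), "[11]")$status, "HHbar")
  # 11/22 is [12][12]: no copy of [11], two copies of [12]
  expect_equal(map_to_composite(c(0, 2), "[11]")$status, "HbarHbar")
  expect_equal(map_to_composite(c(0, 2), "[12]")$status, "HH")
  # every non-(1,1) genotype is unambiguous for every risk choice
  for (risk in 1:4) {
    for (g1 in 0:2) for (g2 in 0:2) {
      if (g1 == 1 && g2 == 1) next
      cd <- map_to_composite(c(g1, g2), risk)
      expect_false(cd$ambiguous)
      expect_length(cd$copies, 1)
    }
  }
})

test_that("the double heterozygote splits into the stated two-component mixture", {
  # symmetric frequencies force a 50/50 split
  cd <- map_to_composite(c(1, 1), "[11]", rep(0.25, 4))
  expect_true(cd$ambiguous)
  expect_equal(sort(cd$weights), c(0.5, 0.5))
  expect_setequal(cd$status, c("HHbar", "HbarHbar"))
  # general frequencies: H-bearing configuration [11][22] has weight phi
  f <- c(0.44, 0.26, 0.16, 0.14)
  phi <- 0.44 * 0.14 / (0.44 * 0.14 + 0.26 * 0.16)
  cd <- map_to_composite(c(1, 1), "[11]", f)
  expect_equal(cd$weights[cd$status == "HHbar"], phi, tolerance = 1e-12)
  # heterozygous risk [12]: the H-bearing configuration is [12][21],
  # weight 1 - phi; [11][22] contributes the HbarHbar component with weight
  # phi (brute-force Bayes over the two configurations)
  cd12 <- map_to_composite(c(1, 1), "[12]", f)
  expect_equal(cd12$weights[cd12$status == "HbarHbar"], phi, tolerance = 1e-12)
  expect_equal(cd12$weights[cd12$status == "HHbar"], 1 - phi, tolerance = 1e-12)
  expect_equal(sum(cd12$weights), 1)
})

test_that("phase_mixture_prior follows the configuration-probability ratio", {
  expect_equal(phase_mixture_prior(rep(0.25, 4)), 0.5)
  f <- c(0.44, 0.26, 0.16, 0.14)
  expect_equal(phase_mixture_prior(f), 0.0616 / (0.0616 + 0.0416),
               tolerance = 1e-12)
  # only one configuration possible
  expect_equal(phase_mixture_prior(c(0.5, 0, 0.2, 0.3)), 1)
  expect_equal(phase_mixture_prior(c(0.5, 0.2, 0, 0.3)), 1)
  expect_error(phase_mixture_prior(c(0.5, 0, 0, 0.5)), NA)  # p11 p22 > 0 fine
  expect_error(phase_mixture_prior(c(0, 0.5, 0, 0.5)), "degenerate")
})

test_that("phase group classification follows the double-heterozygote rule", {
  gs <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 1))
  gt <- rbind(c(2, 2), c(0, 2), c(1, 1), c(1, 1))
  expect_equal(as.character(classify_phase_groups(gs, gt)),
               c("M1", "M2", "M3", "M4"))
})

test_that("block state counts reproduce the two- and three-SNP combinatorics", {
  c2 <- count_block_states(2)
  expect_equal(c2$genotypes_per_block, 9)
  expect_equal(c2$ambiguous_per_block, 1)
  expect_equal(c2$genotype_pairs, 81)
  expect_equal(c2$unambiguous_pairs, 64)
  expect_equal(c2$composite_pairs, 9)
  c3 <- count_block_states(3)
  expect_equal(c3$ambiguous_per_block, 7)
  expect_equal(c3$mixture_cells_two_blocks, 16)
  expect_error(count_block_states(0), "n_snps")
  # ambiguity count equals direct enumeration of >= 2 heterozygous loci
  for (n in 1:5) {
    states <- expand.grid(rep(list(0:2), n))
    n_amb <- sum(rowSums(states == 1) >= 2)
    expect_equal(count_block_states(n)$ambiguous_per_block, n_amb)
  }
})

test_that("haplotype frequency EM matches closed-form counting without double heterozygotes", {
  g <- rbind(c(0, 0), c(0, 1), c(2, 2), c(0, 2), c(1, 0), c(2, 1))
  f <- estimate_haplotype_frequencies(g)
  # direct gamete counting: [11]x2, [11]+[12], [22]x2, [12]x2, [11]+[21], [21]+[22]
  expect_equal(as.numeric(f), c(4, 3, 2, 3) / 12, tolerance = 1e-9)
  expect_true(attr(f, "converged"))
})

test_that("haplotype frequency EM is consistent and monotone in likelihood", {
  set.seed(11)
  truth <- c(0.44, 0.26, 0.16, 0.14)
  h1 <- sample.int(4, 1000, TRUE, truth)
  h2 <- sample.int(4, 1000, TRUE, truth)
  g <- cbind((h1 > 2) + (h2 > 2), (h1 %% 2 == 0) + (h2 %% 2 == 0))
  f <- estimate_haplotype_frequencies(g)
  se <- sqrt(truth * (1 - truth) / 2000)   # binomial SE of a gamete count
  expect_true(all(abs(as.numeric(f) - truth) < 3 * se))
  ll <- attr(f, "loglik")
  expect_true(all(diff(ll) > -1e-9))
})

test_that("a pure double-heterozygote sample is flagged non-identifiable", {
  g <- matrix(1L, 20, 2)
  expect_warning(f <- estimate_haplotype_frequencies(g), "not identifiable")
  expect_equal(as.numeric(f), rep(0.25, 4))
  expect_false(attr(f, "identifiable"))
})

test_that("EM frequencies agree with an exhaustive grid search", {
  set.seed(21)
  truth <- c(0.44, 0.26, 0.16, 0.14)
  h1 <- sample.int(4, 200, TRUE, truth)
  h2 <- sample.int(4, 200, TRUE, truth)
  g <- cbind((h1 > 2) + (h2 > 2), (h1 %% 2 == 0) + (h2 %% 2 == 0))
  f_em <- estimate_haplotype_frequencies(g)
  f_grid <- grid_search_hap_freqs(g, step = 0.005)
  expect_true(all(abs(as.numeric(f_em) - f_grid) < 0.01))
})

test_that("genotype input validation rejects bad codes", {
  expect_error(map_to_composite(c(3, 0), "[11]"), "genotype")
  expect_error(map_to_composite(c(1, 1), "[11]"), "frequencies")
  expect_error(estimate_haplotype_frequencies(matrix(integer(0), 0, 2)),
               "at least one")
  expect_error(estimate_haplotype_frequencies(rbind(c(0, 5))), "0, 1 or 2")
})
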