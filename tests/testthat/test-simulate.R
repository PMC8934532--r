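test_that("alignment simulation is seed-reproducible and invariant-clean", {
  tr <- default_species_tree()
  params <- default_test_params()
  a1 <- simulate_codon_alignment(tr, params, 60, seed = 5)
  a2 <- simulate_codon_alignment(tr, params, 60, seed = 5)
  expect_identical(unclass(a1), unclass(a2))
  expect_equal(nrow(a1), 8L)
  expect_equal(ncol(a1), 60L)
  # constructor enforces the no-stop invariant; presence of the class
  # means the simulated states are all sense codons
  expect_s3_class(a1, "codon_alignment")
  expect_length(attr(a1, "site_class"), 60L)
})

test_that("zero-length branches copy the root state to every taxon", {
  tr <- default_species_tree()
  tr$edge.length[] <- 0
  aln <- simulate_codon_alignment(tr, default_test_params(), 50, seed = 6)
  m <- unclass(aln)
  expect_true(all(apply(m, 2, function(col) length(unique(col)) == 1L)))
})

test_that("pure purifying selection forbids nonsynonymous change", {
  tr <- default_species_tree()
  params <- list(kappa = 2, p0 = 1 - 2e-9, p1 = 1e-9, omega0 = 1e-7,
                 omega2 = 1)
  # omega0 -> 0: class-0 sites accept synonymous changes only
  aln <- simulate_codon_alignment(tr, params, 200, seed = 7)
  aa <- omegascreen:::aln_aa_matrix(aln)
  same <- apply(aa, 2, function(col) length(unique(col)) == 1L)
  expect_gte(mean(same), 0.995)
})

test_that("sequence composition follows the equilibrium distribution", {
  tr <- default_species_tree()
  tab <- codon_table()
  pi <- codon_freq_f3x4_stationary()
  aln <- simulate_codon_alignment(tr, default_test_params(), 4000, seed = 8)
  # one taxon only: its sites are i.i.d. draws from pi marginally, whereas
  # taxa within a column are correlated through shared ancestry
  idx <- omegascreen:::codon_index(unclass(aln)["focal", ], tab)
  obs <- tabulate(idx, nbins = tab$n) / length(idx)
  chisq <- sum((obs - pi)^2 / pi) * length(idx)
  # loose goodness-of-fit bound: statistic ~ chi2 with 60 df under H0
  expect_lt(chisq, stats::qchisq(1 - 1e-4, df = 60))
})

test_that("pairwise divergence tracks branch length through the rate scaling", {
  # two taxa separated by 0.3 substitutions per codon; compare the observed
  # codon difference fraction to its expectation under the simulator's own
  # mixture of transition matrices
  tr <- read_newick(text = "(A:0.15,B:0.15);")
  params <- default_test_params(omega2 = 1)
  pi <- codon_freq_f3x4_stationary()
  tab <- codon_table()
  cls <- omegascreen:::model_classes(params, "M2_branch")
  omegas_eff <- c(params$omega0, 1, 1)
  rate <- sum(cls$p * vapply(omegas_eff, function(w)
    omegascreen:::unscaled_mean_rate(params$kappa, w, pi, tab), numeric(1)))
  expected_diff <- sum(vapply(seq_along(cls$p), function(cc) {
    q <- build_rate_matrix(params$kappa, omegas_eff[cc], pi, rate_scale = rate)
    p <- branch_transition_probabilities(q, 0.3, pi)
    cls$p[cc] * sum(pi * (1 - diag(p)))
  }, numeric(1)))
  aln <- simulate_codon_alignment(tr, params, 10000, seed = 9)
  m <- unclass(aln)
  obs_diff <- mean(m["A", ] != m["B", ])
  expect_equal(obs_diff, expected_diff, tolerance = 0.03)
})

test_that("orthogroup batches carry a consistent truth table", {
  b <- simulate_orthogroup_batch(2, 1, n_codons = 30, seed = 10)
  expect_length(b$alignments, 3L)
  expect_equal(nrow(b$truth), 3L)
  expect_equal(sum(b$truth$foreground_active), 1L)
  expect_equal(b$truth$p2, rep(0.2, 3))
  e <- simulate_orthogroup_batch(0, 0, seed = 1)
  expect_length(e$alignments, 0L)
  expect_equal(nrow(e$truth), 0L)
  # directory emission round-trips
  d <- tempfile()
  simulate_orthogroup_batch(1, 1, n_codons = 20, seed = 11, dir = d)
  expect_length(list.files(d, pattern = "\\.fna$"), 2L)
  back <- read_codon_fasta(list.files(d, pattern = "\\.fna$", full.names = TRUE)[1])
  expect_equal(ncol(back), 20L)
})

test_that("landscape generator honours fractions and planted clusters", {
  lens <- c(s1 = 40e6, s2 = 20e6)
  none <- simulate_landscape(lens, 500, selected_fraction = 0, seed = 12)
  expect_equal(sum(none$loci$selected), 0L)
  expect_true(all(none$loci$start <= none$loci$end))
  expect_true(all(none$loci$end <= lens[none$loci$scaffold]))

  planted <- simulate_landscape(lens, 2000, selected_fraction = 0.005,
                                planted_clusters = data.frame(
                                  scaffold = "s1", center = 10e6,
                                  span = 3e6, n_selected = 6),
                                seed = 13)
  inwin <- planted$loci$selected &
    abs(planted$loci$midpoint - 10e6) <= 1.5e6 &
    planted$loci$scaffold == "s1"
  expect_gte(sum(inwin), 6L)
  hits <- scan_clusters(planted$loci, planted$scaffold_lengths)
  expect_gte(max(hits$count), 3L)

  expect_error(simulate_landscape(lens, 10, planted_clusters = data.frame(
    scaffold = "s1", center = 39.9e6, span = 3e6, n_selected = 3)), "fit within")
  expect_error(simulate_landscape(lens, 10, planted_clusters = data.frame(
    scaffold = "s1", center = 10e6, span = 300, n_selected = 50)), "infeasible")
})

test_that("expression generator plants correlated pairs and bias", {
  tissues <- sprintf("t%02d", 1:6)
  sim <- simulate_expression(300, tissues,
                             correlated_pairs = list(c("t01", "t02")), seed = 14)
  expect_gt(stats::cor(sim$matrix[, "t01"], sim$matrix[, "t02"]), 0.95)
  expect_true(all(sim$matrix >= 0))
  s2 <- simulate_expression(300, tissues, seed = 14)
  expect_identical(sim$matrix[, "t01"], s2$matrix[, "t01"])
})
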