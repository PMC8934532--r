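toy_loci <- function(mids, scaffold = "s1", selected = NULL, exons = NULL) {
  n <- length(mids)
  gene_loci(data.frame(
    gene_id = sprintf("g%03d", seq_len(n)), scaffold = scaffold,
    start = mids, end = mids, strand = "+",
    exon_count = if (is.null(exons)) rep(2L, n) else exons,
    selected = if (is.null(selected)) rep(FALSE, n) else selected,
    stringsAsFactors = FALSE
  ))
}

test_that("window assignment respects boundaries and scaffold filters", {
  lens <- c(s1 = 2.5e6, s2 = 0.9e6)
  loci <- toy_loci(c(1e6, 1e6 + 1, 2.4e6))
  wt <- assign_windows(loci, lens)
  expect_equal(nrow(wt), 3L)                        # s2 dropped entirely
  expect_equal(wt$background, c(1L, 1L, 1L))        # 1e6 -> win 1; 1e6+1 -> win 2
  expect_equal(wt$length, c(1e6, 1e6, 0.5e6))       # final window truncated
  # gene on a short scaffold is excluded, counts unchanged
  loci2 <- rbind(loci, toy_loci(5e5, scaffold = "s2"))
  wt2 <- assign_windows(loci2, lens)
  expect_equal(sum(wt2$background), 3L)
  expect_error(assign_windows(toy_loci(10, scaffold = "sX"), lens), "unknown scaffold")
})

test_that("window counts sum to the included loci", {
  set.seed(19)
  sim <- simulate_landscape(c(a = 5e6, b = 3e6, c = 8e5), n_genes = 400,
                            selected_fraction = 0.1)
  wt <- assign_windows(sim$loci, sim$scaffold_lengths)
  inc <- sim$loci$scaffold %in% c("a", "b")
  expect_equal(sum(wt$background), sum(inc))
  expect_equal(sum(wt$selected), sum(sim$loci$selected & inc))
  expect_true(all(wt$selected <= wt$background))
})

test_that("discrete KS: proportional counts give D = 0 and p = 1", {
  wt <- assign_windows(toy_loci(c(5e5, 15e5, 25e5, 35e5),
                                selected = c(TRUE, TRUE, TRUE, TRUE)),
                       c(s1 = 4e6))
  r <- discrete_ks_test(wt, n_draws = 200, seed = 1)
  expect_equal(r$D, 0)
  expect_equal(r$p_value, 1)
})

test_that("discrete KS: concentration in one window gives large D, small p", {
  mids <- seq(5e5, 99.5e6, by = 1e6)              # one gene per 1-Mb window
  sel <- c(rep(FALSE, 98), TRUE, TRUE)
  loci <- rbind(toy_loci(mids, selected = sel),
                toy_loci(rep(99.5e6, 18) + seq_len(18), selected = TRUE))
  wt <- assign_windows(loci, c(s1 = 100e6))
  r <- discrete_ks_test(wt, n_draws = 5000, seed = 2)
  # D attained at window 98: background CDF 98/118, selected CDF 0
  expect_equal(r$D, 98 / 118, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
})

test_that("discrete KS Monte-Carlo agrees with exhaustive enumeration", {
  # 3 windows of 3 background genes, 2 selected genes both in window 3
  loci <- toy_loci(c(0.5e6, 0.6e6, 0.7e6, 1.5e6, 1.6e6, 1.7e6, 2.5e6, 2.6e6, 2.7e6),
                   selected = c(rep(FALSE, 7), TRUE, TRUE))
  wt <- assign_windows(loci, c(s1 = 3e6))
  bg_cdf <- cumsum(wt$background) / 9
  D_obs <- max(abs(cumsum(wt$selected) / 2 - bg_cdf))
  # enumerate all multinomial placements of 2 genes over 3 equal windows
  exact <- 0
  for (a in 0:2) for (b in 0:(2 - a)) {
    cc <- c(a, b, 2 - a - b)
    pr <- stats::dmultinom(cc, prob = rep(1 / 3, 3))
    D <- max(abs(cumsum(cc) / 2 - bg_cdf))
    if (D >= D_obs - 1e-12) exact <- exact + pr
  }
  n_draws <- 20000
  r <- discrete_ks_test(wt, n_draws = n_draws, seed = 3)
  # the +1/+1 estimator targets (n*exact + 1)/(n + 1)
  expect_equal(r$p_value, (n_draws * exact + 1) / (n_draws + 1), tolerance = 0.15)
})

test_that("D is invariant to merging adjacent empty windows", {
  mids <- c(0.5e6, 1.5e6, 8.5e6, 9.5e6)
  loci <- toy_loci(mids, selected = c(TRUE, FALSE, FALSE, TRUE))
  wt_long <- assign_windows(loci, c(s1 = 10e6))   # windows 3..8 empty
  wt_short <- wt_long[wt_long$background > 0, ]
  r1 <- discrete_ks_test(wt_long, n_draws = 100, seed = 4)
  r2 <- discrete_ks_test(wt_short, n_draws = 100, seed = 4)
  expect_equal(r1$D, r2$D)
})

test_that("cluster scan reports fixed-grid windows at the count threshold", {
  lens <- c(s1 = 10e6)
  # 3 midpoints at 0.1, 2.0, 4.9 Mb: one 5-Mb window with count 3
  hits <- scan_clusters(toy_loci(c(0.1e6, 2e6, 4.9e6),
                                 selected = rep(TRUE, 3)), lens)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$count, 3L)
  expect_equal(hits$window, 1L)
  expect_equal(hits$gene_ids, "g001,g002,g003")
  # 4.0 / 5.5 / 6.0 Mb straddle the grid: no window reaches 3
  none <- scan_clusters(toy_loci(c(4e6, 5.5e6, 6e6), selected = rep(TRUE, 3)), lens)
  expect_equal(nrow(none), 0L)
  # no selected genes -> empty
  expect_equal(nrow(scan_clusters(toy_loci(c(1e6, 2e6)), lens)), 0L)
})

test_that("single-exon association builds the right table and p-value", {
  # 10/100 single-exon selected vs 10/900 multi-exon selected
  loci <- toy_loci(seq_len(1000) * 1000,
                   selected = c(rep(TRUE, 10), rep(FALSE, 90),
                                rep(TRUE, 10), rep(FALSE, 890)),
                   exons = c(rep(1L, 100), rep(5L, 900)))
  r <- single_exon_association(loci)
  expect_equal(unname(r$table["single_exon", "selected"]), 10)
  expect_equal(unname(r$table["multi_exon", "not_selected"]), 890)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$p_value, fisher_enum_p(r$table), tolerance = 1e-9)
  expect_warning(r0 <- single_exon_association(toy_loci(c(1, 2), exons = c(1L, 2L))),
                 "no selected")
  expect_equal(r0$p_value, 1)
})

test_that("exon-independent selection gives calibrated association p-values", {
  set.seed(29)
  ps <- replicate(60, {
    sim <- simulate_landscape(c(a = 50e6), n_genes = 800,
                              selected_fraction = 0.05,
                              single_exon_fraction = 0.1)
    single_exon_association(sim$loci)$p_value
  })
  # under independence p-values should not pile up near 0
  expect_gt(mean(ps > 0.1), 0.6)
  expect_lt(mean(ps < 0.01), 0.1)
})
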