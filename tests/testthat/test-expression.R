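test_that("max normalization is rowwise, flagged, and idempotent", {
  m <- rbind(g1 = c(2, 4, 8), g2 = c(0, 0, 0), g3 = c(1, 1, 1))
  colnames(m) <- c("heart", "liver", "thymus")
  nm <- normalize_to_max(m)
  expect_equal(unname(nm["g1", ]), c(0.25, 0.5, 1))
  expect_equal(unname(nm["g2", ]), c(0, 0, 0))
  expect_equal(attr(nm, "no_expression"), c(g1 = FALSE, g2 = TRUE, g3 = FALSE))
  expect_equal(unclass(normalize_to_max(nm)), unclass(nm), ignore_attr = TRUE)
  expect_error(normalize_to_max(rbind(c(-1, 2))), "nonnegative")
})

test_that("decorrelation removes exactly one member per offending pair", {
  set.seed(31)
  m <- matrix(stats::rlnorm(200 * 4), 200, 4,
              dimnames = list(sprintf("g%03d", 1:200),
                              c("a", "b", "c", "d")))
  m[, "b"] <- m[, "a"]                   # identical pair
  nm <- normalize_to_max(m)
  r <- decorrelate_tissues(nm, seed = 1)
  expect_length(r$removed, 1L)
  expect_true(r$removed %in% c("a", "b"))
  expect_equal(nrow(r$log), 1L)

  # nothing above threshold: identity
  m2 <- matrix(stats::rlnorm(200 * 4), 200, 4, dimnames = dimnames(m))
  r2 <- decorrelate_tissues(normalize_to_max(m2), seed = 1)
  expect_length(r2$removed, 0L)

  # three mutually identical tissues: exactly two removals
  m3 <- m; m3[, "c"] <- m3[, "a"]
  r3 <- decorrelate_tissues(normalize_to_max(m3), seed = 2)
  expect_length(r3$removed, 2L)
  expect_length(intersect(c("a", "b", "c"), r3$retained), 1L)
})

test_that("30 tissues with 5 near-duplicate pairs lose exactly 5, every seed", {
  tissues <- sprintf("tissue%02d", 1:30)
  pairs <- lapply(1:5, function(i) tissues[c(2 * i - 1, 2 * i)])
  for (seed in 1:6) {
    sim <- simulate_expression(500, tissues, correlated_pairs = pairs, seed = seed)
    nm <- normalize_to_max(sim$matrix)
    r <- decorrelate_tissues(nm, r_threshold = 0.90, seed = seed)
    expect_length(r$removed, 5L)
    # one member of each planted pair removed
    expect_true(all(vapply(pairs, function(p) sum(p %in% r$removed) == 1L,
                           logical(1))))
  }
})

test_that("peak tissue uses the configured order for ties", {
  m <- rbind(g1 = c(0.3, 1, 0.2), g2 = c(1, 1, 0.5), g3 = c(0, 0, 0))
  colnames(m) <- c("heart", "thymus", "liver")
  nm <- normalize_to_max(m)
  pk <- peak_tissue(nm)
  expect_equal(pk[["g1"]], "thymus")
  expect_equal(pk[["g2"]], "heart")     # tie broken by first column
  expect_false("g3" %in% names(pk))     # no-expression gene excluded
  # permuting tissue order only changes tie outcomes
  nm2 <- nm[, c("thymus", "heart", "liver")]
  attr(nm2, "no_expression") <- attr(nm, "no_expression")
  pk2 <- peak_tissue(nm2)
  expect_equal(pk2[["g1"]], "thymus")
  expect_equal(pk2[["g2"]], "thymus")
})

test_that("peak enrichment detects a planted focal-tissue bias", {
  set.seed(37)
  tissues <- sprintf("t%02d", 1:10)
  sim <- simulate_expression(4000, tissues, n_selected = 100,
                             bias = list(tissue = "t05", shift = 6, fraction = 0.4))
  nm <- normalize_to_max(sim$matrix)
  pk <- peak_tissue(nm)
  sel <- stats::setNames(sim$selected, rownames(sim$matrix))
  r <- peak_enrichment_test(pk, sel, focal = "t05")
  expect_lt(r$p_value, 1e-6)
  # all-tissue variant flags the focal tissue after BH
  all_r <- peak_enrichment_test(pk, sel, tissues = tissues)
  expect_equal(all_r$tissue[which.min(all_r$p_value)], "t05")
  expect_lt(all_r$p_adjusted[all_r$tissue == "t05"], 0.001)
  # gene-order invariance
  perm <- sample(length(pk))
  r2 <- peak_enrichment_test(pk[perm], sel, focal = "t05")
  expect_equal(r2$p_value, r$p_value)
})

test_that("degenerate peak enrichment cases are handled", {
  pk <- c(g1 = "a", g2 = "b", g3 = "a")
  expect_warning(r <- peak_enrichment_test(pk, c(g1 = FALSE, g2 = FALSE, g3 = FALSE),
                                           focal = "a"), "p = 1")
  expect_equal(r$p_value, 1)
  log <- data.frame(removed = "z", kept = "a", r = 0.95)
  expect_error(peak_enrichment_test(pk, c(g1 = TRUE, g2 = FALSE, g3 = FALSE),
                                    focal = "z", removal_log = log),
               "decorrelation")
})

test_that("mean-expression tests rank a planted shift first and flag it", {
  set.seed(41)
  tissues <- sprintf("t%02d", 1:12)
  sim <- simulate_expression(3000, tissues, n_selected = 150,
                             bias = list(tissue = "t07", shift = 5, fraction = 0.5))
  nm <- normalize_to_max(sim$matrix)
  sel <- stats::setNames(sim$selected, rownames(sim$matrix))
  res <- mean_expression_tests(nm, sel)
  expect_equal(res$tissue[1], "t07")
  expect_lt(res$p_adjusted[1], 0.05)
  expect_gt(res$mean_selected[1], res$mean_other[1])
  # invariant to gene order
  perm <- sample(nrow(nm))
  nm2 <- nm[perm, ]
  attr(nm2, "no_expression") <- attr(nm, "no_expression")[perm]
  res2 <- mean_expression_tests(nm2, sel)
  expect_equal(res2$t, res$t, tolerance = 1e-12)
})

test_that("null expression differences are rarely significant after BH", {
  set.seed(43)
  flagged <- replicate(20, {
    sim <- simulate_expression(800, sprintf("t%02d", 1:8), n_selected = 60)
    nm <- normalize_to_max(sim$matrix)
    res <- mean_expression_tests(nm, stats::setNames(sim$selected,
                                                     rownames(sim$matrix)))
    any(res$p_adjusted < 0.05)
  })
  expect_lte(mean(flagged), 0.25)
})
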