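test_that("internal stops convert to ambiguity; terminal stop is stripped", {
  expect_equal(mask_internal_stops("ATGTAAGGG"), "ATGNNNGGG")
  expect_equal(mask_internal_stops("ATGGGGTAA"), "ATGGGG")
  expect_equal(mask_internal_stops("ATGGGG"), "ATGGGG")
  expect_error(mask_internal_stops("ATGG"), "frame")
})

test_that("back-translation maps protein columns onto codons", {
  aln <- backtranslate_alignment(c(t1 = "M-K", t2 = "MKK"),
                                 c(t1 = "ATGAAA", t2 = "ATGAAGAAA"))
  expect_equal(unclass(aln)["t1", ], c("ATG", "---", "AAA"))
  expect_equal(unclass(aln)["t2", ], c("ATG", "AAG", "AAA"))

  amb <- backtranslate_alignment(c(t1 = "MX"), c(t1 = "ATGNNN"))
  expect_equal(unclass(amb)["t1", ], c("ATG", "NNN"))

  ok <- backtranslate_alignment(c(t1 = "MK"), c(t1 = "ATGAAG"))
  expect_equal(ncol(ok), 2L)
  expect_error(backtranslate_alignment(c(t1 = "MK"), c(t1 = "ATGTTT")),
               "column 2")
  expect_error(backtranslate_alignment(c(t1 = "MKW"), c(t1 = "ATGAAG")),
               "correspondence")
})

test_that("back-translation inverts to the CDS after degapping", {
  set.seed(3)
  tab <- codon_table()
  for (rep in 1:5) {
    n <- 30
    prot <- character(0); cds <- character(0)
    cod <- sample(tab$codons, n, replace = TRUE)
    aa <- tab$aa[match(cod, tab$codons)]
    gaps <- sort(sample(n, 5))
    prot_aln <- aa
    prot_aln[gaps] <- "-"
    cds_str <- paste(cod[-gaps], collapse = "")
    aln <- backtranslate_alignment(stats::setNames(paste(prot_aln, collapse = ""), "x"),
                                   stats::setNames(cds_str, "x"))
    states <- unclass(aln)["x", ]
    expect_equal(paste(states[states != "---"], collapse = ""), cds_str)
  }
})

test_that("edge trimming keeps only the span between outer conserved triplets", {
  # proteins MKAVL / MKAIL / MKAGL: conserved columns {1,2,3,5}, only
  # triplet is 1-3 from both directions
  aln <- backtranslate_alignment(
    c(a = "MKAVL", b = "MKAIL", c = "MKAGL"),
    c(a = "ATGAAAGCCGTTCTT", b = "ATGAAAGCCATTCTT", c = "ATGAAAGCCGGTCTT"))
  tr <- trim_to_conserved_edges(aln)
  expect_equal(ncol(tr), 3L)
  expect_equal(unname(omegascreen:::aln_aa_matrix(tr)[1, ]), c("M", "K", "A"))

  # fully conserved alignment is unchanged, and trimming is idempotent
  cons <- backtranslate_alignment(
    c(a = "MKAV", b = "MKAV"), c(a = "ATGAAAGCCGTT", b = "ATGAAAGCCGTT"))
  expect_equal(ncol(trim_to_conserved_edges(cons)), 4L)
  expect_identical(unclass(trim_to_conserved_edges(trim_to_conserved_edges(aln))),
                   unclass(tr))

  # no conserved triplet anywhere -> zero columns, flagged
  div <- codon_alignment(matrix(c("ATG", "AAA", "TGG", "CCC"), 2, 2,
                                dimnames = list(c("a", "b"), NULL)))
  z <- trim_to_conserved_edges(div)
  expect_equal(ncol(z), 0L)
  expect_true(attr(z, "no_conserved_triplet"))
})

test_that("the 100-codon length filter is boundary-inclusive", {
  taxa <- c("a", "b")
  expect_true(filter_min_length(random_codon_aln(taxa, 100, seed = 1)))
  expect_false(filter_min_length(random_codon_aln(taxa, 99, seed = 1)))
  z <- trim_to_conserved_edges(codon_alignment(
    matrix(c("ATG", "AAA"), 2, 1, dimnames = list(taxa, NULL))))
  expect_false(filter_min_length(z))
})

test_that("suspect-region masking deletes gapped and taxon-unique runs", {
  mk <- function(rows) codon_alignment(do.call(rbind, rows))
  # conserved background: identical sequences
  base <- c("ATG", "AAA", "GGG", "TTT", "CCC", "GAT", "TGG")
  a <- base; b <- base; c_ <- base
  # no gaps, no unique runs -> identity
  clean <- mk(list(a = a, b = b, c = c_))
  res <- mask_suspect_regions(clean)
  expect_equal(ncol(res$alignment), 7L)
  expect_equal(nrow(res$log), 0L)

  # single GAP column flanked by conserved columns -> exactly that column
  g <- base; g[4] <- "---"
  res1 <- mask_suspect_regions(mk(list(a = a, b = b, c = g)))
  expect_equal(ncol(res1$alignment), 6L)
  expect_equal(res1$log$rule, "R1")
  expect_equal(c(res1$log$start_col, res1$log$end_col), c(4L, 4L))

  # one taxon with 4 consecutive unique substitutions (min run 3)
  u <- base
  u[3:6] <- c("CAT", "CAC", "CAA", "CAG")  # H,H,Q,Q vs G,F,P,D consensus
  res2 <- mask_suspect_regions(mk(list(a = a, b = b, c = u)),
                               mask_params(unique_run_min = 3))
  expect_equal(res2$log$rule, "R2")
  expect_equal(c(res2$log$start_col, res2$log$end_col), c(3L, 6L))
  expect_equal(ncol(res2$alignment), 3L)
  # raising the threshold above the run length masks nothing (monotone)
  res3 <- mask_suspect_regions(mk(list(a = a, b = b, c = u)),
                               mask_params(unique_run_min = 5))
  expect_equal(ncol(res3$alignment), 7L)
})

test_that("masking never deletes a conserved column", {
  set.seed(9)
  tr <- default_species_tree()
  for (rep in 1:3) {
    aln <- simulate_codon_alignment(tr, default_test_params(), 80,
                                    foreground_active = FALSE)
    m <- unclass(aln)
    m[sample(length(m), 12)] <- "---"
    noisy <- codon_alignment(m)
    cons_before <- sum(omegascreen:::conserved_columns(noisy))
    res <- mask_suspect_regions(noisy)
    expect_equal(sum(omegascreen:::conserved_columns(res$alignment)), cons_before)
  }
})

test_that("clean, conserved simulated alignments pass masking untouched", {
  # short branches, strong purifying selection: no indels are simulated, so
  # both rules should fire rarely; check they fire never at these settings
  tr <- default_species_tree()
  tr$edge.length <- tr$edge.length / 10
  set.seed(21)
  untouched <- 0L
  for (rep in 1:5) {
    aln <- simulate_codon_alignment(tr, list(kappa = 2, p0 = 0.95, p1 = 0.05,
                                             omega0 = 0.05, omega2 = 1), 120,
                                    foreground_active = FALSE)
    res <- mask_suspect_regions(aln)
    untouched <- untouched + (ncol(res$alignment) == 120L)
  }
  expect_gte(untouched, 4L)
})
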