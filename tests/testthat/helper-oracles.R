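# Shared fixtures and independent oracles.

# Brute-force site-class codon likelihood by explicit summation over all
# internal-node states.  Independent of the pruning engine: transition
# matrices come from branch_transition_probabilities() on the scaled rate
# matrix, and the mixture is summed per site directly.  Practical for
# trees of <= 4 leaves.
brute_force_loglik <- function(aln, tree, params, model, pi = NULL) {
  tab <- codon_table()
  if (is.null(pi)) pi <- codon_freq_f3x4(aln)
  cls <- omegascreen:::model_classes(params, model)
  po <- ape::reorder.phylo(tree, "postorder")
  perm <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  fg_po <- which(perm %in% foreground_edges(tree))
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  ints <- omegascreen:::aln_state_int(aln)[tree$tip.label, , drop = FALSE] + 1L
  ncls <- length(cls$p)
  n <- tab$n
  P <- vector("list", ncls)
  for (cc in seq_len(ncls)) {
    P[[cc]] <- vector("list", nrow(po$edge))
    for (e in seq_len(nrow(po$edge))) {
      w <- cls$omega[cc]
      if (model == "M2_branch" && cc == 3 && !(e %in% fg_po)) w <- 1
      # branch rate under this edge's own mixture
      omegas_edge <- cls$omega
      if (model == "M2_branch" && !(e %in% fg_po)) omegas_edge[3] <- 1
      rate <- sum(cls$p * vapply(omegas_edge, function(ww)
        omegascreen:::unscaled_mean_rate(params$kappa, ww, pi, tab), numeric(1)))
      q <- build_rate_matrix(params$kappa, w, pi, rate_scale = rate, tab = tab)
      P[[cc]][[e]] <- branch_transition_probabilities(q, po$edge.length[e], pi)
    }
  }
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), length(internal))))
  total <- 0
  for (site in seq_len(ncol(ints))) {
    l_site <- 0
    for (cc in seq_len(ncls)) {
      lc <- 0
      for (g in seq_len(nrow(grid))) {
        states <- integer(nnode)
        states[internal] <- grid[g, ]
        states[seq_len(ntip)] <- ints[, site]
        pr <- pi[states[root]]
        for (e in seq_len(nrow(po$edge))) {
          ch <- po$edge[e, 2]
          if (ch <= ntip && states[ch] > n) next   # missing data marginalises out
          pr <- pr * P[[cc]][[e]][states[po$edge[e, 1]], states[ch]]
        }
        lc <- lc + pr
      }
      l_site <- l_site + cls$p[cc] * lc
    }
    total <- total + log(l_site)
  }
  unname(total)
}

# small 4-taxon fixture tree with a foreground tip
quartet_tree <- function() {
  tr <- read_newick(text = "((A:0.10,B:0.20):0.05,C:0.30,D:0.15);")
  set_foreground(tr, "A")
}

random_codon_aln <- function(taxa, n_codons, seed = NULL,
                             gap_frac = 0, ambig_frac = 0) {
  if (!is.null(seed)) set.seed(seed)
  tab <- codon_table()
  m <- matrix(sample(tab$codons, length(taxa) * n_codons, replace = TRUE),
              length(taxa), n_codons, dimnames = list(taxa, NULL))
  k <- length(m)
  if (gap_frac > 0) m[sample.int(k, round(gap_frac * k))] <- "---"
  if (ambig_frac > 0) m[sample.int(k, round(ambig_frac * k))] <- "NNN"
  codon_alignment(m)
}

default_test_params <- function(omega2 = 3) {
  list(kappa = 2, p0 = 0.5, p1 = 0.3, omega0 = 0.1, omega2 = omega2)
}

# exhaustive two-sided Fisher oracle by hypergeometric enumeration
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); nn <- sum(tab)
  lo <- max(0, c1 - (nn - r1)); hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, nn - r1, c1)
  p_obs <- stats::dhyper(a, r1, nn - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small GFF3 text fixture writer
write_gff_fixture <- function(lines, path = tempfile(fileext = ".gff3")) {
  writeLines(c("##gff-version 3", lines), path)
  path
}
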