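# Likelihood of a codon alignment under site-class models, with an optional
# foreground branch.  Three models are supported:
#   M1        -- classes (omega0 < 1, omega1 = 1) with proportions (p0, 1-p0)
#   M2        -- classes (omega0, 1, omega2 >= 1), proportions (p0, p1, p2),
#                every class on every branch
#   M2_branch -- as M2, but class 2 evolves at omega2 on the foreground
#                branch(es) only; on background branches class-2 sites
#                evolve neutrally (omega = 1)
#
# Branch lengths are in expected substitutions per codon under the branch's
# own site-class mixture.  Internally the engine works in unscaled time
# units (the raw Goldman-Yang matrix); the per-branch mixture rate converts
# between the two.

MODEL_NAMES <- c("M1", "M2", "M2_branch")

validate_params <- function(params, model) {
  need <- switch(model,
    M1 = c("kappa", "p0", "omega0"),
    M2 = , M2_branch = c("kappa", "p0", "p1", "omega0", "omega2"))
  miss <- setdiff(need, names(params))
  if (length(miss) > 0) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  with(params, {
    if (kappa <= 0) stop("kappa must be > 0")
    if (omega0 <= 0 || omega0 >= 1) stop("omega0 must be in (0, 1)")
    if (p0 < 0 || p0 > 1) stop("p0 must be in [0, 1]")
    if (model != "M1") {
      if (p1 < 0 || p0 + p1 > 1 + 1e-12) stop("need p0, p1 >= 0 and p0 + p1 <= 1")
      if (omega2 < 1 || omega2 > 999) stop("omega2 must be in [1, 999]")
    }
  })
  invisible(TRUE)
}

# class proportions and per-class omega for a model
model_classes <- function(params, model) {
  switch(model,
    M1 = list(p = c(params$p0, 1 - params$p0),
              omega = c(params$omega0, 1)),
    M2 = , M2_branch = list(
      p = c(params$p0, params$p1, 1 - params$p0 - params$p1),
      omega = c(params$omega0, 1, params$omega2)))
}

# Precompute the tree/alignment geometry used by every likelihood call.
lik_context <- function(aln, tree, pi = NULL, tab = codon_table(attr(aln, "code_id") %||% "1")) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  taxa <- rownames(aln)
  if (!setequal(taxa, tree$tip.label)) {
    stop("alignment taxa and tree leaves differ: ",
         paste(c(setdiff(taxa, tree$tip.label), setdiff(tree$tip.label, taxa)),
               collapse = ", "))
  }
  if (is.null(pi)) pi <- codon_freq_f3x4(aln, tab)
  po <- ape::reorder.phylo(tree, "postorder")
  perm <- match(
    paste(po$edge[, 1], po$edge[, 2]),
    paste(tree$edge[, 1], tree$edge[, 2])
  )
  fg <- foreground_edges(tree)
  fg_po <- which(perm %in% fg)
  ints <- aln_state_int(aln, tab)[tree$tip.label, , drop = FALSE]
  pat <- aln_patterns(ints)
  list(
    tips = pat$tips, weights = pat$weights,
    edge0 = po$edge - 1L,                   # 0-based node ids, postorder
    lengths = po$edge.length,               # substitutions/codon scale
    perm = perm,                            # postorder row -> original edge row
    nnode = ape::Ntip(tree) + tree$Nnode,
    root = ape::Ntip(tree),                 # ape root node id - 1
    fg = fg_po,                             # postorder indices of foreground
    pi = pi, tab = tab, n_sites = ncol(ints)
  )
}

# Map a model + params onto the engine inputs: eigen decompositions of the
# unscaled rate matrices for the distinct omegas, the class x edge omega
# assignment, and the per-edge mixture rate (for branch-length units).
model_machinery <- function(ctx, params, model) {
  cls <- model_classes(params, model)
  omegas <- unique(cls$omega)
  eigs <- lapply(omegas, function(w) {
    q <- build_rate_matrix(params$kappa, w, ctx$pi, rate_scale = 1, tab = ctx$tab)
    rate_eigen(q, ctx$pi)
  })
  rates <- vapply(omegas, function(w)
    unscaled_mean_rate(params$kappa, w, ctx$pi, ctx$tab), numeric(1))
  nedge <- nrow(ctx$edge0)
  class_omega <- matrix(0L, length(cls$p), nedge)
  for (c in seq_along(cls$p)) {
    class_omega[c, ] <- match(cls$omega[c], omegas) - 1L
  }
  edge_rate <- rep(sum(cls$p * rates[match(cls$omega, omegas)]), nedge)
  if (model == "M2_branch" && length(ctx$fg) > 0) {
    # background branches: class 2 evolves neutrally
    bg <- setdiff(seq_len(nedge), ctx$fg)
    class_omega[3, bg] <- match(1, omegas) - 1L
    bg_omega <- cls$omega
    bg_omega[3] <- 1
    edge_rate[bg] <- sum(cls$p * rates[match(bg_omega, omegas)])
  }
  list(eigs = eigs, class_omega = class_omega, class_p = cls$p,
       edge_rate = edge_rate)
}

engine_eval <- function(ctx, mach, s, gradient = FALSE) {
  .cpp_codon_loglik(ctx$tips, ctx$weights, ctx$edge0, ctx$nnode, ctx$root,
                    s, mach$eigs, mach$class_omega, mach$class_p, ctx$pi,
                    gradient)
}

#' Log-likelihood of a codon alignment under a site-class model
#'
#' Computes the phylogenetic log-likelihood by the pruning algorithm, summing
#' over site classes per column.  Gap and ambiguous states contribute
#' all-ones partial likelihoods (missing data).  Branch lengths of `tree`
#' are interpreted as expected substitutions per codon under the branch's
#' site-class mixture.
#'
#' @param aln A [codon_alignment()].
#' @param tree Unrooted `ape::phylo` tree whose tips match the alignment
#'   taxa; for `model = "M2_branch"` it must carry a foreground branch (see
#'   [set_foreground()]).
#' @param params Named list of model parameters: `kappa`, `p0`, `omega0`,
#'   and for M2 models `p1` and `omega2`.
#' @param model One of `"M1"`, `"M2"`, `"M2_branch"`.
#' @param pi Codon frequencies; default empirical F3x4 from the alignment.
#' @return The log-likelihood (scalar).  `-Inf` with a warning when some
#'   column has probability zero (e.g. differing codons on an all-zero
#'   length tree).
#' @export
log_likelihood <- function(aln, tree, params, model = c("M2_branch", "M1", "M2"),
                           pi = NULL) {
  model <- match.arg(model)
  validate_params(params, model)
  ctx <- lik_context(aln, tree, pi)
  if (model == "M2_branch" && length(ctx$fg) == 0) {
    stop("model 'M2_branch' needs a foreground branch; see set_foreground()")
  }
  mach <- model_machinery(ctx, params, model)
  s <- ctx$lengths / mach$edge_rate
  res <- engine_eval(ctx, mach, s)
  if (!is.finite(res$loglik)) {
    warning("zero-probability column(s); log-likelihood is -Inf")
  }
  res$loglik
}
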