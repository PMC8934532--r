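# Goldman-Yang codon rate matrices and their spectral decomposition.

#' Goldman-Yang instantaneous codon rate matrix
#'
#' Builds the reversible codon substitution rate matrix in which codons
#' exchange only through single-nucleotide changes: the rate from codon i to
#' codon j is `pi[j]`, multiplied by `kappa` for transitions and by `omega`
#' for nonsynonymous changes.  The diagonal is set so rows sum to zero.
#'
#' @param kappa Transition/transversion rate ratio, > 0.
#' @param omega Nonsynonymous/synonymous rate ratio, >= 0.
#' @param pi Equilibrium frequencies over the sense codons, summing to 1.
#' @param rate_scale Divisor applied to the whole matrix.  With the default
#'   `NULL` the matrix is scaled so that its own expected substitution rate
#'   at equilibrium is 1 (branch lengths in expected substitutions per
#'   codon).  Site-class model code passes the expected rate of the full
#'   class mixture instead, so that branch lengths measure substitutions per
#'   codon under the mixture.
#' @param tab Codon table, see [codon_table()].
#' @return A square rate matrix over sense codons with attribute
#'   `"mean_rate"` giving the unscaled expected rate `-sum(pi * diag(Q))`.
#' @export
build_rate_matrix <- function(kappa, omega, pi = NULL, rate_scale = NULL,
                              tab = codon_table()) {
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0) {
    stop("'kappa' must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1 || omega < 0) {
    stop("'omega' must be a single nonnegative number")
  }
  n <- tab$n
  if (is.null(pi)) pi <- rep(1 / n, n)
  if (length(pi) != n || any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("'pi' must be ", n, " nonnegative frequencies summing to 1")
  }
  fac <- matrix(0, n, n)
  fac[tab$step == 1L] <- 1
  fac[tab$step == 2L] <- kappa
  fac[tab$syn == 0L & tab$step > 0L] <- fac[tab$syn == 0L & tab$step > 0L] * omega
  q <- fac * rep(pi, each = n)  # q[i, j] = fac[i, j] * pi[j]
  diag(q) <- -rowSums(q)
  mean_rate <- -sum(pi * diag(q))
  if (is.null(rate_scale)) rate_scale <- mean_rate
  if (rate_scale <= 0) stop("'rate_scale' must be positive")
  q <- q / rate_scale
  dimnames(q) <- list(tab$codons, tab$codons)
  attr(q, "mean_rate") <- mean_rate
  q
}

# Expected substitution rate at equilibrium of the *unscaled* GY matrix for
# one omega -- used to form the site-class mixture scale.
unscaled_mean_rate <- function(kappa, omega, pi, tab = codon_table()) {
  n <- tab$n
  fac <- matrix(0, n, n)
  fac[tab$step == 1L] <- 1
  fac[tab$step == 2L] <- kappa
  ns <- tab$syn == 0L & tab$step > 0L
  fac[ns] <- fac[ns] * omega
  q_off <- fac * rep(pi, each = n)
  sum(pi * rowSums(q_off))
}

# Spectral decomposition of a reversible rate matrix.  Returns U, W, lambda
# such that expm(Q t) = U %*% diag(exp(lambda * t)) %*% W.
rate_eigen <- function(q, pi) {
  d <- sqrt(pi)
  b <- q * (d / rep(d, each = length(d)))   # b[i,j] = d[i] * q[i,j] / d[j]
  b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  list(
    U = e$vectors / d,                       # diag(1/d) %*% V
    W = t(e$vectors) * rep(d, each = length(d)),  # t(V) %*% diag(d)
    lambda = e$values
  )
}

#' Transition probability matrix for a branch
#'
#' Matrix exponential `expm(Q * t)` of a reversible codon rate matrix,
#' computed through its spectral decomposition.
#'
#' @param q Rate matrix from [build_rate_matrix()].
#' @param t Branch length, >= 0 (same units as the matrix scaling).
#' @param pi Equilibrium frequencies used to build `q`; recovered from a
#'   uniform default if missing.
#' @return Stochastic matrix of the same dimension as `q`.
#' @export
branch_transition_probabilities <- function(q, t, pi = NULL) {
  if (!is.numeric(t) || length(t) != 1 || t < 0) {
    stop("branch length 't' must be a single nonnegative number")
  }
  n <- nrow(q)
  if (is.null(pi)) {
    # stationary distribution of a reversible Q solves pi Q = 0; recover it
    # from the left null space
    ns <- Re(eigen(t(q))$vectors[, n])
    pi <- ns / sum(ns)
  }
  e <- rate_eigen(q, pi)
  p <- e$U %*% (exp(e$lambda * t) * e$W)
  p[p < 0] <- 0
  dimnames(p) <- dimnames(q)
  p
}
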