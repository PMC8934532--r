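# Maximum-likelihood fitting of site-class codon models and the foreground
# branch likelihood-ratio test.
#
# Optimization is bounded quasi-Newton (L-BFGS-B) over branch lengths and
# model parameters jointly.  Branch lengths are optimized in the unscaled
# time units of the raw Goldman-Yang matrix (the likelihood is invariant to
# the substitutions-per-codon rescaling, which is applied when reporting);
# their gradient is analytic from the pruning engine, as are the site-class
# proportion gradients.  kappa, omega0 and omega2 use central finite
# differences (kappa and omega2 on the log scale).

PAR_BOUNDS <- list(
  log_kappa = c(log(0.05), log(50)),
  a = c(1e-6, 1 - 1e-6),        # p0
  b = c(1e-6, 1 - 1e-6),        # p1 / (1 - p0)
  omega0 = c(1e-4, 0.9999),
  log_omega2 = c(0, log(999)),
  s = c(1e-8, 30)               # per-branch unscaled time
)

default_control <- function(control) {
  utils::modifyList(list(lnL_tol = 1e-8, maxit = 300, fd_step = 1e-5), control)
}

# pack/unpack between the optimizer vector and (params, s)
pack_theta <- function(params, s, model, fix_omega2) {
  th <- c(log(params$kappa), params$p0)
  if (model != "M1") {
    b <- if (params$p0 >= 1) 0.5 else params$p1 / (1 - params$p0)
    th <- c(th, min(max(b, 1e-6), 1 - 1e-6))
  }
  th <- c(th, params$omega0)
  if (model != "M1" && is.null(fix_omega2)) th <- c(th, log(params$omega2))
  c(th, s)
}

unpack_theta <- function(theta, model, fix_omega2, nedge) {
  i <- 1
  kappa <- exp(theta[i]); i <- i + 1
  a <- theta[i]; i <- i + 1
  if (model != "M1") { b <- theta[i]; i <- i + 1 }
  omega0 <- theta[i]; i <- i + 1
  params <- list(kappa = kappa, omega0 = omega0)
  if (model == "M1") {
    params$p0 <- a
  } else {
    params$p0 <- a
    params$p1 <- (1 - a) * b
    if (is.null(fix_omega2)) {
      params$omega2 <- exp(theta[i]); i <- i + 1
    } else {
      params$omega2 <- fix_omega2
    }
  }
  list(params = params, s = theta[i:length(theta)], a = a,
       b = if (model != "M1") b else NULL)
}

theta_bounds <- function(model, fix_omega2, nedge) {
  lower <- c(PAR_BOUNDS$log_kappa[1], PAR_BOUNDS$a[1])
  upper <- c(PAR_BOUNDS$log_kappa[2], PAR_BOUNDS$a[2])
  if (model != "M1") {
    lower <- c(lower, PAR_BOUNDS$b[1]); upper <- c(upper, PAR_BOUNDS$b[2])
  }
  lower <- c(lower, PAR_BOUNDS$omega0[1]); upper <- c(upper, PAR_BOUNDS$omega0[2])
  if (model != "M1" && is.null(fix_omega2)) {
    lower <- c(lower, PAR_BOUNDS$log_omega2[1])
    upper <- c(upper, PAR_BOUNDS$log_omega2[2])
  }
  list(lower = c(lower, rep(PAR_BOUNDS$s[1], nedge)),
       upper = c(upper, rep(PAR_BOUNDS$s[2], nedge)),
       n_model = length(lower))
}

#' Fit a site-class codon model by maximum likelihood
#'
#' Jointly maximizes the log-likelihood over model parameters and branch
#' lengths by bounded quasi-Newton iteration with seeded multi-start.  The
#' species-tree branch lengths serve only as starting values; fitted branch
#' lengths are re-estimated and reported in expected substitutions per
#' codon under the fitted site-class mixture.
#'
#' @param aln A [codon_alignment()] that has passed quality control.
#' @param tree Unrooted `ape::phylo` with branch lengths (starting values)
#'   and, for `"M2_branch"`, a foreground branch ([set_foreground()]).
#' @param model `"M1"`, `"M2"` or `"M2_branch"`.
#' @param params_init Optional starting parameter list; sensible defaults
#'   otherwise.
#' @param fix_omega2 Fix omega2 at this value instead of estimating it
#'   (used for the null of the branch LRT, `fix_omega2 = 1`).
#' @param pi Codon frequencies; default empirical F3x4.
#' @param n_starts Number of seeded optimizer starts (first start is
#'   `params_init` itself, the rest are jittered).
#' @param seed Integer seed for the start jitter.
#' @param control List: `lnL_tol` (convergence tolerance on the
#'   log-likelihood, default 1e-8), `maxit`, `fd_step`.
#' @return An object of class `codon_fit`: list with `params` (omega2
#'   clipped to `[1, 999]`), `lnL`, `tree` (fitted branch lengths),
#'   `tree_length` (sum of fitted lengths, substitutions per codon),
#'   `converged`, `model`, `pi`, `n_starts`.
#' @export
fit_model <- function(aln, tree, model = c("M2_branch", "M1", "M2"),
                      params_init = NULL, fix_omega2 = NULL, pi = NULL,
                      n_starts = 3, seed = NULL, control = list()) {
  model <- match.arg(model)
  ctrl <- default_control(control)
  ctx <- lik_context(aln, tree, pi)
  if (model == "M2_branch" && length(ctx$fg) == 0) {
    stop("model 'M2_branch' needs a foreground branch; see set_foreground()")
  }
  if (is.null(params_init)) {
    params_init <- list(kappa = 2, p0 = 0.6, p1 = 0.3, omega0 = 0.1, omega2 = 2)
  }
  if (!is.null(fix_omega2)) params_init$omega2 <- fix_omega2
  nedge <- nrow(ctx$edge0)
  bounds <- theta_bounds(model, fix_omega2, nedge)
  nm <- bounds$n_model

  mach0 <- model_machinery(ctx, params_init, model)
  s0 <- pmin(pmax(ctx$lengths / mach0$edge_rate, PAR_BOUNDS$s[1]), PAR_BOUNDS$s[2])

  cache <- new.env(parent = emptyenv())
  evaluate <- function(theta, gradient = FALSE) {
    key <- paste(theta, collapse = "|")
    if (identical(cache$key, key) && (!gradient || !is.null(cache$val$grad))) {
      return(cache$val)
    }
    up <- unpack_theta(theta, model, fix_omega2, nedge)
    mach <- model_machinery(ctx, up$params, model)
    r <- engine_eval(ctx, mach, up$s, gradient = gradient)
    r$up <- up
    cache$key <- key; cache$val <- r
    r
  }
  fn <- function(theta) {
    r <- evaluate(theta)
    if (!is.finite(r$loglik)) return(1e10)
    -r$loglik
  }
  gr <- function(theta) {
    r <- evaluate(theta, gradient = TRUE)
    if (!is.finite(r$loglik)) return(rep(0, length(theta)))
    up <- r$up
    # analytic class-proportion gradients from per-class site likelihoods
    g <- numeric(length(theta))
    rel <- exp(sweep(r$class_site_ll, 2, as.numeric(r$site_ll), "-"))
    G <- as.numeric(rel %*% ctx$weights)
    h <- ctrl$fd_step
    fd <- function(idx) {
      tp <- theta; tp[idx] <- theta[idx] + h
      tm <- theta; tm[idx] <- theta[idx] - h
      (fn(tp) - fn(tm)) / (2 * h)
    }
    i <- 1
    g[i] <- fd(i); i <- i + 1                       # log kappa
    if (model == "M1") {
      g[i] <- -(G[1] - G[2]); i <- i + 1            # a = p0
    } else {
      b <- up$b
      g[i] <- -(G[1] - b * G[2] - (1 - b) * G[3]); i <- i + 1   # a
      g[i] <- -((1 - up$a) * (G[2] - G[3])); i <- i + 1          # b
    }
    g[i] <- fd(i); i <- i + 1                       # omega0
    if (model != "M1" && is.null(fix_omega2)) {
      g[i] <- fd(i); i <- i + 1                     # log omega2
    }
    g[i:length(theta)] <- -r$grad
    g
  }

  jitter_start <- function(theta) {
    th <- theta
    th[1] <- th[1] + stats::runif(1, -0.5, 0.5)
    th[2] <- stats::runif(1, 0.3, 0.9)
    if (model != "M1") th[3] <- stats::runif(1, 0.2, 0.9)
    om0_i <- if (model == "M1") 3 else 4
    th[om0_i] <- stats::runif(1, 0.02, 0.5)
    if (model != "M1" && is.null(fix_omega2)) th[om0_i + 1] <- stats::runif(1, 0, 3)
    th[(nm + 1):length(th)] <- th[(nm + 1):length(th)] * exp(stats::runif(nedge, -0.3, 0.3))
    pmin(pmax(th, bounds$lower), bounds$upper)
  }

  if (!is.null(seed)) set.seed(seed)
  theta0 <- pmin(pmax(pack_theta(params_init, s0, model, fix_omega2),
                      bounds$lower), bounds$upper)
  starts <- list(theta0)
  if (n_starts > 1) for (k in 2:n_starts) starts[[k]] <- jitter_start(theta0)

  factr <- max(ctrl$lnL_tol / .Machine$double.eps / 1e4, 10)
  best <- NULL
  for (th in starts) {
    opt <- try(stats::optim(th, fn, gr, method = "L-BFGS-B",
                            lower = bounds$lower, upper = bounds$upper,
                            control = list(maxit = ctrl$maxit, factr = factr)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    # ties resolved by best lnL then lowest omega2
    if (is.null(best) || opt$value < best$value - 1e-9 ||
        (abs(opt$value - best$value) <= 1e-9 && omega2_of(opt$par, model, fix_omega2) <
           omega2_of(best$par, model, fix_omega2))) {
      best <- opt
    }
  }
  if (is.null(best)) stop("all optimizer starts failed")

  up <- unpack_theta(best$par, model, fix_omega2, nedge)
  mach <- model_machinery(ctx, up$params, model)
  t_scaled <- up$s * mach$edge_rate
  fitted_tree <- tree
  fitted_tree$edge.length[ctx$perm] <- t_scaled
  params <- up$params
  if (model != "M1") params$omega2 <- min(max(params$omega2, 1), 999)
  structure(list(
    model = model, params = params, lnL = -best$value,
    tree = fitted_tree, tree_length = sum(t_scaled),
    converged = best$convergence == 0, message = best$message,
    pi = ctx$pi, n_starts = n_starts, n_codons = ctx$n_sites
  ), class = "codon_fit")
}

omega2_of <- function(theta, model, fix_omega2) {
  if (model == "M1" || !is.null(fix_omega2)) return(1)
  exp(theta[5])
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("codon model fit:", x$model, "\n")
  cat("  lnL =", format(x$lnL, digits = 10),
      if (!x$converged) "(not converged)" else "", "\n")
  cat("  kappa =", signif(x$params$kappa, 4),
      " omega0 =", signif(x$params$omega0, 4),
      if (!is.null(x$params$omega2)) paste(" omega2 =", signif(x$params$omega2, 4)),
      "\n")
  cat("  p0 =", signif(x$params$p0, 4),
      if (!is.null(x$params$p1)) paste(" p1 =", signif(x$params$p1, 4)), "\n")
  cat("  tree length =", signif(x$tree_length, 5), "subs/codon\n")
  invisible(x)
}
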