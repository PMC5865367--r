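#' Bayesian ridge regression with additive and dominance effect classes
#'
#' Fits `y_i = mu + sum_j X_ij a_j + sum_j Z_ij d_j + e_i` by single-site
#' Gibbs sampling, where `X` holds allele dosages (0/1/2) and `Z` the
#' heterozygosity indicators. Additive effects share a common normal prior
#' `N(0, s2a)`, dominance effects `N(0, s2d)`, and the three variance
#' components (`s2a`, `s2d`, residual `s2e`) carry scaled-inverse-chi-square
#' hyperpriors with `df_prior` degrees of freedom. Hyperprior scales are set
#' from the training phenotypic variance assuming a marker-explained
#' proportion `R2` split equally between the two effect classes.
#'
#' Each Gibbs iteration updates the intercept, then sweeps all additive and
#' all dominance effects. SNPs with no heterozygotes in the training set keep
#' a dominance effect of exactly 0. Posterior means are accumulated after
#' `burnin`. With `fix_var` supplied, the variance components are held fixed,
#' in which case the posterior mean coincides (in expectation) with the
#' closed-form joint ridge solution.
#'
#' @param y Phenotype vector.
#' @param X Dosage matrix (n x p), coded 0/1/2.
#' @param Z Heterozygosity indicator matrix (n x p); derived from `X` when
#'   omitted.
#' @param chain A [chain_config()].
#' @param fix_var Optional named list/vector with `s2a`, `s2d`, `s2e` to hold
#'   the variance components fixed (no hyperprior updates).
#' @return An object of class `brr_dom` with posterior means `mu`, `a`, `d`,
#'   posterior-mean variance components, the thinned monitoring chains and
#'   their Geweke z-scores.
#' @seealso [predict.brr_dom()], [geweke_z()]
#' @export
brr_dom <- function(y, X, Z = NULL, chain = chain_config(), fix_var = NULL) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) stop("data error: non-finite phenotypes", call. = FALSE)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(Z)) Z <- (X == 1) * 1.0
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- length(y)
  if (n < 2L) stop("need at least 2 training records", call. = FALSE)
  if (ncol(X) < 1L) stop("need at least 1 marker", call. = FALSE)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1  # degenerate (constant) y: unit scale
  df0 <- chain$df_prior
  msx <- sum(apply(X, 2, stats::var))
  msz <- sum(apply(Z, 2, stats::var))
  r2c <- chain$R2 / 2
  Sa <- vy * r2c * (df0 + 2) / df0 / max(msx, .Machine$double.eps)
  Sd <- vy * r2c * (df0 + 2) / df0 / max(msz, .Machine$double.eps)
  Se <- vy * (1 - chain$R2) * (df0 + 2) / df0

  if (is.null(fix_var)) {
    fixed <- FALSE
    s2a0 <- Sa; s2d0 <- Sd; s2e0 <- Se
  } else {
    fixed <- TRUE
    s2a0 <- fix_var[["s2a"]]; s2d0 <- fix_var[["s2d"]]; s2e0 <- fix_var[["s2e"]]
  }

  res <- cpp_brr_gibbs(y, X, Z, chain$niter, chain$burnin, chain$thin,
                       df0, Sa, Sd, Se, fixed, s2a0, s2d0, s2e0)

  chains <- data.frame(mu = res$mu_chain, s2a = res$s2a_chain,
                       s2d = res$s2d_chain, s2e = res$s2e_chain)
  gz <- vapply(chains, function(ch) {
    kept <- ch[seq.int(ceiling(chain$burnin / chain$thin) + 1L, nrow(chains))]
    if (length(kept) >= 100L) geweke_z(kept) else NA_real_
  }, numeric(1))

  structure(list(mu = res$mu, a = as.numeric(res$a), d = as.numeric(res$d),
                 s2a = res$s2a, s2d = res$s2d, s2e = res$s2e,
                 chains = chains, geweke = gz,
                 chain_config = chain, fixed_var = fixed,
                 n = n, p = ncol(X), call = match.call()),
            class = "brr_dom")
}

#' @export
print.brr_dom <- function(x, ...) {
  cat(sprintf("Bayesian ridge regression (additive + dominance), n = %d, p = %d\n",
              x$n, x$p))
  cat(sprintf("  chain: %d iterations, %d burn-in%s\n",
              x$chain_config$niter, x$chain_config$burnin,
              if (x$fixed_var) ", variance components fixed" else ""))
  cat(sprintf("  mu = %.4f, s2a = %.5f, s2d = %.5f, s2e = %.4f\n",
              x$mu, x$s2a, x$s2d, x$s2e))
  invisible(x)
}

#' @export
summary.brr_dom <- function(object, ...) {
  out <- list(
    fit = object,
    effect_summary = rbind(
      additive = summary(object$a),
      dominance = summary(object$d)),
    geweke = object$geweke)
  class(out) <- "summary.brr_dom"
  out
}

#' @export
print.summary.brr_dom <- function(x, ...) {
  print(x$fit)
  cat("\nPosterior-mean marker effects:\n")
  print(x$effect_summary)
  cat("\nGeweke z (monitoring chains):\n")
  print(round(x$geweke, 2))
  invisible(x)
}

#' @export
coef.brr_dom <- function(object, ...) {
  list(mu = object$mu, a = object$a, d = object$d)
}

#' Predict from a fitted additive + dominance ridge model
#'
#' Returns `mu + X a + Z d` for new genotypes coded like the training data.
#'
#' @param object A `brr_dom` fit.
#' @param X Dosage matrix (n x p).
#' @param Z Heterozygosity indicators; derived from `X` when omitted.
#' @param ... Unused.
#' @return Numeric vector of fitted values.
#' @export
predict.brr_dom <- function(object, X, Z = NULL, ...) {
  X <- as.matrix(X)
  if (ncol(X) != object$p)
    stop("alignment error: marker set does not match the fit", call. = FALSE)
  if (is.null(Z)) Z <- (X == 1) * 1.0
  object$mu + drop(X %*% object$a) + drop(Z %*% object$d)
}

#' @export
plot.brr_dom <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(oldpar))
  for (nm in names(x$chains)) {
    graphics::plot(x$chains[[nm]], type = "l", xlab = "thinned iteration",
                   ylab = nm, main = nm, ...)
  }
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' Compares the means of the first `first_fraction` and last `last_fraction`
#' of a chain, standardized by spectral-density estimates of the variance at
#' frequency zero (autoregressive estimator). Values of |z| well above 2
#' indicate that the chain has not reached its stationary distribution.
#'
#' @param chain Numeric chain (post burn-in).
#' @param first_fraction,last_fraction Window fractions (defaults 0.1, 0.5).
#' @return The Geweke z-score; exactly 0 for a constant chain.
#' @export
geweke_z <- function(chain, first_fraction = 0.1, last_fraction = 0.5) {
  n <- length(chain)
  if (n < 100L) stop("diagnostic error: chain too short (need >= 100)", call. = FALSE)
  if (first_fraction + last_fraction > 1)
    stop("window fractions must not overlap", call. = FALSE)
  a <- chain[seq_len(max(2L, floor(first_fraction * n)))]
  b <- chain[seq.int(n - max(2L, floor(last_fraction * n)) + 1L, n)]
  floor_var <- 1e-12 * max(stats::var(chain), .Machine$double.eps)
  sa <- spectrum0_ar(a)
  sb <- spectrum0_ar(b)
  if (sa <= floor_var && sb <= floor_var) return(0)
  (mean(a) - mean(b)) / sqrt(sa / length(a) + sb / length(b))
}

# Spectral density at frequency zero via an AIC-selected AR fit,
# var.pred / (1 - sum(ar))^2. Returns 0 for (near-)constant segments.
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE, order.max = min(30L, length(x) - 1L)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(stats::var(x))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}
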