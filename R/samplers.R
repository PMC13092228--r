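# MCMC building blocks: univariate slice sampling, conjugate normal-linear
# Gibbs updates, a marginalized squared-exponential GP likelihood, and
# rank-normalized split-chain convergence diagnostics.

# Univariate slice sampler (Neal 2003, stepping out + shrinkage).
slice_sample_1d <- function(x0, logf, w = 1, max_steps = 50, lower = -Inf, upper = Inf) {
  f0 <- logf(x0)
  if (!is.finite(f0)) abort("Slice sampler started at a zero-density point.")
  z <- f0 + log(runif(1))
  u <- runif(1)
  L <- max(x0 - w * u, lower)
  R <- max(L, min(x0 + w * (1 - u), upper))
  j <- floor(max_steps * runif(1))
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > z) { L <- max(L - w, lower); j <- j - 1 }
  while (k > 0 && R < upper && logf(R) > z) { R <- min(R + w, upper); k <- k - 1 }
  repeat {
    x1 <- runif(1, L, R)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

# Conjugate draw of regression coefficients for y ~ N(X beta, sigma^2 I)
# with independent N(prior_mean, prior_sd^2) priors.
draw_beta_conjugate <- function(y, X, sigma, prior_mean, prior_sd) {
  p <- ncol(X)
  prec <- crossprod(X) / sigma^2 + diag(1 / prior_sd^2, p)
  b <- crossprod(X, y) / sigma^2 + prior_mean / prior_sd^2
  U <- chol(prec)
  mu <- backsolve(U, forwardsolve(t(U), b))
  drop(mu + backsolve(U, rnorm(p)))
}

# Gibbs sampler for the normal linear model with an Exponential(rate) prior
# on the residual SD (slice step). Returns a list of per-chain draw matrices.
gibbs_normal_lm <- function(y, X, prior_mean, prior_sd, sigma_rate,
                            n_chains = 4, n_iter = 3000, n_warmup = 1500,
                            seed = 1) {
  n <- length(y); p <- ncol(X)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    chains[[ch]] <- local_seed(seed + ch, {
      sigma <- sd(y) * exp(runif(1, -0.5, 0.5))
      if (!is.finite(sigma) || sigma <= 0) sigma <- 1
      beta <- prior_mean + prior_sd * rnorm(p) * 0.1
      kept <- matrix(NA_real_, n_iter - n_warmup, p + 1)
      for (it in seq_len(n_iter)) {
        beta <- draw_beta_conjugate(y, X, sigma, prior_mean, prior_sd)
        resid <- y - drop(X %*% beta)
        ssr <- sum(resid^2)
        log_sigma_post <- function(ls) {
          s <- exp(ls)
          -n * ls - ssr / (2 * s^2) - sigma_rate * s + ls # + Jacobian
        }
        sigma <- exp(slice_sample_1d(log(sigma), log_sigma_post, w = 0.5))
        if (it > n_warmup) kept[it - n_warmup, ] <- c(beta, sigma)
      }
      colnames(kept) <- c(colnames(X), "sigma")
      kept
    })
  }
  chains
}

# log marginal likelihood of y ~ MVN(mean, eta^2 K + sigma^2 I + jitter I)
gp_marginal_loglik <- function(r, K, eta, sigma, jitter = 1e-6) {
  S <- eta^2 * K + diag(sigma^2 + jitter, nrow(K))
  U <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(U)) return(-Inf)
  alpha <- backsolve(U, forwardsolve(t(U), r))
  -sum(log(diag(U))) - 0.5 * sum(r * alpha) - 0.5 * length(r) * log(2 * pi)
}

se_kernel <- function(d2, ell) exp(-d2 / (2 * ell^2))

# --- Convergence diagnostics (rank-normalized split chains) ---------------

rank_normalize <- function(mat) {
  # mat: iterations x chains
  z <- qnorm((rank(mat, ties.method = "average") - 3 / 8) / (length(mat) + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[seq.int(n - half + 1, n), , drop = FALSE])
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4 || m < 2) return(NA_real_)
  means <- colMeans(mat)
  vars <- apply(mat, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @keywords internal
rhat_rank_normalized <- function(mat) {
  sp <- split_chains(mat)
  if (ncol(sp) < 2 || nrow(sp) < 4) return(NA_real_)
  max(rhat_basic(rank_normalize(sp)),
      rhat_basic(rank_normalize(abs(sweep(sp, 2, apply(sp, 2, median))))),
      na.rm = TRUE)
}

acov_fft <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  m <- nextn(2 * n)
  f <- fft(c(x, rep(0, m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (m * n)
  ac * n / (n - 1)
}

ess_rank_normalized <- function(mat) {
  sp <- rank_normalize(split_chains(mat))
  n <- nrow(sp); m <- ncol(sp)
  if (n < 4) return(NA_real_)
  acovs <- sapply(seq_len(m), function(j) acov_fft(sp[, j]))
  W <- mean(acovs[1, ]) * n / (n - 1)
  var_plus <- W * (n - 1) / n + if (m > 1) var(colMeans(sp)) else 0
  if (var_plus <= 0) return(n * m)
  # rho_0 = 1 by construction; rho_t from the multi-chain estimator
  rho <- c(1, 1 - (W - rowMeans(acovs)[-1]) / var_plus)
  # Geyer: sum initial positive, monotone-decreasing pair sums
  n_pairs <- floor(length(rho) / 2)
  P <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  pos <- which(P <= 0)
  K <- if (length(pos) > 0) pos[1] - 1 else n_pairs
  if (K == 0) return(n * m)
  P <- cummin(P[seq_len(K)])
  tau <- max(-1 + 2 * sum(P), 1e-3)
  min(n * m / tau, n * m * log10(max(n * m, 10)))
}
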