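#' Fit a Gaussian mixture to log10 genetic distances
#'
#' Expectation-maximization fit of a one- or two-component Gaussian mixture
#' on the log10 scale of binwise distances.  Two components model the
#' bimodal variant-density distribution of genomes with stratified ancestry
#' (a low, same-ancestry component and a high, different-ancestry
#' component); one component suits an unstratified (sub)genome.  Zero or
#' no-data distances must be excluded before the log transform: a zero
#' window is unambiguous shared ancestry and carries no information about
#' the component shapes.
#'
#' The fit is deterministic given `seed` (used only to jitter the
#' quantile-based initialization out of exact ties).  The per-iteration
#' log-likelihood trace is kept so the EM ascent property can be checked.
#'
#' @param values positive distances in variants/bp (at least 100).
#' @param n_components 1 or 2.
#' @param seed integer seed.
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood
#'   improves by less than `tol` (default 1e-8) or after `max_iter`
#'   (default 500) iterations.
#' @return A `distance_mixture` object: list with `mean`, `sd`, `weight`
#'   (components ordered by ascending mean, log10 scale), `n`, `loglik`
#'   (final), `loglik_trace`, `converged`, `iterations`.
#' @export
fit_distance_mixture <- function(values, n_components = 2, seed = 1,
                                 max_iter = 500, tol = 1e-8) {
  values <- values[!is.na(values)]
  if (any(values <= 0))
    stop("values must be positive; drop zero/no-data windows before fitting")
  if (length(values) < 100)
    stop("need at least 100 positive distances to fit")
  x <- log10(values)
  if (diff(range(x)) == 0)
    stop("degenerate fit: all distances identical")
  k <- as.integer(n_components)
  if (!k %in% 1:2) stop("n_components must be 1 or 2")
  n <- length(x)
  if (k == 1L) {
    m <- mean(x); s <- sd(x)
    ll <- sum(dnorm(x, m, s, log = TRUE))
    return(new_mixture(m, s, 1, n, ll, ll, TRUE, 0L))
  }
  set.seed(seed)
  mu <- quantile(x, c(0.25, 0.75), names = FALSE) + rnorm(2, 0, 1e-6)
  sg <- rep(sd(x) / 2, 2)
  w <- c(0.5, 0.5)
  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E step: responsibilities via log-sum-exp
    lp <- cbind(log(w[1]) + dnorm(x, mu[1], sg[1], log = TRUE),
                log(w[2]) + dnorm(x, mu[2], sg[2], log = TRUE))
    mx <- pmax(lp[, 1], lp[, 2])
    lse <- mx + log(exp(lp[, 1] - mx) + exp(lp[, 2] - mx))
    ll <- sum(lse)
    trace <- c(trace, ll)
    r <- exp(lp - lse)
    # M step
    nk <- colSums(r)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sg <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    sg <- pmax(sg, 1e-8)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
  }
  ord <- order(mu)
  new_mixture(mu[ord], sg[ord], w[ord], n, trace[length(trace)], trace,
              converged, length(trace))
}

new_mixture <- function(mean, sd, weight, n, loglik, trace, converged, iter) {
  structure(list(mean = mean, sd = sd, weight = weight, n = n,
                 loglik = loglik, loglik_trace = trace,
                 converged = converged, iterations = iter),
            class = "distance_mixture")
}

#' @export
print.distance_mixture <- function(x, ...) {
  cat(sprintf("Gaussian mixture on log10(variants/bp), %d component(s), n = %d\n",
              length(x$mean), x$n))
  for (i in seq_along(x$mean))
    cat(sprintf("  comp %d: mean %.4f (%.3g variants/bp), sd %.4f, weight %.3f\n",
                i, x$mean[i], 10^x$mean[i], x$sd[i], x$weight[i]))
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Derive the ancestry threshold from a mixture fit
#'
#' In `fixed` mode, returns the configured constant (default `1e-3`
#' variants/bp, the wheat A&B-subgenome value).  In `crossover` mode,
#' returns the distance between the two component means at which the
#' posterior responsibilities are equal, i.e. the solution of
#' `w1 * N(x; m1, s1) = w2 * N(x; m2, s2)` on the log10 scale.
#'
#' @param fit a [fit_distance_mixture()] result (2 components required for
#'   crossover mode).
#' @param mode `"fixed"` or `"crossover"`.
#' @param fixed the fixed-mode constant, variants/bp.
#' @return Threshold in variants/bp.
#' @export
derive_threshold <- function(fit, mode = c("fixed", "crossover"),
                             fixed = 1e-3) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(fixed)
  if (length(fit$mean) != 2L)
    stop("crossover mode requires a 2-component fit")
  m <- fit$mean; s <- fit$sd; w <- fit$weight
  # equal-posterior point: quadratic in x from the log density difference
  a <- 1 / s[2]^2 - 1 / s[1]^2
  b <- 2 * (m[1] / s[1]^2 - m[2] / s[2]^2)
  cc <- m[2]^2 / s[2]^2 - m[1]^2 / s[1]^2 +
    2 * (log(w[1] / s[1]) - log(w[2] / s[2]))
  if (abs(a) < 1e-14) {
    x <- -cc / b
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("no real crossover point between the components")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    inside <- roots[roots >= m[1] & roots <= m[2]]
    x <- if (length(inside)) inside[1] else roots[which.min(abs(roots - mean(m)))]
  }
  10^x
}
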