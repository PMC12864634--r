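# Deterministic quadrature utilities. Marginal likelihoods are integrals of
# the likelihood against the prior; each is mapped onto (0,1) through the
# prior's quantile function (so heavy Cauchy / inverse-gamma tails are
# handled by the substitution, not by truncation) and evaluated with
# Gauss-Legendre rules, refined by node doubling until two successive
# refinements agree in log units.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf
  m + log(sum(exp(x - m)))
}

# Gauss-Legendre nodes/weights on (0,1) via the Golub-Welsch eigenvalue
# method on the Jacobi matrix. Cached per node count.
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre01 <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  ord <- order(x)
  res <- list(x = (x[ord] + 1) / 2, w = w[ord] / 2)
  .gl_cache[[key]] <- res
  res
}

#' Quadrature control settings
#'
#' Node counts and tolerances for the marginal-likelihood quadrature and the
#' posterior density grid. Rules start at `n_start` nodes per axis and are
#' refined (nodes roughly doubled) until two successive refinements of a log
#' marginal likelihood differ by less than `tol_log`, capped at `n_max`
#' nodes per axis; an unmet tolerance attaches a warning to the result
#' rather than failing silently.
#'
#' @param n_start Initial Gauss-Legendre nodes per axis (default 201).
#' @param n_max Hard cap on nodes per axis (default 1601).
#' @param tol_log Refinement tolerance in log-marginal-likelihood units.
#' @param n_grid Points in the posterior density grid (odd; Simpson rule).
#' @param mass_tol Maximum posterior mass the density grid may miss before
#'   automatic widening kicks in.
#' @return A list of class `quad_control`.
#' @export
quad_control <- function(n_start = 201, n_max = 1601, tol_log = 1e-6,
                         n_grid = 2049, mass_tol = 1e-5) {
  stopifnot(n_start >= 11, n_max >= n_start, tol_log > 0,
            n_grid %% 2 == 1, n_grid >= 101, mass_tol > 0)
  structure(list(n_start = n_start, n_max = n_max, tol_log = tol_log,
                 n_grid = n_grid, mass_tol = mass_tol),
            class = "quad_control")
}

# 1-D refinement loop. log_f maps a vector of u in (0,1) to log integrand
# values (likelihood evaluated at the prior quantile of u).
quad_refine_1d <- function(log_f, control) {
  n <- control$n_start
  prev <- NA_real_
  repeat {
    gl <- gauss_legendre01(n)
    val <- logsumexp(log_f(gl$x) + log(gl$w))
    err <- abs(val - prev)
    if (!is.na(prev) && err < control$tol_log) {
      return(list(logml = val, nodes = n, err = err, converged = TRUE))
    }
    if (2 * n - 1 > control$n_max) {
      warning("quadrature refinement stopped at ", n,
              " nodes with log-scale change ", signif(err, 3), call. = FALSE)
      return(list(logml = val, nodes = n, err = err, converged = FALSE))
    }
    prev <- val
    n <- 2 * n - 1
  }
}

# 2-D product-rule refinement; log_f(u, v) takes vectors and returns the
# length(u) x length(v) matrix of log integrand values.
quad_refine_2d <- function(log_f, control) {
  n <- control$n_start
  prev <- NA_real_
  repeat {
    gl <- gauss_legendre01(n)
    lw <- log(gl$w)
    m <- log_f(gl$x, gl$x) + outer(lw, lw, `+`)
    val <- logsumexp(m)
    err <- abs(val - prev)
    if (!is.na(prev) && err < control$tol_log) {
      return(list(logml = val, nodes = n, err = err, converged = TRUE))
    }
    if (2 * n - 1 > control$n_max) {
      warning("2-D quadrature refinement stopped at ", n,
              " nodes per axis with log-scale change ", signif(err, 3),
              call. = FALSE)
      return(list(logml = val, nodes = n, err = err, converged = FALSE))
    }
    prev <- val
    n <- 2 * n - 1
  }
}

# Composite Simpson weights on a uniform grid with an odd number of points.
simpson_weights <- function(n, h) {
  w <- rep(c(2, 4), length.out = n)
  w[1] <- 1
  w[n] <- 1
  w * h / 3
}
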