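#' Mixture parameter sets
#'
#' A full model for heterogeneous gene-content evolution: a gain/loss model
#' kind, a heterogeneity kind, K clusters with mixing probabilities
#' \code{phi}, and per-cluster generators and root distributions. The three
#' heterogeneity kinds share a uniform "K clusters, each with
#' (R_k, pi_k, phi_k)" view (see [cluster_view()]):
#' \describe{
#'   \item{gamma}{discretized-gamma rate multipliers: one base generator
#'     \code{R}, one shared root distribution \code{pi}, shape
#'     \code{gamma_shape}; \code{phi_k = 1/K} and the multipliers \code{r_k}
#'     are the K equal-probability category means of a unit-mean gamma
#'     distribution.}
#'   \item{pdf}{probability-distribution-free multipliers: free \code{r_k}
#'     and \code{phi}, shared base \code{R} and \code{pi}; identifiable only
#'     up to scale, fixed by the convention \code{sum(phi * r) = 1}.}
#'   \item{pm}{pattern mixture: K free generators \code{R_1..R_K} and root
#'     distributions \code{pi_1..pi_K}.}
#' }
#'
#' @param kind gain/loss model kind (see [build_rate_matrix()]).
#' @param hetero one of \code{"gamma"}, \code{"pdf"}, \code{"pm"}.
#' @param K number of clusters.
#' @param lmax copy-number truncation bound.
#' @param phi mixing probabilities (ignored for \code{"gamma"}, where they
#'   are fixed at 1/K).
#' @param rates for \code{"pm"} a list of K [build_rate_matrix()] objects;
#'   otherwise a single base rate matrix.
#' @param pi for \code{"pm"} a K x (lmax+1) matrix of root distributions
#'   (rows on the simplex); otherwise a single (lmax+1) vector.
#' @param r free multipliers (pdf only; rescaled so \code{sum(phi*r) = 1}).
#' @param gamma_shape gamma shape parameter (gamma only).
#' @return an object of class \code{mixture_params}.
#' @export
mixture_params <- function(kind, hetero = c("pm", "pdf", "gamma"), K, lmax,
                           phi = NULL, rates, pi, r = NULL,
                           gamma_shape = NULL) {
  hetero <- match.arg(hetero)
  K <- as.integer(K)
  lmax <- as.integer(lmax)
  if (K < 1L) stop("K must be >= 1")
  s <- lmax + 1L
  if (hetero == "pm") {
    if (!is.list(rates) || length(rates) != K) {
      stop("pm model needs a list of K rate matrices")
    }
    pi <- matrix(as.numeric(pi), nrow = K)
    if (ncol(pi) != s) stop("pi must be K x (lmax+1)")
    pi <- pi / rowSums(pi)
  } else {
    if (inherits(rates, "rate_matrix")) rates <- list(rates)
    if (length(rates) != 1L) stop("gamma/pdf models use a single base rate matrix")
    pi <- as.numeric(pi)
    if (length(pi) != s) stop("pi must have lmax+1 entries")
    pi <- pi / sum(pi)
  }
  for (rm in rates) {
    if (!inherits(rm, "rate_matrix") || rm$lmax != lmax || rm$kind != kind) {
      stop("every rate matrix must be a rate_matrix of matching kind and lmax")
    }
  }
  if (hetero == "gamma") {
    if (is.null(gamma_shape) || gamma_shape <= 0) stop("gamma model needs gamma_shape > 0")
    phi <- rep(1 / K, K)
    r <- gamma_category_rates(gamma_shape, K)
  } else {
    if (is.null(phi) || length(phi) != K || any(phi < 0)) {
      stop("phi must be a nonnegative K-vector")
    }
    phi <- phi / sum(phi)
  }
  if (hetero == "pdf") {
    if (is.null(r) || length(r) != K || any(r <= 0)) {
      stop("pdf model needs positive multipliers r of length K")
    }
    cs <- sum(phi * r)   # scale-identifiability convention
    r <- r / cs
    rates <- list(scale_rate_matrix(rates[[1L]], cs))
  }
  structure(list(kind = kind, hetero = hetero, K = K, lmax = lmax,
                 phi = phi, rates = rates, pi = pi, r = r,
                 gamma_shape = gamma_shape),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  cat("mixture_params: ", toupper(x$kind), " + ", toupper(x$hetero),
      ", K = ", x$K, ", lmax = ", x$lmax, "\n", sep = "")
  cat("phi:", paste(signif(x$phi, 4), collapse = " "), "\n")
  if (!is.null(x$r)) cat("r:  ", paste(signif(x$r, 4), collapse = " "), "\n")
  if (!is.null(x$gamma_shape)) cat("gamma shape:", signif(x$gamma_shape, 4), "\n")
  invisible(x)
}

#' Discretized-gamma category rate multipliers
#'
#' Divides a unit-mean gamma distribution with shape \code{alpha} (rate also
#' \code{alpha}) into K categories of equal probability and returns the
#' conditional mean of each category, computed from the incomplete-gamma
#' ratio; the multipliers average to 1.
#'
#' @param alpha positive shape parameter.
#' @param K number of categories.
#' @return numeric vector of K increasing multipliers with mean 1.
#' @export
gamma_category_rates <- function(alpha, K) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("'alpha' must be a single positive number")
  }
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K == 1L) return(1)
  b <- stats::qgamma(seq_len(K - 1L) / K, shape = alpha, rate = alpha)
  # integral of x * dgamma(x; a, a) over (b1, b2) equals
  # pgamma(b2; a+1, a) - pgamma(b1; a+1, a) since the distribution has mean 1
  pb <- c(0, stats::pgamma(b, shape = alpha + 1, rate = alpha), 1)
  K * diff(pb)
}

#' Uniform per-cluster view of a mixture
#'
#' Expands any heterogeneity kind to an explicit list of K clusters, each
#' with its own generator (the base matrix scaled by \code{r_k} for
#' gamma/pdf), root distribution and mixing probability.
#'
#' @param theta a [mixture_params()] object.
#' @return list of K lists with elements \code{R} (a \code{rate_matrix}),
#'   \code{pi} and \code{phi}.
#' @export
cluster_view <- function(theta) {
  stopifnot(inherits(theta, "mixture_params"))
  lapply(seq_len(theta$K), function(k) {
    if (theta$hetero == "pm") {
      list(R = theta$rates[[k]], pi = theta$pi[k, ], phi = theta$phi[k])
    } else {
      list(R = scale_rate_matrix(theta$rates[[1L]], theta$r[k]),
           pi = theta$pi, phi = theta$phi[k])
    }
  })
}

# flat Dirichlet draw
rdirichlet1 <- function(n) {
  x <- stats::rgamma(n, shape = 1)
  x / sum(x)
}

# random free-rate draw on [0.1, 2.0] for a given kind
random_rate_matrix <- function(kind, lmax) {
  runif2 <- function(n) stats::runif(n, 0.1, 2.0)
  params <- switch(kind,
                   bd = list(alpha = runif2(1), beta = runif2(1)),
                   cm = list(alpha = runif2(1), beta = runif2(1), gamma = runif2(1)),
                   bdi = list(delta = runif2(1), alpha = runif2(1), beta = runif2(1)),
                   bdard = list(gain = runif2(lmax), loss = runif2(lmax)))
  build_rate_matrix(kind, params, lmax)
}

#' Random initial parameters
#'
#' Draws a random starting point for the EM algorithm: free rates uniform on
#' [0.1, 2.0], mixing and root probabilities from a flat Dirichlet, and the
#' gamma shape log-uniform on [0.2, 5]. Uses the current R random stream, so
#' results are reproducible after \code{set.seed()}.
#'
#' @inheritParams mixture_params
#' @return a [mixture_params()] object.
#' @export
random_init <- function(kind, hetero = c("pm", "pdf", "gamma"), K, lmax) {
  hetero <- match.arg(hetero)
  s <- lmax + 1L
  if (hetero == "pm") {
    mixture_params(kind, "pm", K, lmax,
                   phi = rdirichlet1(K),
                   rates = lapply(seq_len(K), function(k) random_rate_matrix(kind, lmax)),
                   pi = t(vapply(seq_len(K), function(k) rdirichlet1(s), numeric(s))))
  } else if (hetero == "pdf") {
    mixture_params(kind, "pdf", K, lmax,
                   phi = rdirichlet1(K),
                   rates = random_rate_matrix(kind, lmax),
                   pi = rdirichlet1(s),
                   r = stats::runif(K, 0.1, 2.0))
  } else {
    mixture_params(kind, "gamma", K, lmax,
                   rates = random_rate_matrix(kind, lmax),
                   pi = rdirichlet1(s),
                   gamma_shape = exp(stats::runif(1, log(0.2), log(5))))
  }
}
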