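#' Gain/loss rate matrices
#'
#' Gene-content evolution is modelled as a continuous-time Markov chain on
#' copy numbers 0..lmax whose generator is tridiagonal: in an infinitesimal
#' interval at most one gene is gained or lost. Four parameterisations are
#' supported:
#' \describe{
#'   \item{bd}{birth-death: constant gain rate \code{alpha} (i -> i+1) and
#'     loss rate \code{beta} (i -> i-1).}
#'   \item{cm}{Csuros-Miklos: gain \code{alpha + i*gamma} (HGT acquisition
#'     plus per-copy duplication), loss \code{i*beta}.}
#'   \item{bdi}{birth-death-innovation: like \code{bd} but the 0 -> 1
#'     acquisition of a novel family has its own rate \code{delta}.}
#'   \item{bdard}{all rates different: every gain rate \code{g_i}
#'     (i -> i+1, i = 0..lmax-1) and loss rate \code{d_i} (i -> i-1,
#'     i = 1..lmax) is free.}
#' }
#' State \code{lmax} has no gain rate (truncation boundary) and state 0 no
#' loss rate. Diagonals are filled so rows sum to zero.
#'
#' @param kind one of \code{"bd"}, \code{"cm"}, \code{"bdi"}, \code{"bdard"}.
#' @param params named numeric vector/list of free parameters:
#'   bd: \code{alpha, beta}; cm: \code{alpha, beta, gamma};
#'   bdi: \code{delta, alpha, beta}; bdard: \code{gain} (length lmax) and
#'   \code{loss} (length lmax).
#' @param lmax positive integer truncation bound (states 0..lmax).
#' @return an object of class \code{rate_matrix}: list with the
#'   \code{(lmax+1) x (lmax+1)} generator \code{R}, \code{kind}, \code{lmax}
#'   and the free-parameter list \code{params}.
#' @export
build_rate_matrix <- function(kind = c("bd", "cm", "bdi", "bdard"),
                              params, lmax) {
  kind <- match.arg(kind)
  if (!is.numeric(lmax) || length(lmax) != 1L || lmax < 1 || lmax != round(lmax)) {
    stop("'lmax' must be a positive integer")
  }
  lmax <- as.integer(lmax)
  p <- as.list(params)
  need <- switch(kind,
                 bd = c("alpha", "beta"),
                 cm = c("alpha", "beta", "gamma"),
                 bdi = c("delta", "alpha", "beta"),
                 bdard = c("gain", "loss"))
  if (is.null(names(p)) || !setequal(names(p), need)) {
    # allow positional vectors in the documented order
    if (kind != "bdard" && length(p) == length(need) &&
        (is.null(names(p)) || all(names(p) == ""))) {
      names(p) <- need
    } else if (!all(need %in% names(p))) {
      stop("parameters for kind '", kind, "' must be named: ",
           paste(need, collapse = ", "))
    }
  }
  p <- p[need]
  vals <- unlist(p, use.names = FALSE)
  if (anyNA(vals) || any(vals < 0)) stop("all rate parameters must be >= 0")
  i <- 0:(lmax - 1L)  # states with a gain rate
  gains <- switch(kind,
                  bd = rep(p$alpha, lmax),
                  cm = p$alpha + i * p$gamma,
                  bdi = c(p$delta, rep(p$alpha, lmax - 1L)),
                  bdard = p$gain)
  j <- 1:lmax  # states with a loss rate
  losses <- switch(kind,
                   bd = rep(p$beta, lmax),
                   cm = j * p$beta,
                   bdi = rep(p$beta, lmax),
                   bdard = p$loss)
  if (length(gains) != lmax || length(losses) != lmax) {
    stop("bdard needs 'gain' and 'loss' vectors of length lmax")
  }
  R <- matrix(0, lmax + 1L, lmax + 1L)
  for (s in seq_len(lmax)) {
    R[s, s + 1L] <- gains[s]
    R[s + 1L, s] <- losses[s]
  }
  diag(R) <- -rowSums(R)
  structure(list(R = R, kind = kind, lmax = lmax,
                 params = lapply(p, unname)),
            class = "rate_matrix")
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat("rate_matrix (", x$kind, "), lmax = ", x$lmax, "\n", sep = "")
  print(round(x$R, 4))
  invisible(x)
}

# superdiagonal gain rates g_0..g_{lmax-1}
rate_gains <- function(rm) rm$R[cbind(1:rm$lmax, 2:(rm$lmax + 1L))]
# subdiagonal loss rates d_1..d_lmax
rate_losses <- function(rm) rm$R[cbind(2:(rm$lmax + 1L), 1:rm$lmax)]

#' Recover model parameters from a generator
#'
#' Inverse of [build_rate_matrix()]: maps a tridiagonal generator back to the
#' free-parameter vector of the given model kind (exact for matrices built by
#' that kind).
#'
#' @inheritParams build_rate_matrix
#' @param R a \code{rate_matrix} or plain generator matrix.
#' @return named list of parameters.
#' @export
params_from_matrix <- function(R, kind = c("bd", "cm", "bdi", "bdard")) {
  kind <- match.arg(kind)
  if (inherits(R, "rate_matrix")) R <- R$R
  lmax <- nrow(R) - 1L
  gains <- R[cbind(1:lmax, 2:(lmax + 1L))]
  losses <- R[cbind(2:(lmax + 1L), 1:lmax)]
  switch(kind,
         bd = list(alpha = gains[1L], beta = losses[1L]),
         cm = list(alpha = gains[1L], beta = losses[1L],
                   gamma = if (lmax >= 2L) gains[2L] - gains[1L] else 0),
         bdi = list(delta = gains[1L],
                    alpha = if (lmax >= 2L) gains[2L] else gains[1L],
                    beta = losses[1L]),
         bdard = list(gain = gains, loss = losses))
}

# scale every free rate by c (all four kinds are linear in their rates)
scale_rate_matrix <- function(rm, c) {
  build_rate_matrix(rm$kind, lapply(rm$params, function(v) v * c), rm$lmax)
}

# Floor applied to rates before spectral decomposition; a strictly positive
# tridiagonal generator is similar to a symmetric matrix and therefore has a
# real eigensystem.
RATE_FLOOR <- 1e-8

#' Eigendecomposition of a birth-death generator
#'
#' Uses the diagonal similarity transform that symmetrizes a tridiagonal
#' generator with positive off-diagonals: with weights
#' \code{w_0 = 1, w_i = prod(g_{j-1}/d_j)}, \code{S = D R D^{-1}}
#' (\code{D = diag(sqrt(w))^{-1}}... computed in log space) is symmetric, so
#' all eigenvalues are real and the decomposition is numerically stable.
#' Rates below \code{1e-8} are floored before decomposition.
#'
#' @param rm a [build_rate_matrix()] object.
#' @return list with \code{values} (real eigenvalues, one of them 0),
#'   \code{U} (right eigenvectors as columns) and \code{Uinv} such that
#'   \code{R = U diag(values) Uinv}.
#' @export
rate_eigen <- function(rm) {
  lmax <- rm$lmax
  g <- pmax(rate_gains(rm), RATE_FLOOR)
  d <- pmax(rate_losses(rm), RATE_FLOOR)
  R <- matrix(0, lmax + 1L, lmax + 1L)
  for (s in seq_len(lmax)) {
    R[s, s + 1L] <- g[s]
    R[s + 1L, s] <- d[s]
  }
  diag(R) <- -rowSums(R)
  # log detailed-balance weights: w_0 = 0, w_i = sum log(g_{j-1}/d_j)
  logw <- c(0, cumsum(log(g) - log(d)))
  ds <- exp(0.5 * (logw - mean(logw)))  # center to avoid overflow
  S <- R * (ds %o% (1 / ds))            # S_ij = d_i R_ij / d_j, symmetric
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)
  U <- es$vectors / ds            # rows scaled: U = D^{-1} V
  Uinv <- t(es$vectors) * rep(ds, each = lmax + 1L)  # Uinv = V^T D
  err <- max(abs(U %*% (es$values * Uinv) - R))
  if (!is.finite(err) || err > 1e-8 * max(1, max(abs(R)))) {
    stop("eigendecomposition of the rate matrix failed (reconstruction error ",
         signif(err, 3), ")")
  }
  list(values = es$values, U = U, Uinv = Uinv, R = R)
}

#' Transition probability matrix
#'
#' \code{P(t) = exp(tR)} computed from the real eigensystem of the generator;
#' rows sum to one and tiny negative round-off entries are clipped to zero.
#'
#' @param rm a [build_rate_matrix()] object (or a precomputed [rate_eigen()]
#'   result).
#' @param t nonnegative elapsed time (same unit as the rates).
#' @return an \code{(lmax+1) x (lmax+1)} stochastic matrix.
#' @export
transition_matrix <- function(rm, t) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("'t' must be a single nonnegative number")
  }
  es <- if (inherits(rm, "rate_matrix")) rate_eigen(rm) else rm
  P <- es$U %*% (exp(t * es$values) * es$Uinv)
  P[P < 0] <- 0
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    stop("transition matrix rows do not sum to 1 (max deviation ",
         signif(max(abs(rs - 1)), 3), ")")
  }
  P / rs
}
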