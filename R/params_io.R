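# JSON parameter files: written after fitting, read back for reconstruction
# and held-out scoring.
# Schema: {model, hetero, K, lmax, phi[], clusters:[{gain[], loss[], pi[]}],
#          gamma_shape?, r?, loglik?, seed?, version}

#' Write mixture parameters to JSON
#'
#' @param theta a [mixture_params()] object.
#' @param path output path.
#' @param loglik,seed optional provenance fields recorded in the file.
#' @export
write_params <- function(theta, path, loglik = NULL, seed = NULL) {
  view <- cluster_view(theta)
  obj <- list(model = theta$kind, hetero = theta$hetero,
              K = theta$K, lmax = theta$lmax, phi = theta$phi,
              clusters = lapply(view, function(cl) {
                list(gain = rate_gains(cl$R), loss = rate_losses(cl$R),
                     pi = cl$pi)
              }),
              version = as.character(utils::packageVersion("gcevo")))
  if (theta$hetero == "gamma") obj$gamma_shape <- theta$gamma_shape
  if (theta$hetero == "pdf") obj$r <- theta$r
  if (!is.null(loglik)) obj$loglik <- loglik
  if (!is.null(seed)) obj$seed <- seed
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read mixture parameters from JSON
#'
#' Inverse of [write_params()]. For gamma/pdf models the per-cluster matrices
#' in the file are the scaled \code{r_k R}; the base matrix is recovered from
#' the stored multipliers.
#'
#' @param path path to a parameter JSON file.
#' @return a [mixture_params()] object.
#' @export
read_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- obj$K
  lmax <- obj$lmax
  cl <- obj$clusters
  mk <- function(gain, loss) {
    build_rate_matrix("bdard", list(gain = gain, loss = loss), lmax)
  }
  # reconstruct free parameters of the declared kind from the stored rates
  as_kind <- function(rm) {
    build_rate_matrix(obj$model, params_from_matrix(rm, obj$model), lmax)
  }
  get_cl <- function(k, field) {
    if (is.data.frame(cl)) cl[[field]][[k]] else cl[[k]][[field]]
  }
  if (obj$hetero == "pm") {
    rates <- lapply(seq_len(K), function(k) as_kind(mk(get_cl(k, "gain"), get_cl(k, "loss"))))
    pi <- t(vapply(seq_len(K), function(k) as.numeric(get_cl(k, "pi")),
                   numeric(lmax + 1L)))
    mixture_params(obj$model, "pm", K, lmax, phi = obj$phi, rates = rates,
                   pi = pi)
  } else {
    r <- if (obj$hetero == "pdf") obj$r else gamma_category_rates(obj$gamma_shape, K)
    base <- as_kind(scale_rate_matrix(mk(get_cl(1L, "gain"), get_cl(1L, "loss")),
                                      1 / r[1L]))
    if (obj$hetero == "pdf") {
      mixture_params(obj$model, "pdf", K, lmax, phi = obj$phi, rates = base,
                     pi = as.numeric(get_cl(1L, "pi")), r = r)
    } else {
      mixture_params(obj$model, "gamma", K, lmax, rates = base,
                     pi = as.numeric(get_cl(1L, "pi")),
                     gamma_shape = obj$gamma_shape)
    }
  }
}

#' Worked-example archaeal cluster parameters
#'
#' A published BDARD + pattern-mixture fit to an archaeal ortholog table
#' (151 genomes, K = 5 clusters, lmax = 3), with parameters rounded to three
#' decimals. Used as the worked example for [normalized_cluster_rates()]: the
#' five clusters span almost two orders of magnitude in evolutionary rate.
#'
#' @return a [mixture_params()] object (BDARD + PM, K = 5, lmax = 3).
#' @export
example_archaea_params <- function() {
  phi <- c(0.318, 0.316, 0.269, 0.058, 0.039)
  pi <- rbind(c(0.305, 0.226, 0.051, 0.418),
              c(0.001, 0.955, 0.000, 0.044),
              c(0.848, 0.122, 0.023, 0.008),
              c(0.399, 0.466, 0.000, 0.135),
              c(0.539, 0.134, 0.025, 0.302))
  gain <- rbind(c(0.153, 1.591, 3.480),
                c(0.017, 0.310, 0.981),
                c(0.029, 0.059, 0.290),
                c(0.207, 0.316, 0.847),
                c(0.584, 2.029, 1.744))
  loss <- rbind(c(8.067, 11.767, 6.571),
                c(2.414, 4.540, 3.381),
                c(0.095, 0.591, 0.314),
                c(0.439, 1.792, 2.512),
                c(2.300, 5.649, 1.538))
  rates <- lapply(1:5, function(k) {
    build_rate_matrix("bdard", list(gain = gain[k, ], loss = loss[k, ]), 3L)
  })
  mixture_params("bdard", "pm", K = 5L, lmax = 3L, phi = phi, rates = rates,
                 pi = pi)
}
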