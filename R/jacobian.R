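## Zero-filled copies of the per-patch parameter vectors. Entries a species
## never uses are stored as NA in gm_params; arithmetic below multiplies them
## by structural zeros, so they are replaced by 0 first.
patch_pars <- function(web, params, k) {
  stopifnot(inherits(web, "food_web"), inherits(params, "gm_params"),
            k >= 1, k <= params$N, web$S == params$S)
  zf <- function(x) ifelse(is.na(x), 0, x)
  list(rho = params$rho,
       sigma = params$sigma[k, ],
       phi = zf(params$phi[k, ]),
       psi = zf(params$psi[k, ]),
       gamma = zf(params$gamma[k, ]),
       mu = params$mu[k, ],
       beta = params$beta[, , k],
       chi = params$chi[, , k])
}

#' Local food web Jacobian from generalized-model parameters
#'
#' Builds the S x S Jacobian of the normalized local dynamics, evaluated at
#' the normalized steady state b = 1, for patch `k`. Writing b_n for the
#' normalized density of species n, the entry in row n, column m is
#' \deqn{J_{nm} = \alpha_n [ (1-\rho_n)\phi_n \delta_{nm}
#'   + \rho_n(\gamma_n \chi_{nm} + \psi_n \delta_{nm})
#'   - (1-\sigma_n)\mu_n \delta_{nm}
#'   - \sigma_n \sum_j \beta_{nj}(\delta_{nm} + (\gamma_j - 1)\chi_{jm}
#'       + \psi_j \delta_{jm}) ]}
#' where the sum runs over the predators j of n. An entry is structurally
#' zero unless m = n, m is prey of n, m is a predator of n, or n and m share
#' a predator. The analytic expression is validated in the test suite
#' against central finite differences of [normalized_rhs()].
#'
#' @param web a `food_web`.
#' @param params a `gm_params` sampled for this web.
#' @param k patch index.
#' @return S x S numeric matrix.
#' @seealso [normalized_rhs()], [local_jacobians()]
#' @export
local_jacobian <- function(web, params, k) {
  p <- patch_pars(web, params, k)
  S <- web$S
  alpha <- web$turnover
  ## gains: producers phi on the diagonal, consumers gamma * chi + psi
  J <- (p$rho * p$gamma) * p$chi                         # row-scaled
  ## losses through predators: shared-prey and predator-density terms
  pred_loss <- p$beta %*% ((p$gamma - 1) * p$chi) +      # rows j scaled
    sweep(p$beta, 2, p$psi, `*`)                         # beta[n, m] psi_m
  J <- J - p$sigma * pred_loss
  diag(J) <- diag(J) +
    ifelse(p$rho == 1, p$psi, p$phi) -                   # self-density gain
    (1 - p$sigma) * p$mu -                               # mortality
    p$sigma                                              # sum_j beta_nj = 1
  alpha * J
}

#' All local Jacobians of a metacommunity's patches
#'
#' @param web a `food_web`.
#' @param params a `gm_params`.
#' @return list of N matrices, one per patch.
#' @export
local_jacobians <- function(web, params) {
  lapply(seq_len(params$N), function(k) local_jacobian(web, params, k))
}

#' Normalized local dynamics (power-law realization)
#'
#' Evaluates the right-hand side of the normalized local dynamics for patch
#' `k` using concrete power-law realizations whose elasticities at b = 1
#' equal the sampled parameters exactly: producer growth \eqn{g(b) = b^\phi},
#' mortality \eqn{x(b) = b^\mu}, predation gain
#' \eqn{f(c, b) = b^\psi c^\gamma} with available food
#' \eqn{c_j = \sum_i \chi_{ji} b_i} (prey-contribution elasticity
#' \eqn{\lambda = 1}), and normalized loss of prey n to predator j
#' \eqn{e_{jn} = b_j^{\psi_j} c_j^{\gamma_j - 1} b_n}. Every normalized rate
#' equals 1 at the steady state b = 1, so the returned growth rates are 0
#' there; central finite differences of this function at b = 1 reproduce
#' [local_jacobian()].
#'
#' @param web a `food_web`.
#' @param params a `gm_params`.
#' @param k patch index.
#' @param b positive numeric vector of normalized densities, length S.
#' @return numeric vector of per-species normalized growth rates.
#' @export
normalized_rhs <- function(web, params, k, b) {
  stopifnot(length(b) == web$S, all(b > 0))
  p <- patch_pars(web, params, k)
  alpha <- web$turnover
  consumers <- p$rho == 1
  cvec <- as.vector(p$chi %*% b)          # total food available, lambda = 1
  gain <- b^p$phi                          # producers: g(b) = b^phi
  gain[consumers] <- b[consumers]^p$psi[consumers] *
    cvec[consumers]^p$gamma[consumers]     # consumers: f(c, b)
  mortality <- b^p$mu
  w <- numeric(web$S)                      # predator-side factor of e_jn
  w[consumers] <- b[consumers]^p$psi[consumers] *
    cvec[consumers]^(p$gamma[consumers] - 1)
  predation <- as.vector(p$beta %*% w) * b
  alpha * (gain - (1 - p$sigma) * mortality - p$sigma * predation)
}
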