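#' Default generalized-model parameter ranges
#'
#' Uniform sampling ranges for the spatially variable branching and
#' elasticity parameters. The branching fractions sigma (loss to
#' predation), beta (share of a prey's predation loss per predator) and
#' chi (share of a consumer's gains per prey) are drawn on [0, 1]; beta
#' and chi are subsequently normalized to sum to one over a species'
#' predators and prey respectively, and sigma is forced to 0 for species
#' without predators. Elasticities: phi (producer growth, nutrient
#' availability), psi (predator self-density), gamma (total prey density,
#' i.e. functional-response saturation), mu (mortality density
#' dependence). The prey-contribution elasticity lambda is fixed at 1
#' (constant foraging preferences).
#'
#' @return Named list of length-2 numeric ranges plus the fixed `lambda`.
#' @export
gm_ranges <- function() {
  list(sigma = c(0, 1),
       phi   = c(0, 1),
       psi   = c(0.5, 1),
       gamma = c(0.5, 1.5),
       mu    = c(1, 1.5),
       lambda = 1)
}

#' Sample per-patch generalized-model parameters for a food web
#'
#' Draws all spatially variable branching and elasticity parameters
#' independently per patch and per species (per feeding link for beta and
#' chi) from uniform distributions, then normalizes so the generalized
#' model's steady-state bookkeeping holds: for every prey with at least
#' one predator the beta shares sum to 1 over its predators, for every
#' consumer the chi shares sum to 1 over its prey, and sigma is exactly 0
#' for species nothing eats. The gain branching rho is 1 for species with
#' prey and 0 for producers, identical in all patches. Parameters that a
#' species never uses (phi for consumers; psi and gamma for producers)
#' are stored as NA.
#'
#' @param web a `food_web`.
#' @param N number of patches.
#' @param ranges sampling ranges, see [gm_ranges()].
#' @return An object of class `gm_params`: list with `S`, `N`, `rho`
#'   (length S, 0/1), N x S matrices `sigma`, `phi`, `psi`, `gamma`, `mu`
#'   (rows are patches), S x S x N arrays `beta` (`beta[i, j, k]` =
#'   fraction of i's predation loss taken by predator j in patch k) and
#'   `chi` (`chi[j, i, k]` = fraction of consumer j's gains coming from
#'   prey i in patch k), and the fixed `lambda`.
#' @examples
#' set.seed(1)
#' web <- niche_web(10, 0.15)
#' p <- sample_patch_params(web, N = 10)
#' range(rowSums(p$chi[, , 1])[p$rho == 1]) # consumer chi shares sum to 1
#' @export
sample_patch_params <- function(web, N, ranges = gm_ranges()) {
  stopifnot(inherits(web, "food_web"), N >= 1)
  S <- web$S
  feeding <- web$feeding
  has_prey <- rowSums(feeding) > 0
  has_pred <- colSums(feeding) > 0
  rho <- as.integer(has_prey)

  draw <- function(range) matrix(runif(N * S, range[1], range[2]), N, S)
  sigma <- draw(ranges$sigma)
  sigma[, !has_pred] <- 0
  phi <- draw(ranges$phi)
  phi[, has_prey] <- NA_real_
  psi <- draw(ranges$psi)
  psi[, !has_prey] <- NA_real_
  gamma <- draw(ranges$gamma)
  gamma[, !has_prey] <- NA_real_
  mu <- draw(ranges$mu)

  beta <- array(0, c(S, S, N))
  chi <- array(0, c(S, S, N))
  pred_mask <- t(feeding)  # pred_mask[i, j]: j eats i
  for (k in seq_len(N)) {
    raw_b <- matrix(runif(S * S), S, S) * pred_mask
    rs <- rowSums(raw_b)
    beta[, , k] <- raw_b / ifelse(rs > 0, rs, 1)
    raw_c <- matrix(runif(S * S), S, S) * feeding
    rs <- rowSums(raw_c)
    chi[, , k] <- raw_c / ifelse(rs > 0, rs, 1)
  }

  structure(list(S = S, N = N, rho = rho, sigma = sigma, phi = phi,
                 psi = psi, gamma = gamma, mu = mu, beta = beta, chi = chi,
                 lambda = ranges$lambda, ranges = ranges),
            class = "gm_params")
}

#' @export
print.gm_params <- function(x, ...) {
  cat("generalized-model parameter set\n")
  cat("  species:", x$S, "  patches:", x$N, "\n")
  cat("  producers:", sum(x$rho == 0), " consumers:", sum(x$rho == 1), "\n")
  invisible(x)
}

#' Serialize generalized-model parameters to a long-form table
#'
#' One row per (parameter, patch, species) scalar entry and per
#' (parameter, patch, link) entry for beta and chi. `table_to_params()`
#' inverts the operation.
#'
#' @param params a `gm_params`.
#' @return A data.frame with columns `parameter`, `patch`, `i`, `j`
#'   (NA for non-link parameters) and `value`.
#' @export
params_to_table <- function(params) {
  stopifnot(inherits(params, "gm_params"))
  S <- params$S
  N <- params$N
  rows <- list()
  rows[[1]] <- data.frame(parameter = "rho", patch = NA_integer_,
                          i = seq_len(S), j = NA_integer_,
                          value = as.numeric(params$rho))
  for (nm in c("sigma", "phi", "psi", "gamma", "mu")) {
    m <- params[[nm]]
    rows[[length(rows) + 1]] <- data.frame(
      parameter = nm,
      patch = rep(seq_len(N), times = S),
      i = rep(seq_len(S), each = N),
      j = NA_integer_,
      value = as.numeric(m))
  }
  for (nm in c("beta", "chi")) {
    a <- params[[nm]]
    nz <- which(a != 0, arr.ind = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      parameter = nm,
      patch = as.integer(nz[, 3]),
      i = as.integer(nz[, 1]),
      j = as.integer(nz[, 2]),
      value = a[nz])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname params_to_table
#' @param tab a data.frame produced by [params_to_table()].
#' @param ranges the ranges to record on the rebuilt object.
#' @export
table_to_params <- function(tab, ranges = gm_ranges()) {
  S <- max(tab$i, na.rm = TRUE)
  N <- max(tab$patch, na.rm = TRUE)
  take <- function(nm) tab[tab$parameter == nm, , drop = FALSE]
  rho <- as.integer(take("rho")$value[order(take("rho")$i)])
  scalar <- function(nm) {
    d <- take(nm)
    m <- matrix(NA_real_, N, S)
    m[cbind(d$patch, d$i)] <- d$value
    m
  }
  arr <- function(nm) {
    d <- take(nm)
    a <- array(0, c(S, S, N))
    if (nrow(d)) a[cbind(d$i, d$j, d$patch)] <- d$value
    a
  }
  structure(list(S = S, N = N, rho = rho, sigma = scalar("sigma"),
                 phi = scalar("phi"), psi = scalar("psi"),
                 gamma = scalar("gamma"), mu = scalar("mu"),
                 beta = arr("beta"), chi = arr("chi"),
                 lambda = ranges$lambda, ranges = ranges),
            class = "gm_params")
}

#' Write / read generalized-model parameters as CSV
#'
#' @param params a `gm_params`.
#' @param path file path.
#' @return `write_params_csv()` returns `path` invisibly;
#'   `read_params_csv()` returns a `gm_params`.
#' @export
write_params_csv <- function(params, path) {
  write.csv(params_to_table(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  table_to_params(read.csv(path))
}
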