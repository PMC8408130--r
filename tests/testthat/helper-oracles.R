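# Independent oracles and small constructors shared across tests.

# Central finite differences of the normalized dynamics at b = 1; the
# power-law realizations have constant elasticities, so this approximates
# the local Jacobian up to O(h^2) truncation error.
fd_jacobian <- function(web, params, k, h = 1e-5) {
  S <- web$S
  J <- matrix(0, S, S)
  for (m in seq_len(S)) {
    up <- rep(1, S); up[m] <- 1 + h
    dn <- rep(1, S); dn[m] <- 1 - h
    J[, m] <- (normalized_rhs(web, params, k, up) -
                 normalized_rhs(web, params, k, dn)) / (2 * h)
  }
  J
}

# Shortest consumer->prey path length to any producer, via igraph's BFS
# distances (independent of the package's level-set computation).
igraph_trophic_positions <- function(feeding) {
  paths <- feeding
  diag(paths) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(paths * 1, mode = "directed")
  producers <- which(rowSums(feeding) == 0)
  dmat <- igraph::distances(g, to = producers, mode = "out")
  as.integer(apply(dmat, 1, min))
}

# Linear chain: species i eats species i - 1; species 1 is the producer.
chain_web <- function(S, R = 42) {
  feeding <- matrix(FALSE, S, S)
  for (i in 2:S) feeding[i, i - 1] <- TRUE
  as_food_web(feeding, R = R)
}

# One random retained (web, spatial network, params) triple.
random_system <- function(S, C, N = 4, radius = 0.6, R = 42) {
  web <- niche_web(S, C, R = R)
  net <- rgg_network(N, radius)
  params <- sample_patch_params(web, N)
  list(web = web, net = net, params = params)
}

# Multiset comparison of two complex spectra by greedy nearest matching.
# (Sorting by real part is not usable here: conjugate pairs tie in Re up to
# numerical jitter, so lexicographic order can pair eigenvalues across
# different conjugate pairs.)
expect_spectra_equal <- function(a, b, tol = 1e-8) {
  expect_equal(length(a), length(b))
  a <- as.complex(a)
  b <- as.complex(b)
  worst <- 0
  for (x in a) {
    i <- which.min(Mod(b - x))
    worst <- max(worst, Mod(b[i] - x))
    b <- b[-i]
  }
  expect_lt(worst, tol)
}

# Exact stability classification used as reference in categorization tests.
sign_category <- function(lambda_orig, median_perm) {
  orig_stable <- lambda_orig < 0
  med_stable <- median_perm < 0
  if (orig_stable == med_stable) "stability unaffected"
  else if (med_stable) "stability gained" else "stability lost"
}
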