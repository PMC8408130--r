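#' Deterministic per-run seed derivation
#'
#' Derives the seed of run `i` from a master seed by a counter-based linear
#' congruential step, so that any single run of an ensemble can be
#' regenerated in isolation. All arithmetic stays exact in double precision
#' and the result lies in [0, 2^31 - 2].
#'
#' @param seed integer master seed.
#' @param i run counter (>= 1).
#' @return integer seed.
#' @export
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 16807 + 1) %%
               2147483647)
}

#' Ensemble sweep configuration
#'
#' Defines the grids of a stability sweep. Grid values are validated
#' against the study's parameter ranges: S in [10, 30], C in [0.12, 0.24],
#' d in [1e-4, 1], z in [-0.75, 0.75].
#'
#' @param S_grid species richness values.
#' @param C_grid connectance values.
#' @param d_grid global link strengths.
#' @param z_grid allometric dispersal exponents.
#' @param webs_per_cell independent (web, spatial network, parameter)
#'   triples per (S, C) cell.
#' @param n_perm dispersal permutations per metacommunity (0 disables the
#'   permutation analysis).
#' @param perm_mode `"exact"` or `"sign"`, see [permutation_analysis()].
#' @param N number of habitat patches.
#' @param radius random-geometric-graph connection threshold.
#' @param R body mass ratio per trophic level.
#' @param master_seed integer seed; per-run seeds derive from it via
#'   [derive_seed()].
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(S_grid = seq(10, 30, by = 2),
                            C_grid = seq(0.12, 0.24, by = 0.02),
                            d_grid = 10^seq(-4, 0),
                            z_grid = seq(-0.75, 0.75, by = 0.25),
                            webs_per_cell = 1,
                            n_perm = 0,
                            perm_mode = "exact",
                            N = 10, radius = 0.32, R = 42,
                            master_seed = 1) {
  stopifnot(length(S_grid) >= 1, length(C_grid) >= 1, length(d_grid) >= 1,
            length(z_grid) >= 1, webs_per_cell >= 1,
            all(S_grid >= 10 & S_grid <= 30),
            all(C_grid >= 0.12 & C_grid <= 0.24),
            all(d_grid >= 1e-4 & d_grid <= 1),
            all(z_grid >= -0.75 & z_grid <= 0.75))
  structure(list(S_grid = S_grid, C_grid = C_grid, d_grid = d_grid,
                 z_grid = z_grid, webs_per_cell = webs_per_cell,
                 n_perm = n_perm, perm_mode = perm_mode, N = N,
                 radius = radius, R = R, master_seed = master_seed),
            class = "ensemble_config")
}

#' Read an ensemble configuration from a YAML file
#'
#' Keys mirror the arguments of [ensemble_config()]; missing keys take the
#' defaults.
#'
#' @param path YAML file path.
#' @return An `ensemble_config`.
#' @export
read_ensemble_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(ensemble_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(ensemble_config, vals)
}

## Spatial means and variances of selected generalized-model parameters,
## used as GLM predictors: saturation gamma (consumers), nutrient
## availability phi (producers) and interaction-strength shares chi
## (feeding links). The mean pools every patch x entry value; the variance
## is the across-patch variance averaged over entries.
spatial_param_summaries <- function(web, params) {
  N <- params$N
  consumers <- params$rho == 1
  msd <- function(m) { # patches in rows
    if (!ncol(m)) return(c(NA_real_, NA_real_))
    c(mean(m), if (N > 1) mean(apply(m, 2, var)) else 0)
  }
  g <- msd(params$gamma[, consumers, drop = FALSE])
  ph <- msd(params$phi[, !consumers, drop = FALSE])
  links <- which(web$feeding, arr.ind = TRUE)
  chi_vals <- vapply(seq_len(N),
                     function(k) params$chi[, , k][links],
                     numeric(nrow(links)))
  if (is.null(dim(chi_vals))) chi_vals <- matrix(chi_vals, nrow = 1)
  ch <- msd(t(chi_vals))
  c(mean_gamma = g[1], var_gamma = g[2], mean_phi = ph[1], var_phi = ph[2],
    mean_chi = ch[1], var_chi = ch[2])
}

#' Run a metacommunity stability ensemble
#'
#' For every (S, C) cell, generates `webs_per_cell` independent base
#' systems (niche web, connected random geometric graph, per-patch
#' generalized-model parameters), then evaluates metacommunity stability at
#' every (d, z) combination, optionally with a dispersal permutation
#' analysis. Deterministic under `master_seed`: base system `i` uses seed
#' `derive_seed(master_seed, i)` and its permutations at combination `j`
#' use `derive_seed(derive_seed(master_seed, i), j)`. Base systems whose
#' generation fails are logged in the `failures` attribute and skipped,
#' never silently dropped.
#'
#' @param config an `ensemble_config`.
#' @param verbose print per-cell progress messages.
#' @return A long-form data.frame with one row per (base system, d, z):
#'   columns `web_id`, `seed`, `S`, `C`, `N`, `d`, `z`,
#'   `prop_local_stable`, `lambda1`, `stable`, `category`,
#'   `median_permuted` and the spatial summaries `mean_gamma`, `var_gamma`,
#'   `mean_phi`, `var_phi`, `mean_chi`, `var_chi`. Attribute `failures`
#'   holds a data.frame of failed base systems (zero rows when none).
#' @export
run_ensemble <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ensemble_config"))
  cells <- expand.grid(S = config$S_grid, C = config$C_grid,
                       w = seq_len(config$webs_per_cell))
  combos <- expand.grid(d = config$d_grid, z = config$z_grid)
  records <- vector("list", nrow(cells))
  failures <- list()
  for (i in seq_len(nrow(cells))) {
    seed <- derive_seed(config$master_seed, i)
    records[[i]] <- tryCatch(
      ensemble_one(i, seed, cells$S[i], cells$C[i], combos, config),
      error = function(e) {
        failures[[length(failures) + 1]] <<- data.frame(
          web_id = i, S = cells$S[i], C = cells$C[i], seed = seed,
          error = conditionMessage(e))
        message("base system ", i, " failed and was skipped: ",
                conditionMessage(e))
        NULL
      })
    if (verbose && (i %% 25 == 0)) {
      message("ensemble: ", i, " / ", nrow(cells), " base systems done")
    }
  }
  out <- do.call(rbind, records)
  attr(out, "failures") <- if (length(failures)) {
    do.call(rbind, failures)
  } else {
    data.frame(web_id = integer(), S = integer(), C = numeric(),
               seed = integer(), error = character())
  }
  out
}

ensemble_one <- function(i, seed, S, C, combos, config) {
  set.seed(seed)
  web <- niche_web(S, C, R = config$R)
  net <- rgg_network(config$N, config$radius)
  params <- sample_patch_params(web, config$N)
  meta <- metacommunity(web, net, params)
  sums <- spatial_param_summaries(web, params)
  rows <- vector("list", nrow(combos))
  for (j in seq_len(nrow(combos))) {
    d <- combos$d[j]
    z <- combos$z[j]
    st <- stability(meta, d, z)
    category <- NA_character_
    median_permuted <- NA_real_
    if (config$n_perm > 0) {
      set.seed(derive_seed(seed, j))
      pa <- permutation_analysis(meta, d, z, n_perm = config$n_perm,
                                 mode = config$perm_mode)
      category <- pa$category
      median_permuted <- pa$median_permuted
    }
    rows[[j]] <- data.frame(
      web_id = i, seed = seed, S = S, C = C, N = config$N, d = d, z = z,
      prop_local_stable = st$prop_local_stable, lambda1 = st$lambda1,
      stable = st$metacommunity_stable, category = category,
      median_permuted = median_permuted,
      mean_gamma = sums[["mean_gamma"]], var_gamma = sums[["var_gamma"]],
      mean_phi = sums[["mean_phi"]], var_phi = sums[["var_phi"]],
      mean_chi = sums[["mean_chi"]], var_chi = sums[["var_chi"]])
  }
  do.call(rbind, rows)
}

#' Metacommunity stability by proportion of locally stable patches
#'
#' Bins ensemble records by the exact proportion of locally stable patches
#' (multiples of 1/N) within each (d, z) combination and reports the
#' fraction of stable metacommunities with its binomial standard error
#' sqrt(p (1 - p) / n). Empty bins are simply absent from the table.
#'
#' @param results a data.frame from [run_ensemble()].
#' @return data.frame with columns `d`, `z`, `prop_local_stable`, `n`,
#'   `frac_stable`, `sem`.
#' @export
stability_by_local_proportion <- function(results) {
  stopifnot(nrow(results) > 0)
  key <- interaction(results$d, results$z, results$prop_local_stable,
                     drop = TRUE)
  parts <- split(results, key)
  out <- do.call(rbind, lapply(parts, function(g) {
    p <- mean(g$stable)
    data.frame(d = g$d[1], z = g$z[1],
               prop_local_stable = g$prop_local_stable[1],
               n = nrow(g), frac_stable = p,
               sem = sqrt(p * (1 - p) / nrow(g)))
  }))
  out <- out[order(out$d, out$z, out$prop_local_stable), ]
  rownames(out) <- NULL
  out
}

#' Binomial GLM attribution of metacommunity stability with AIC selection
#'
#' Fits logit-link binomial GLMs for metacommunity stability on every
#' subset of the candidate predictors (including the intercept-only
#' model), computes Akaike's information criterion for each submodel and
#' returns the minimum-AIC fit. Default candidates are the study's global
#' model: richness S, connectance C, link strength d, dispersal allometry
#' z, and the per-metacommunity spatial means and variances of
#' functional-response saturation (gamma), producer nutrient availability
#' (phi) and interaction-strength shares (chi). Predictors are centred and
#' scaled to unit variance before fitting so coefficient magnitudes are
#' comparable; constant predictors are dropped with a warning. Submodels
#' that fail to converge or show complete separation are excluded from the
#' selection with a warning.
#'
#' @param results a data.frame from [run_ensemble()].
#' @param candidates character vector of predictor column names.
#' @param standardize centre/scale predictors (default TRUE).
#' @return An object of class `stability_glm`: list with `aic_table`
#'   (one row per submodel: `terms`, `k`, `aic`, `status`), `best_terms`,
#'   `coefficients` (estimate, std. error, z value, p), `fit` (the glm
#'   object) and `n`.
#' @export
fit_stability_glm <- function(results,
                              candidates = c("S", "C", "d", "z",
                                             "mean_gamma", "var_gamma",
                                             "mean_phi", "var_phi",
                                             "mean_chi", "var_chi"),
                              standardize = TRUE) {
  stopifnot(nrow(results) >= 50, all(candidates %in% names(results)),
            length(unique(results$stable)) == 2)
  if (length(candidates) > 12) {
    stop("at most 12 candidate terms are supported (all-subset search)",
         call. = FALSE)
  }
  dat <- results[, c("stable", candidates)]
  constant <- vapply(dat[candidates],
                     function(x) var(x, na.rm = TRUE) == 0 || all(is.na(x)),
                     TRUE)
  if (any(constant)) {
    warning("dropping constant predictors: ",
            paste(candidates[constant], collapse = ", "), call. = FALSE)
    candidates <- candidates[!constant]
  }
  if (standardize) {
    dat[candidates] <- lapply(dat[candidates],
                              function(x) as.numeric(scale(x)))
  }
  nsub <- 2^length(candidates)
  aic_rows <- vector("list", nsub)
  fits <- vector("list", nsub)
  for (m in seq_len(nsub)) {
    in_model <- as.logical(bitwAnd(m - 1, 2^(seq_along(candidates) - 1)))
    terms <- candidates[in_model]
    fml <- if (length(terms)) {
      as.formula(paste("stable ~", paste(terms, collapse = " + ")))
    } else {
      stable ~ 1
    }
    status <- "ok"
    fit <- withCallingHandlers(
      glm(fml, family = binomial(link = "logit"), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) status <<- "separation"
        invokeRestart("muffleWarning")
      })
    if (!fit$converged) status <- "non-convergence"
    if (status != "ok") {
      warning("submodel {", paste(terms, collapse = ", "), "} excluded: ",
              status, call. = FALSE)
    }
    fits[[m]] <- fit
    aic_rows[[m]] <- data.frame(
      terms = paste(terms, collapse = "+"),
      k = length(coef(fit)), aic = AIC(fit), status = status)
  }
  aic_table <- do.call(rbind, aic_rows)
  ok <- aic_table$status == "ok"
  if (!any(ok)) stop("no submodel converged cleanly", call. = FALSE)
  best_idx <- which(ok)[which.min(aic_table$aic[ok])]
  best <- fits[[best_idx]]
  structure(list(aic_table = aic_table[order(aic_table$aic), ],
                 best_terms = setdiff(names(coef(best)), "(Intercept)"),
                 coefficients = summary(best)$coefficients,
                 fit = best, n = nrow(dat)),
            class = "stability_glm")
}

#' @export
print.stability_glm <- function(x, ...) {
  cat("binomial GLM for metacommunity stability (", x$n, " records, ",
      nrow(x$aic_table), " submodels)\n", sep = "")
  cat("  minimum-AIC model:", if (length(x$best_terms))
    paste(x$best_terms, collapse = " + ") else "(intercept only)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Sign changes under dispersal permutation across the (d, z) grid
#'
#' Generates `n_meta` base metacommunities (cycling through the (S, C)
#' cells), evaluates each at every (d, z) combination and runs the
#' dispersal permutation analysis, recording whether the sign of the
#' median permuted leading eigenvalue differs from the original one. The
#' per-combination fraction of such qualitative stability changes is the
#' quantity bounded by 25% in the study.
#'
#' @param n_meta number of base metacommunities shared across combinations.
#' @param S_values,C_values cells cycled over when generating webs.
#' @param d_values,z_values dispersal grids.
#' @param n_perm permutations per metacommunity and combination.
#' @param N,radius,R study constants, see [ensemble_config()].
#' @param master_seed integer seed.
#' @param mode permutation mode, see [permutation_analysis()].
#' @param verbose print progress messages.
#' @return list with `by_combination` (data.frame: `d`, `z`, `n`,
#'   `n_changed`, `frac_changed`) and `max_frac_changed`.
#' @export
dispersal_permutation_grid <- function(n_meta = 100,
                                       S_values = c(10, 20, 30),
                                       C_values = c(0.12, 0.18, 0.24),
                                       d_values = 10^seq(-4, 0),
                                       z_values = seq(-0.75, 0.75,
                                                      by = 0.25),
                                       n_perm = 20,
                                       N = 10, radius = 0.32, R = 42,
                                       master_seed = 1,
                                       mode = "sign",
                                       verbose = FALSE) {
  cells <- expand.grid(S = S_values, C = C_values)
  combos <- expand.grid(d = d_values, z = z_values)
  changed <- matrix(0L, nrow(combos), 2,
                    dimnames = list(NULL, c("n", "n_changed")))
  for (i in seq_len(n_meta)) {
    cell <- cells[((i - 1) %% nrow(cells)) + 1, ]
    seed <- derive_seed(master_seed, i)
    set.seed(seed)
    web <- niche_web(cell$S, cell$C, R = R)
    net <- rgg_network(N, radius)
    params <- sample_patch_params(web, N)
    meta <- metacommunity(web, net, params)
    for (j in seq_len(nrow(combos))) {
      set.seed(derive_seed(seed, j))
      pa <- permutation_analysis(meta, combos$d[j], combos$z[j],
                                 n_perm = n_perm, mode = mode)
      changed[j, "n"] <- changed[j, "n"] + 1L
      changed[j, "n_changed"] <- changed[j, "n_changed"] +
        (pa$category != "stability unaffected")
    }
    if (verbose && (i %% 10 == 0)) {
      message("permutation grid: ", i, " / ", n_meta,
              " metacommunities done")
    }
  }
  by_combination <- cbind(combos, as.data.frame(changed))
  by_combination$frac_changed <- by_combination$n_changed / by_combination$n
  list(by_combination = by_combination,
       max_frac_changed = max(by_combination$frac_changed))
}
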