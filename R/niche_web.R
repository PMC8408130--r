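#' Generate a niche-model food web with allometric body masses
#'
#' Draws food web topologies from the niche model: each species receives a
#' niche value \eqn{n_i \sim U(0,1)} and consumes every species whose niche
#' value falls inside a feeding interval of width \eqn{r_i = x n_i}, where
#' \eqn{x \sim Beta(1, 1/(2C) - 1)} so that the expected width fraction is
#' \eqn{2C}, and the interval centre is drawn uniformly on
#' \eqn{[r_i/2, n_i]}. Webs are regenerated until they pass a retention
#' filter: at least one basal producer, a single connected component when
#' links are treated as undirected, and a directed path from every consumer
#' to some producer (required for trophic positions to be defined).
#'
#' Retained webs are annotated with trophic positions (shortest directed
#' path to a producer), body masses \eqn{M_i = R^{T_i}} and mass-specific
#' turnover rates \eqn{\alpha_i = M_i^{-1/4}}.
#'
#' @param S integer species richness (>= 2).
#' @param C target connectance, links / S^2, in (0, 0.5).
#' @param R consumer-resource body mass ratio per trophic level (default 42,
#'   the average empirical predator-prey mass ratio).
#' @param allow_cannibalism keep self-links produced by the niche model
#'   (default TRUE). Self-links never enter trophic-position paths.
#' @param max_attempts regeneration budget before the (S, C) combination is
#'   declared infeasible.
#' @return An object of class `food_web`: a list with elements `S`,
#'   `C_target`, `niche`, `feeding` (S x S logical, `feeding[i, j]` TRUE when
#'   i eats j), `realized_connectance`, `trophic_position`, `mass`,
#'   `turnover` and `R`.
#' @examples
#' set.seed(1)
#' web <- niche_web(S = 15, C = 0.15)
#' web$realized_connectance
#' table(web$trophic_position)
#' @seealso [trophic_positions()], [assign_allometry()], [as_food_web()]
#' @export
niche_web <- function(S, C, R = 42, allow_cannibalism = TRUE,
                      max_attempts = 10000) {
  stopifnot(S >= 2, C > 0, C < 0.5, R > 0, max_attempts >= 1)
  for (attempt in seq_len(max_attempts)) {
    niche <- runif(S)
    width <- draw_range_fractions(S, C) * niche
    centre <- runif(S, min = width / 2, max = niche)
    lo <- centre - width / 2
    hi <- centre + width / 2
    feeding <- matrix(FALSE, S, S)
    for (i in seq_len(S)) {
      feeding[i, ] <- niche >= lo[i] & niche <= hi[i]
    }
    if (!allow_cannibalism) diag(feeding) <- FALSE
    if (web_retained(feeding)) {
      return(as_food_web(feeding, R = R, niche = niche, C_target = C))
    }
  }
  stop("no retained niche web in ", max_attempts, " attempts; (S = ", S,
       ", C = ", C, ") appears infeasible", call. = FALSE)
}

#' Beta-distributed feeding-range fractions
#'
#' The niche model draws the feeding range of species i as a fraction x of
#' its niche value, with x ~ Beta(1, 1/(2C) - 1) so that E[x] = 2C and the
#' expected connectance of the web equals C.
#'
#' @param n number of draws.
#' @param C target connectance in (0, 0.5).
#' @return numeric vector of n fractions in (0, 1).
#' @keywords internal
draw_range_fractions <- function(n, C) {
  stopifnot(C > 0, C < 0.5)
  rbeta(n, shape1 = 1, shape2 = 1 / (2 * C) - 1)
}

## Retention filter: producer present, undirected single component, and a
## directed consumer->prey path from every species to some producer.
web_retained <- function(feeding) {
  S <- nrow(feeding)
  producers <- rowSums(feeding) == 0
  if (!any(producers)) return(FALSE)
  undirected <- feeding | t(feeding)
  diag(undirected) <- FALSE
  if (!graph_connected(undirected)) return(FALSE)
  ## backward reachability from producers along reversed prey links
  prey_links <- feeding
  diag(prey_links) <- FALSE
  reach <- producers
  repeat {
    newly <- rowSums(prey_links[, reach, drop = FALSE]) > 0 & !reach
    if (!any(newly)) break
    reach <- reach | newly
  }
  all(reach)
}

## Connectivity of a symmetric logical adjacency matrix by breadth-first search.
graph_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 1) return(TRUE)
  seen <- logical(n)
  seen[1] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

#' Build a food web object from a feeding adjacency matrix
#'
#' Validates the retention invariants, computes trophic positions and fills
#' in allometric masses and turnover rates. Mostly useful for constructing
#' small hand-made webs; random webs come from [niche_web()].
#'
#' @param feeding S x S logical matrix, `feeding[i, j]` TRUE when i eats j.
#' @param R body mass ratio per trophic level.
#' @param niche optional niche values to attach.
#' @param C_target optional target connectance to record.
#' @return A `food_web` object.
#' @export
as_food_web <- function(feeding, R = 42, niche = NULL, C_target = NA_real_) {
  stopifnot(is.matrix(feeding), nrow(feeding) == ncol(feeding))
  mode(feeding) <- "logical"
  S <- nrow(feeding)
  web <- structure(
    list(S = S, C_target = C_target, niche = niche, feeding = feeding,
         realized_connectance = sum(feeding) / S^2,
         trophic_position = trophic_positions(feeding),
         mass = NULL, turnover = NULL, R = NULL),
    class = "food_web")
  assign_allometry(web, R = R)
}

#' Trophic positions as shortest paths to a basal producer
#'
#' The trophic position of species i is the length of the shortest directed
#' consumer-to-prey path from i to any producer (a species with no prey);
#' producers sit at position 0. Cannibalistic self-links are ignored for
#' path computation.
#'
#' @param web a `food_web` object or a logical feeding matrix.
#' @return integer vector of trophic positions.
#' @export
trophic_positions <- function(web) {
  feeding <- if (inherits(web, "food_web")) web$feeding else web
  stopifnot(is.matrix(feeding), nrow(feeding) == ncol(feeding))
  S <- nrow(feeding)
  paths <- feeding
  diag(paths) <- FALSE
  tp <- rep(NA_integer_, S)
  tp[rowSums(feeding) == 0] <- 0L
  level <- 0L
  while (anyNA(tp)) {
    frontier <- which(tp == level)
    if (!length(frontier)) {
      stop("species without a directed path to a basal producer; ",
           "the web does not satisfy the retention filter", call. = FALSE)
    }
    reached <- rowSums(paths[, frontier, drop = FALSE]) > 0 & is.na(tp)
    tp[reached] <- level + 1L
    level <- level + 1L
  }
  tp
}

#' Assign allometric body masses and turnover rates
#'
#' Masses scale with trophic position as \eqn{M_i = R^{T_i}} (producers have
#' mass exactly 1) and mass-specific turnover follows quarter-power scaling,
#' \eqn{\alpha_i = M_i^{-1/4}}.
#'
#' @param web a `food_web` with trophic positions computed.
#' @param R body mass ratio per trophic level (> 0).
#' @return The web with `mass`, `turnover` and `R` filled in.
#' @export
assign_allometry <- function(web, R = 42) {
  stopifnot(inherits(web, "food_web"), R > 0,
            !is.null(web$trophic_position))
  web$mass <- R^web$trophic_position
  web$turnover <- web$mass^(-1 / 4)
  web$R <- R
  web
}

#' @export
print.food_web <- function(x, ...) {
  cat("niche-model food web\n")
  cat("  species:             ", x$S, "\n")
  cat("  target connectance:  ", x$C_target, "\n")
  cat("  realized connectance:", signif(x$realized_connectance, 4), "\n")
  cat("  trophic positions:   ", paste(range(x$trophic_position),
                                       collapse = " .. "), "\n")
  cat("  body mass ratio R:   ", x$R, "\n")
  invisible(x)
}

#' Convert a food web to an igraph object
#'
#' Edges point from consumer to prey; niche values, trophic positions and
#' masses are attached as vertex attributes.
#'
#' @param web a `food_web`.
#' @return an igraph directed graph.
#' @export
food_web_igraph <- function(web) {
  stopifnot(inherits(web, "food_web"))
  g <- igraph::graph_from_adjacency_matrix(web$feeding * 1, mode = "directed")
  if (!is.null(web$niche)) igraph::V(g)$niche <- web$niche
  igraph::V(g)$trophic_position <- web$trophic_position
  igraph::V(g)$mass <- web$mass
  g
}

#' Write / read a food web as a tab-separated edge list
#'
#' The file carries a `#`-prefixed header block with S, the target
#' connectance, R and the niche values, followed by a two-column
#' consumer/prey edge list. `read_food_web()` reconstructs the full object
#' (trophic positions and allometry are recomputed).
#'
#' @param web a `food_web`.
#' @param path file path.
#' @return `write_food_web()` returns `path` invisibly; `read_food_web()`
#'   returns a `food_web`.
#' @export
write_food_web <- function(web, path) {
  stopifnot(inherits(web, "food_web"))
  niche <- if (is.null(web$niche)) rep(NA_real_, web$S) else web$niche
  header <- c(
    paste0("# S\t", web$S),
    paste0("# C_target\t", format(web$C_target, digits = 17)),
    paste0("# R\t", format(web$R, digits = 17)),
    paste0("# niche\t", paste(format(niche, digits = 17), collapse = ",")),
    "consumer\tprey")
  edges <- which(web$feeding, arr.ind = TRUE)
  lines <- c(header, paste(edges[, 1], edges[, 2], sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_food_web
#' @export
read_food_web <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("# ", key, "\t"))]
    sub(paste0("^# ", key, "\t"), "", ln)
  }
  S <- as.integer(field("S"))
  C_target <- as.numeric(field("C_target"))
  R <- as.numeric(field("R"))
  niche <- as.numeric(strsplit(field("niche"), ",")[[1]])
  body <- lines[!grepl("^#", lines)][-1] # drop column header
  feeding <- matrix(FALSE, S, S)
  if (length(body)) {
    edges <- do.call(rbind, strsplit(body, "\t"))
    feeding[cbind(as.integer(edges[, 1]), as.integer(edges[, 2]))] <- TRUE
  }
  if (all(is.na(niche))) niche <- NULL
  as_food_web(feeding, R = R, niche = niche, C_target = C_target)
}

#' Export a food web as GraphML
#'
#' @param web a `food_web`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_food_web_graphml <- function(web, path) {
  igraph::write_graph(food_web_igraph(web), path, format = "graphml")
  invisible(path)
}
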