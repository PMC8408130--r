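test_that("feeding-range fractions follow Beta(1, 1/(2C) - 1) with mean 2C", {
  set.seed(401)
  # At C = 0.25 the distribution is Beta(1, 1), i.e. uniform with mean 1/2.
  x <- metastab:::draw_range_fractions(1e5, 0.25)
  expect_lt(abs(mean(x) - 0.5), 0.005)
  expect_true(all(x >= 0 & x <= 1))
  # Closed-form mean 1/(1 + shape2) = 2C at another connectance.
  y <- metastab:::draw_range_fractions(1e5, 0.1)
  expect_lt(abs(mean(y) - 0.2), 0.005)
})

test_that("retained webs satisfy the retention invariants", {
  set.seed(402)
  for (i in 1:30) {
    S <- sample(5:25, 1)
    C <- runif(1, 0.1, 0.3)
    web <- niche_web(S, C)
    expect_true(any(rowSums(web$feeding) == 0))        # a producer exists
    und <- web$feeding | t(web$feeding)
    diag(und) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(und * 1, mode = "undirected")
    expect_equal(igraph::components(g)$no, 1)          # single component
    expect_false(anyNA(web$trophic_position))          # all reach a producer
    expect_equal(web$realized_connectance,
                 sum(web$feeding) / S^2)
  }
})

test_that("trophic positions are shortest directed paths to a producer", {
  # chain 3 eats 2 eats 1
  expect_identical(chain_web(3)$trophic_position, c(0L, 1L, 2L))
  # omnivore eating both a producer and a herbivore sits at position 1
  feeding <- matrix(FALSE, 3, 3)
  feeding[2, 1] <- TRUE              # herbivore eats producer
  feeding[3, 1] <- TRUE              # omnivore eats producer...
  feeding[3, 2] <- TRUE              # ...and the herbivore
  expect_identical(trophic_positions(feeding), c(0L, 1L, 1L))
  # cannibalistic self-links do not enter path computation
  diag(feeding) <- TRUE
  feeding[1, 1] <- FALSE
  expect_identical(trophic_positions(feeding), c(0L, 1L, 1L))
})

test_that("trophic positions agree with an igraph BFS oracle on random webs", {
  set.seed(403)
  for (i in 1:50) {
    web <- niche_web(sample(5:20, 1), runif(1, 0.1, 0.3))
    expect_identical(web$trophic_position,
                     igraph_trophic_positions(web$feeding))
  }
})

test_that("webs without a path to a producer are rejected", {
  feeding <- matrix(FALSE, 3, 3)
  feeding[2, 3] <- TRUE
  feeding[3, 2] <- TRUE              # 2 and 3 feed only on each other
  expect_error(trophic_positions(feeding), "path to a basal producer")
  expect_false(metastab:::web_retained(feeding))
})

test_that("allometric masses and turnover follow R^T and quarter-power scaling", {
  web <- chain_web(3, R = 42)
  expect_identical(web$mass, c(1, 42, 1764))
  expect_identical(web$turnover, c(1, 42, 1764)^(-0.25))
  # M(T = 2) turnover equals the square of the single-level turnover
  expect_equal(web$turnover[3], (42^(-0.25))^2, tolerance = 1e-15)
  # exact identities on random webs
  set.seed(404)
  web <- niche_web(15, 0.2, R = 42)
  expect_identical(web$mass, 42^web$trophic_position)
  expect_identical(web$turnover, web$mass^(-0.25))
  expect_true(all(web$mass[web$trophic_position == 0] == 1))
  # rescaling with a different mass ratio
  web5 <- assign_allometry(web, R = 5)
  expect_identical(web5$mass, 5^web$trophic_position)
})

test_that("feeding is biased down the niche axis", {
  set.seed(405)
  below <- total <- 0
  for (i in 1:40) {
    web <- niche_web(15, 0.15)
    links <- which(web$feeding & !diag(TRUE, web$S), arr.ind = TRUE)
    below <- below + sum(web$niche[links[, 2]] < web$niche[links[, 1]])
    total <- total + nrow(links)
  }
  expect_gt(below / total, 0.5)
})

test_that("mean realized connectance approximates the target", {
  set.seed(406)
  cc <- replicate(200, niche_web(20, 0.15)$realized_connectance)
  expect_lt(abs(mean(cc) - 0.15), 0.015)
})

test_that("infeasible (S, C) exhausts the attempt budget with an error", {
  set.seed(407)
  expect_error(niche_web(2, 0.001, max_attempts = 3), "infeasible")
})

test_that("edge-list and GraphML round trips preserve the web", {
  set.seed(408)
  web <- niche_web(12, 0.18)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_food_web(web, path)
  back <- read_food_web(path)
  expect_identical(back$feeding, web$feeding)
  expect_equal(back$niche, web$niche, tolerance = 1e-15)
  expect_identical(back$trophic_position, web$trophic_position)
  expect_equal(back$C_target, web$C_target)
  expect_equal(back$R, web$R)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_food_web_graphml(web, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), web$S)
  expect_equal(igraph::ecount(g), sum(web$feeding))
})
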