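gs3 <- data.frame(sample = c("a", "b", "c"),
                  x = c(0, 1, 0.5), y = c(0, 0, 1),
                  locality = c("L1", "L2", "L3"), haplogroup = NA)

test_that("connectivity network: triangle, quad diagonal, fallbacks", {
  net <- connectivityNetwork(gs3)
  expect_equal(nrow(net$edges), 3)

  # convex quadrilateral, not cocircular: the empty-circumcircle rule
  # selects exactly one diagonal -> 5 edges
  gs4 <- data.frame(sample = letters[1:4],
                    x = c(0, 4, 4.2, 0.1), y = c(0, 0.2, 3, 2.5),
                    locality = paste0("L", 1:4), haplogroup = NA)
  net4 <- connectivityNetwork(gs4)
  expect_equal(nrow(net4$edges), 5)
  # verify against an independent circumcircle check of the kept diagonal
  d1 <- sort(c("L1", "L3")); d2 <- sort(c("L2", "L4"))
  eds <- t(apply(net4$edges[, 1:2], 1, sort))
  hasD1 <- any(eds[, 1] == d1[1] & eds[, 2] == d1[2])
  hasD2 <- any(eds[, 1] == d2[1] & eds[, 2] == d2[2])
  expect_true(xor(hasD1, hasD2))

  two <- connectivityNetwork(gs3[1:2, ])
  expect_equal(nrow(two$edges), 1)
  expect_error(connectivityNetwork(gs3[1, ]), "at least 2")

  # collinear localities fall back to a path graph
  gsc <- data.frame(sample = letters[1:4], x = 1:4, y = rep(0, 4),
                    locality = paste0("L", 1:4), haplogroup = NA)
  netc <- connectivityNetwork(gsc)
  expect_equal(nrow(netc$edges), 3)
})

test_that("midpoint distances average inter-locality pairs", {
  aln <- aln_from(a = "AAAAAAAAAAAAAAAAAAAA",
                  b = "CAAAAAAAAAAAAAAAAAAA",   # d(a,b) = 0.05
                  c = "AAAAAAAAAAAAAAAAAAAA")
  pd <- pairwisePDistance(aln)
  net <- connectivityNetwork(gs3)
  mp <- midpointDistances(net, gs3, pd)
  e_ab <- mp[(mp$from == "L1" & mp$to == "L2") |
               (mp$from == "L2" & mp$to == "L1"), ]
  expect_equal(e_ab$z, 0.05)
  expect_equal(e_ab$x, 0.5)
  expect_equal(e_ab$y, 0)

  # two individuals per locality: mean of the four cross pairs
  gs2 <- data.frame(sample = c("a", "b", "c", "d"),
                    x = c(0, 0, 1, 1), y = c(0, 0, 0, 0),
                    locality = c("L1", "L1", "L2", "L2"), haplogroup = NA)
  aln2 <- aln_from(a = "AAAAAAAAAA", b = "AAAAAAAAAA",
                   c = "CAAAAAAAAA", d = "CCCAAAAAAA")
  net2 <- list(localities = data.frame(locality = c("L1", "L2"),
                                       x = c(0, 1), y = c(0, 0)),
               edges = data.frame(from = "L1", to = "L2", length = 1))
  mp2 <- midpointDistances(net2, gs2, pairwisePDistance(aln2))
  expect_equal(mp2$z, mean(c(0.1, 0.3, 0.1, 0.3)))

  # residual mode: perfectly linear z over edge length -> all residuals 0
  net3 <- list(localities = data.frame(locality = c("A", "B", "C"),
                                       x = c(0, 1, 3), y = 0),
               edges = data.frame(from = c("A", "A", "B"),
                                  to = c("B", "C", "C"),
                                  length = c(1, 3, 2)))
  gsl <- data.frame(sample = c("a", "b", "c"), x = c(0, 1, 3), y = 0,
                    locality = c("A", "B", "C"), haplogroup = NA)
  # construct distances exactly linear in edge length: d = 0.01 * len
  d <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d["a", "b"] <- d["b", "a"] <- 0.01
  d["a", "c"] <- d["c", "a"] <- 0.03
  d["b", "c"] <- d["c", "b"] <- 0.02
  mp3 <- midpointDistances(net3, gsl, list(d = d), mode = "residual")
  expect_equal(mp3$z, rep(0, 3), tolerance = 1e-12)

  # locality without sequence data is a named error
  gsm <- gs3; gsm$sample[3] <- "zz"
  expect_error(midpointDistances(net, gsm, pd), "L3")
})

test_that("IDW surface is exact at midpoints and a convex combination", {
  mp <- data.frame(x = c(0, 1), y = c(0, 0), z = c(0.1, 0.3),
                   from = "a", to = "b", length = 1)
  g <- interpolateSurface(mp, nx = 5, ny = 3, a = 1)
  v <- gridValues(g)
  expect_true(all(v >= 0.1 - 1e-12 & v <= 0.3 + 1e-12))

  # node equidistant from two midpoints averages them
  mp2 <- data.frame(x = c(-1, 1), y = c(0, 0), z = c(0.1, 0.3),
                    from = "a", to = "b", length = 1)
  gg <- interpolateSurface(mp2, nx = 3, ny = 3, a = 2)
  centre <- gridValues(gg)[2, 2]
  expect_equal(centre, 0.2)

  # node coinciding with a midpoint takes its value exactly
  mp1 <- data.frame(x = c(0, 2), y = c(0, 0), z = c(0.07, 0.2),
                    from = "a", to = "b", length = 1)
  # padded range [-0.05, 2.05] with 43 nodes puts a node exactly at x = 0
  g1 <- interpolateSurface(mp1, nx = 43, ny = 3, a = 1)
  i <- which.min(abs(g1@x - 0))
  expect_lt(abs(g1@x[i]), 1e-13)
  expect_equal(gridValues(g1)[i, 2], 0.07)

  expect_error(interpolateSurface(mp, nx = 1, ny = 3), "at least 2 x 2")
  expect_error(interpolateSurface(mp, a = 0), "a must be > 0")
})

test_that("large weighting exponent approaches nearest-neighbour values", {
  set.seed(31)
  mp <- data.frame(x = runif(6), y = runif(6), z = runif(6, 0, 0.2),
                   from = "a", to = "b", length = 1)
  g <- interpolateSurface(mp, nx = 12, ny = 12, a = 50)
  v <- gridValues(g)
  for (i in seq_along(g@x)) for (j in seq_along(g@y)) {
    d <- sort(sqrt((mp$x - g@x[i])^2 + (mp$y - g@y[j])^2))
    if (d[2] / d[1] < 1.2) next  # near-tie: limit not yet reached at a = 50
    dd <- sqrt((mp$x - g@x[i])^2 + (mp$y - g@y[j])^2)
    expect_equal(v[i, j], mp$z[which.min(dd)], tolerance = 1e-3)
  }
})

test_that("surface is translation invariant and grid-size stable", {
  set.seed(17)
  mp <- data.frame(x = runif(8), y = runif(8), z = runif(8, 0, 0.1),
                   from = "a", to = "b", length = 1)
  g1 <- interpolateSurface(mp, nx = 10, ny = 10, a = 1)
  mp2 <- mp; mp2$x <- mp2$x + 100; mp2$y <- mp2$y - 50
  g2 <- interpolateSurface(mp2, nx = 10, ny = 10, a = 1)
  expect_equal(gridValues(g1), gridValues(g2), tolerance = 1e-9)

  # rank correlation between 50x50 and 100x100 surfaces at shared scale
  gA <- interpolateSurface(mp, nx = 50, ny = 50, a = 1)
  gB <- interpolateSurface(mp, nx = 100, ny = 100, a = 1)
  # compare on the coarse grid by sampling the fine one at nearest nodes
  fine <- gridValues(gB)
  near <- function(x, gx) which.min(abs(gx - x))
  vB <- outer(seq_along(gA@x), seq_along(gA@y), Vectorize(function(i, j)
    fine[near(gA@x[i], gB@x), near(gA@y[j], gB@y)]))
  expect_gt(cor(as.vector(gridValues(gA)), as.vector(vB),
                method = "spearman"), 0.95)
})
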