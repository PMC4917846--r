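test_that("flux cone of fixtures matches hand enumeration", {
  chain <- enumerate_flux_cone(make_toy_network("chain"))
  expect_equal(ncol(chain$rays), 1)
  expect_equal(unname(chain$rays[, 1]), rep(1 / sqrt(3), 3))

  cyc <- enumerate_flux_cone(make_toy_network("cycle"))
  expect_equal(ncol(cyc$rays), 2)
  expect_same_ray_set(cyc$rays,
                      cbind(c(1, 1, 0, 1) / sqrt(3), c(0, 1, 1, 0) / sqrt(2)))
})

test_that("every flux ray is steady-state feasible to 1e-9", {
  for (kind in c("chain", "branch", "cycle", "glycolysis_mini")) {
    net <- make_toy_network(kind)
    if (any(net$reactions$reversible)) net <- split_reversible(net)
    basis <- enumerate_flux_cone(net)
    expect_lte(max(abs(net$S %*% basis$rays)), 1e-9)
    expect_equal(unname(colSums(basis$rays^2)),
                 rep(1, ncol(basis$rays)), tolerance = 1e-12)
    expect_true(all(basis$rays >= -1e-12))
  }
})

test_that("double description equals the minimal-support oracle", {
  for (kind in c("chain", "branch", "cycle")) {
    net <- make_toy_network(kind)
    expect_same_ray_set(enumerate_flux_cone(net)$rays,
                        oracle_extreme_rays(net$S), tol = 1e-6)
  }
  for (seed in 1:6) {
    net <- random_small_network(n_reactions = 7 + seed %% 2,
                                n_mets = 3 + seed %% 2, seed = seed)
    expect_same_ray_set(enumerate_flux_cone(net)$rays,
                        oracle_extreme_rays(net$S), tol = 1e-6)
  }
})

test_that("split reversible reaction keeps cone equal to an oracle H-rep", {
  net <- split_reversible(network_from_strings(
    c(R1 = "-> A", R2 = "A <=> B", R3 = "B ->")))
  expect_same_ray_set(enumerate_flux_cone(net)$rays,
                      oracle_extreme_rays(net$S), tol = 1e-6)
})

test_that("k-cone rays are M^{-1} flux rays and satisfy S M k = 0", {
  net <- make_toy_network("chain")
  fc <- enumerate_flux_cone(net)
  m <- c(1, 2, 4)
  kc <- compute_kcone(fc, m)
  hand <- c(1, 0.5, 0.25)
  expect_equal(unname(kc$rays[, 1]), hand / sqrt(sum(hand^2)))
  expect_lte(max(abs(net$S %*% (m * kc$rays))), 1e-9)
  # identity mass-action terms leave the cone unchanged
  expect_equal(compute_kcone(fc, rep(1, 3))$rays, fc$rays)
  expect_error(compute_kcone(fc, c(1, 0, 4)), "R2")
})

test_that("equilibrium constraints shrink the basis and pin k_f/k_b", {
  cy <- make_toy_network("cycle")
  m <- c(IN = 1, AB = 1, BA = 1, OUT = 1)
  keq <- data.frame(forward = "AB", backward = "BA", keq = 1)
  un <- constrain_by_keq(cy, m, NULL)
  co <- constrain_by_keq(cy, m, keq)
  expect_lt(ncol(co$rays), ncol(un$rays))
  expect_equal(unname(co$rays["AB", ] / co$rays["BA", ]), 1,
               tolerance = 1e-9)
  # empty table reduces to the plain k-cone
  m2 <- c(IN = 1, AB = 2, BA = 3, OUT = 2)
  expect_equal(constrain_by_keq(cy, m2, NULL)$rays,
               compute_kcone(enumerate_flux_cone(cy), m2)$rays,
               ignore_attr = TRUE)
  # keq ratios other than 1 are honoured too
  co2 <- constrain_by_keq(cy, m, data.frame(forward = "AB",
                                            backward = "BA", keq = 2.5))
  if (ncol(co2$rays) > 0)
    expect_equal(unname(co2$rays["AB", ] / co2$rays["BA", ]), 2.5,
                 tolerance = 1e-9)
  expect_error(constrain_by_keq(cy, m, data.frame(forward = "AB",
                                                  backward = "BA",
                                                  keq = -1)),
               "> 0")
})

test_that("cone membership is invariant to positive scaling", {
  net <- split_reversible(make_toy_network("glycolysis_mini"))
  basis <- enumerate_flux_cone(net)
  r <- basis$rays[, 1]
  for (c in c(0.01, 1, 250)) expect_true(in_cone(basis, c * r))
  # a coordinate direction outside the cone is rejected
  e1 <- numeric(nrow(basis$rays)); e1[4] <- 1
  expect_false(in_cone(basis, e1))
})

test_that("filtering by changed reactions keeps exactly the scanned rows", {
  basis <- cone_basis(diag(3) + 0.1, "kcone",
                      reaction_ids = c("a", "b", "c"))
  tm <- structure(list(diag = c(a = 1, b = 2, c = 1),
                       condition_pair = c("n", "d")),
                  class = "transform_matrix")
  f2 <- filter_changed_reactions(basis, tm, threshold = 2)
  expect_equal(f2$reaction_ids, "b")
  expect_equal(unname(colSums(f2$rays^2)), rep(1, ncol(f2$rays)))
  f1 <- filter_changed_reactions(basis, tm, threshold = 1)
  expect_equal(f1$reaction_ids, c("a", "b", "c"))
  # scan oracle on a random transformation
  set.seed(8)
  diag_t <- exp(rnorm(10))
  tm2 <- structure(list(diag = setNames(diag_t, letters[1:10]),
                        condition_pair = c("n", "d")),
                   class = "transform_matrix")
  b10 <- cone_basis(matrix(runif(100), 10), "kcone",
                    reaction_ids = letters[1:10])
  got <- filter_changed_reactions(b10, tm2, 2)$reaction_ids
  expect_equal(got, letters[1:10][abs(log2(diag_t)) >= 1])
  expect_warning(filter_changed_reactions(basis, tm, threshold = 100),
                 "empty")
})

test_that("projection reports its own stated definitions", {
  # rays already in a 2-D plane embed with ~zero relative error
  set.seed(3)
  plane <- matrix(runif(10), 5, 2)
  rays <- plane %*% matrix(runif(24), 2, 12)
  basis <- cone_basis(kcone:::normalize_columns(abs(rays)), "flux",
                      reaction_ids = paste0("r", 1:5))
  proj <- project_cone(basis, k_clusters = 3)
  expect_lte(proj$relative_error, 1e-9)
  # convex hull contains every projected point
  hull <- proj$coordinates[proj$hull_vertices, c("pc1", "pc2")]
  inside <- function(p, hull) {
    # point-in-convex-polygon via sign of cross products
    h <- as.matrix(hull)
    n <- nrow(h)
    s <- sapply(seq_len(n), function(i) {
      a <- h[i, ]; b <- h[i %% n + 1, ]
      (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    })
    all(s >= -1e-8) || all(s <= 1e-8)
  }
  pts <- as.matrix(proj$coordinates[, c("pc1", "pc2")])
  expect_true(all(apply(pts, 1, inside, hull = hull)))
  # identical bases produce identical cluster centers
  proj2 <- project_cone(list(a = basis, b = basis), k_clusters = 3)
  expect_equal(proj2$cluster_centers$a, proj2$cluster_centers$b,
               ignore_attr = TRUE)
  expect_warning(project_cone(basis, k_clusters = 50), "clamped")
})

test_that("ray-count guard aborts with guidance", {
  net <- make_toy_network("cycle")
  expect_error(enumerate_flux_cone(net, max_rays = 1), "guard")
})
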