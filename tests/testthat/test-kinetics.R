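panel_from <- function(net, x_by_sample, conds, reps = NULL) {
  if (is.null(reps)) reps <- ave(seq_along(conds), conds, FUN = seq_along)
  metabolome_panel(x_by_sample, conditions = conds, replicates = reps)
}

test_that("mass-action terms are substrate monomials", {
  net <- network_from_strings(c(R1 = "A -> B", R2 = "2 A -> B",
                                R3 = "-> A", R4 = "B ->"))
  p <- panel_from(net, rbind(A = c(2, 3), B = c(5, 7)), c("n", "d"))
  prof <- mass_action_terms(net, p)
  expect_equal(unname(prof$terms["R1", ]), c(2, 3))
  expect_equal(unname(prof$terms["R2", ]), c(4, 9))
  expect_equal(unname(prof$terms["R3", ]), c(1, 1))   # empty product
  expect_equal(unname(prof$terms["R4", ]), c(5, 7))
})

test_that("spectator products never change a mass-action term", {
  n1 <- network_from_strings(c(R = "A -> B", RIN = "-> A", ROUT = "B ->"))
  n2 <- network_from_strings(c(R = "A -> B + C", RIN = "-> A",
                               ROUT = "B ->", RC = "C ->"))
  vals <- rbind(A = c(2, 3), B = c(4, 4), C = c(9, 1))
  p1 <- panel_from(n1, vals[1:2, ], c("n", "d"))
  p2 <- panel_from(n2, vals, c("n", "d"))
  expect_equal(mass_action_terms(n1, p1)$terms["R", ],
               mass_action_terms(n2, p2)$terms["R", ])
})

test_that("missing internal substrates mark reactions undefined, not zero", {
  net <- network_from_strings(c(R1 = "A -> B", R2 = "B -> C",
                                RIN = "-> A", ROUT = "C ->"))
  vals <- rbind(A = c(2, 3), B = c(NA, NA), C = c(1, 1))
  p <- panel_from(net, vals, c("n", "d"))
  prof <- mass_action_terms(net, p)
  expect_true(all(is.na(prof$terms["R2", ])))
  expect_equal(prof$undefined, "R2")
  expect_error(mass_action_terms(net, p, on_missing = "error"), "B")
})

test_that("transformation matrix reproduces the chain hand oracle", {
  net <- make_toy_network("chain")
  # x_A: 2 -> 1, x_B: 4 -> 4
  p <- panel_from(net, rbind(A = c(2, 1), B = c(4, 4)),
                  c("normal", "disease"))
  prof <- mass_action_terms(net, p)
  tm <- transformation_matrix(prof)
  expect_equal(unname(tm$diag), c(1, 2, 1))
  expect_equal(unname(log2(tm$diag)), c(0, 1, 0))
  # identical conditions give the identity transformation
  p0 <- panel_from(net, rbind(A = c(2, 2), B = c(4, 4)),
                   c("normal", "disease"))
  expect_equal(unname(transformation_matrix(
    mass_action_terms(net, p0))$diag), rep(1, 3))
})

test_that("swapping condition roles inverts the transformation", {
  net <- split_reversible(make_toy_network("glycolysis_mini"))
  sc <- make_scenario(net, c(PFK = 3), noise_cv = 0.2, seed = 4)
  prof <- mass_action_terms(net, sc$panel)
  t_nd <- transformation_matrix(prof, normal = "normal",
                                disease = "disease")
  t_dn <- transformation_matrix(prof, normal = "disease",
                                disease = "normal")
  expect_equal(unname(t_nd$diag * t_dn$diag), rep(1, length(t_nd$diag)))
})

test_that("EDA lfcs decompose into stoichiometry-weighted metabolite lfcs", {
  net <- split_reversible(make_toy_network("glycolysis_mini"))
  sc <- make_scenario(net, c(HK = 2), noise_cv = 0.3, seed = 9)
  prof <- mass_action_terms(net, sc$panel)
  eda <- eda_log_fold_changes(prof)
  ex <- kcone:::substrate_exponents(net)
  z <- log2(sc$panel$values)
  cn <- which(sc$panel$conditions == "normal")
  cd <- which(sc$panel$conditions == "disease")
  combos <- expand.grid(d = seq_along(cd), n = seq_along(cn))
  for (j in seq_len(nrow(combos))) {
    met_lfc <- z[, cn[combos$n[j]]] - z[, cd[combos$d[j]]]
    expected <- as.numeric(t(ex[names(met_lfc), ]) %*% met_lfc)
    expect_equal(unname(eda$samples[, j]), expected, tolerance = 1e-12)
  }
  # doubling every substrate of a 2-substrate reaction doubles in log2 twice
  n2 <- network_from_strings(c(R = "A + B -> C", RIN = "-> A",
                               RIN2 = "-> B", ROUT = "C ->"))
  p <- panel_from(n2, rbind(A = c(2, 1), B = c(2, 1), C = c(1, 1)),
                  c("normal", "disease"))
  eda2 <- eda_log_fold_changes(mass_action_terms(n2, p))
  expect_equal(unname(eda2$mean_lfc[["R"]]), 2)
})

test_that("flux weights pinpoint exact kinetic constants", {
  net <- make_toy_network("chain")
  p <- panel_from(net, rbind(A = c(2, 1), B = c(4, 4)),
                  c("normal", "disease"))
  tm <- transformation_matrix(mass_action_terms(net, p))
  k_n <- c(1, 0.5, 0.25)
  # equal fluxes: w = 1, so k_d = T k_n and the perturbed step doubles
  k_d <- apply_flux_weights(k_n, tm)
  expect_equal(k_d[2] / k_n[2], 2)
  # recovery k = v / m in both conditions
  m_n <- aggregate <- c(1, 2, 4)
  v <- k_n * m_n
  expect_equal(v / m_n, k_n)
  expect_error(apply_flux_weights(k_n[1:2], tm), "mismatch")
})

test_that("noise-free planted regulation is recovered to 1e-6", {
  net <- make_toy_network("chain")
  sc <- make_scenario(net, c(R2 = 2), noise_cv = 0, seed = 1)
  tm <- transformation_matrix(mass_action_terms(net, sc$panel))
  expect_equal(unname(log2(tm$diag)), unname(sc$truth), tolerance = 1e-6)
})

test_that("EDA estimator is approximately unbiased under replicate noise", {
  net <- make_toy_network("chain")
  est <- vapply(1:100, function(s) {
    sc <- make_scenario(net, c(R2 = 2), noise_cv = 0.2, replicates = 3,
                        seed = s)
    log2(transformation_matrix(
      mass_action_terms(net, sc$panel))$diag[["R2"]])
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.05)
})
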