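# binary tree with a mix of known and unknown leaf pressures
tree_partial_bcs <- function(net, frac_known, root_p = 60, leaf_p = 20,
                             seed = 1) {
  bix <- which(net$nodes$is_boundary)
  ids <- net$nodes$node_id[bix]
  root <- ids[1]
  leaves <- ids[-1]
  set.seed(seed)
  known <- sample(leaves, max(1, round(frac_known * length(leaves))))
  boundary_conditions(data.frame(
    node_id = ids,
    kind = ifelse(ids == root, "pressure",
                  ifelse(ids %in% known, "pressure", "unknown")),
    value = ifelse(ids == root, root_p,
                   ifelse(ids %in% known, leaf_p, NA_real_))
  ))
}

test_that("with all BCs supplied the estimation reproduces the plain solve", {
  net <- fx$binary_tree
  bix <- which(net$nodes$is_boundary)
  ids <- net$nodes$node_id[bix]
  bcs <- boundary_conditions(data.frame(
    node_id = ids, kind = "pressure",
    value = c(60, rep(20, length(ids) - 1))
  ))
  mu <- rep(2, nrow(net$segments))
  st_known <- solve_known_bcs(net, bcs, mu)
  st_est <- estimate_bcs(net, bcs, flow_config(seed = 5), mu)
  expect_equal(st_est$segments$flow_nlmin, st_known$segments$flow_nlmin,
               tolerance = 1e-8)
  expect_equal(st_est$nodes$pressure_mmHg, st_known$nodes$pressure_mmHg,
               tolerance = 1e-8)
})

test_that("sparse KKT solve matches a dense brute-force solve to 1e-10", {
  net <- fx$cascade_toy   # 13 nodes
  bcs <- tree_partial_bcs(net, frac_known = 0, root_p = 60)
  cfg <- flow_config(seed = 3)
  mu <- effective_viscosity(net$segments$diameter_um,
                            rep(0.45, nrow(net$segments)))
  signs <- rep(1, nrow(net$segments))
  warm <- list(signs = signs, k_tau = 1e-4, tau0_mag = 5)
  st <- estimate_bcs(net, bcs, cfg, mu, warm = warm, freeze = TRUE)
  oracle <- dense_kkt(net, bcs, cfg, mu, signs, 1e-4, 5)
  scale <- max(abs(oracle$Q))
  expect_lt(max(abs(st$segments$flow_nlmin - oracle$Q)) / scale, 1e-10)
  expect_lt(max(abs(st$nodes$pressure_mmHg - oracle$p)), 1e-8)
})

test_that("a single vessel with one unknown boundary matches the 3x3 hand system", {
  net <- two_node_net(d = 10, l = 100)
  bcs <- boundary_conditions(data.frame(node_id = 1:2,
                                        kind = c("pressure", "unknown"),
                                        value = c(50, NA)))
  cfg <- flow_config(seed = 1)
  mu <- 2
  g <- 7.99934324489 * pi * 1e4 / (128 * mu * 100)
  cvec <- (1e-2 * (1e-6 / 60) / 1e-12) * 32 * mu / (pi * 1e3)
  l <- 100
  k_tau <- 1e-4
  tau0 <- 5
  hess_d <- k_tau * cvec^2 * l * g^2 + cfg$k_p * l / 2
  hess_o <- -k_tau * cvec^2 * l * g^2
  kkt <- rbind(c(1, 0, 0),
               c(hess_d, hess_o, 1),
               c(hess_o, hess_d, 0))
  rhs <- c(50,
           cfg$k_p * (l / 2) * 31 + k_tau * g * tau0 * cvec * l,
           cfg$k_p * (l / 2) * 31 - k_tau * g * tau0 * cvec * l)
  hand <- solve(kkt, rhs)
  st <- estimate_bcs(net, bcs, cfg, mu,
                     warm = list(signs = 1, k_tau = k_tau, tau0_mag = tau0),
                     freeze = TRUE)
  expect_equal(st$nodes$pressure_mmHg, hand[1:2], tolerance = 1e-10)
  # flow is driven towards the positive target shear
  expect_gt(st$segments$flow_nlmin, 0)
})

test_that("a large pressure weight drives nodal pressures to the target", {
  net <- fx$binary_tree
  bcs <- tree_partial_bcs(net, frac_known = 0.25)
  mu <- rep(2, nrow(net$segments))
  dev <- function(k_p) {
    st <- estimate_bcs(net, bcs, flow_config(k_p = k_p, seed = 2), mu)
    w <- 1  # uniform weighting is enough for a monotonicity check
    sum((st$nodes$pressure_mmHg - 31)^2)
  }
  d1 <- dev(0.1)
  d2 <- dev(10)
  d3 <- dev(1000)
  expect_gt(d1, d2)
  expect_gt(d2, d3)
})

test_that("the converged coupled state is robust to the shear-sign seed", {
  net <- fx$binary_tree
  bcs <- tree_partial_bcs(net, frac_known = 0.5)
  st1 <- converge_flow_haematocrit(net, bcs, flow_config(seed = 11))
  st2 <- converge_flow_haematocrit(net, bcs, flow_config(seed = 77))
  q1 <- st1$segments$flow_nlmin
  q2 <- st2$segments$flow_nlmin
  expect_lt(sqrt(sum((q1 - q2)^2) / sum(q1^2)), 1e-3)
})

test_that("supplying more boundary conditions reduces the flow error", {
  # ground truth: all leaf pressures known; then hide a growing fraction
  net <- fx$binary_tree
  mu0 <- rep(2, nrow(net$segments))
  bcs_full <- tree_partial_bcs(net, frac_known = 1)
  truth <- solve_known_bcs(net, bcs_full, mu0)$segments$flow_nlmin
  nrmsd <- vapply(c(0.1, 0.3, 0.5, 0.7, 1.0), function(f) {
    st <- estimate_bcs(net, tree_partial_bcs(net, frac_known = f),
                       flow_config(seed = 4), mu0)
    sqrt(mean((st$segments$flow_nlmin - truth)^2)) / sqrt(mean(truth^2))
  }, numeric(1))
  expect_lt(suppressWarnings(cor(seq_along(nrmsd), nrmsd,
                                 method = "spearman")), 0)
  expect_lt(nrmsd[5], 1e-6)
})
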