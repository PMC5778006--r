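# hand unit conversion: conductance of d = 10 um, l = 100 um, mu = 1 cP is
# pi d^4 / (128 mu l) expressed in nl/min per mmHg:
#   (133.322387415 Pa/mmHg) * (1e-6)^4 / (1e-3 * 1e-6) * 1e12 * 60 * pi*1e4/12800
G_REF <- 19.6333421654

test_that("conductance assembly reproduces the Poiseuille prefactor", {
  net <- two_node_net(d = 10, l = 100)
  mats <- assemble_conductance(net, viscosities = 1)
  expect_equal(mats$g, G_REF, tolerance = 1e-9)
  # K is 2x2 with zero row sums (conservation structure)
  expect_equal(as.numeric(Matrix::rowSums(mats$K)), c(0, 0), tolerance = 1e-12)
  # d^4 law: doubling the diameter multiplies conductance by 16
  net2 <- two_node_net(d = 20, l = 100)
  expect_equal(assemble_conductance(net2, 1)$g / mats$g, 16, tolerance = 1e-12)
  # zero-length segment refused
  net$segments$length_um <- 0
  expect_error(assemble_conductance(net, 1), "length")
})

test_that("single-vessel flow matches the Poiseuille closed form to 1e-10", {
  net <- two_node_net(d = 10, l = 100)
  st <- solve_known_bcs(net, dp_bcs(20, 10), viscosities = 1)
  expect_equal(st$segments$flow_nlmin, G_REF * 10, tolerance = 1e-10)
  # velocity = flow / area, in mm/s
  v_expect <- (G_REF * 10) * 1e-12 / 60 / (pi * (5e-6)^2) * 1e3
  expect_equal(st$segments$velocity_mm_s, v_expect, tolerance = 1e-10)
  # wall shear from the pressure gradient: tau = (d/4) dp/dx
  tau_expect <- (10 / 4) / 100 * 10 * 1333.22387415 * 1e-4
  expect_equal(st$segments$shear_dyn_cm2, tau_expect * 1e4, tolerance = 1e-6)
})

test_that("series and parallel circuits match brute-force resistor algebra", {
  # series: 3 unequal segments
  net <- fx$series_chain
  mu <- c(1.2, 2.0, 3.5)
  bcs <- boundary_conditions(data.frame(node_id = c(1, 4), kind = "pressure",
                                        value = c(50, 10)))
  st <- solve_known_bcs(net, bcs, viscosities = mu)
  d <- net$segments$diameter_um
  l <- net$segments$length_um
  g <- 7.99934324489 * pi * d^4 / (128 * mu * l)
  q_expect <- 40 / sum(1 / g)      # resistors in series
  expect_equal(st$segments$flow_nlmin, rep(q_expect, 3), tolerance = 1e-10)
  # symmetric Y: equal daughters get equal flows, half the parent each
  y <- fx$y_symmetric
  bcs <- boundary_conditions(data.frame(node_id = c(1, 3, 4),
                                        kind = "pressure",
                                        value = c(60, 20, 20)))
  st <- solve_known_bcs(y, bcs, viscosities = rep(2, 3))
  q <- st$segments$flow_nlmin
  expect_equal(q[2], q[3], tolerance = 1e-12)
  expect_equal(q[1], q[2] + q[3], tolerance = 1e-10)
})

test_that("flow and known-flux boundary conditions combine correctly", {
  net <- fx$series_chain
  bcs <- boundary_conditions(data.frame(node_id = c(1, 4),
                                        kind = c("flow", "pressure"),
                                        value = c(5, 10)))
  st <- solve_known_bcs(net, bcs, viscosities = rep(1, 3))
  expect_equal(st$segments$flow_nlmin, rep(5, 3), tolerance = 1e-10)
  # no pressure anchor -> informative singularity error
  bcs2 <- boundary_conditions(data.frame(node_id = c(1, 4), kind = "flow",
                                         value = c(5, -5)))
  expect_error(solve_known_bcs(net, bcs2, rep(1, 3)), "pressure")
})

test_that("interior mass conservation holds in every returned state", {
  net <- cached_network(2)
  bcs <- baseline_bcs(net)
  st <- cached_baseline(2)$state
  mats <- assemble_conductance(net, st$segments$viscosity_cP)
  resid <- as.numeric(mats$K %*% st$nodes$pressure_mmHg)
  interior <- !net$nodes$is_boundary
  expect_lt(max(abs(resid[interior])),
            1e-5 * mean(abs(st$segments$flow_nlmin)))
})

test_that("solutions are invariant to relabelling and orientation flips", {
  net <- fx$y_asymmetric
  bcs <- boundary_conditions(data.frame(node_id = c(1, 3, 4),
                                        kind = "pressure",
                                        value = c(60, 25, 15)))
  mu <- c(1.5, 2.5, 3.0)
  st <- solve_known_bcs(net, bcs, mu)
  # flip segment 2's orientation: its flow sign flips, nothing else changes
  flip <- net
  flip$segments$node_a[2] <- net$segments$node_b[2]
  flip$segments$node_b[2] <- net$segments$node_a[2]
  st2 <- solve_known_bcs(flip, bcs, mu)
  expect_equal(st2$segments$flow_nlmin[2], -st$segments$flow_nlmin[2],
               tolerance = 1e-12)
  expect_equal(st2$segments$flow_nlmin[c(1, 3)],
               st$segments$flow_nlmin[c(1, 3)], tolerance = 1e-12)
  # relabel nodes: identical flows per segment id
  relab <- net
  map <- c(11, 12, 13, 14)
  relab$nodes$node_id <- map[match(net$nodes$node_id, 1:4)]
  relab$segments$node_a <- map[match(net$segments$node_a, 1:4)]
  relab$segments$node_b <- map[match(net$segments$node_b, 1:4)]
  bcs3 <- boundary_conditions(data.frame(node_id = c(11, 13, 14),
                                         kind = "pressure",
                                         value = c(60, 25, 15)))
  st3 <- solve_known_bcs(relab, bcs3, mu)
  expect_equal(st3$segments$flow_nlmin, st$segments$flow_nlmin,
               tolerance = 1e-12)
})

test_that("perfusion applies the exact unit conversion and is linear", {
  net <- two_node_net()
  st <- solve_known_bcs(net, dp_bcs(20, 10), 1)
  # closed form: inflow [nl/min] * 1e-6 / (V[um^3] * 1e-12 * rho) * 100
  q <- st$nodes$boundary_inflow_nlmin[1]
  expect_equal(perfusion(net, st, 1e6, tissue_density_g_ml = 1),
               q * 1e-6 / (1e6 * 1e-12) * 100, tolerance = 1e-12)
  # doubling the pressure drop doubles the perfusion
  st2 <- solve_known_bcs(net, dp_bcs(30, 10), 1)
  expect_equal(perfusion(net, st2, 1e6), 2 * perfusion(net, st, 1e6),
               tolerance = 1e-10)
  # zero drop -> zero perfusion; zero volume -> error
  st0 <- solve_known_bcs(net, dp_bcs(10, 10), 1)
  expect_equal(perfusion(net, st0, 1e6), 0)
  expect_error(perfusion(net, st, 0), "tissue_volume")
})
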