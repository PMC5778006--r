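test_that("Hill saturation has the defining fixed points", {
  p <- oxygen_params()
  expect_equal(hill_saturation(p$P50_mmHg, p), 0.5, tolerance = 1e-12)
  expect_equal(hill_saturation(0, p), 0)
  # hand evaluation at 3 * P50 with n = 3: 27/28
  p3 <- oxygen_params(hill_n = 3)
  expect_equal(hill_saturation(3 * p3$P50_mmHg, p3), 27 / 28,
               tolerance = 1e-12)
  expect_error(hill_saturation(-1, p), "non-negative")
  x <- seq(0, 150, by = 1)
  expect_true(all(diff(hill_saturation(x, p)) > 0))
})

test_that("Michaelis-Menten consumption is half-maximal at P0 and bounded", {
  p <- oxygen_params()
  m <- p$M_demand
  expect_equal(consumption_rate(p$P0_mmHg, p), m / 2, tolerance = 1e-12)
  expect_equal(consumption_rate(0, p), 0)
  expect_equal(consumption_rate(9 * p$P0_mmHg, p), 0.9 * m, tolerance = 1e-12)
  expect_true(all(consumption_rate(c(1, 10, 1e4), p) <= m))
})

test_that("convective flux follows Q [Hd C0 S + alpha_eff P]", {
  p <- oxygen_params()
  expect_equal(convective_flux(0, 0.45, 60, p), 0)
  # no red cells: dissolved O2 only
  expect_equal(convective_flux(10, 0, 50, p),
               10 * 1e-6 * p$alpha_eff_umol_cm3_mmHg * 50, tolerance = 1e-12)
  # hand evaluation of a stated triple
  q <- 5; hd <- 0.3; pb <- 45
  s <- pb^p$hill_n / (pb^p$hill_n + p$P50_mmHg^p$hill_n)
  expect_equal(convective_flux(q, hd, pb, p),
               5e-6 * (0.3 * p$C0_umol_cm3 * s +
                         p$alpha_eff_umol_cm3_mmHg * 45), tolerance = 1e-12)
})

test_that("source discretisation respects the spacing bound", {
  net <- two_node_net(d = 10, l = 100)
  s10 <- discretize_sources(net, 10)
  expect_equal(nrow(s10), 10L)
  expect_equal(nrow(discretize_sources(net, 5)), 20L)
  # every segment carries at least one element
  net2 <- fx$cascade_toy
  s <- discretize_sources(net2, 200)
  expect_setequal(unique(s$segment_id), net2$segments$segment_id)
  # element lengths sum to the segment length
  sums <- tapply(s10$ds_um, s10$segment_id, sum)
  expect_equal(as.numeric(sums), 100)
})

test_that("the free-space kernel is symmetric and fields superpose linearly", {
  p <- oxygen_params()
  set.seed(9)
  pts <- tibble::tibble(x_um = runif(6, 0, 200), y_um = runif(6, 0, 200),
                        z_um = runif(6, 0, 200))
  src1 <- tibble::tibble(x_um = c(50, 120), y_um = c(40, 160),
                         z_um = c(30, 90), strength_umol_min = c(2e-7, -1e-7),
                         radius_um = 3)
  src2 <- tibble::tibble(x_um = c(80, 10), y_um = c(140, 20), z_um = c(60, 180),
                         strength_umol_min = c(5e-8, 1.5e-7), radius_um = 3)
  f1 <- tissue_field(pts, src1, p)
  f2 <- tissue_field(pts, src2, p)
  f12 <- tissue_field(pts, dplyr::bind_rows(src1, src2), p)
  expect_equal(f12, f1 + f2, tolerance = 1e-12)
  # symmetry G(x; x') = G(x'; x): swap roles of a source and an observer
  a <- tibble::tibble(x_um = 10, y_um = 20, z_um = 30)
  b <- tibble::tibble(x_um = 110, y_um = 90, z_um = 70,
                      strength_umol_min = 1, radius_um = 1)
  fab <- tissue_field(a, b, p)
  b2 <- tibble::tibble(a, strength_umol_min = 1, radius_um = 1)
  fba <- tissue_field(b[, 1:3], b2, p)
  expect_equal(fab, fba, tolerance = 1e-12)
})

test_that("zero consumption conserves convected O2 and flattens the field", {
  net <- two_node_net(d = 10, l = 100)
  st <- converge_flow_haematocrit(net, dp_bcs(40, 20), flow_config(seed = 1))
  pars0 <- oxygen_params(M0_umol_cm3_min = 0)
  grid <- tissue_grid(rbind(c(-50, -50, -50), c(150, 50, 50)), spacing_um = 25)
  sol <- solve_oxygen(net, st, tibble::tibble(node_id = 1, po2_mmHg = 60),
                      pars0, grid, max_source_spacing = 10)
  expect_equal(sol$balance$o2_efflux_umol_min, sol$balance$o2_influx_umol_min,
               tolerance = 1e-6)
  expect_equal(extraction_fraction(sol), 0, tolerance = 1e-6)
  # tissue PO2 equals the wall PO2 everywhere (no sources, no sinks)
  expect_equal(mean(sol$tissue$po2_mmHg),
               mean(sol$sources$wall_po2_mmHg), tolerance = 1e-3)
})

test_that("O2 balance closes on the Krogh fixture", {
  k <- memo("krogh10", krogh_solution(10))
  b <- k$sol$balance
  expect_lt(abs(b$o2_influx_umol_min - b$o2_efflux_umol_min -
                  b$consumption_umol_min),
            0.02 * b$consumption_umol_min)
})

test_that("tissue PO2 matches the Krogh closed form within 5% at mid-height", {
  k <- memo("krogh10", krogh_solution(10))
  tz <- k$sol$tissue
  mid <- tz[abs(tz$z_um - 200) < 15, ]
  r <- sqrt((mid$x_um - 50)^2 + (mid$y_um - 50)^2)
  M <- k$pars$M_demand
  Dalpha <- k$pars$D_cm2_s * 60 * k$pars$alpha_umol_cm3_mmHg
  rv <- 3e-4
  Rc <- 40e-4
  krogh <- function(r_cm) M / (4 * Dalpha) * (r_cm^2 - rv^2) -
    M * Rc^2 / (2 * Dalpha) * log(r_cm / rv)
  pred <- krogh(pmax(r, 3) * 1e-4)
  # anchor the closed form at the innermost sampled ring (the wall jump is a
  # separately parameterised mechanism, not the radial diffusion under test)
  inner <- r < 12
  pred <- pred + mean(mid$po2_mmHg[inner]) - mean(pred[inner])
  expect_lt(max(abs(mid$po2_mmHg - pred) / pred), 0.05)
})

test_that("raising the demand lowers mean tissue PO2", {
  k1 <- memo("krogh_m_low", krogh_solution(10, m0 = 0.8, grid_spacing = 14))
  k2 <- memo("krogh_m_mid", krogh_solution(10, m0 = 1.71, grid_spacing = 14))
  k3 <- memo("krogh_m_high", krogh_solution(10, m0 = 2.6, grid_spacing = 14))
  m <- c(mean(k1$sol$tissue$po2_mmHg), mean(k2$sol$tissue$po2_mmHg),
         mean(k3$sol$tissue$po2_mmHg))
  expect_true(all(diff(m) < 0))
})

test_that("the tissue field is grid- and source-refinement independent", {
  # single vessel through a box; fields compared at common probe points
  net <- vascular_network(
    data.frame(node_id = 1:2, x_um = 48, y_um = 48, z_um = c(0, 192),
               is_boundary = TRUE),
    data.frame(segment_id = 1, node_a = 1, node_b = 2, diameter_um = 6,
               length_um = 192, sma = FALSE)
  )
  st <- converge_flow_haematocrit(net, dp_bcs(60, 30), flow_config(seed = 1))
  ang <- seq(0, 2 * pi, length.out = 9)[-9]
  probes <- tibble::tibble(x_um = 48 + 20 * cos(ang),
                           y_um = 48 + 20 * sin(ang), z_um = 96)
  run <- function(grid_spacing, src_spacing) {
    grid <- tissue_grid(rbind(c(0, 0, 0), c(96, 96, 192)),
                        spacing_um = grid_spacing)
    solve_oxygen(net, st, tibble::tibble(node_id = 1, po2_mmHg = 60),
                 oxygen_params(), grid, max_source_spacing = src_spacing,
                 tol = 0.02)
  }
  ref <- po2_at(run(16, 12), probes)
  expect_lt(max(abs(po2_at(run(32, 12), probes) - ref) / ref), 0.01)
  expect_lt(max(abs(po2_at(run(16, 24), probes) - ref) / ref), 0.01)
  expect_lt(max(abs(po2_at(run(16, 6), probes) - ref) / ref), 0.01)
})

test_that("boundary PO2 assignment follows class and depth", {
  net <- fx$cascade_toy
  bcs <- boundary_conditions(data.frame(node_id = c(1, 13), kind = "pressure",
                                        value = c(60, 15)))
  st <- memo("toy_flow", converge_flow_haematocrit(net, bcs, flow_config(seed = 1)))
  bp <- assign_boundary_po2(net, st)
  # node 1 feeds the pial arteriole: 90 mmHg; node 13 is venular outflow
  expect_equal(bp$po2_mmHg[bp$node_id == 1], 90)
  expect_false(13 %in% bp$node_id)  # outflow boundaries carry no inflow PO2
  # a capillary inflow takes the depth curve value
  crv <- boundary_curves()
  expect_equal(capillary_po2_depth(0, crv),
               crv$po2_depth$base_mmHg + crv$po2_depth$amp_mmHg)
})

test_that("missing inflow PO2 raises an error naming the node", {
  net <- two_node_net()
  st <- converge_flow_haematocrit(net, dp_bcs(40, 20), flow_config(seed = 1))
  grid <- tissue_grid(rbind(c(-50, -50, -50), c(150, 50, 50)), spacing_um = 50)
  expect_error(
    solve_oxygen(net, st, tibble::tibble(node_id = 2, po2_mmHg = 60),
                 oxygen_params(), grid),
    "missing inflow boundary PO2.*1"
  )
})
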