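# shared fixtures and memoised heavy objects (built once per test run)

fx <- generate_fixtures()

.memo <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .memo)) assign(key, force(expr), envir = .memo)
  get(key, envir = .memo)
}

small_spec <- function(seed) synthetic_network_spec(seed = seed)

cached_network <- function(seed = 1) {
  memo(paste0("net", seed), generate_cortical_network(small_spec(seed)))
}

cached_baseline <- function(seed = 1, oxygen = FALSE) {
  memo(paste0("bl", seed, "_", oxygen), {
    net <- cached_network(seed)
    baseline_solution(net, oxygen = oxygen, grid_spacing_um = 40,
                      max_source_spacing = 40,
                      config = flow_config(seed = 100 + seed))
  })
}

# two-node, one-segment network with explicit geometry
two_node_net <- function(d = 10, l = 100) {
  vascular_network(
    data.frame(node_id = 1:2, x_um = c(0, l), y_um = 0, z_um = 0,
               is_boundary = TRUE),
    data.frame(segment_id = 1L, node_a = 1L, node_b = 2L,
               diameter_um = d, length_um = l, sma = FALSE)
  )
}

# pressure BCs at both ends of a single vessel
dp_bcs <- function(p1, p2) {
  boundary_conditions(data.frame(node_id = 1:2, kind = "pressure",
                                 value = c(p1, p2)))
}

# independent dense assembly of the constrained-estimation KKT system,
# built with plain loops from the defining formulas; used as the brute-force
# oracle for the sparse path
dense_kkt <- function(net, bcs, config, mu, signs, k_tau, tau0_mag) {
  nodes <- net$nodes
  segs <- net$segments
  n <- nrow(nodes)
  ns <- nrow(segs)
  conv <- 133.322387415 * 1e-24 / (1e-3 * 1e-6) * 1e12 * 60
  shear <- 1e-2 * (1e-6 / 60) / (1e-4)^3
  g <- conv * pi * segs$diameter_um^4 / (128 * mu * segs$length_um)
  M <- matrix(0, ns, n)
  for (j in seq_len(ns)) {
    M[j, match(segs$node_a[j], nodes$node_id)] <- g[j]
    M[j, match(segs$node_b[j], nodes$node_id)] <- -g[j]
  }
  L <- matrix(0, n, ns)
  for (j in seq_len(ns)) {
    L[match(segs$node_a[j], nodes$node_id), j] <- -1
    L[match(segs$node_b[j], nodes$node_id), j] <- 1
  }
  K <- L %*% M
  cvec <- shear * 32 * mu / (pi * segs$diameter_um^3)
  H <- t(M) %*% diag(cvec^2 * segs$length_um, ns) %*% M
  w <- numeric(n)
  for (j in seq_len(ns)) {
    w[match(segs$node_a[j], nodes$node_id)] <-
      w[match(segs$node_a[j], nodes$node_id)] + segs$length_um[j] / 2
    w[match(segs$node_b[j], nodes$node_id)] <-
      w[match(segs$node_b[j], nodes$node_id)] + segs$length_um[j] / 2
  }
  kind <- rep("interior", n)
  val <- rep(NA_real_, n)
  ix <- match(bcs$node_id, nodes$node_id)
  kind[ix] <- bcs$kind
  val[ix] <- bcs$value
  cons <- which(!nodes$is_boundary | kind == "flow")
  pres <- which(kind == "pressure")
  A <- rbind(K[cons, , drop = FALSE],
             diag(n)[pres, , drop = FALSE])
  q0 <- ifelse(kind == "flow" & !is.na(val), val, 0)
  b <- c(-q0[cons], val[pres])
  hess <- k_tau * H + config$k_p * diag(w, n)
  kkt <- rbind(cbind(A, matrix(0, nrow(A), nrow(A))),
               cbind(hess, t(A)))
  rhs <- c(b, config$k_p * w * config$target_pressure +
             k_tau * as.numeric(t(M) %*% (signs * tau0_mag * cvec *
                                            segs$length_um)))
  sol <- solve(kkt, rhs)
  list(p = sol[seq_len(n)], Q = as.numeric(M %*% sol[seq_len(n)]))
}


krogh_solution <- function(spacing_um = 10, m0 = NULL, grid_spacing = 10) {
  net <- fx$krogh
  st <- memo("krogh_flow",
             converge_flow_haematocrit(net, dp_bcs(80, 20), flow_config(seed = 1)))
  pars <- if (is.null(m0)) oxygen_params(P0_mmHg = 0.01)
  else oxygen_params(P0_mmHg = 0.01, M0_umol_cm3_min = m0)
  mask <- function(x, y, z) (x - 50)^2 + (y - 50)^2 <= 40^2
  grid <- tissue_grid(rbind(c(10, 10, 0), c(90, 90, 400)),
                      spacing_um = grid_spacing, mask = mask)
  list(net = net, st = st, pars = pars, grid = grid,
       sol = solve_oxygen(net, st, tibble::tibble(node_id = 1, po2_mmHg = 60),
                          pars, grid, max_source_spacing = spacing_um,
                          tol = 0.02))
}

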