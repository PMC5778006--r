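#' Load an oxygen transport parameter set
#'
#' Physical parameters of the Green's-function oxygen model: tissue
#' diffusivity and solubility, Michaelis-Menten consumption (maximal demand
#' `M0` times the 80--85% operating-range midpoint `demand_scale`), Hill
#' saturation curve, effective blood solubility (constant approximation), and
#' a diameter-indexed intravascular resistance lookup.
#'
#' @param path YAML parameter file; default is the packaged
#'   `oxygen_params.yaml`.
#' @param ... Named overrides of individual entries (e.g. `M0_umol_cm3_min = 0`).
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(path = NULL, ...) {
  if (is.null(path))
    path <- system.file("extdata", "oxygen_params.yaml", package = "cbfsim")
  p <- yaml::read_yaml(path)
  dots <- list(...)
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  stopifnot(p$D_cm2_s > 0, p$alpha_umol_cm3_mmHg > 0, p$hill_n >= 1,
            p$P50_mmHg > 0, p$P0_mmHg > 0, p$M0_umol_cm3_min >= 0)
  p$M_demand <- p$M0_umol_cm3_min * p$demand_scale
  structure(p, class = "oxygen_params")
}

#' @method print oxygen_params
#' @export
print.oxygen_params <- function(x, ...) {
  cat("<oxygen_params> M0 =", x$M0_umol_cm3_min, "(demand",
      signif(x$M_demand, 4), ") umol/cm^3/min; P50 =", x$P50_mmHg,
      "mmHg; n =", x$hill_n, "\n")
  invisible(x)
}

#' Hill oxyhaemoglobin saturation
#'
#' `S(P) = P^n / (P^n + P50^n)`; monotone increasing, `S(P50) = 0.5`.
#'
#' @param p_b Blood PO2, mmHg (>= 0; vectorised).
#' @param params An [oxygen_params()] object.
#' @return Saturation fraction in `[0, 1)`.
#' @export
hill_saturation <- function(p_b, params = oxygen_params()) {
  if (any(p_b < 0)) stop("blood PO2 must be non-negative")
  p_b^params$hill_n / (p_b^params$hill_n + params$P50_mmHg^params$hill_n)
}

#' Michaelis-Menten oxygen consumption rate
#'
#' `M(P) = M * P / (P0 + P)` with `M` the exerted demand
#' (`M0 * demand_scale`); bounded by `M` and half-maximal at `P = P0`.
#'
#' @param p Tissue PO2, mmHg (vectorised; negative values consume nothing).
#' @param params An [oxygen_params()] object.
#' @return Consumption in umol cm^-3 min^-1.
#' @export
consumption_rate <- function(p, params = oxygen_params()) {
  p <- pmax(p, 0)
  params$M_demand * p / (params$P0_mmHg + p)
}

#' Convective oxygen flux
#'
#' Rate of convective O2 transport along a vessel:
#' `f = Q [H_D C0 S(P_b) + alpha_eff P_b]`.
#'
#' @param q_blood_nlmin Blood flow, nl/min.
#' @param h_d Discharge haematocrit.
#' @param p_b Blood PO2, mmHg.
#' @param params An [oxygen_params()] object.
#' @return O2 flux in umol/min.
#' @export
convective_flux <- function(q_blood_nlmin, h_d, p_b, params = oxygen_params()) {
  q_cm3 <- abs(q_blood_nlmin) * .NLMIN_CM3MIN
  q_cm3 * (h_d * params$C0_umol_cm3 * hill_saturation(p_b, params) +
             params$alpha_eff_umol_cm3_mmHg * p_b)
}

# invert concentration -> PO2: solve hd*C0*S(P) + a_eff*P = conc (vectorised
# damped Newton with bisection clamp; conc in umol/cm^3)
invert_blood_po2 <- function(conc, h_d, params, p_init = NULL) {
  n <- length(conc)
  a <- params$alpha_eff_umol_cm3_mmHg
  C0 <- params$C0_umol_cm3
  nh <- params$hill_n
  p50n <- params$P50_mmHg^nh
  P <- if (is.null(p_init)) rep(40, n) else pmax(p_init, 1e-3)
  lo <- rep(0, n); hi <- rep(500, n)
  conc <- pmax(conc, 0)
  for (i in 1:60) {
    Pn <- P^nh
    S <- Pn / (Pn + p50n)
    g <- h_d * C0 * S + a * P - conc
    lo[g < 0] <- P[g < 0]
    hi[g > 0] <- P[g > 0]
    dS <- nh * P^(nh - 1) * p50n / (Pn + p50n)^2
    step <- g / (h_d * C0 * dS + a)
    P <- P - step
    bad <- P <= lo | P >= hi | !is.finite(P)
    P[bad] <- (lo[bad] + hi[bad]) / 2
    if (max(abs(step[is.finite(step)]), 0) < 1e-10) break
  }
  pmax(P, 0)
}

#' Discretise vessels into oxygen source elements
#'
#' Splits every segment into equal axial sub-elements no longer than
#' `max_source_spacing`; each element carries one point source on the vessel
#' axis (wall values use a ring-average at the vessel radius). Every segment
#' gets at least one element.
#'
#' @param net A `vasc_network`.
#' @param max_source_spacing Maximum element length, um (default 20).
#' @return Tibble of source elements: `source_id`, `segment_id`, positions
#'   (um), `ds_um`, `radius_um`, `s_frac` (fractional position along the
#'   segment, from `node_a`).
#' @export
discretize_sources <- function(net, max_source_spacing = 20) {
  stopifnot(max_source_spacing > 0)
  segs <- net$segments
  nodes <- net$nodes
  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  n_el <- pmax(1L, ceiling(segs$length_um / max_source_spacing))
  idx <- rep(seq_len(nrow(segs)), n_el)
  within <- unlist(lapply(n_el, seq_len))
  frac <- (within - 0.5) / n_el[idx]
  dx <- nodes$x_um[ib] - nodes$x_um[ia]
  dy <- nodes$y_um[ib] - nodes$y_um[ia]
  dz <- nodes$z_um[ib] - nodes$z_um[ia]
  chord <- pmax(sqrt(dx^2 + dy^2 + dz^2), 1e-12)
  tibble::tibble(
    source_id = seq_along(idx),
    segment_id = segs$segment_id[idx],
    x_um = nodes$x_um[ia][idx] + frac * dx[idx],
    y_um = nodes$y_um[ia][idx] + frac * dy[idx],
    z_um = nodes$z_um[ia][idx] + frac * dz[idx],
    ds_um = segs$length_um[idx] / n_el[idx],
    radius_um = segs$diameter_um[idx] / 2,
    s_frac = frac,
    ux = (dx / chord)[idx],
    uy = (dy / chord)[idx],
    uz = (dz / chord)[idx]
  )
}

#' Regular tissue sampling grid
#'
#' Cell-centred rectangular grid over a bounding box; each point carries its
#' cell volume. An optional mask keeps a subset of cells (e.g. a coaxial
#' cylinder for the Krogh fixture).
#'
#' @param bbox 2x3 matrix (rows = min/max, cols = x/y/z, um), or a
#'   `vasc_network` whose node bounding box is used.
#' @param spacing_um Target cell edge length (default 30 um).
#' @param mask Optional predicate `function(x, y, z)` returning `TRUE` for
#'   cells to keep.
#' @return Tibble with `x_um`, `y_um`, `z_um`, `vol_um3`.
#' @export
tissue_grid <- function(bbox, spacing_um = 30, mask = NULL) {
  if (inherits(bbox, "vasc_network")) {
    p <- bbox$nodes
    bbox <- rbind(c(min(p$x_um), min(p$y_um), min(p$z_um)),
                  c(max(p$x_um), max(p$y_um), max(p$z_um)))
  }
  centres <- lapply(1:3, function(k) {
    w <- bbox[2, k] - bbox[1, k]
    n <- max(1L, round(w / spacing_um))
    bbox[1, k] + (seq_len(n) - 0.5) * w / n
  })
  ns <- vapply(centres, length, integer(1))
  vol <- prod((bbox[2, ] - bbox[1, ]) / ns)
  g <- expand.grid(x_um = centres[[1]], y_um = centres[[2]], z_um = centres[[3]])
  g$vol_um3 <- vol
  g <- tibble::as_tibble(g)
  if (!is.null(mask)) g <- g[mask(g$x_um, g$y_um, g$z_um), ]
  g
}

# diameter-indexed intravascular resistance
k_iv_lookup <- function(diameter_um, params) {
  tab <- params$K_iv
  if (is.null(tab)) return(rep(params$K_iv_constant_fallback, length(diameter_um)))
  stats::approx(tab$diameter_um, tab$K_mmHg_per_umol_cm_min, xout = diameter_um,
                rule = 2)$y
}

#' Assign boundary PO2 at network inflows
#'
#' Arteriolar inflow boundaries get 90 mmHg, venular inflows 40 mmHg, and
#' capillary inflows the value of a cortical-depth curve evaluated at the
#' boundary node's depth.
#'
#' @param net A classified `vasc_network`.
#' @param state A converged `flow_state` (defines which boundaries inflow).
#' @param capillary_curve Function of depth (um) returning PO2 (mmHg);
#'   default is the packaged [capillary_po2_depth()] curve.
#' @param arteriole_po2,venule_po2 Class values, mmHg (defaults 90 and 40).
#' @return Tibble `node_id`, `po2_mmHg` for every inflow boundary node.
#' @export
assign_boundary_po2 <- function(net, state, capillary_curve = NULL,
                                arteriole_po2 = 90, venule_po2 = 40) {
  if (!"class" %in% names(net$segments))
    stop("classes not assigned; run classify_vessels() first")
  if (is.null(capillary_curve)) {
    crv <- boundary_curves()
    capillary_curve <- function(depth) capillary_po2_depth(depth, crv)
  }
  nodes <- net$nodes
  segs <- net$segments
  q0 <- state$nodes$boundary_inflow_nlmin
  bix <- which(nodes$is_boundary & q0 > 0)
  dep <- node_depth(net)
  seg_of <- vapply(bix, function(k) {
    which(segs$node_a == nodes$node_id[k] | segs$node_b == nodes$node_id[k])[1]
  }, integer(1))
  cls <- segs$class[seg_of]
  po2 <- ifelse(cls == "arteriole", arteriole_po2,
                ifelse(cls == "venule", venule_po2, NA_real_))
  cap <- is.na(po2)
  po2[cap] <- capillary_curve(dep[bix][cap])
  tibble::tibble(node_id = nodes$node_id[bix], po2_mmHg = po2)
}

# free-space diffusion kernel: mmHg at distance r_cm per unit source (umol/min)
greens_coef <- function(params) {
  1 / (4 * pi * params$D_cm2_s * 60 * params$alpha_umol_cm3_mmHg)
}

#' Tissue PO2 field from a set of point sources
#'
#' Superposition of the free-space kernel `G = 1/(4 pi D alpha r)`; the
#' elementary building block of the Green's-function solution (linear in the
#' source strengths).
#'
#' @param points Data frame with `x_um`, `y_um`, `z_um`.
#' @param sources Data frame with `x_um`, `y_um`, `z_um`, `strength_umol_min`,
#'   and optionally `radius_um` (kernel floor; default 1 um).
#' @param params An [oxygen_params()] object.
#' @return Numeric PO2 (mmHg) at each point.
#' @export
tissue_field <- function(points, sources, params = oxygen_params()) {
  r_fl <- if ("radius_um" %in% names(sources)) sources$radius_um else rep(1, nrow(sources))
  G <- if (all(c("ux", "uy", "uz", "ds_um") %in% names(sources))) {
    kernel_matrix_line(points, sources, params = params)
  } else {
    kernel_matrix(points, sources, floor_col = r_fl, params = params)
  }
  as.numeric(G %*% sources$strength_umol_min)
}

# kernel matrix of uniform finite-line sources (columns): each source element
# is a line of length ds_um along (ux, uy, uz) centred at (x, y, z); the
# kernel is the element-averaged potential, with the perpendicular distance
# floored at the vessel radius (closed form via asinh)
kernel_matrix_line <- function(pts, src, params) {
  cf <- greens_coef(params)
  np <- nrow(pts)
  ns <- nrow(src)
  G <- matrix(0, np, ns)
  px <- pts$x_um; py <- pts$y_um; pz <- pts$z_um
  for (j in seq_len(ns)) {
    ax <- px - src$x_um[j]
    ay <- py - src$y_um[j]
    az <- pz - src$z_um[j]
    s0 <- ax * src$ux[j] + ay * src$uy[j] + az * src$uz[j]  # axial offset
    rho2 <- pmax(ax^2 + ay^2 + az^2 - s0^2, 0)
    rho <- pmax(sqrt(rho2), src$radius_um[j])
    h <- src$ds_um[j] / 2
    G[, j] <- cf / (src$ds_um[j] * .UM_CM) *
      (asinh((h - s0) / rho) + asinh((h + s0) / rho))
  }
  G
}

# kernel matrix between `pts` (rows) and `src` (cols); distances floored at
# per-row and/or per-column radii (um): r_eff = max(r, floor_row_i, floor_col_j)
kernel_matrix <- function(pts, src, floor_row = NULL, floor_col = NULL,
                          params) {
  cf <- greens_coef(params)
  dx <- outer(pts$x_um, src$x_um, "-")
  dy <- outer(pts$y_um, src$y_um, "-")
  dz <- outer(pts$z_um, src$z_um, "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  if (!is.null(floor_row)) r <- pmax(r, floor_row)            # recycles by row
  if (!is.null(floor_col)) r <- pmax(r, rep(floor_col, each = nrow(r)))
  cf / (r * .UM_CM)
}

#' Solve steady-state oxygen transport
#'
#' Green's-function solution of coupled intravascular and tissue oxygen
#' transport on a converged flow state. Vessels are represented by axial
#' source elements; tissue consumption by Michaelis-Menten point sinks on a
#' sampling grid. The fixed-point iteration alternates (i) advection of the
#' convective flux along every flow path, (ii) wall coupling through the
#' intravascular-resistance jump condition, (iii) a linear solve for the
#' source strengths with an explicit far-field offset and a zero-net-monopole
#' constraint (total sources + sinks = 0) that enforces global O2
#' conservation, and (iv) a Picard update of the nonlinear sink field with
#' under-relaxation. Negative tissue values are clamped to zero and counted.
#'
#' @param net A classified `vasc_network`.
#' @param state A converged `flow_state` (with `hd`).
#' @param boundary_po2 Tibble `node_id`, `po2_mmHg` covering every inflow
#'   boundary (see [assign_boundary_po2()]).
#' @param params An [oxygen_params()] object.
#' @param grid A [tissue_grid()] tibble.
#' @param max_source_spacing Axial element length bound, um (default 20).
#' @param tol Convergence tolerance on the maximum PO2 change, mmHg
#'   (default 0.05).
#' @param max_iter Maximum fixed-point iterations (default 200).
#' @param relax Initial under-relaxation factor for sources and sinks
#'   (default 0.5); shrunk automatically whenever the residual stalls.
#' @param zero_flow_nlmin Stagnation threshold (default 1e-6).
#' @param init Optional warm start: a previous `oxygen_solution` on the same
#'   grid (and, when the vessel discretisation matches, the same elements).
#' @return An `oxygen_solution`: tibbles `sources` (per-element strength,
#'   blood and wall PO2), `segments` (per-segment mean blood PO2, SO2, wall
#'   PO2), `tissue` (grid PO2), plus `extraction_fraction`, `balance`
#'   (influx / efflux / consumption, umol/min), `clamp_events`, `iterations`.
#' @export
solve_oxygen <- function(net, state, boundary_po2, params = oxygen_params(),
                         grid, max_source_spacing = 20, tol = 0.05,
                         max_iter = 200L, relax = 0.5,
                         zero_flow_nlmin = 1e-6, init = NULL) {
  nodes <- net$nodes
  segs <- net$segments
  src <- discretize_sources(net, max_source_spacing)
  ne <- nrow(src)
  nt <- nrow(grid)
  Q <- state$segments$flow_nlmin
  hd <- state$segments$hd
  if (all(is.na(hd))) stop("flow state carries no haematocrit")
  p <- state$nodes$pressure_mmHg
  inflow0 <- state$nodes$boundary_inflow_nlmin

  # inflow boundary PO2 must be present
  bin <- which(nodes$is_boundary & inflow0 > zero_flow_nlmin)
  po2_at <- boundary_po2$po2_mmHg[match(nodes$node_id[bin], boundary_po2$node_id)]
  if (anyNA(po2_at))
    stop("missing inflow boundary PO2 at node(s): ",
         paste(nodes$node_id[bin][is.na(po2_at)], collapse = ", "))

  seg_row <- match(src$segment_id, segs$segment_id)
  live_seg <- abs(Q) > zero_flow_nlmin
  live <- live_seg[seg_row]
  ds_cm <- src$ds_um * .UM_CM
  Kiv <- k_iv_lookup(segs$diameter_um[seg_row], params)

  # kernel matrices (dense; the solve reuses a single LU factorisation).
  # Observation at the wall of element i floors distances at r_i; observation
  # at a tissue point floors at the emitting radius (vessel or cell).
  cell_r <- (3 * grid$vol_um3 / (4 * pi))^(1 / 3)
  Gvv <- kernel_matrix_line(src, src, params = params)       # wall <- sources
  Gvt <- kernel_matrix(src, grid, floor_row = src$radius_um,
                       floor_col = cell_r, params = params)  # wall <- sinks
  Gtv <- kernel_matrix_line(grid, src, params = params)      # tissue <- sources
  Gtt <- kernel_matrix(grid, grid, floor_col = cell_r,
                       params = params)                      # tissue <- sinks
  diag(Gtt) <- greens_coef(params) * 1.2 / (cell_r * .UM_CM) # uniform-ball mean

  il <- which(live)
  nl <- length(il)
  Amat <- Gvv[il, il, drop = FALSE]
  diag(Amat) <- diag(Amat) + Kiv[il] / ds_cm[il]
  Aug <- rbind(cbind(Amat, 1), c(rep(1, nl), 0))
  lu <- tryCatch(Matrix::lu(Aug), error = function(e)
    stop("oxygen source system is singular (", conditionMessage(e), ")"))

  # flow-ordered sweep structures
  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  up <- ifelse(Q >= 0, ia, ib)
  dn <- ifelse(Q >= 0, ib, ia)
  node_ord <- order(p, decreasing = TRUE)
  out_by_node <- split(which(live_seg), up[live_seg])
  el_of_seg <- split(seq_len(ne), seg_row)
  # elements ordered along the flow direction
  el_of_seg <- lapply(el_of_seg, function(e) {
    s <- seg_row[e[1]]
    if (Q[s] >= 0) e[order(src$s_frac[e])] else e[order(-src$s_frac[e])]
  })
  absQ_cm3 <- abs(Q) * .NLMIN_CM3MIN

  sweep_pb <- function(qe) {
    f_node_in <- numeric(nrow(nodes))   # umol/min arriving at each node
    q_node_in <- numeric(nrow(nodes))   # cm^3/min arriving
    # boundary inflow flux
    for (j in seq_along(bin)) {
      k <- bin[j]
      s <- which(up == k & live_seg)[1]
      if (is.na(s)) next
      qin <- inflow0[k] * .NLMIN_CM3MIN
      f_node_in[k] <- f_node_in[k] + qin *
        (hd[s] * params$C0_umol_cm3 * hill_saturation(po2_at[j], params) +
           params$alpha_eff_umol_cm3_mmHg * po2_at[j])
      q_node_in[k] <- q_node_in[k] + qin
    }
    f_mid <- numeric(ne)
    f_in_seg <- numeric(nrow(segs))
    clamped <- 0L
    for (k in node_ord) {
      outs <- out_by_node[[as.character(k)]]
      if (is.null(outs)) next
      # haemoglobin-bound O2 travels with the red cells: daughters leave the
      # junction at a common equilibrium PO2, not a common concentration
      qt <- sum(absQ_cm3[outs])
      hmix <- sum(absQ_cm3[outs] * hd[outs]) / qt
      Pstar <- if (q_node_in[k] > 0)
        invert_blood_po2(f_node_in[k] / qt, hmix, params) else 0
      for (s in outs) {
        f0 <- absQ_cm3[s] *
          (hd[s] * params$C0_umol_cm3 * hill_saturation(Pstar, params) +
             params$alpha_eff_umol_cm3_mmHg * Pstar)
        f_in_seg[s] <- f0
        e <- el_of_seg[[as.character(s)]]
        cq <- cumsum(qe[e])
        fm <- f0 - cq + qe[e] / 2
        neg <- fm < 0
        if (any(neg)) { clamped <- clamped + sum(neg); fm[neg] <- 0 }
        f_mid[e] <- fm
        fend <- max(f0 - cq[length(cq)], 0)
        d <- dn[s]
        f_node_in[d] <- f_node_in[d] + fend
        q_node_in[d] <- q_node_in[d] + absQ_cm3[s]
      }
    }
    list(f_mid = f_mid, f_in_seg = f_in_seg, f_node_in = f_node_in,
         q_node_in = q_node_in, clamped = clamped)
  }

  # physically plausible caps that keep early iterates out of runaway regimes:
  # blood PO2 cannot exceed the highest inflow value, and a single element
  # cannot source/sink far beyond its per-length share of the total demand
  pb_cap <- max(po2_at, 40) * 1.3
  P_t <- rep(40, nt)
  P_b <- rep(40, ne)
  s_sink <- -consumption_rate(P_t, params) * grid$vol_um3 * 1e-12
  qe <- numeric(ne)
  if (nl > 0) qe[il] <- -sum(s_sink) * ds_cm[il] / sum(ds_cm[il])
  Pinf <- 0
  if (!is.null(init) && inherits(init, "oxygen_solution")) {
    if (nrow(init$tissue) == nt) {
      P_t <- init$tissue$po2_mmHg
      s_sink <- init$sinks$strength_umol_min
    }
    if (nrow(init$sources) == ne) {
      qe <- init$sources$strength_umol_min
      P_b <- pmin(init$sources$blood_po2_mmHg, pb_cap)
    }
    Pinf <- init$far_field_offset_mmHg
  }
  clamp_events <- 0L
  history <- numeric(0)
  relax_it <- relax
  for (it in seq_len(max_iter)) {
    # shrink the relaxation whenever the residual stalls (limit-cycle
    # quenching); restore it slowly while progress is steady
    if (it > 2) {
      if (history[it - 1L] > history[it - 2L]) {
        relax_it <- max(relax_it * 0.7, 0.02)
      } else if (history[it - 1L] < 0.9 * history[it - 2L]) {
        relax_it <- min(relax_it * 1.05, relax)
      }
    }
    sw <- sweep_pb(qe)
    conc <- ifelse(absQ_cm3[seg_row] > 0, sw$f_mid / absQ_cm3[seg_row], 0)
    P_b_new <- pmin(invert_blood_po2(conc, hd[seg_row], params, p_init = P_b),
                    pb_cap)
    # stagnant elements equilibrate with the local tissue field
    if (any(!live)) {
      P_b_new[!live] <- pmax(
        as.numeric(Gvv[!live, il, drop = FALSE] %*% qe[il]) +
          as.numeric(Gvt[!live, , drop = FALSE] %*% s_sink) + Pinf, 0)
    }
    P_b <- P_b + relax_it * (P_b_new - P_b)
    rhs <- c(P_b[il] - as.numeric(Gvt[il, , drop = FALSE] %*% s_sink),
             -sum(s_sink))
    sol <- as.numeric(Matrix::solve(lu, rhs))
    qe_new <- numeric(ne)
    qe_new[il] <- sol[seq_len(nl)]
    if (any(!is.finite(qe_new))) stop("oxygen source solve returned NA")
    qcap <- 25 * max(-sum(s_sink), 1e-300) * ds_cm / sum(ds_cm[il])
    qe_new <- pmin(pmax(qe_new, -qcap), qcap)
    qe <- qe + relax_it * (qe_new - qe)
    # far-field offset consistent with the damped sources: wall conditions
    # hold in the mean
    srcw <- as.numeric(Gvv[il, il, drop = FALSE] %*% qe[il]) +
      Kiv[il] * qe[il] / ds_cm[il]
    Pinf <- mean(P_b[il] - as.numeric(Gvt[il, , drop = FALSE] %*% s_sink) - srcw)
    P_t_new <- as.numeric(Gtv[, il, drop = FALSE] %*% qe[il]) +
      as.numeric(Gtt %*% s_sink) + Pinf
    nneg <- sum(P_t_new < 0)
    if (nneg) { clamp_events <- clamp_events + nneg; P_t_new[P_t_new < 0] <- 0 }
    s_new <- -consumption_rate(P_t_new, params) * grid$vol_um3 * 1e-12
    dmax <- max(abs(P_t_new - P_t))
    history <- c(history, dmax)
    P_t <- P_t_new
    s_sink <- s_sink + relax_it * (s_new - s_sink)
    if (it > 2 && dmax < tol) break
  }
  if (history[length(history)] >= tol * 10)
    stop("oxygen fixed point did not converge; residual history: ",
         paste(signif(utils::tail(history, 5), 3), collapse = ", "))

  # final bookkeeping on the converged source strengths
  sw <- sweep_pb(qe)
  influx <- sum(sw$f_node_in[bin])
  bout <- which(nodes$is_boundary & inflow0 < -zero_flow_nlmin)
  efflux <- sum(sw$f_node_in[bout])
  consumption <- -sum(s_sink)
  fs <- factor(seg_row, levels = seq_len(nrow(segs)))
  ds_sum <- as.numeric(tapply(src$ds_um, fs, sum))
  seg_tbl <- tibble::tibble(
    segment_id = segs$segment_id,
    po2_mmHg = as.numeric(tapply(P_b * src$ds_um, fs, sum)) / ds_sum
  )
  seg_tbl$so2 <- hill_saturation(seg_tbl$po2_mmHg, params)
  seg_tbl$wall_po2_mmHg <-
    as.numeric(tapply((P_b - Kiv * qe / ds_cm) * src$ds_um, fs, sum)) / ds_sum
  structure(list(
    sources = tibble::tibble(
      src,
      strength_umol_min = qe,
      q_per_length_umol_cm_min = qe / ds_cm,
      blood_po2_mmHg = P_b,
      wall_po2_mmHg = P_b - Kiv * qe / ds_cm
    ),
    segments = seg_tbl,
    tissue = tibble::tibble(grid, po2_mmHg = P_t),
    sinks = tibble::tibble(grid[, c("x_um", "y_um", "z_um")],
                           strength_umol_min = s_sink,
                           radius_um = cell_r),
    params = params,
    far_field_offset_mmHg = Pinf,
    extraction_fraction = if (influx > 0) (influx - efflux) / influx else NA_real_,
    balance = tibble::tibble(
      o2_influx_umol_min = influx,
      o2_efflux_umol_min = efflux,
      consumption_umol_min = consumption,
      vessel_efflux_umol_min = sum(qe)
    ),
    clamp_events = clamp_events,
    advection_clamped = sw$clamped,
    iterations = length(history),
    residual_history = history
  ), class = "oxygen_solution")
}

#' @method print oxygen_solution
#' @export
print.oxygen_solution <- function(x, ...) {
  cat("<oxygen_solution> ", nrow(x$sources), " vessel elements, ",
      nrow(x$tissue), " tissue cells; mean tissue PO2 ",
      signif(mean(x$tissue$po2_mmHg), 4), " mmHg; OEF ",
      signif(x$extraction_fraction, 3), "; ", x$iterations,
      " iterations\n", sep = "")
  invisible(x)
}

#' Evaluate the tissue PO2 field at arbitrary probe points
#'
#' Superposes the converged vessel sources, tissue sinks and far-field offset
#' of an [solve_oxygen()] solution at the given locations; negative values are
#' clamped to zero.
#'
#' @param solution An `oxygen_solution`.
#' @param points Data frame with `x_um`, `y_um`, `z_um`.
#' @return PO2 (mmHg) at each probe.
#' @export
po2_at <- function(solution, points) {
  p <- solution$params
  src <- solution$sources
  src_tbl <- tibble::tibble(x_um = src$x_um, y_um = src$y_um, z_um = src$z_um,
                            strength_umol_min = src$strength_umol_min,
                            radius_um = src$radius_um)
  v <- tissue_field(points, src_tbl, p) +
    tissue_field(points, solution$sinks, p) +
    solution$far_field_offset_mmHg
  pmax(v, 0)
}

#' Oxygen extraction fraction
#'
#' Fraction of the convected O2 inflow consumed by the network:
#' `(influx - efflux) / influx`.
#'
#' @param solution An `oxygen_solution`.
#' @return A fraction in `[0, 1]`.
#' @export
extraction_fraction <- function(solution) {
  b <- solution$balance
  if (b$o2_influx_umol_min <= 0) stop("zero oxygen inflow")
  (b$o2_influx_umol_min - b$o2_efflux_umol_min) / b$o2_influx_umol_min
}
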