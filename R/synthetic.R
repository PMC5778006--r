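#' Boundary-value curves
#'
#' Loads the parametrised pressure--diameter curves used for pial boundary
#' assignment (arteriolar side rising towards ~75 mmHg, venular side falling
#' towards ~15 mmHg, pivoting on a 31 mmHg mean capillary pressure) and the
#' capillary-inflow PO2 versus cortical-depth curve.
#'
#' @param path YAML file; default is the packaged `boundary_curves.yaml`.
#' @return An object of class `boundary_curves`.
#' @export
boundary_curves <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "boundary_curves.yaml", package = "cbfsim")
  structure(yaml::read_yaml(path), class = "boundary_curves")
}

#' Diameter-dependent boundary pressure
#'
#' Monotone pressure assignment for pial boundary vessels: arterioles increase
#' with diameter towards the upper plateau, venules decrease towards the lower
#' plateau.
#'
#' @param diameter_um Vessel diameter(s), um.
#' @param vessel_class `"arteriole"` or `"venule"` (capillary boundaries are
#'   handled by the experiment BC policy and raise an error here).
#' @param curves A [boundary_curves()] object.
#' @return Pressure(s) in mmHg.
#' @export
boundary_pressure <- function(diameter_um, vessel_class,
                              curves = boundary_curves()) {
  k <- curves$pressure
  if (any(!vessel_class %in% c("arteriole", "venule")))
    stop("boundary_pressure is defined for arterioles and venules only")
  ifelse(vessel_class == "arteriole",
         k$p_cap_mmHg + k$a_span_mmHg /
           (1 + exp(-(diameter_um - k$a_mid_um) / k$a_scale_um)),
         k$p_cap_mmHg - k$v_span_mmHg /
           (1 + exp(-(diameter_um - k$v_mid_um) / k$v_scale_um)))
}

#' Capillary inflow PO2 versus cortical depth
#'
#' Smooth positive curve `base + amp * exp(-depth/decay)`; depths outside the
#' declared domain are clamped with a warning.
#'
#' @param depth_um Cortical depth(s), um.
#' @param curves A [boundary_curves()] object.
#' @return PO2 in mmHg.
#' @export
capillary_po2_depth <- function(depth_um, curves = boundary_curves()) {
  k <- curves$po2_depth
  if (any(depth_um < 0 | depth_um > k$depth_max_um)) {
    warning("depth outside [0, ", k$depth_max_um, "] um clamped")
    depth_um <- pmin(pmax(depth_um, 0), k$depth_max_um)
  }
  k$base_mmHg + k$amp_mmHg * exp(-depth_um / k$decay_um)
}

#' Synthetic cortical network specification
#'
#' Generator parameters for cortical-like vascular networks: pial vessels at
#' the surface feeding descending penetrating arterioles (SMA, > 10 um),
#' precapillary side branches (SMA, < 10 um), a jittered 3-D capillary
#' lattice (3--9 um, no SMA) and ascending venular trees (non-SMA, > 8 um)
#' draining to pial venules, inside a 420 x 420 x 400 um^3 tissue block.
#'
#' @param seed Mandatory integer seed; the network is a pure function of the
#'   spec.
#' @param domain_um Domain edge lengths, um.
#' @param n_penetrating,n_venule_trees Counts of descending arteriolar trunks
#'   and ascending venular trunks.
#' @param capillary_spacing_um Capillary lattice pitch.
#' @param capillary_jitter Jitter amplitude as a fraction of the pitch.
#' @param capillary_degree Target mean degree of the capillary mesh.
#' @param capillary_diameter_range,capillary_diameter_mean,capillary_diameter_sd
#'   Truncated-normal capillary diameter model (um).
#' @param penetrating_diameter_range Trunk taper (deep end, surface end), um.
#' @param pial_arteriole_diameter_range,pial_venule_diameter_range Pial vessel
#'   diameters, um.
#' @param precapillary_diameter_range Precapillary branch diameters, um
#'   (must stay below 10).
#' @param venule_trunk_diameter_range Venular trunk taper (deep, surface), um.
#' @param trunk_step_um Axial step of descending trunks.
#' @param branch_reach_um Search radius when attaching branches to the
#'   capillary lattice.
#' @param n_capillary_stubs Number of capillary boundary stubs cut at the
#'   domain faces.
#' @return A `synthetic_network_spec` list.
#' @export
synthetic_network_spec <- function(
    seed,
    domain_um = c(420, 420, 400),
    n_penetrating = 2L,
    n_venule_trees = 2L,
    capillary_spacing_um = 62,
    capillary_jitter = 0.22,
    capillary_degree = 3,
    capillary_diameter_range = c(3, 9),
    capillary_diameter_mean = 5.5,
    capillary_diameter_sd = 1.2,
    penetrating_diameter_range = c(11, 18),
    pial_arteriole_diameter_range = c(20, 26),
    pial_venule_diameter_range = c(12, 16),
    precapillary_diameter_range = c(5, 9),
    venule_trunk_diameter_range = c(9, 13),
    trunk_step_um = 50,
    branch_reach_um = 130,
    n_capillary_stubs = 12L) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(capillary_diameter_range[1] >= 3, capillary_diameter_range[2] <= 9,
            precapillary_diameter_range[2] < 10,
            penetrating_diameter_range[1] > 10,
            venule_trunk_diameter_range[1] > 8)
  structure(as.list(environment()), class = "synthetic_network_spec")
}

#' Generate a synthetic cortical vascular network
#'
#' Builds a connected cortical-like network from a seeded spec: a jittered
#' cubic capillary lattice (pruned to the target mean degree but kept
#' connected through a random spanning tree), descending penetrating
#' arterioles fed by pial arterioles, SMA precapillary side branches into the
#' lattice, ascending venular trunks with capillary drains and pial venules,
#' and capillary stubs cut at the domain faces. Boundary nodes (degree 1) lie
#' exactly on domain faces; the result is fully reproducible from the seed.
#'
#' @param spec A [synthetic_network_spec()].
#' @return A validated, classified `vasc_network` (classes, subtypes and
#'   capillary branching orders assigned).
#' @export
generate_cortical_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  rng <- local_rng(spec$seed)
  with_rng(rng, build_cortical_network(spec))
}

build_cortical_network <- function(spec) {
  L <- spec$domain_um
  h <- spec$capillary_spacing_um
  nxyz <- pmax(3L, round(L / h))
  pitch <- L / nxyz

  # --- jittered capillary lattice -------------------------------------------
  gi <- expand.grid(i = seq_len(nxyz[1]), j = seq_len(nxyz[2]), k = seq_len(nxyz[3]))
  nc <- nrow(gi)
  jit <- function(n) (stats::runif(n) - 0.5) * 2 * spec$capillary_jitter
  pos <- cbind(
    (gi$i - 0.5 + jit(nc)) * pitch[1],
    (gi$j - 0.5 + jit(nc)) * pitch[2],
    (gi$k - 0.5 + jit(nc)) * pitch[3]
  )
  lat_id <- function(i, j, k) i + (j - 1) * nxyz[1] + (k - 1) * nxyz[1] * nxyz[2]
  edges <- list()
  if (nxyz[1] > 1) edges$x <- cbind(lat_id(gi$i, gi$j, gi$k), lat_id(gi$i + 1, gi$j, gi$k))[gi$i < nxyz[1], ]
  if (nxyz[2] > 1) edges$y <- cbind(lat_id(gi$i, gi$j, gi$k), lat_id(gi$i, gi$j + 1, gi$k))[gi$j < nxyz[2], ]
  if (nxyz[3] > 1) edges$z <- cbind(lat_id(gi$i, gi$j, gi$k), lat_id(gi$i, gi$j, gi$k + 1))[gi$k < nxyz[3], ]
  ee <- do.call(rbind, edges)
  # random spanning tree first (connectivity), then fill to target degree
  g <- igraph::graph_from_edgelist(ee, directed = FALSE)
  igraph::E(g)$eid <- seq_len(nrow(ee))
  igraph::E(g)$w <- stats::runif(nrow(ee))
  mst <- igraph::mst(g, weights = igraph::E(g)$w)
  in_tree <- igraph::E(mst)$eid
  n_target <- ceiling(spec$capillary_degree * nc / 2)
  extra_pool <- setdiff(seq_len(nrow(ee)), in_tree)
  n_extra <- max(0L, min(length(extra_pool), n_target - length(in_tree)))
  keep <- c(in_tree, sample(extra_pool, n_extra))
  cap_edges <- ee[sort(keep), , drop = FALSE]

  nodes <- tibble::tibble(
    node_id = seq_len(nc),
    x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3],
    is_boundary = FALSE
  )
  rtrunc <- function(n, mean, sd, lo, hi) {
    x <- stats::rnorm(n, mean, sd)
    while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
    x
  }
  segs <- tibble::tibble(
    segment_id = seq_len(nrow(cap_edges)),
    node_a = cap_edges[, 1], node_b = cap_edges[, 2],
    diameter_um = rtrunc(nrow(cap_edges), spec$capillary_diameter_mean,
                         spec$capillary_diameter_sd,
                         spec$capillary_diameter_range[1],
                         spec$capillary_diameter_range[2]),
    sma = FALSE
  )
  next_node <- nc
  next_seg <- nrow(segs)
  add_node <- function(x, y, z, boundary = FALSE) {
    next_node <<- next_node + 1L
    nodes <<- dplyr::bind_rows(nodes, tibble::tibble(
      node_id = next_node, x_um = x, y_um = y, z_um = z, is_boundary = boundary))
    next_node
  }
  add_seg <- function(a, b, d, sma) {
    next_seg <<- next_seg + 1L
    segs <<- dplyr::bind_rows(segs, tibble::tibble(
      segment_id = next_seg, node_a = a, node_b = b, diameter_um = d, sma = sma))
    next_seg
  }
  nearest_caps <- function(x, y, z, n, reach, exclude = integer(0)) {
    d2 <- (nodes$x_um[1:nc] - x)^2 + (nodes$y_um[1:nc] - y)^2 +
      (nodes$z_um[1:nc] - z)^2
    cand <- setdiff(order(d2), exclude)
    cand <- cand[d2[cand] <= reach^2][seq_len(min(n, sum(d2[cand] <= reach^2)))]
    cand
  }

  # --- descending trunks (shared builder for arterioles and venules) --------
  margin <- 1.2 * h
  build_trunk <- function(d_range, sma, pial_d_range, depth_frac) {
    x <- stats::runif(1, margin, L[1] - margin)
    y <- stats::runif(1, margin, L[2] - margin)
    zmax <- depth_frac * L[3]
    zs <- seq(0, zmax, by = spec$trunk_step_um)
    ids <- integer(length(zs))
    ids[1] <- add_node(x, y, 0)
    dtap <- seq(d_range[2], d_range[1], length.out = length(zs) - 1)
    for (t in 2:length(zs)) {
      ids[t] <- add_node(x, y, zs[t])
      add_seg(ids[t - 1L], ids[t], dtap[t - 1L], sma)
    }
    # pial feeder: surface path to the nearest x/y face
    dx <- c(x, L[1] - x, y, L[2] - y)
    f <- which.min(dx)
    bx <- switch(f, c(0, y), c(L[1], y), c(x, 0), c(x, L[2]))
    if (f <= 2) { bxy <- c(bx[1], bx[2]) } else { bxy <- c(bx[1], bx[2]) }
    mid <- add_node((x + bxy[1]) / 2, (y + bxy[2]) / 2, 0)
    bnd <- add_node(bxy[1], bxy[2], 0, boundary = TRUE)
    dpial <- stats::runif(1, pial_d_range[1], pial_d_range[2])
    add_seg(ids[1], mid, dpial, sma)
    add_seg(mid, bnd, dpial, sma)
    list(trunk_nodes = ids, x = x, y = y)
  }

  for (t in seq_len(spec$n_penetrating)) {
    tr <- build_trunk(spec$penetrating_diameter_range, TRUE,
                      spec$pial_arteriole_diameter_range, 0.8)
    # precapillary side branches into the lattice
    deep <- tr$trunk_nodes[-1]
    for (nd in deep) {
      caps <- nearest_caps(nodes$x_um[nd], nodes$y_um[nd], nodes$z_um[nd],
                           2L, spec$branch_reach_um)
      for (cn in caps) {
        mx <- (nodes$x_um[nd] + nodes$x_um[cn]) / 2 + jit(1) * pitch[1]
        my <- (nodes$y_um[nd] + nodes$y_um[cn]) / 2 + jit(1) * pitch[2]
        mz <- (nodes$z_um[nd] + nodes$z_um[cn]) / 2 + jit(1) * pitch[3]
        mid <- add_node(mx, my, mz)
        d1 <- stats::runif(1, mean(spec$precapillary_diameter_range),
                           spec$precapillary_diameter_range[2])
        d2 <- stats::runif(1, spec$precapillary_diameter_range[1],
                           mean(spec$precapillary_diameter_range))
        add_seg(nd, mid, d1, TRUE)
        add_seg(mid, cn, d2, TRUE)
      }
    }
  }

  for (t in seq_len(spec$n_venule_trees)) {
    tr <- build_trunk(spec$venule_trunk_diameter_range, FALSE,
                      spec$pial_venule_diameter_range, 0.75)
    deep <- tr$trunk_nodes[-1]
    for (nd in deep) {
      caps <- nearest_caps(nodes$x_um[nd], nodes$y_um[nd], nodes$z_um[nd],
                           3L, spec$branch_reach_um)
      for (cn in caps) {
        add_seg(nd, cn, stats::runif(1, 6.5, 7.8), FALSE)
      }
    }
  }

  # --- capillary stubs cut at the faces -------------------------------------
  n_stub <- spec$n_capillary_stubs
  face <- rep_len(1:4, n_stub)
  for (s in seq_len(n_stub)) {
    fx <- face[s]
    coord <- switch(fx, nodes$x_um[1:nc], L[1] - nodes$x_um[1:nc],
                    nodes$y_um[1:nc], L[2] - nodes$y_um[1:nc])
    cand <- order(coord)[seq_len(8L)]
    cn <- sample(cand, 1L)
    bpos <- c(nodes$x_um[cn], nodes$y_um[cn], nodes$z_um[cn])
    if (fx == 1) bpos[1] <- 0 else if (fx == 2) bpos[1] <- L[1]
    else if (fx == 3) bpos[2] <- 0 else bpos[2] <- L[2]
    bnd <- add_node(bpos[1], bpos[2], bpos[3], boundary = TRUE)
    add_seg(cn, bnd, stats::runif(1, 3.5, 6), FALSE)
  }

  # lengths from geometry; drop duplicate undirected edges if any
  key <- paste(pmin(segs$node_a, segs$node_b), pmax(segs$node_a, segs$node_b))
  segs <- segs[!duplicated(key), ]
  segs$segment_id <- seq_len(nrow(segs))
  net <- vascular_network(nodes, segs, cortical_axis = c(0, 0, 1),
                          validate = FALSE)
  # boundary degree sanity: stub targets may have become degree-1 by pruning
  deg <- node_degree(net)
  net$nodes$is_boundary <- net$nodes$is_boundary & deg == 1L
  if (any(deg == 0L)) {
    keep_n <- deg > 0L
    net$nodes <- net$nodes[keep_n, ]
  }
  validate_network(net)
  net <- classify_vessels(net)
  net <- classify_arteriole_subtype(net)
  capillary_branching_order(net)
}

#' Baseline boundary conditions for a classified network
#'
#' Pial arteriolar and venular boundaries receive diameter-dependent pressure
#' conditions from the [boundary_curves()]; every other (capillary) boundary
#' is marked unknown and handled by the estimation scheme. Boundary
#' haematocrit is uniform.
#'
#' @param net A classified `vasc_network`.
#' @param curves A [boundary_curves()] object.
#' @param boundary_haematocrit Inflow discharge haematocrit (default 0.45).
#' @return A [boundary_conditions()] set.
#' @export
baseline_bcs <- function(net, curves = boundary_curves(),
                         boundary_haematocrit = 0.45) {
  nodes <- net$nodes
  segs <- net$segments
  bix <- which(nodes$is_boundary)
  seg_of <- vapply(bix, function(k) {
    which(segs$node_a == nodes$node_id[k] | segs$node_b == nodes$node_id[k])[1]
  }, integer(1))
  cls <- segs$class[seg_of]
  kind <- ifelse(cls %in% c("arteriole", "venule"), "pressure", "unknown")
  val <- rep(NA_real_, length(bix))
  known <- kind == "pressure"
  val[known] <- boundary_pressure(segs$diameter_um[seg_of[known]], cls[known], curves)
  boundary_conditions(
    tibble::tibble(node_id = nodes$node_id[bix], kind = kind, value = val),
    boundary_haematocrit = boundary_haematocrit
  )
}
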