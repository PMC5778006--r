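#' Perturbation specification
#'
#' Describes one in-silico intervention: a vasoconstriction (negative
#' `diameter_change`) or dilation of one or more target segments with a given
#' spatial extent, or a viscosity scaling (erythrocyte deformation) gated on
#' baseline capillary PO2.
#'
#' @param kind `"constriction"`, `"dilation"` or `"viscosity_scaling"`.
#' @param target_segments Segment ids of the activation sites (ignored for
#'   `viscosity_scaling`).
#' @param diameter_change Signed fraction (> -1), e.g. `-0.1941` for a
#'   -19.41% constriction.
#' @param extent One of `"single_cell_10um"` (a 10 um sub-segment at the
#'   target midpoint), `"whole_vessel"` (to the nearest branch points),
#'   `"bidirectional_cascade"` (whole vessel plus the entire adjoining
#'   penetrating arteriole) or `"unidirectional_cascade"` (whole vessel plus
#'   the penetrating arteriole upstream towards the cortical surface only).
#' @param viscosity_factor Multiplier applied to the viscosity of selected
#'   capillaries in the deformation experiment (default 0.8).
#' @param po2_gate Baseline PO2 threshold, mmHg, selecting capillaries for
#'   deformation (default 25).
#' @param bc_policy `"paper_constriction"` (capillary boundaries at baseline
#'   pressures, arteriolar/venular boundaries at baseline flows, base of the
#'   local penetrating arteriole unknown) or `"baseline"` (reuse the baseline
#'   BC set unchanged).
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(kind = c("constriction", "dilation",
                                       "viscosity_scaling"),
                              target_segments = integer(0),
                              diameter_change = 0,
                              extent = c("single_cell_10um", "whole_vessel",
                                         "bidirectional_cascade",
                                         "unidirectional_cascade"),
                              viscosity_factor = 0.8, po2_gate = 25,
                              bc_policy = c("paper_constriction", "baseline")) {
  kind <- match.arg(kind)
  extent <- match.arg(extent)
  bc_policy <- match.arg(bc_policy)
  stopifnot(diameter_change > -1, viscosity_factor > 0)
  structure(list(kind = kind, target_segments = target_segments,
                 diameter_change = diameter_change, extent = extent,
                 viscosity_factor = viscosity_factor, po2_gate = po2_gate,
                 bc_policy = bc_policy),
            class = "perturbation_spec")
}

# maximal unbranched vessel (path through degree-2 nodes, within one vessel
# class/subtype) containing `sid`; returns segment row indices
vessel_of <- function(net, sid) {
  segs <- net$segments
  deg <- node_degree(net)
  names(deg) <- net$nodes$node_id
  row0 <- match(sid, segs$segment_id)
  if (is.na(row0)) stop("no such segment: ", sid)
  same_vessel <- function(r) {
    ok <- TRUE
    if ("class" %in% names(segs))
      ok <- ok && identical(segs$class[r], segs$class[row0])
    if ("subtype" %in% names(segs))
      ok <- ok && identical(segs$subtype[r], segs$subtype[row0])
    ok
  }
  grow <- function(row, node) {
    path <- integer(0)
    repeat {
      if (deg[as.character(node)] != 2L) break
      nxt <- which((segs$node_a == node | segs$node_b == node) &
                     seq_len(nrow(segs)) != row)
      nxt <- setdiff(nxt, c(row0, path))
      if (length(nxt) != 1L || !same_vessel(nxt)) break
      path <- c(path, nxt)
      node <- if (segs$node_a[nxt] == node) segs$node_b[nxt] else segs$node_a[nxt]
      row <- nxt
    }
    path
  }
  sort(unique(c(grow(row0, segs$node_a[row0]), row0,
                grow(row0, segs$node_b[row0]))))
}

# walk along penetrating-subtype segments from `node`; direction "both" takes
# every connected penetrating segment, "surface" only those whose far endpoint
# is shallower (towards the cortical surface)
penetrating_path <- function(net, node, direction = c("both", "surface")) {
  direction <- match.arg(direction)
  segs <- net$segments
  dep <- node_depth(net)
  names(dep) <- net$nodes$node_id
  is_pen <- !is.na(segs$subtype) & segs$subtype == "penetrating"
  taken <- logical(nrow(segs))
  frontier <- node
  repeat {
    new_rows <- which(is_pen & !taken &
                        (segs$node_a %in% frontier | segs$node_b %in% frontier))
    if (direction == "surface") {
      keep <- vapply(new_rows, function(r) {
        near <- if (segs$node_a[r] %in% frontier) segs$node_a[r] else segs$node_b[r]
        far <- if (segs$node_a[r] == near) segs$node_b[r] else segs$node_a[r]
        dep[as.character(far)] <= dep[as.character(near)] + 1e-9
      }, logical(1))
      new_rows <- new_rows[keep]
    }
    if (!length(new_rows)) break
    taken[new_rows] <- TRUE
    frontier <- unique(c(segs$node_a[new_rows], segs$node_b[new_rows]))
  }
  which(taken)
}

#' Trace upstream to the nearest penetrating arteriole
#'
#' Follows the baseline flow backwards from a target segment (taking the
#' largest inflow at each junction) until a penetrating-arteriole segment is
#' reached. Tracing from a capillary therefore passes through its precapillary
#' arteriole first.
#'
#' @param net A classified `vasc_network` (with subtypes).
#' @param state A converged baseline `flow_state` (defines upstream).
#' @param segment_id The target segment.
#' @return List: `path` (segment ids from the target up to, excluding, the
#'   penetrating segment), `junction_node` (node where the path meets the
#'   penetrating arteriole), `penetrating_segment` (its id).
#' @export
trace_upstream_penetrating <- function(net, state, segment_id) {
  segs <- net$segments
  if (!"subtype" %in% names(segs)) stop("subtypes not assigned")
  Q <- state$segments$flow_nlmin[match(segs$segment_id,
                                       state$segments$segment_id)]
  row <- match(segment_id, segs$segment_id)
  if (is.na(row)) stop("no such segment: ", segment_id)
  is_pen <- !is.na(segs$subtype) & segs$subtype %in% c("penetrating", "pial")
  path <- integer(0)
  cur <- row
  entry <- up_node(segs, Q, cur, entering = TRUE)
  for (step in seq_len(nrow(segs))) {
    if (is_pen[cur]) {
      return(list(path = segs$segment_id[path],
                  junction_node = entry,
                  penetrating_segment = segs$segment_id[cur]))
    }
    if (cur != row) path <- c(path, cur)
    upn <- up_node(segs, Q, cur, entering = TRUE)
    ins <- which((segs$node_a == upn | segs$node_b == upn) &
                   seq_len(nrow(segs)) != cur)
    # inflow segments at upn: their downstream node is upn
    ins <- ins[vapply(ins, function(r) up_node(segs, Q, r, entering = FALSE) == upn,
                      logical(1))]
    if (!length(ins))
      stop("no penetrating arteriole reachable upstream of segment ", segment_id)
    cur <- ins[which.max(abs(Q[ins]))]
    entry <- upn   # node through which the walk enters `cur`
  }
  stop("no penetrating arteriole reachable upstream of segment ", segment_id)
}

# upstream (entering=TRUE) or downstream node of a segment row under flow Q
up_node <- function(segs, Q, row, entering = TRUE) {
  fwd <- Q[row] >= 0
  if (entering == fwd) segs$node_a[row] else segs$node_b[row]
}

#' Apply a constriction or dilation to a network
#'
#' Builds the modified network for a [perturbation_spec()]. For
#' `single_cell_10um` the target segment is split into three colinear
#' sub-segments and the central 10 um piece is rescaled (segments shorter
#' than 10 um are rescaled whole and flagged); the other extents rescale
#' whole-vessel paths and, for cascades, the adjoining penetrating arteriole
#' traced from the baseline flow state.
#'
#' @param net A classified `vasc_network`.
#' @param spec A [perturbation_spec()].
#' @param state Baseline `flow_state`; required for cascade extents.
#' @return List: `network` (modified), `constricted` (segment ids at their
#'   new diameter), `throat` (id of the 10 um piece per target, for
#'   single-cell), `map` (tibble original/child ids for split segments),
#'   `whole_segment_fallback` (targets too short to split).
#' @export
apply_constriction <- function(net, spec, state = NULL) {
  stopifnot(inherits(spec, "perturbation_spec"))
  segs <- net$segments
  scale <- 1 + spec$diameter_change
  rows_target <- match(spec$target_segments, segs$segment_id)
  if (anyNA(rows_target)) stop("unknown target segment(s)")
  out <- net
  throat <- integer(0)
  fallback <- integer(0)
  map <- list()
  constricted <- integer(0)

  if (spec$extent == "single_cell_10um") {
    for (row0 in rows_target) {
      sid <- segs$segment_id[row0]
      srow <- match(sid, out$segments$segment_id)
      l <- out$segments$length_um[srow]
      if (l < 10 + 1e-9) {
        out$segments$diameter_um[srow] <- out$segments$diameter_um[srow] * scale
        fallback <- c(fallback, sid)
        constricted <- c(constricted, sid)
        next
      }
      sp <- split_segment(out, sid, cell_um = 10)
      out <- sp$network
      out$segments$diameter_um[match(sp$throat, out$segments$segment_id)] <-
        out$segments$diameter_um[match(sp$throat, out$segments$segment_id)] * scale
      throat <- c(throat, sp$throat)
      constricted <- c(constricted, sp$throat)
      map[[length(map) + 1L]] <- tibble::tibble(
        original = sid, children = list(sp$children), throat = sp$throat)
    }
  } else {
    rows <- unique(unlist(lapply(rows_target, function(r) vessel_of(net, segs$segment_id[r]))))
    if (spec$extent %in% c("bidirectional_cascade", "unidirectional_cascade")) {
      if (is.null(state)) stop("cascade extents need the baseline flow state")
      for (r in rows_target) {
        sid <- segs$segment_id[r]
        if (!is.na(segs$subtype[r]) && segs$subtype[r] %in% c("penetrating", "pial")) {
          junction <- up_node(segs, state$segments$flow_nlmin, r, entering = TRUE)
        } else {
          tr <- trace_upstream_penetrating(net, state, sid)
          rows <- unique(c(rows, match(tr$path, segs$segment_id)))
          junction <- tr$junction_node
        }
        dirn <- if (spec$extent == "bidirectional_cascade") "both" else "surface"
        rows <- unique(c(rows, penetrating_path(net, junction, dirn)))
      }
    }
    sids <- segs$segment_id[rows]
    srows <- match(sids, out$segments$segment_id)
    out$segments$diameter_um[srows] <- out$segments$diameter_um[srows] * scale
    constricted <- sids
  }
  list(network = out, constricted = constricted, throat = throat,
       map = if (length(map)) dplyr::bind_rows(map) else NULL,
       whole_segment_fallback = fallback)
}

# split segment `sid` into (l-10)/2 | 10 | (l-10)/2 colinear pieces; children
# inherit diameter/sma/class/subtype; returns new network + child ids
split_segment <- function(net, sid, cell_um = 10) {
  segs <- net$segments
  nodes <- net$nodes
  row <- match(sid, segs$segment_id)
  ia <- match(segs$node_a[row], nodes$node_id)
  ib <- match(segs$node_b[row], nodes$node_id)
  l <- segs$length_um[row]
  f1 <- (l - cell_um) / 2 / l
  f2 <- (l + cell_um) / 2 / l
  pa <- c(nodes$x_um[ia], nodes$y_um[ia], nodes$z_um[ia])
  pb <- c(nodes$x_um[ib], nodes$y_um[ib], nodes$z_um[ib])
  nid <- max(nodes$node_id) + 1:2
  newnodes <- tibble::tibble(
    node_id = nid,
    x_um = pa[1] + c(f1, f2) * (pb[1] - pa[1]),
    y_um = pa[2] + c(f1, f2) * (pb[2] - pa[2]),
    z_um = pa[3] + c(f1, f2) * (pb[3] - pa[3]),
    is_boundary = FALSE
  )
  sid_new <- max(segs$segment_id) + 1:3
  tmpl <- segs[rep(row, 3), ]
  tmpl$segment_id <- sid_new
  tmpl$node_a <- c(segs$node_a[row], nid[1], nid[2])
  tmpl$node_b <- c(nid[1], nid[2], segs$node_b[row])
  tmpl$length_um <- c((l - cell_um) / 2, cell_um, (l - cell_um) / 2)
  net$nodes <- dplyr::bind_rows(nodes, newnodes)
  net$segments <- dplyr::bind_rows(segs[-row, ], tmpl)
  list(network = net, children = sid_new, throat = sid_new[2])
}

#' First downstream neighbour of a segment
#'
#' The segment that receives the largest share of the target's outflow at its
#' downstream node, under a given flow state. Used to report velocity changes
#' in the first unconstricted vessel downstream of a constriction site.
#'
#' @param net A `vasc_network`.
#' @param state A `flow_state` defining the flow directions.
#' @param segment_id Target segment.
#' @param exclude Segment ids to walk through rather than report (e.g. the
#'   constricted set): if the largest outflow is excluded the walk continues
#'   from it until the first non-excluded vessel.
#' @return A segment id, or `NA` if the flow path ends at a boundary.
#' @export
downstream_of <- function(net, state, segment_id, exclude = integer(0)) {
  segs <- net$segments
  Q <- state$segments$flow_nlmin[match(segs$segment_id,
                                       state$segments$segment_id)]
  row <- match(segment_id, segs$segment_id)
  if (is.na(row)) stop("no such segment: ", segment_id)
  visited <- integer(0)
  for (step in seq_len(nrow(segs))) {
    dnn <- up_node(segs, Q, row, entering = FALSE)
    outs <- which((segs$node_a == dnn | segs$node_b == dnn) &
                    seq_len(nrow(segs)) != row &
                    !(seq_len(nrow(segs)) %in% visited))
    outs <- outs[vapply(outs, function(r)
      up_node(segs, Q, r, entering = TRUE) == dnn, logical(1))]
    if (!length(outs)) return(NA_integer_)
    best <- outs[which.max(abs(Q[outs]))]
    if (!(segs$segment_id[best] %in% exclude)) return(segs$segment_id[best])
    visited <- c(visited, best)
    row <- best
  }
  NA_integer_
}

#' Apply a global arteriolar dilation
#'
#' Scales the diameter of every SMA-covered segment not labelled pial by
#' `1 + fraction`; capillaries, venules and pial vessels are untouched.
#'
#' @param net A `vasc_network` with subtypes assigned.
#' @param fraction Signed fraction (default +0.045).
#' @return The modified network.
#' @export
apply_global_dilation <- function(net, fraction = 0.045) {
  if (!"subtype" %in% names(net$segments)) stop("subtypes not assigned")
  segs <- net$segments
  sel <- segs$sma & (is.na(segs$subtype) | segs$subtype != "pial")
  net$segments$diameter_um[sel] <- segs$diameter_um[sel] * (1 + fraction)
  net
}

#' Solve a baseline flow (and optionally oxygen) solution
#'
#' Bundles network, boundary conditions, configuration and the converged
#' solutions into a reusable baseline object for the perturbation
#' experiments.
#'
#' @param net A classified `vasc_network`.
#' @param bcs A [boundary_conditions()] set; default [baseline_bcs()].
#' @param config A [flow_config()].
#' @param rheology A [rheology_params()] object.
#' @param oxygen Solve oxygen transport too (default `FALSE`).
#' @param oxygen_params An [oxygen_params()] object.
#' @param grid_spacing_um Tissue grid spacing for the oxygen solve.
#' @param max_source_spacing Vessel source element bound, um.
#' @return A `cbf_baseline` list: `net`, `bcs`, `config`, `rheology`,
#'   `state`, and (optionally) `oxygen`, `oxygen_params`, `grid`.
#' @export
baseline_solution <- function(net, bcs = baseline_bcs(net),
                              config = flow_config(),
                              rheology = rheology_params(),
                              oxygen = FALSE,
                              oxygen_params = cbfsim::oxygen_params(),
                              grid_spacing_um = 40,
                              max_source_spacing = 30) {
  state <- converge_flow_haematocrit(net, bcs, config, rheology)
  out <- list(net = net, bcs = bcs, config = config, rheology = rheology,
              state = state, src_spacing = max_source_spacing)
  if (oxygen) {
    grid <- tissue_grid(net, spacing_um = grid_spacing_um)
    bpo2 <- assign_boundary_po2(net, state)
    out$oxygen <- solve_oxygen(net, state, bpo2, oxygen_params, grid,
                               max_source_spacing = max_source_spacing)
    out$oxygen_params <- oxygen_params
    out$grid <- grid
    out$boundary_po2 <- bpo2
  }
  class(out) <- "cbf_baseline"
  out
}

#' @method print cbf_baseline
#' @export
print.cbf_baseline <- function(x, ...) {
  cat("<cbf_baseline>\n")
  print(x$net)
  print(x$state)
  if (!is.null(x$oxygen)) print(x$oxygen)
  invisible(x)
}

# BC set for the constriction re-solve: capillary boundaries at baseline
# pressures, arteriole/venule boundaries at baseline flows, the boundary node
# feeding the local penetrating arteriole unknown
constriction_bcs <- function(baseline, junction_nodes) {
  net <- baseline$net
  st <- baseline$state
  nodes <- net$nodes
  segs <- net$segments
  bix <- which(nodes$is_boundary)
  seg_of <- vapply(bix, function(k) {
    which(segs$node_a == nodes$node_id[k] | segs$node_b == nodes$node_id[k])[1]
  }, integer(1))
  cls <- segs$class[seg_of]
  p <- st$nodes$pressure_mmHg[match(nodes$node_id[bix], st$nodes$node_id)]
  q0 <- st$nodes$boundary_inflow_nlmin[match(nodes$node_id[bix], st$nodes$node_id)]
  kind <- ifelse(cls == "capillary", "pressure", "flow")
  val <- ifelse(cls == "capillary", p, q0)
  # base of the local penetrating arteriole: boundary reached by tracing the
  # baseline flow upstream from each junction
  Q <- st$segments$flow_nlmin
  for (jn in junction_nodes) {
    base <- trace_to_boundary(net, Q, jn)
    if (!is.na(base)) {
      i <- match(base, nodes$node_id[bix])
      if (!is.na(i)) { kind[i] <- "unknown"; val[i] <- NA_real_ }
    }
  }
  if (!any(kind == "pressure"))
    stop("constriction BC policy left no pressure anchor")
  boundary_conditions(
    tibble::tibble(node_id = nodes$node_id[bix], kind = kind, value = val),
    boundary_haematocrit = attr(baseline$bcs, "boundary_haematocrit") %||% 0.45
  )
}

# map the baseline's estimation warm start onto a (possibly split) modified
# network: shared segments keep their target-shear sign, split children
# inherit the parent's
map_warm <- function(baseline, mod, split_map) {
  w <- attr(baseline$state, "warm")
  if (is.null(w)) return(NULL)
  base_ids <- baseline$net$segments$segment_id
  signs <- w$signs[match(mod$segments$segment_id, base_ids)]
  if (!is.null(split_map) && nrow(split_map)) {
    for (i in seq_len(nrow(split_map))) {
      parent_sign <- w$signs[match(split_map$original[i], base_ids)]
      kids <- split_map$children[[i]]
      signs[match(kids, mod$segments$segment_id)] <- parent_sign
    }
  }
  signs[is.na(signs)] <- 1
  list(signs = signs, k_tau = w$k_tau, tau0_mag = w$tau0_mag)
}

# estimation targets anchored to the baseline state, mapped onto a (possibly
# split) modified network: target pressures are the baseline nodal pressures
# (split nodes inherit the parent segment's endpoint mean) and target shears
# are the baseline signed wall shear stresses (children inherit the parent's);
# a null perturbation is then an exact fixed point of the re-estimation
map_targets <- function(baseline, mod, split_map) {
  bst <- baseline$state
  p0 <- bst$nodes$pressure_mmHg[match(mod$nodes$node_id, bst$nodes$node_id)]
  tau0 <- bst$segments$shear_dyn_cm2[match(mod$segments$segment_id,
                                           bst$segments$segment_id)]
  if (!is.null(split_map) && nrow(split_map)) {
    base_net <- baseline$net
    for (i in seq_len(nrow(split_map))) {
      orig <- split_map$original[i]
      r <- match(orig, base_net$segments$segment_id)
      pa <- bst$nodes$pressure_mmHg[match(base_net$segments$node_a[r],
                                          bst$nodes$node_id)]
      pb <- bst$nodes$pressure_mmHg[match(base_net$segments$node_b[r],
                                          bst$nodes$node_id)]
      kids <- split_map$children[[i]]
      throat_row <- match(split_map$throat[i], mod$segments$segment_id)
      new_nodes <- c(mod$segments$node_a[throat_row],
                     mod$segments$node_b[throat_row])
      p0[match(new_nodes, mod$nodes$node_id)] <- (pa + pb) / 2
      tau0[match(kids, mod$segments$segment_id)] <-
        bst$segments$shear_dyn_cm2[match(orig, bst$segments$segment_id)]
    }
  }
  p0[is.na(p0)] <- mean(bst$nodes$pressure_mmHg)
  tau0[is.na(tau0)] <- 0
  list(p0 = p0, tau0 = tau0)
}

# follow the largest inflow upstream from `node` until a boundary node
trace_to_boundary <- function(net, Q, node) {
  segs <- net$segments
  nodes <- net$nodes
  for (step in seq_len(nrow(segs))) {
    if (nodes$is_boundary[match(node, nodes$node_id)]) return(node)
    ins <- which(segs$node_a == node | segs$node_b == node)
    ins <- ins[vapply(ins, function(r) up_node(segs, Q, r, entering = FALSE) == node,
                      logical(1))]
    if (!length(ins)) return(NA)
    r <- ins[which.max(abs(Q[ins]))]
    node <- up_node(segs, Q, r, entering = TRUE)
  }
  NA
}

#' Run a constriction experiment
#'
#' Applies the constriction described by `spec` to the baseline network,
#' rebuilds boundary conditions per the spec's `bc_policy`, re-runs the
#' coupled flow--haematocrit solve (and the oxygen solve when the baseline
#' carries one), and reports per-segment percentage changes against baseline.
#'
#' @param baseline A [baseline_solution()].
#' @param spec A [perturbation_spec()] of kind `"constriction"` or
#'   `"dilation"`.
#' @param oxygen Recompute oxygen transport (default: whether the baseline
#'   has an oxygen solution).
#' @return A `perturbation_result`; see [summarize_changes()].
#' @export
run_constriction_experiment <- function(baseline, spec,
                                        oxygen = !is.null(baseline$oxygen)) {
  stopifnot(inherits(baseline, "cbf_baseline"))
  net <- baseline$net
  ap <- apply_constriction(net, spec, state = baseline$state)
  mod <- ap$network

  junctions <- integer(0)
  if (spec$bc_policy == "paper_constriction") {
    for (sid in spec$target_segments) {
      r <- match(sid, net$segments$segment_id)
      jn <- if (!is.na(net$segments$subtype[r]) &&
                net$segments$subtype[r] %in% c("penetrating", "pial")) {
        up_node(net$segments, baseline$state$segments$flow_nlmin, r, TRUE)
      } else {
        tryCatch(trace_upstream_penetrating(net, baseline$state, sid)$junction_node,
                 error = function(e) NA)
      }
      if (!is.na(jn)) junctions <- c(junctions, jn)
    }
    bcs <- constriction_bcs(baseline, junctions)
  } else {
    bcs <- baseline$bcs
  }
  state <- tryCatch(
    converge_flow_haematocrit(mod, bcs, baseline$config, baseline$rheology,
                              warm = map_warm(baseline, mod, ap$map),
                              targets = map_targets(baseline, mod, ap$map)),
    error = function(e) stop("perturbed flow solve failed for target(s) ",
                             paste(spec$target_segments, collapse = ","),
                             ": ", conditionMessage(e), call. = FALSE)
  )
  oxy <- NULL
  if (oxygen) {
    bpo2 <- assign_boundary_po2(mod, state)
    oxy <- solve_oxygen(mod, state, bpo2, baseline$oxygen_params,
                        baseline$grid,
                        max_source_spacing = baseline$src_spacing,
                        init = baseline$oxygen)
  }
  perturbation_result(baseline, mod, state, oxy, spec, ap)
}

#' Run an erythrocyte-deformation experiment
#'
#' Selects capillaries whose baseline PO2 falls below `spec$po2_gate`, scales
#' their viscosity by `spec$viscosity_factor` (held fixed through the
#' re-solve), optionally combines this with a global arteriolar dilation, and
#' re-runs flow (and oxygen) with the baseline boundary conditions.
#'
#' @param baseline A [baseline_solution()] carrying an oxygen solution.
#' @param spec A [perturbation_spec()] of kind `"viscosity_scaling"`.
#' @param with_dilation Also apply [apply_global_dilation()] (+4.5% to
#'   non-pial SMA vessels).
#' @param oxygen Recompute oxygen transport (default `TRUE`).
#' @return A `perturbation_result` whose `selected` field lists the deformed
#'   capillaries; empty selections return a no-change result.
#' @export
run_deformation_experiment <- function(baseline, spec, with_dilation = FALSE,
                                       oxygen = TRUE) {
  stopifnot(inherits(baseline, "cbf_baseline"))
  if (is.null(baseline$oxygen))
    stop("deformation gating needs a baseline oxygen solution")
  net <- baseline$net
  po2 <- baseline$oxygen$segments$po2_mmHg[
    match(net$segments$segment_id, baseline$oxygen$segments$segment_id)]
  sel <- net$segments$class == "capillary" & po2 < spec$po2_gate
  selected <- net$segments$segment_id[sel]
  mod <- net
  if (with_dilation) mod <- apply_global_dilation(mod)
  mod$segments$viscosity_factor <- ifelse(sel, spec$viscosity_factor, 1)
  if (!length(selected) && !with_dilation) {
    # empty selection: the pipeline is a no-op by construction
    res <- perturbation_result(baseline, mod, baseline$state, baseline$oxygen,
                               spec, NULL)
    res$selected <- integer(0)
    return(res)
  }
  state <- converge_flow_haematocrit(mod, baseline$bcs, baseline$config,
                                     baseline$rheology,
                                     warm = map_warm(baseline, mod, NULL),
                                     targets = map_targets(baseline, mod, NULL))
  oxy <- NULL
  if (oxygen) {
    bpo2 <- assign_boundary_po2(mod, state)
    oxy <- solve_oxygen(mod, state, bpo2, baseline$oxygen_params,
                        baseline$grid,
                        max_source_spacing = baseline$src_spacing,
                        init = baseline$oxygen)
  }
  res <- perturbation_result(baseline, mod, state, oxy, spec, NULL)
  res$selected <- selected
  res
}

# assemble the percentage-change tables shared by all experiments
perturbation_result <- function(baseline, mod, state, oxy, spec, ap) {
  net <- baseline$net
  base_seg <- baseline$state$segments
  pert_seg <- state$segments
  shared <- intersect(base_seg$segment_id, pert_seg$segment_id)
  b <- base_seg[match(shared, base_seg$segment_id), ]
  p <- pert_seg[match(shared, pert_seg$segment_id), ]
  # nodal pressures -> per-segment mean of endpoints (baseline topology)
  segp <- function(st, nn) {
    pr <- st$nodes$pressure_mmHg[match(nn$nodes$node_id, st$nodes$node_id)]
    ia <- match(nn$segments$node_a, nn$nodes$node_id)
    ib <- match(nn$segments$node_b, nn$nodes$node_id)
    stats::setNames((pr[ia] + pr[ib]) / 2, nn$segments$segment_id)
  }
  pb <- segp(baseline$state, net)[as.character(shared)]
  pp <- segp(state, mod)[as.character(shared)]
  # segments stagnant at baseline carry no meaningful relative change
  qb_all <- b$flow_nlmin
  stag <- abs(qb_all) < max(baseline$config$zero_flow_nlmin,
                            baseline$config$stagnation_rel * mean(abs(qb_all)))
  pct <- function(base, pert, mask = stag) {
    ifelse(mask | abs(base) <= 0, NA_real_, 100 * (pert - base) / abs(base))
  }
  mrow <- match(shared, net$segments$segment_id)
  col_or_na <- function(nm, default) {
    if (nm %in% names(net$segments)) net$segments[[nm]][mrow] else default
  }
  tbl <- tibble::tibble(
    segment_id = shared,
    class = col_or_na("class", NA_character_),
    subtype = col_or_na("subtype", NA_character_),
    cap_order = col_or_na("cap_order", NA_integer_),
    pressure_pct = pct(pb, pp, mask = FALSE),
    flow_pct = pct(abs(b$flow_nlmin), abs(p$flow_nlmin)),
    velocity_pct = pct(abs(b$velocity_mm_s), abs(p$velocity_mm_s)),
    hd_pct = pct(b$hd, p$hd)
  )
  if (!is.null(oxy) && !is.null(baseline$oxygen)) {
    ob <- baseline$oxygen$segments$po2_mmHg[
      match(shared, baseline$oxygen$segments$segment_id)]
    op <- oxy$segments$po2_mmHg[match(shared, oxy$segments$segment_id)]
    tbl$po2_pct <- pct(ob, op)
  }
  throat_tbl <- NULL
  if (!is.null(ap) && length(ap$throat)) {
    orig <- ap$map$original
    tb <- base_seg[match(orig, base_seg$segment_id), ]
    tp <- pert_seg[match(ap$map$throat, pert_seg$segment_id), ]
    throat_tbl <- tibble::tibble(
      target = orig, throat = ap$map$throat,
      velocity_pct = 100 * (abs(tp$velocity_mm_s) - abs(tb$velocity_mm_s)) /
        abs(tb$velocity_mm_s),
      flow_pct = 100 * (abs(tp$flow_nlmin) - abs(tb$flow_nlmin)) /
        abs(tb$flow_nlmin)
    )
  } else if (!is.null(ap)) {
    cons <- intersect(ap$constricted, shared)
    throat_tbl <- tbl[match(cons, tbl$segment_id),
                      c("segment_id", "velocity_pct", "flow_pct")]
    names(throat_tbl)[1] <- "target"
    throat_tbl$throat <- throat_tbl$target
  }
  tissue <- NULL
  if (!is.null(oxy) && !is.null(baseline$oxygen)) {
    tb0 <- baseline$oxygen$tissue$po2_mmHg
    tp0 <- oxy$tissue$po2_mmHg
    tissue <- tibble::tibble(
      baseline$oxygen$tissue[, c("x_um", "y_um", "z_um")],
      base_po2 = tb0, pert_po2 = tp0,
      po2_pct = ifelse(tb0 > 0.1, 100 * (tp0 - tb0) / tb0, NA_real_)
    )
  }
  structure(list(
    spec = spec,
    segments = tbl,
    throat = throat_tbl,
    tissue = tissue,
    constricted = if (!is.null(ap)) ap$constricted else integer(0),
    excluded_zero_flow = sum(is.na(tbl$flow_pct)),
    state = state,
    oxygen = oxy,
    network = mod
  ), class = "perturbation_result")
}

#' @method print perturbation_result
#' @export
print.perturbation_result <- function(x, ...) {
  cat("<perturbation_result> ", x$spec$kind, " / ", x$spec$extent, "; ",
      length(x$constricted), " modified segment(s)\n", sep = "")
  if (!is.null(x$throat) && nrow(x$throat)) {
    cat("  throat velocity change: ",
        paste(sprintf("%+.1f%%", x$throat$velocity_pct), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
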