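#' Propagate discharge haematocrit through a flow solution
#'
#' Haematocrit is assigned in topological order of the flow-directed graph
#' (node pressure strictly decreases along flow, so ordering nodes by pressure
#' yields a valid sweep order): converging junctions mix red-cell flux
#' (flux-weighted), diverging bifurcations apply the empirical
#' phase-separation law ([split_haematocrit()]), and junctions of degree > 3
#' are split sequentially, largest-flow daughter first. Segments whose flow
#' magnitude is below the stagnation threshold inherit the haematocrit of
#' their higher-pressure node and are flagged.
#'
#' @param net A `vasc_network`.
#' @param state A `flow_state` (flows + nodal pressures).
#' @param bcs A [boundary_conditions()] set (provides the boundary
#'   haematocrit).
#' @param rheology A [rheology_params()] object.
#' @param zero_flow_nlmin Stagnation threshold (default 1e-6 nl/min).
#' @param split_rank Optional per-segment ranking used to order daughters in
#'   sequential (> 2-way) splitting; defaults to the current |flow|. The
#'   coupled loop freezes this ranking so that near-equal daughter flows
#'   cannot flip the splitting order between iterations.
#' @return A tibble with `segment_id`, `hd`, and logical `stagnant`.
#' @export
propagate_haematocrit <- function(net, state, bcs, rheology = rheology_params(),
                                  zero_flow_nlmin = 1e-6, split_rank = NULL) {
  nodes <- net$nodes
  segs <- net$segments
  n <- nrow(nodes)
  ns <- nrow(segs)
  hd_bnd <- attr(bcs, "boundary_haematocrit") %||% 0.45
  Q <- state$segments$flow_nlmin
  p <- state$nodes$pressure_mmHg
  inflow0 <- state$nodes$boundary_inflow_nlmin

  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  # upstream / downstream node index per segment under the signed flow
  up <- ifelse(Q >= 0, ia, ib)
  dn <- ifelse(Q >= 0, ib, ia)
  absQ <- abs(Q)
  if (is.null(split_rank)) split_rank <- absQ
  live <- absQ > zero_flow_nlmin

  hd <- rep(hd_bnd, ns)
  node_hd <- rep(hd_bnd, n)

  in_segs <- split(which(live), dn[live])
  out_segs <- split(which(live), up[live])

  # Gauss-Seidel sweeps in descending-pressure order. When flow directions
  # follow the pressure gradient the directed graph is acyclic and a single
  # sweep is exact; otherwise (enforced orientations, ties) the sweep is
  # iterated to a fixed point.
  ord <- order(p, decreasing = TRUE)
  for (pass in seq_len(50L)) {
    hd_prev <- hd
    for (k in ord) {
      flux_in <- 0
      flow_in <- 0
      if (nodes$is_boundary[k] && inflow0[k] > zero_flow_nlmin) {
        flow_in <- inflow0[k]
        flux_in <- inflow0[k] * hd_bnd
      }
      ins <- in_segs[[as.character(k)]]
      if (!is.null(ins)) {
        flow_in <- flow_in + sum(absQ[ins])
        flux_in <- flux_in + sum(absQ[ins] * hd[ins])
      }
      mixed <- if (flow_in > 0) flux_in / flow_in else hd_bnd
      node_hd[k] <- mixed
      outs <- out_segs[[as.character(k)]]
      if (is.null(outs) || !length(outs)) next
      if (length(outs) == 1L || flow_in <= 0) {
        hd[outs] <- mixed
      } else {
        # parent diameter: the single feeding segment if there is one,
        # else flow-weighted mean of the feeding diameters
        pd <- if (!is.null(ins) && length(ins) == 1L) segs$diameter_um[ins]
        else if (!is.null(ins) && length(ins)) {
          sum(segs$diameter_um[ins] * absQ[ins]) / sum(absQ[ins])
        } else {
          sum(segs$diameter_um[outs] * absQ[outs]) / sum(absQ[outs])
        }
        hd[outs] <- split_many(mixed, sum(absQ[outs]), pd,
                               absQ[outs], segs$diameter_um[outs], rheology,
                               rank = split_rank[outs])
      }
    }
    if (max(abs(hd - hd_prev)) < 1e-12) break
  }

  # stagnant segments inherit the haematocrit at their higher-pressure node
  stag <- !live
  if (any(stag)) hd[stag] <- node_hd[up[stag]]
  tibble::tibble(segment_id = segs$segment_id, hd = hd, stagnant = stag)
}

# sequential pairwise phase separation for >2 daughters (largest flow first;
# the ordering key can be frozen by the caller to keep the map continuous)
split_many <- function(parent_hd, parent_flow, parent_diameter,
                       flows, diameters, rheology, rank = flows) {
  m <- length(flows)
  if (m == 1L) return(parent_hd)
  if (m == 2L) {
    return(split_haematocrit(parent_hd, parent_flow, parent_diameter,
                             flows, diameters, rheology))
  }
  ord <- order(rank, decreasing = TRUE)
  hd <- numeric(m)
  rest <- ord[-1L]
  rest_flow <- sum(flows[rest])
  rest_diam <- sum(diameters[rest] * flows[rest]) / rest_flow
  two <- split_haematocrit(parent_hd, parent_flow, parent_diameter,
                           c(flows[ord[1L]], rest_flow),
                           c(diameters[ord[1L]], rest_diam), rheology)
  hd[ord[1L]] <- two[1L]
  hd[rest] <- split_many(two[2L], rest_flow, rest_diam,
                         flows[rest], diameters[rest], rheology,
                         rank = rank[rest])
  hd
}

#' Network red-cell flux balance
#'
#' Total boundary red-cell influx and efflux of a flow + haematocrit solution;
#' used to verify global RBC conservation.
#'
#' @param net A `vasc_network`.
#' @param state A `flow_state` whose `segments$hd` is filled.
#' @param bcs A [boundary_conditions()] set.
#' @return One-row tibble: `rbc_influx`, `rbc_efflux` (nl/min of red cells),
#'   and `outflow_mean_hd` (flux-weighted mean haematocrit of the outflows).
#' @export
rbc_balance <- function(net, state, bcs) {
  hd_bnd <- attr(bcs, "boundary_haematocrit") %||% 0.45
  nodes <- net$nodes
  segs <- net$segments
  q0 <- state$nodes$boundary_inflow_nlmin
  bix <- which(nodes$is_boundary)
  # each boundary node has exactly one adjoining segment
  seg_of <- vapply(bix, function(k) {
    which(segs$node_a == nodes$node_id[k] | segs$node_b == nodes$node_id[k])[1]
  }, integer(1))
  inflow <- q0[bix] > 0
  influx <- sum(q0[bix][inflow]) * hd_bnd
  out_q <- -q0[bix][!inflow]
  out_hd <- state$segments$hd[seg_of[!inflow]]
  efflux <- sum(out_q * out_hd)
  tibble::tibble(
    rbc_influx = influx,
    rbc_efflux = efflux,
    outflow_mean_hd = if (sum(out_q) > 0) sum(out_q * out_hd) / sum(out_q) else NA_real_
  )
}
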