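#' Coupled flow--haematocrit solution
#'
#' Alternates the flow solve (boundary-condition estimation when any BC is
#' unknown, plain conservation solve otherwise), the viscosity update from the
#' diameter/haematocrit law, and haematocrit propagation, until the maximum
#' relative flow change and the maximum absolute haematocrit change both fall
#' below `config$flow_hd_tolerance`. The shear-sign pattern of the estimation
#' scheme is warm-started between outer iterations. A per-segment
#' `viscosity_factor` column on `net$segments` (if present) multiplies the law
#' viscosity; this carries the erythrocyte-deformation perturbation.
#'
#' @param net A `vasc_network`.
#' @param bcs A [boundary_conditions()] set.
#' @param config A [flow_config()].
#' @param rheology A [rheology_params()] object.
#' @param warm Optional estimation warm start (`list(signs, k_tau,
#'   tau0_mag)`, as stored in the `warm` attribute of a previous state):
#'   perturbation re-solves continue the baseline's optimisation state
#'   instead of restarting it.
#' @param targets Optional fixed estimation targets (see [estimate_bcs()]):
#'   anchors the re-estimation to a baseline state.
#' @return A converged `flow_state` with `hd` filled; attributes `iterations`
#'   (residual log) and `warm` (continuation state).
#' @export
converge_flow_haematocrit <- function(net, bcs, config = flow_config(),
                                      rheology = rheology_params(),
                                      warm = NULL, targets = NULL) {
  segs <- net$segments
  ns <- nrow(segs)
  vf <- if ("viscosity_factor" %in% names(segs)) segs$viscosity_factor else rep(1, ns)
  hd_bnd <- attr(bcs, "boundary_haematocrit") %||% 0.45
  hd <- rep(hd_bnd, ns)
  any_unknown <- any(bcs$kind == "unknown")
  Q_prev <- NULL
  frozen_dirs <- NULL   # +-1 orientation once the flow pattern has settled
  frozen_stag <- NULL
  frozen_rank <- NULL
  omega <- rep(config$hd_damping, ns)  # per-segment adaptive under-relaxation
  prev_delta <- rep(0, ns)
  log <- list()
  state <- NULL
  for (it in seq_len(config$max_outer_iter)) {
    mu <- effective_viscosity(segs$diameter_um, pmin(hd, 0.99), rheology) * vf
    state <- if (any_unknown) {
      estimate_bcs(net, bcs, config, mu, warm = warm,
                   freeze = !is.null(frozen_dirs), targets = targets)
    } else {
      solve_known_bcs(net, bcs, mu)
    }
    if (any_unknown) warm <- attr(state, "warm")
    Q <- state$segments$flow_nlmin
    if (is.null(frozen_dirs)) {
      hp <- propagate_haematocrit(
        net, state, bcs, rheology,
        zero_flow_nlmin = max(config$zero_flow_nlmin,
                              config$stagnation_rel * mean(abs(Q))))
    } else {
      # propagation on the frozen orientation so that micro-flow direction
      # flicker cannot re-route haematocrit between iterations
      stf <- state
      stf$segments$flow_nlmin <- ifelse(frozen_stag, 0, frozen_dirs * abs(Q))
      hp <- propagate_haematocrit(net, stf, bcs, rheology,
                                  zero_flow_nlmin = config$zero_flow_nlmin,
                                  split_rank = frozen_rank)
    }
    hd_new <- hp$hd
    delta <- hd_new - hd
    # halve the relaxation of any segment whose update oscillates in sign,
    # recover it slowly once the update direction is consistent again
    osc <- delta * prev_delta < 0
    omega[osc] <- pmax(omega[osc] / 2, 0.02)
    omega[!osc] <- pmin(omega[!osc] * 1.15, config$hd_damping)
    prev_delta <- delta
    dq <- if (is.null(Q_prev)) Inf else {
      ref <- pmax(abs(Q_prev), 0.01 * mean(abs(Q_prev)))
      max(abs(Q - Q_prev) / ref)
    }
    dq2 <- if (is.null(Q_prev)) Inf else
      sqrt(sum((Q - Q_prev)^2) / sum(Q_prev^2))
    dh <- max(abs(delta))
    log[[it]] <- c(iter = it, flow_change = dq, flow_change_l2 = dq2,
                   hd_change = dh, frozen = as.numeric(!is.null(frozen_dirs)))
    # per-segment max criterion, with an L2 escape for the case where the
    # global field has converged but a near-stagnant segment still dithers
    # at the numerical floor
    converged <- it > 1 && dh < config$flow_hd_tolerance &&
      (dq < config$flow_hd_tolerance || dq2 < 1e-4)
    hd <- pmin(pmax(hd + (if (it == 1) 1 else omega) * delta, 0), 1)
    if (is.null(frozen_dirs) && dq2 < config$freeze_flow_tol) {
      frozen_dirs <- ifelse(Q >= 0, 1, -1)
      frozen_stag <- abs(Q) <= max(config$zero_flow_nlmin,
                                   config$stagnation_rel * mean(abs(Q)))
      frozen_rank <- abs(Q)
    }
    Q_prev <- Q
    if (converged) {
      state$segments$hd <- hd_new
      state$segments$stagnant <- hp$stagnant
      attr(state, "iterations") <- dplyr::bind_rows(lapply(log, as.list))
      attr(state, "converged") <- TRUE
      return(state)
    }
  }
  hist <- dplyr::bind_rows(lapply(log, as.list))
  stop(paste0(
    "flow-haematocrit iteration did not converge in ", config$max_outer_iter,
    " iterations (last flow change ", signif(hist$flow_change[nrow(hist)], 3),
    ", hd change ", signif(hist$hd_change[nrow(hist)], 3), ")"
  ))
}

#' Vascular perfusion
#'
#' Total boundary inflow divided by tissue mass, scaled per 100 g.
#'
#' @param net A `vasc_network`.
#' @param state A converged `flow_state`.
#' @param tissue_volume_um3 Tissue volume in cubic micrometres (> 0).
#' @param tissue_density_g_ml Tissue density (default 1.05 g/ml).
#' @return Perfusion in ml/min/100 g.
#' @export
perfusion <- function(net, state, tissue_volume_um3,
                      tissue_density_g_ml = 1.05) {
  stopifnot(tissue_volume_um3 > 0)
  q0 <- state$nodes$boundary_inflow_nlmin
  inflow_ml_min <- sum(q0[q0 > 0]) * 1e-6     # nl/min -> ml/min
  mass_g <- tissue_volume_um3 * 1e-12 * tissue_density_g_ml  # um^3 -> ml
  100 * inflow_ml_min / mass_g
}
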