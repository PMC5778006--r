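#' Boundary condition set
#'
#' One row per boundary node. `kind` is `"pressure"` (value in mmHg),
#' `"flow"` (value in nl/min, inflow positive) or `"unknown"` (no value; the
#' node is handled by the estimation scheme). At least one pressure condition
#' is required whenever any condition is known, otherwise the nodal system has
#' no pressure anchor.
#'
#' @param df Data frame with columns `node_id`, `kind`, `value`.
#' @param boundary_haematocrit Discharge haematocrit assigned at inflow
#'   boundaries (default 0.45).
#' @return A `vasc_bcs` tibble.
#' @export
boundary_conditions <- function(df, boundary_haematocrit = 0.45) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("node_id", "kind") %in% names(df)))
  if (!"value" %in% names(df)) df$value <- NA_real_
  bad <- setdiff(unique(df$kind), c("pressure", "flow", "unknown"))
  if (length(bad)) stop("unknown BC kind(s): ", paste(bad, collapse = ", "))
  if (any(df$kind != "unknown" & is.na(df$value)))
    stop("known BCs must carry a value")
  df$value[df$kind == "unknown"] <- NA_real_
  structure(df, class = c("vasc_bcs", class(df)),
            boundary_haematocrit = boundary_haematocrit)
}

#' Flow estimation configuration
#'
#' Tunables of the constrained boundary-condition estimation scheme and of the
#' coupled flow--haematocrit iteration.
#'
#' @param k_p Pressure deviation weight (default 0.1).
#' @param k_tau_init Initial shear deviation weight (default 1e-4); doubled
#'   every outer iteration until the flow-direction pattern repeats.
#' @param target_pressure Target nodal pressure, mmHg (default 31).
#' @param target_shear_init Initial target wall shear stress magnitude,
#'   dyn/cm^2 (default 5); the per-segment sign starts random (seeded) and the
#'   magnitude is updated to the length-weighted mean |shear| of the previous
#'   iterate.
#' @param flow_hd_tolerance Convergence tolerance on relative flow change and
#'   absolute haematocrit change (default 1e-3).
#' @param max_sign_iter Maximum shear-sign iterations (default 60).
#' @param max_outer_iter Maximum flow/haematocrit iterations (default 200).
#' @param hd_damping Under-relaxation of the haematocrit update (default 0.5).
#' @param zero_flow_nlmin Flows below this magnitude are treated as stagnant
#'   in the phase-separation update (default 1e-6 nl/min).
#' @param stagnation_rel Relative stagnation floor: segments whose flow is
#'   below this fraction of the network mean |flow| are additionally treated
#'   as stagnant for direction bookkeeping (default 1e-4).
#' @param k_tau_max Cap on the doubled shear weight, for conditioning
#'   (default 1e4).
#' @param freeze_flow_tol Relative L2 flow change below which the coupled
#'   loop freezes the flow-direction pattern and the estimation objective
#'   (default 0.01).
#' @param seed Seed for the random initial shear signs (default 1).
#' @return A `flow_config` list.
#' @export
flow_config <- function(k_p = 0.1, k_tau_init = 1e-4, target_pressure = 31,
                        target_shear_init = 5, flow_hd_tolerance = 1e-3,
                        max_sign_iter = 60L, max_outer_iter = 200L,
                        hd_damping = 0.5, zero_flow_nlmin = 1e-6,
                        stagnation_rel = 1e-4, k_tau_max = 1e4,
                        freeze_flow_tol = 0.01, seed = 1L) {
  stopifnot(k_p > 0, k_tau_init > 0, flow_hd_tolerance > 0)
  structure(list(
    k_p = k_p, k_tau_init = k_tau_init, target_pressure = target_pressure,
    target_shear_init = target_shear_init,
    flow_hd_tolerance = flow_hd_tolerance,
    max_sign_iter = as.integer(max_sign_iter),
    max_outer_iter = as.integer(max_outer_iter),
    hd_damping = hd_damping, zero_flow_nlmin = zero_flow_nlmin,
    stagnation_rel = stagnation_rel, k_tau_max = k_tau_max,
    freeze_flow_tol = freeze_flow_tol,
    seed = as.integer(seed)
  ), class = "flow_config")
}

#' Assemble network conductance matrices
#'
#' Builds the signed segment conductance matrix `M` (`M[j, k] = +- pi d^4 /
#' (128 mu l)` at the start/end node of segment j, in nl/min per mmHg), the
#' incidence matrix `L` and the nodal conductivity matrix `K = L M`, so that
#' `K p = -Q0` expresses mass conservation with `p` in mmHg.
#'
#' @param net A `vasc_network`.
#' @param viscosities Per-segment effective viscosity, cP.
#' @return List with sparse `M` (segments x nodes), `L` (nodes x segments),
#'   `K` (nodes x nodes) and the conductance vector `g`.
#' @export
assemble_conductance <- function(net, viscosities) {
  segs <- net$segments
  stopifnot(length(viscosities) == nrow(segs), all(viscosities > 0))
  if (any(segs$length_um <= 0)) stop("zero-length segment in assembly")
  n_n <- nrow(net$nodes)
  n_s <- nrow(segs)
  ia <- match(segs$node_a, net$nodes$node_id)
  ib <- match(segs$node_b, net$nodes$node_id)
  g <- .COND_UM_CP_NLMIN * pi * segs$diameter_um^4 /
    (128 * viscosities * segs$length_um)
  M <- Matrix::sparseMatrix(
    i = c(seq_len(n_s), seq_len(n_s)),
    j = c(ia, ib),
    x = c(g, -g),
    dims = c(n_s, n_n)
  )
  L <- Matrix::sparseMatrix(
    i = c(ia, ib),
    j = c(seq_len(n_s), seq_len(n_s)),
    x = c(rep(-1, n_s), rep(1, n_s)),
    dims = c(n_n, n_s)
  )
  list(M = M, L = L, K = L %*% M, g = g)
}

# build a flow_state from nodal pressures
make_flow_state <- function(net, p, mats, viscosities, hd = NULL,
                            extra = list()) {
  segs <- net$segments
  Q <- as.numeric(mats$M %*% p)
  d <- segs$diameter_um
  vel <- Q * .VEL_FACTOR / d^2
  tau <- .SHEAR_FACTOR * 32 * viscosities * Q / (pi * d^3)
  inflow <- -as.numeric(mats$K %*% p)  # K p = -Q0  =>  Q0 = -K p
  st <- structure(list(
    nodes = tibble::tibble(
      node_id = net$nodes$node_id,
      pressure_mmHg = as.numeric(p),
      boundary_inflow_nlmin = ifelse(net$nodes$is_boundary, inflow, 0)
    ),
    segments = tibble::tibble(
      segment_id = segs$segment_id,
      flow_nlmin = Q,
      velocity_mm_s = vel,
      shear_dyn_cm2 = tau,
      viscosity_cP = viscosities,
      hd = if (is.null(hd)) NA_real_ else hd
    )
  ), class = "flow_state")
  for (nm in names(extra)) attr(st, nm) <- extra[[nm]]
  st
}

#' @method print flow_state
#' @export
print.flow_state <- function(x, ...) {
  cat("<flow_state> ", nrow(x$segments), " segments; mean |flow| ",
      signif(mean(abs(x$segments$flow_nlmin)), 4), " nl/min; pressure range [",
      signif(min(x$nodes$pressure_mmHg), 4), ", ",
      signif(max(x$nodes$pressure_mmHg), 4), "] mmHg\n", sep = "")
  invisible(x)
}

#' Solve network flow with fully known boundary conditions
#'
#' Poiseuille flow on the segment graph: solves the nodal conservation system
#' `K p = -Q0` with pressures fixed at pressure-BC nodes. Every boundary node
#' must carry a known condition and at least one must be a pressure.
#'
#' @param net A `vasc_network`.
#' @param bcs A [boundary_conditions()] set with no `"unknown"` rows.
#' @param viscosities Per-segment viscosity, cP.
#' @return A `flow_state` with nodal pressures (mmHg), per-segment flow
#'   (nl/min, positive from `node_a` to `node_b`), velocity (mm/s), wall shear
#'   stress (dyn/cm^2) and viscosity.
#' @export
solve_known_bcs <- function(net, bcs, viscosities) {
  nodes <- net$nodes
  if (any(bcs$kind == "unknown"))
    stop("solve_known_bcs requires fully specified BCs; use estimate_bcs")
  bnd_ids <- nodes$node_id[nodes$is_boundary]
  miss <- setdiff(bnd_ids, bcs$node_id)
  if (length(miss)) stop("boundary node(s) without BC: ", paste(miss, collapse = ", "))
  if (!any(bcs$kind == "pressure"))
    stop("singular system: no pressure boundary condition anchors the pressure level")
  mats <- assemble_conductance(net, viscosities)
  n <- nrow(nodes)
  p <- numeric(n)
  kind <- rep("interior", n)
  val <- rep(NA_real_, n)
  ix <- match(bcs$node_id, nodes$node_id)
  kind[ix] <- bcs$kind
  val[ix] <- bcs$value
  fixed <- kind == "pressure"
  rows <- which(!fixed)             # interior + flow-BC nodes
  Q0 <- numeric(n)
  Q0[kind == "flow"] <- val[kind == "flow"]
  b <- -Q0[rows] - as.numeric(mats$K[rows, fixed, drop = FALSE] %*% val[fixed])
  A <- mats$K[rows, !fixed, drop = FALSE]
  sol <- tryCatch(
    Matrix::solve(A, b),
    error = function(e) stop("flow system could not be solved (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  p[fixed] <- val[fixed]
  p[!fixed] <- as.numeric(sol)
  make_flow_state(net, p, mats, viscosities)
}

#' Estimate unknown boundary conditions
#'
#' Constrained least-squares estimation of nodal pressures when some (or all)
#' boundary values are unknown: minimises the weighted squared deviation of
#' nodal pressures from a target pressure and of segment wall shear stresses
#' from a target shear stress, subject to mass conservation at interior nodes
#' and to the known boundary conditions, via a sparse KKT system in the
#' pressures and Lagrange multipliers. The target shear sign of each segment
#' starts random (seeded), is replaced by the sign of the current flow after
#' each solve, and the shear weight is doubled until two consecutive
#' iterations give identical flow directions in every segment.
#'
#' Within the coupled flow--haematocrit loop the optimisation is continued,
#' not restarted: `warm` carries the previous sign pattern, shear weight and
#' target magnitude, and `freeze = TRUE` performs a single solve with that
#' pattern held fixed (used once the flow-direction pattern has stabilised).
#' The shear weight is capped at `config$k_tau_max` to keep the saddle-point
#' system well conditioned.
#'
#' @param net A `vasc_network`.
#' @param bcs A [boundary_conditions()] set (any subset may be `"unknown"`;
#'   at least one known pressure required).
#' @param config A [flow_config()].
#' @param viscosities Per-segment viscosity, cP.
#' @param warm Optional warm start: list with `signs` (+-1 per segment),
#'   `k_tau`, `tau0_mag`.
#' @param freeze Single solve with the warm pattern held fixed
#'   (requires `warm`).
#' @param targets Optional per-node / per-segment target overrides: a list
#'   with `p0` (target pressure per node, mmHg) and `tau0` (signed target
#'   shear per segment, dyn/cm^2). Used by the perturbation experiments to
#'   anchor the re-estimation to the baseline haemodynamic state, so that a
#'   null perturbation is an exact fixed point; implies a single solve with
#'   fixed targets (the shear weight is taken from `warm`, else the config).
#' @return A `flow_state`; attributes `lambda` (multipliers), `warm` (the
#'   continuation state), `sign_iterations`.
#' @export
estimate_bcs <- function(net, bcs, config = flow_config(), viscosities,
                         warm = NULL, freeze = FALSE, targets = NULL) {
  if (freeze && is.null(warm)) stop("freeze = TRUE requires a warm start")
  nodes <- net$nodes
  n <- nrow(nodes)
  segs <- net$segments
  ns <- nrow(segs)
  if (!any(bcs$kind == "pressure"))
    stop("at least one known pressure boundary condition is required")
  mats <- assemble_conductance(net, viscosities)

  kind <- rep("interior", n)
  val <- rep(NA_real_, n)
  ix <- match(bcs$node_id, nodes$node_id)
  kind[ix] <- bcs$kind
  val[ix] <- bcs$value
  is_int <- !nodes$is_boundary
  r_cons <- which(is_int | kind == "flow")   # conservation rows
  r_pres <- which(kind == "pressure")        # pressure-value rows

  Q0 <- numeric(n)
  Q0[kind == "flow"] <- val[kind == "flow"]
  A <- rbind(
    mats$K[r_cons, , drop = FALSE],
    Matrix::sparseMatrix(i = seq_along(r_pres), j = r_pres, x = 1,
                         dims = c(length(r_pres), n))
  )
  b <- c(-Q0[r_cons], val[r_pres])
  n_c <- nrow(A)

  # shear coefficient: tau_j = c_j * Q_j  (dyn/cm^2 per nl/min)
  cvec <- .SHEAR_FACTOR * 32 * viscosities / (pi * segs$diameter_um^3)
  lvec <- segs$length_um
  H <- Matrix::t(mats$M) %*% (Matrix::Diagonal(ns, cvec^2 * lvec) %*% mats$M)
  # w_k = half the summed length of segments adjoining node k
  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  w <- 0.5 * (tabulate2(ia, lvec, n) + tabulate2(ib, lvec, n))
  W <- Matrix::Diagonal(n, w)
  p0 <- if (!is.null(targets)) targets$p0 else rep(config$target_pressure, n)
  stopifnot(length(p0) == n)

  if (is.null(warm)) {
    rng <- local_rng(config$seed)
    signs <- sample_signs(ns, rng)
    tau0_mag <- config$target_shear_init
    k_tau <- config$k_tau_init
  } else {
    signs <- warm$signs
    tau0_mag <- warm$tau0_mag
    k_tau <- warm$k_tau
  }
  k_p <- config$k_p
  prev_signs <- NULL
  p <- NULL
  history <- list()
  fixed_targets <- !is.null(targets)
  if (fixed_targets) freeze <- TRUE
  for (it in seq_len(config$max_sign_iter)) {
    tau0 <- if (fixed_targets) targets$tau0 else signs * tau0_mag
    kkt <- rbind(
      cbind(A, Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                    dims = c(n_c, n_c))),
      cbind(k_tau * H + k_p * W, Matrix::t(A))
    )
    rhs <- c(b, as.numeric(k_p * W %*% p0) +
               k_tau * as.numeric(Matrix::t(mats$M) %*% (tau0 * cvec * lvec)))
    # sparse QR: robust on the saddle-point structure; residual checked below
    sol <- tryCatch(
      Matrix::qr.coef(Matrix::qr(methods::as(kkt, "CsparseMatrix")), rhs),
      error = function(e) stop("KKT system could not be solved (",
                               conditionMessage(e), ")", call. = FALSE)
    )
    res <- max(abs(as.numeric(kkt %*% sol) - rhs))
    if (!is.finite(res) || res > 1e-10 * max(1, max(abs(rhs))))
      stop("KKT solve residual too large: ", signif(res, 3))
    p <- as.numeric(sol[seq_len(n)])
    lambda <- as.numeric(sol[n + seq_len(n_c)])
    Q <- as.numeric(mats$M %*% p)
    if (anyNA(Q)) stop("KKT solve returned NA")
    # stagnant segments have no meaningful direction: keep the previous sign
    live_q <- abs(Q) > max(config$zero_flow_nlmin,
                           config$stagnation_rel * mean(abs(Q)))
    new_signs <- ifelse(live_q, sign(Q), signs)
    history[[it]] <- new_signs
    # converged when the directions of two consecutive iterates agree
    # (the initial random signs do not count as an iterate)
    if (freeze || (it > 1 && all(new_signs == signs))) {
      final_signs <- if (freeze) signs else new_signs
      st <- make_flow_state(net, p, mats, viscosities, extra = list(
        lambda = lambda,
        warm = list(signs = final_signs, k_tau = k_tau, tau0_mag = tau0_mag),
        sign_iterations = it
      ))
      return(st)
    }
    tau <- cvec * Q
    tau0_mag <- sum(lvec * abs(tau)) / sum(lvec)  # length-weighted mean |tau|
    prev_signs <- signs
    signs <- new_signs
    k_tau <- min(2 * k_tau, config$k_tau_max)
  }
  err <- structure(class = c("cbfsim_sign_error", "error", "condition"),
                   list(message = paste0(
                     "shear-sign pattern did not converge in ",
                     config$max_sign_iter, " iterations"),
                     call = sys.call(-1),
                     last_signs = history[[length(history)]],
                     prev_signs = history[[length(history) - 1L]]))
  stop(err)
}

# sum `values` into bins given by idx (length n)
tabulate2 <- function(idx, values, n) {
  out <- numeric(n)
  add <- tapply(values, idx, sum)
  out[as.integer(names(add))] <- as.numeric(add)
  out
}

# isolated RNG so library code does not disturb the global stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  eval(expr, envir = parent.frame())
}

sample_signs <- function(n, rng) {
  with_rng(rng, sample(c(-1, 1), n, replace = TRUE))
}
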