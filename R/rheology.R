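#' Load a blood rheology parameter set
#'
#' Rheology (apparent viscosity and red-cell phase separation) enters the flow
#' solver only through this parameter object, so alternative parametrisations
#' can be swapped and audited. The packaged default implements the in-vivo
#' apparent viscosity law (endothelial-surface-layer corrected) and the
#' empirical bifurcation partition law; an in-vitro viscosity parametrisation
#' (with the classical Fåhræus–Lindqvist minimum near 7 um) is also shipped.
#'
#' @param path YAML parameter file; default is the packaged
#'   `rheology_params.yaml`.
#' @return An object of class `rheology_params`.
#' @export
rheology_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rheology_params.yaml", package = "cbfsim")
  p <- yaml::read_yaml(path)
  stopifnot(p$plasma_viscosity_cP > 0)
  if (!p$viscosity_law %in% names(p$viscosity_coefficients))
    stop("no coefficients for viscosity law '", p$viscosity_law, "'")
  if (!p$phase_separation_law %in% names(p$phase_separation_coefficients))
    stop("no coefficients for phase separation law '", p$phase_separation_law, "'")
  structure(p, class = "rheology_params")
}

#' @method print rheology_params
#' @export
print.rheology_params <- function(x, ...) {
  cat("<rheology_params> viscosity:", x$viscosity_law,
      "| phase separation:", x$phase_separation_law,
      "| plasma", x$plasma_viscosity_cP, "cP\n")
  invisible(x)
}

#' Effective blood viscosity
#'
#' Apparent viscosity of blood in a microvessel as a function of lumen
#' diameter and discharge haematocrit, from the empirical in-vivo law
#' (default) or the in-vitro law, times the plasma viscosity.
#'
#' @param diameter_um Vessel diameter(s), um (> 0).
#' @param h_d Discharge haematocrit(s) in `[0, 1)`.
#' @param params A [rheology_params()] object.
#' @return Viscosity in cP (vectorised; strictly positive).
#' @export
effective_viscosity <- function(diameter_um, h_d, params = rheology_params()) {
  stopifnot(all(diameter_um > 0))
  if (any(h_d < 0 | h_d >= 1)) stop("h_d must lie in [0, 1)")
  k <- params$viscosity_coefficients[[params$viscosity_law]]
  D <- diameter_um
  mu45 <- k$a1 * exp(k$a2 * D) + k$a3 + k$a4 * exp(k$a5 * D^k$a6)
  C <- (k$c1 + exp(k$c2 * D)) * (-1 + 1 / (1 + k$c3 * D^k$c4)) +
    1 / (1 + k$c3 * D^k$c4)
  href <- k$reference_hd
  frac <- ifelse(
    h_d == 0, 0,
    ((1 - h_d)^C - 1) / ((1 - href)^C - 1)
  )
  if (k$delta_um > 0) {
    if (any(D <= k$delta_um)) stop("diameter below the ESL width")
    shrink <- (D / (D - k$delta_um))^2
    rel <- (1 + (mu45 - 1) * frac * shrink) * shrink
  } else {
    rel <- 1 + (mu45 - 1) * frac
  }
  params$plasma_viscosity_cP * rel
}

#' Red-cell partition at a diverging bifurcation
#'
#' Splits the red-cell flux of a parent vessel between two daughters by the
#' empirical phase-separation (plasma skimming) law. RBC flux is conserved
#' exactly: `sum(Q_i * hd_i) == parent_flow * parent_hd`. A daughter whose
#' predicted haematocrit exceeds `hd_max` is clamped and the excess flux is
#' routed to its sibling.
#'
#' @param parent_hd Discharge haematocrit of the feeding vessel.
#' @param parent_flow Feeding flow (>= 0); zero returns zero haematocrits.
#' @param parent_diameter Feeding diameter, um.
#' @param daughter_flows Length-2 non-negative vector, oriented out of the
#'   bifurcation; must sum to `parent_flow` to solver tolerance.
#' @param daughter_diameters Length-2 vector, um.
#' @param params A [rheology_params()] object.
#' @return Length-2 vector of daughter discharge haematocrits.
#' @export
split_haematocrit <- function(parent_hd, parent_flow, parent_diameter,
                              daughter_flows, daughter_diameters,
                              params = rheology_params()) {
  stopifnot(length(daughter_flows) == 2L, length(daughter_diameters) == 2L,
            all(daughter_flows >= 0))
  if (parent_flow <= 0) return(c(0, 0))
  if (abs(sum(daughter_flows) - parent_flow) >
      1e-6 * max(parent_flow, 1e-12))
    stop("daughter flows do not sum to the parent flow")
  k <- params$phase_separation_coefficients[[params$phase_separation_law]]
  hd_max <- params$hd_max %||% 1.0

  q1 <- daughter_flows[1]
  q2 <- daughter_flows[2]
  if (q1 == 0) return(c(0, parent_hd * parent_flow / q2))
  if (q2 == 0) return(c(parent_hd * parent_flow / q1, 0))

  da <- daughter_diameters[1]
  db <- daughter_diameters[2]
  x <- (1 - parent_hd) / parent_diameter
  A <- k$a * ((da^2 / db^2 - 1) / (da^2 / db^2 + 1)) * x
  B <- 1 + k$b * x
  X0 <- k$x0 * x
  fqb <- q1 / parent_flow
  if (X0 >= 0.5) {
    # degenerate regime (very narrow feed): no skimming, proportional split
    return(c(parent_hd, parent_hd))
  }
  fqe <- if (fqb <= X0) 0
  else if (fqb >= 1 - X0) 1
  else {
    logit <- A + B * log((fqb - X0) / (1 - fqb - X0))
    1 / (1 + exp(-logit))
  }
  flux <- parent_flow * parent_hd
  hd1 <- fqe * flux / q1
  hd2 <- (1 - fqe) * flux / q2
  # clamp with flux reassignment to the sibling
  if (hd1 > hd_max) {
    hd2 <- hd2 + (hd1 - hd_max) * q1 / q2
    hd1 <- hd_max
  }
  if (hd2 > hd_max) {
    hd1 <- hd1 + (hd2 - hd_max) * q2 / q1
    hd2 <- hd_max
  }
  c(hd1, hd2)
}
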