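#' Construct a vascular network
#'
#' A vascular network is the geometric/topological graph of a segmented
#' microvascular bed: nodes with 3-D positions (micrometres) and cylindrical
#' vessel segments with a diameter, length and a smooth-muscle-actin (SMA)
#' coverage flag. Vessel class labels (arteriole / capillary / venule) and
#' arteriole subtypes (pial / penetrating / precapillary) are carried as
#' columns of the segment table once assigned.
#'
#' @param nodes A data frame with columns `node_id`, `x_um`, `y_um`, `z_um`,
#'   `is_boundary` (logical; boundary nodes must have graph degree 1).
#' @param segments A data frame with columns `segment_id`, `node_a`, `node_b`,
#'   `diameter_um`, `length_um` (both strictly positive) and logical `sma`.
#'   If `length_um` is missing it is computed from the node positions.
#' @param cortical_axis Unit 3-vector giving the direction of increasing
#'   cortical depth (default `c(0, 0, 1)`; the cortical surface is the
#'   minimum-depth plane).
#' @param validate Run [validate_network()] on the result (default `TRUE`).
#'
#' @return An object of class `vasc_network`: a list with tibbles `nodes` and
#'   `segments` plus the `cortical_axis`.
#' @export
vascular_network <- function(nodes, segments, cortical_axis = c(0, 0, 1),
                             validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  req_n <- c("node_id", "x_um", "y_um", "z_um", "is_boundary")
  req_s <- c("segment_id", "node_a", "node_b", "diameter_um", "sma")
  miss <- setdiff(req_n, names(nodes))
  if (length(miss)) stop("nodes is missing column(s): ", paste(miss, collapse = ", "))
  miss <- setdiff(req_s, names(segments))
  if (length(miss)) stop("segments is missing column(s): ", paste(miss, collapse = ", "))
  nodes$is_boundary <- as.logical(nodes$is_boundary)
  segments$sma <- as.logical(segments$sma)
  if (!"length_um" %in% names(segments)) {
    ia <- match(segments$node_a, nodes$node_id)
    ib <- match(segments$node_b, nodes$node_id)
    segments$length_um <- sqrt((nodes$x_um[ia] - nodes$x_um[ib])^2 +
                               (nodes$y_um[ia] - nodes$y_um[ib])^2 +
                               (nodes$z_um[ia] - nodes$z_um[ib])^2)
  }
  cortical_axis <- as.numeric(cortical_axis)
  cortical_axis <- cortical_axis / sqrt(sum(cortical_axis^2))
  net <- structure(
    list(nodes = nodes, segments = segments, cortical_axis = cortical_axis),
    class = "vasc_network"
  )
  if (validate) validate_network(net) else net
}

#' Validate a vascular network
#'
#' Checks the structural invariants: segments reference two existing, distinct
#' nodes; no duplicate node or segment ids; diameters and lengths strictly
#' positive; boundary nodes have degree 1; the graph has a single connected
#' component.
#'
#' @param net A `vasc_network`.
#' @return `net`, invisibly unchanged, if valid; otherwise an error naming the
#'   offending record.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "vasc_network"))
  nodes <- net$nodes
  segs <- net$segments
  if (nrow(segs) == 0L) stop("network has no segments")
  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) stop("duplicate node id(s): ", paste(unique(dup), collapse = ", "))
  dup <- segs$segment_id[duplicated(segs$segment_id)]
  if (length(dup)) stop("duplicate segment id(s): ", paste(unique(dup), collapse = ", "))
  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  bad <- segs$segment_id[is.na(ia) | is.na(ib)]
  if (length(bad)) stop("segment(s) reference unknown node id: ",
                        paste(bad, collapse = ", "))
  bad <- segs$segment_id[segs$node_a == segs$node_b]
  if (length(bad)) stop("self-loop segment(s): ", paste(bad, collapse = ", "))
  bad <- segs$segment_id[!(segs$diameter_um > 0)]
  if (length(bad)) stop("non-positive diameter in segment(s): ",
                        paste(bad, collapse = ", "))
  bad <- segs$segment_id[!(segs$length_um > 0)]
  if (length(bad)) stop("non-positive length in segment(s): ",
                        paste(bad, collapse = ", "))
  deg <- node_degree(net)
  bnd <- nodes$node_id[nodes$is_boundary]
  bad <- bnd[deg[match(bnd, nodes$node_id)] != 1L]
  if (length(bad)) stop("boundary node(s) with degree != 1: ",
                        paste(bad, collapse = ", "))
  g <- network_igraph(net)
  if (igraph::count_components(g) != 1L)
    stop("network is not a single connected component (",
         igraph::count_components(g), " components)")
  invisible(net)
}

#' @method print vasc_network
#' @export
print.vasc_network <- function(x, ...) {
  cat("<vasc_network> ", nrow(x$segments), " segments, ", nrow(x$nodes),
      " nodes (", sum(x$nodes$is_boundary), " boundary)\n", sep = "")
  if ("class" %in% names(x$segments)) {
    tab <- table(x$segments$class)
    cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# degree of every node, in nodes-table order
node_degree <- function(net) {
  idx <- c(match(net$segments$node_a, net$nodes$node_id),
           match(net$segments$node_b, net$nodes$node_id))
  tabulate(idx, nbins = nrow(net$nodes))
}

# igraph view of the network (undirected), vertex name = node_id
network_igraph <- function(net) {
  igraph::graph_from_data_frame(
    data.frame(from = as.character(net$segments$node_a),
               to = as.character(net$segments$node_b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(net$nodes$node_id))
  )
}

#' Cortical depth of every node
#'
#' Depth is the projection of the node position on the cortical axis, measured
#' from the minimum-depth (surface) plane, in micrometres.
#'
#' @param net A `vasc_network`.
#' @return Numeric vector aligned with `net$nodes`.
#' @export
node_depth <- function(net) {
  p <- as.matrix(net$nodes[, c("x_um", "y_um", "z_um")])
  d <- drop(p %*% net$cortical_axis)
  d - min(d)
}

# per-segment mean depth (mean of endpoint depths)
segment_depth <- function(net) {
  d <- node_depth(net)
  ia <- match(net$segments$node_a, net$nodes$node_id)
  ib <- match(net$segments$node_b, net$nodes$node_id)
  (d[ia] + d[ib]) / 2
}

#' Summarise a vascular network
#'
#' @param object A `vasc_network`.
#' @param ... Unused.
#' @return A list with `counts` (one-row tibble: segments, nodes, boundary
#'   nodes) and `by_class` (per-class diameter/length mean and sd; only when
#'   classes have been assigned).
#' @method summary vasc_network
#' @export
summary.vasc_network <- function(object, ...) {
  counts <- tibble::tibble(
    n_segments = nrow(object$segments),
    n_nodes = nrow(object$nodes),
    n_boundary = sum(object$nodes$is_boundary)
  )
  by_class <- NULL
  if ("class" %in% names(object$segments)) {
    by_class <- object$segments |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(
        n = dplyr::n(),
        diameter_mean = mean(.data$diameter_um),
        diameter_sd = stats::sd(.data$diameter_um),
        length_mean = mean(.data$length_um),
        length_sd = stats::sd(.data$length_um),
        .groups = "drop"
      )
  }
  structure(list(counts = counts, by_class = by_class),
            class = "summary.vasc_network")
}

#' @method print summary.vasc_network
#' @export
print.summary.vasc_network <- function(x, ...) {
  print(x$counts)
  if (!is.null(x$by_class)) print(x$by_class)
  invisible(x)
}
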