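#' Classify vessel segments
#'
#' Assigns every segment exactly one class:
#' * `arteriole` — any SMA-covered segment;
#' * `venule` — non-SMA segments wider than `venule_diameter_threshold` that
#'   form a connected tree component touching at least one boundary node;
#' * `capillary` — everything else.
#'
#' A non-SMA segment exactly at the threshold falls to `capillary` (the rule
#' is a strict `>`).
#'
#' @param net A `vasc_network` with `sma` flags.
#' @param venule_diameter_threshold Diameter threshold in micrometres
#'   (default 8).
#' @return The network with a `class` column on `segments`.
#' @export
classify_vessels <- function(net, venule_diameter_threshold = 8) {
  segs <- net$segments
  cls <- rep("capillary", nrow(segs))
  cls[segs$sma] <- "arteriole"
  cand <- !segs$sma & segs$diameter_um > venule_diameter_threshold
  if (any(cand)) {
    sub <- segs[cand, ]
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(sub$node_a), to = as.character(sub$node_b)),
      directed = FALSE
    )
    comp <- igraph::components(g)
    bnd <- as.character(net$nodes$node_id[net$nodes$is_boundary])
    touch <- unique(comp$membership[names(comp$membership) %in% bnd])
    keep <- comp$membership[as.character(sub$node_a)] %in% touch
    cls[which(cand)[keep]] <- "venule"
  }
  net$segments$class <- cls
  net
}

#' Classify arteriole subtypes
#'
#' Splits arterioles into:
#' * `penetrating` — diameter >= 10 um (tie at exactly 10 um resolves to the
#'   larger class);
#' * `pial` — penetrating-calibre arterioles whose both endpoints lie within
#'   one mean segment length of the cortical surface plane;
#' * `precapillary` — SMA arterioles < 10 um at the arteriole/capillary
#'   interface.
#'
#' @param net A `vasc_network` with classes assigned
#'   (see [classify_vessels()]).
#' @param penetrating_threshold Diameter split in micrometres (default 10).
#' @return The network with a `subtype` column on `segments`
#'   (`NA` for non-arterioles).
#' @export
classify_arteriole_subtype <- function(net, penetrating_threshold = 10) {
  if (!"class" %in% names(net$segments))
    stop("classes not assigned; run classify_vessels() first")
  segs <- net$segments
  sub <- rep(NA_character_, nrow(segs))
  art <- segs$class == "arteriole"
  big <- art & segs$diameter_um >= penetrating_threshold
  sub[big] <- "penetrating"
  sub[art & !big] <- "precapillary"
  # pial: both endpoints within one mean segment length of the surface plane
  d <- node_depth(net)
  tol <- mean(segs$length_um)
  ia <- match(segs$node_a, net$nodes$node_id)
  ib <- match(segs$node_b, net$nodes$node_id)
  sub[big & d[ia] <= tol & d[ib] <= tol] <- "pial"
  net$segments$subtype <- sub
  net
}

#' Capillary branching order
#'
#' Breadth-first distance, in segment steps, of every capillary segment from
#' the nearest precapillary-arteriole/capillary interface. Order 1 means the
#' capillary shares a node with a precapillary arteriole. Capillaries
#' unreachable from any interface get `NA`.
#'
#' @param net A `vasc_network` with classes (and subtypes) assigned.
#' @return The network with a `cap_order` integer column on `segments`
#'   (`NA` for non-capillaries and unreachable capillaries).
#' @export
capillary_branching_order <- function(net) {
  segs <- net$segments
  if (!"class" %in% names(segs))
    stop("classes not assigned; run classify_vessels() first")
  if (!"subtype" %in% names(segs)) net <- classify_arteriole_subtype(net)
  segs <- net$segments
  is_cap <- segs$class == "capillary"
  is_pre <- !is.na(segs$subtype) & segs$subtype == "precapillary"
  ord <- rep(NA_integer_, nrow(segs))
  # seed nodes: endpoints of precapillary arterioles
  seed_nodes <- unique(c(segs$node_a[is_pre], segs$node_b[is_pre]))
  if (length(seed_nodes) == 0L) {
    net$segments$cap_order <- ord
    return(net)
  }
  # BFS over capillary segments: frontier is a set of nodes
  frontier <- seed_nodes
  visited_nodes <- character(0)
  level <- 0L
  cap_idx <- which(is_cap)
  assigned <- rep(FALSE, length(cap_idx))
  na <- segs$node_a[cap_idx]
  nb <- segs$node_b[cap_idx]
  while (length(frontier) && !all(assigned)) {
    level <- level + 1L
    hit <- !assigned & (na %in% frontier | nb %in% frontier)
    if (!any(hit)) break
    ord[cap_idx[hit]] <- level
    assigned[hit] <- TRUE
    visited_nodes <- union(visited_nodes, frontier)
    frontier <- setdiff(unique(c(na[hit], nb[hit])), visited_nodes)
  }
  net$segments$cap_order <- ord
  net
}
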