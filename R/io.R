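#' Read a vascular network from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`"csv"`}{a directory holding `nodes.csv`
#'     (`node_id,x_um,y_um,z_um,is_boundary`) and `segments.csv`
#'     (`segment_id,node_a,node_b,diameter_um,length_um,sma`).}
#'   \item{`"json"`}{a single JSON file mirroring the two tables plus the
#'     cortical axis.}
#'   \item{`"amira"`}{an Amira SpatialGraph ASCII file (VERTEX / EDGE / POINT
#'     sections); per-point radii are averaged to a segment diameter and the
#'     polyline length is used as the segment length. An optional
#'     `EDGE { int sma }` data section carries the SMA flag.}
#' }
#' All coordinates are taken to be micrometres.
#'
#' @param path File (json/amira) or directory (csv) to read.
#' @param format One of `"csv"`, `"json"`, `"amira"`; guessed from `path`
#'   when omitted.
#' @return A validated [vascular_network()].
#' @export
read_network <- function(path, format = c("auto", "csv", "json", "amira")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "csv"
    else if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
    else "amira"
  }
  if (!file.exists(path)) stop("no such file or directory: ", path)
  switch(format,
    csv = read_network_csv(path),
    json = read_network_json(path),
    amira = read_network_amira(path)
  )
}

#' Write a vascular network to disk
#'
#' Lossless serialisation in any of the formats accepted by [read_network()].
#' Refuses to serialise an empty network.
#'
#' @param net A validated `vasc_network`.
#' @param path Output file (json/amira) or directory (csv; created if absent).
#' @param format `"csv"`, `"json"` or `"amira"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("csv", "json", "amira")) {
  stopifnot(inherits(net, "vasc_network"))
  if (nrow(net$segments) == 0L) stop("refusing to serialise an empty network")
  format <- match.arg(format)
  switch(format,
    csv = write_network_csv(net, path),
    json = write_network_json(net, path),
    amira = write_network_amira(net, path)
  )
  invisible(path)
}

read_network_csv <- function(dir) {
  nf <- file.path(dir, "nodes.csv")
  sf <- file.path(dir, "segments.csv")
  if (!file.exists(nf) || !file.exists(sf))
    stop("expected nodes.csv and segments.csv under ", dir)
  nodes <- utils::read.csv(nf)
  segs <- utils::read.csv(sf)
  ax <- c(0, 0, 1)
  af <- file.path(dir, "cortical_axis.csv")
  if (file.exists(af)) ax <- as.numeric(utils::read.csv(af)[1, ])
  vascular_network(nodes, segs, cortical_axis = ax)
}

write_network_csv <- function(net, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(net$nodes, file.path(dir, "nodes.csv"), row.names = FALSE)
  utils::write.csv(net$segments, file.path(dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(
    stats::setNames(as.data.frame(t(net$cortical_axis)), c("ax", "ay", "az")),
    file.path(dir, "cortical_axis.csv"), row.names = FALSE
  )
}

read_network_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  vascular_network(x$nodes, x$segments,
                   cortical_axis = x$cortical_axis %||% c(0, 0, 1))
}

write_network_json <- function(net, path) {
  jsonlite::write_json(
    list(nodes = net$nodes, segments = net$segments,
         cortical_axis = net$cortical_axis),
    path, digits = NA, auto_unbox = FALSE, pretty = FALSE
  )
}

# ---- Amira SpatialGraph ASCII ----------------------------------------------

read_network_amira <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get_count <- function(what) {
    m <- grep(paste0("^\\s*define\\s+", what, "\\s+"), lines, value = TRUE)
    if (!length(m)) stop("Amira file lacks 'define ", what, "'")
    as.integer(sub(paste0(".*define\\s+", what, "\\s+(\\d+).*"), "\\1", m[1]))
  }
  nv <- get_count("VERTEX")
  ne <- get_count("EDGE")
  np <- get_count("POINT")

  # map declaration "... @k" labels to section meaning
  decl <- grep("@\\d+\\s*$", lines, value = TRUE)
  section_of <- function(pattern) {
    m <- grep(pattern, decl, value = TRUE, ignore.case = TRUE)
    if (!length(m)) return(NA_integer_)
    as.integer(sub(".*@(\\d+)\\s*$", "\\1", m[1]))
  }
  s_coords <- section_of("VertexCoordinates")
  s_conn <- section_of("EdgeConnectivity")
  s_npts <- section_of("NumEdgePoints")
  s_pts <- section_of("EdgePointCoordinates")
  s_thick <- section_of("thickness|Radius")
  s_sma <- section_of("\\bsma\\b")
  s_bnd <- section_of("\\bboundary\\b")
  if (anyNA(c(s_coords, s_conn, s_npts, s_pts)))
    stop("Amira file is missing a required data section")

  at <- grep("^@\\d+\\s*$", lines)
  read_block <- function(k, n_items) {
    i <- at[match(k, as.integer(sub("^@(\\d+)\\s*$", "\\1", lines[at])))]
    if (is.na(i)) stop("Amira data block @", k, " not found")
    vals <- numeric(0)
    j <- i + 1L
    while (length(vals) < n_items && j <= length(lines)) {
      ln <- trimws(lines[j])
      if (grepl("^@\\d+", ln)) break
      if (nzchar(ln)) vals <- c(vals, as.numeric(strsplit(ln, "\\s+")[[1]]))
      j <- j + 1L
    }
    if (length(vals) < n_items) stop("Amira data block @", k, " truncated")
    vals[seq_len(n_items)]
  }

  vc <- matrix(read_block(s_coords, 3L * nv), ncol = 3, byrow = TRUE)
  conn <- matrix(as.integer(read_block(s_conn, 2L * ne)), ncol = 2, byrow = TRUE)
  npts <- as.integer(read_block(s_npts, ne))
  pts <- matrix(read_block(s_pts, 3L * np), ncol = 3, byrow = TRUE)
  thick <- if (!is.na(s_thick)) read_block(s_thick, np) else rep(2.5, np)
  sma <- if (!is.na(s_sma)) as.logical(read_block(s_sma, ne)) else rep(FALSE, ne)

  off <- c(0L, cumsum(npts))
  seg_len <- numeric(ne)
  seg_diam <- numeric(ne)
  for (e in seq_len(ne)) {
    rows <- (off[e] + 1L):off[e + 1L]
    p <- pts[rows, , drop = FALSE]
    if (nrow(p) > 1) {
      seg_len[e] <- sum(sqrt(rowSums((p[-1, , drop = FALSE] -
                                      p[-nrow(p), , drop = FALSE])^2)))
    } else {
      seg_len[e] <- 0
    }
    seg_diam[e] <- 2 * mean(thick[rows])  # per-point radii -> mean diameter
  }
  # straight-line fallback for degenerate polylines
  zero <- seg_len <= 0
  if (any(zero)) {
    a <- conn[zero, 1] + 1L; b <- conn[zero, 2] + 1L
    seg_len[zero] <- sqrt(rowSums((vc[a, , drop = FALSE] - vc[b, , drop = FALSE])^2))
  }

  deg <- tabulate(c(conn[, 1], conn[, 2]) + 1L, nbins = nv)
  is_bnd <- if (!is.na(s_bnd)) as.logical(read_block(s_bnd, nv)) else deg == 1L
  nodes <- tibble::tibble(
    node_id = seq_len(nv),
    x_um = vc[, 1], y_um = vc[, 2], z_um = vc[, 3],
    is_boundary = is_bnd
  )
  segs <- tibble::tibble(
    segment_id = seq_len(ne),
    node_a = conn[, 1] + 1L, node_b = conn[, 2] + 1L,
    diameter_um = seg_diam, length_um = seg_len, sma = sma
  )
  vascular_network(nodes, segs)
}

write_network_amira <- function(net, path) {
  nodes <- net$nodes
  segs <- net$segments
  ia <- match(segs$node_a, nodes$node_id)
  ib <- match(segs$node_b, nodes$node_id)
  nv <- nrow(nodes); ne <- nrow(segs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# AmiraMesh 3D ASCII 2.0",
    "",
    paste("define VERTEX", nv),
    paste("define EDGE", ne),
    paste("define POINT", 2L * ne),
    "",
    "Parameters { ContentType \"HxSpatialGraph\" }",
    "",
    "VERTEX { float[3] VertexCoordinates } @1",
    "EDGE { int[2] EdgeConnectivity } @2",
    "EDGE { int NumEdgePoints } @3",
    "POINT { float[3] EdgePointCoordinates } @4",
    "POINT { float thickness } @5",
    "EDGE { int sma } @6",
    "VERTEX { int boundary } @7",
    ""
  ), con)
  writeLines("@1", con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes$x_um, nodes$y_um, nodes$z_um), con)
  writeLines(c("", "@2"), con)
  writeLines(sprintf("%d %d", ia - 1L, ib - 1L), con)
  writeLines(c("", "@3"), con)
  writeLines(rep("2", ne), con)
  writeLines(c("", "@4"), con)
  for (e in seq_len(ne)) {
    writeLines(sprintf("%.9g %.9g %.9g",
                       c(nodes$x_um[ia[e]], nodes$x_um[ib[e]]),
                       c(nodes$y_um[ia[e]], nodes$y_um[ib[e]]),
                       c(nodes$z_um[ia[e]], nodes$z_um[ib[e]])), con)
  }
  writeLines(c("", "@5"), con)
  writeLines(sprintf("%.9g", rep(segs$diameter_um / 2, each = 2L)), con)
  writeLines(c("", "@6"), con)
  writeLines(sprintf("%d", as.integer(segs$sma)), con)
  writeLines(c("", "@7"), con)
  writeLines(sprintf("%d", as.integer(nodes$is_boundary)), con)
}

# ---- field export -----------------------------------------------------------

#' Export per-segment scalar fields
#'
#' Writes per-segment scalars either as a plain CSV or as legacy VTK polydata
#' (one line cell per segment) for 3-D visualisation.
#'
#' @param net A `vasc_network`.
#' @param values A data frame of per-segment scalars; must contain
#'   `segment_id`, all other numeric columns are exported.
#' @param path Output file.
#' @param format `"csv"` or `"vtk"`.
#' @return `path`, invisibly.
#' @export
export_segment_fields <- function(net, values, path, format = c("csv", "vtk")) {
  format <- match.arg(format)
  values <- tibble::as_tibble(values)
  stopifnot("segment_id" %in% names(values))
  values <- values[match(net$segments$segment_id, values$segment_id), ]
  if (format == "csv") {
    utils::write.csv(values, path, row.names = FALSE)
    return(invisible(path))
  }
  nodes <- net$nodes
  ia <- match(net$segments$node_a, nodes$node_id)
  ib <- match(net$segments$node_b, nodes$node_id)
  ne <- nrow(net$segments)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vascular network fields",
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(nodes), "float")), con)
  writeLines(sprintf("%.9g %.9g %.9g", nodes$x_um, nodes$y_um, nodes$z_um), con)
  writeLines(paste("LINES", ne, 3L * ne), con)
  writeLines(sprintf("2 %d %d", ia - 1L, ib - 1L), con)
  writeLines(paste("CELL_DATA", ne), con)
  for (nm in setdiff(names(values), "segment_id")) {
    v <- values[[nm]]
    if (!is.numeric(v)) next
    writeLines(c(paste("SCALARS", nm, "float 1"), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", v), con)
  }
  invisible(path)
}

#' Canonical topology hash of a network
#'
#' Order-independent digest of topology, geometry (rounded to 1e-6 um) and
#' flags; identical hashes imply identical networks up to row order and
#' segment orientation.
#'
#' @param net A `vasc_network`.
#' @return A character scalar.
#' @export
network_hash <- function(net) {
  n <- net$nodes[order(net$nodes$node_id), ]
  s <- net$segments
  ends <- t(apply(cbind(as.character(s$node_a), as.character(s$node_b)), 1, sort))
  s <- s[order(ends[, 1], ends[, 2], s$segment_id), ]
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  txt <- paste(
    paste(n$node_id, round(n$x_um, 6), round(n$y_um, 6), round(n$z_um, 6),
          n$is_boundary, collapse = ";"),
    paste(ends[, 1], ends[, 2], round(s$diameter_um, 6), round(s$length_um, 6),
          s$sma, collapse = ";"),
    sep = "|"
  )
  # small rolling hash; no external digest dependency
  bytes <- utf8ToInt(txt)
  h <- c(5381, 52711)
  for (b in bytes) {
    h[1] <- (h[1] * 33 + b) %% 4294967291
    h[2] <- (h[2] * 31 + b) %% 4294967279
  }
  paste0(format(h[1], scientific = FALSE), "-",
         format(h[2], scientific = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
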