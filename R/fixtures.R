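#' Canonical test fixtures
#'
#' Small networks with closed-form or hand-traceable expectations, used
#' throughout the test-suite and as worked examples:
#' \describe{
#'   \item{`single_vessel`}{one 10 um x 100 um segment between two boundary
#'     nodes (Poiseuille closed form).}
#'   \item{`series_chain`}{three unequal segments in series (resistor
#'     algebra).}
#'   \item{`y_symmetric`, `y_asymmetric`}{one parent feeding two daughters
#'     (symmetry / phase-separation checks).}
#'   \item{`cascade_toy`}{a 12-segment pial-arteriole, penetrating-arteriole,
#'     precapillary, capillary, venule chain with known classes, for
#'     hand-traced cascade tests.}
#'   \item{`binary_tree`}{a seeded bifurcating tree with a single inflow
#'     root (red-cell conservation checks).}
#'   \item{`krogh`}{a single axial vessel spanning a tissue block, for
#'     comparison against the Krogh cylinder solution.}
#' }
#'
#' @param tree_depth Depth of the binary tree fixture (default 5).
#' @param seed Seed for the tree's diameter jitter (default 1).
#' @return Named list of `vasc_network` objects.
#' @export
generate_fixtures <- function(tree_depth = 5L, seed = 1L) {
  list(
    single_vessel = fixture_single_vessel(),
    series_chain = fixture_series_chain(),
    y_symmetric = fixture_y(7, 7),
    y_asymmetric = fixture_y(8, 5),
    cascade_toy = fixture_cascade_toy(),
    binary_tree = fixture_binary_tree(depth = tree_depth, seed = seed),
    krogh = fixture_krogh()
  )
}

fixture_single_vessel <- function(diameter_um = 10, length_um = 100) {
  vascular_network(
    tibble::tibble(node_id = 1:2, x_um = c(0, length_um), y_um = 0, z_um = 0,
                   is_boundary = TRUE),
    tibble::tibble(segment_id = 1L, node_a = 1L, node_b = 2L,
                   diameter_um = diameter_um, length_um = length_um,
                   sma = FALSE)
  )
}

fixture_series_chain <- function(diameters = c(10, 8, 6),
                                 lengths = c(100, 80, 120)) {
  x <- c(0, cumsum(lengths))
  vascular_network(
    tibble::tibble(node_id = seq_along(x), x_um = x, y_um = 0, z_um = 0,
                   is_boundary = c(TRUE, FALSE, FALSE, TRUE)),
    tibble::tibble(segment_id = 1:3, node_a = 1:3, node_b = 2:4,
                   diameter_um = diameters, length_um = lengths, sma = FALSE)
  )
}

fixture_y <- function(d1, d2, d_parent = 10) {
  vascular_network(
    tibble::tibble(node_id = 1:4,
                   x_um = c(0, 100, 200, 200),
                   y_um = c(0, 0, 60, -60), z_um = 0,
                   is_boundary = c(TRUE, FALSE, TRUE, TRUE)),
    tibble::tibble(segment_id = 1:3, node_a = c(1, 2, 2), node_b = c(2, 3, 4),
                   diameter_um = c(d_parent, d1, d2),
                   length_um = c(100, sqrt(100^2 + 60^2), sqrt(100^2 + 60^2)),
                   sma = FALSE)
  )
}

# 12 segments: boundary -> pial arteriole -> descending penetrating arteriole
# (3 sections, one continuing deeper) -> precapillary side branch (2) ->
# capillary chain (3) -> ascending venule (2) -> pial venule -> boundary
fixture_cascade_toy <- function() {
  nodes <- tibble::tibble(
    node_id = 1:13,
    x_um = c(0,  60, 100, 100, 100, 100, 150, 200, 260, 320, 320, 320, 380),
    y_um = c(0,   0,   0,   0,   0,   0,  40,  60,  60,  60,  60,  60,  60),
    z_um = c(0,   0,   0,  60, 120, 180,  90,  70,  70,  70,  35,   0,   0),
    is_boundary = c(TRUE, rep(FALSE, 11), TRUE)
  )
  segs <- tibble::tibble(
    segment_id = 1:12,
    node_a = c(1, 2, 3, 4, 5, 4, 7, 8, 9, 10, 11, 12),
    node_b = c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13),
    diameter_um = c(22, 20, 15, 13, 12, 7, 6, 5, 5, 6, 9.5, 12),
    sma = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
            FALSE, FALSE, FALSE, FALSE, FALSE)
  )
  net <- vascular_network(nodes, segs)
  net <- classify_vessels(net)
  net <- classify_arteriole_subtype(net)
  capillary_branching_order(net)
}

fixture_binary_tree <- function(depth = 5L, seed = 1L) {
  rng <- local_rng(seed)
  with_rng(rng, {
    # single-inflow stem from the boundary root, then a bifurcating tree
    nodes <- tibble::tibble(node_id = 1:2, x_um = c(0, 120), y_um = 0,
                            z_um = 0, is_boundary = c(TRUE, FALSE))
    segs <- tibble::tibble(segment_id = 1L, node_a = 1L, node_b = 2L,
                           diameter_um = 12, sma = FALSE)
    frontier <- tibble::tibble(node = 2L, d = 12, y = 0)
    nid <- 2L; sid <- 1L
    for (lev in seq_len(depth)) {
      nxt <- list()
      spread <- 400 / 2^lev
      for (r in seq_len(nrow(frontier))) {
        for (s in c(-1, 1)) {
          nid <- nid + 1L; sid <- sid + 1L
          d <- max(4, frontier$d[r] * stats::runif(1, 0.72, 0.86))
          y <- frontier$y[r] + s * spread
          nodes <- dplyr::bind_rows(nodes, tibble::tibble(
            node_id = nid, x_um = (lev + 1) * 120, y_um = y, z_um = 0,
            is_boundary = lev == depth))
          segs <- dplyr::bind_rows(segs, tibble::tibble(
            segment_id = sid, node_a = frontier$node[r], node_b = nid,
            diameter_um = d, sma = FALSE))
          nxt[[length(nxt) + 1L]] <- tibble::tibble(node = nid, d = d, y = y)
        }
      }
      frontier <- dplyr::bind_rows(nxt)
    }
    vascular_network(nodes, segs)
  })
}

# one axial vessel through the centre of a block; tissue cylinder for the
# analytic comparison is carved out with a tissue_grid() mask in the tests
fixture_krogh <- function(diameter_um = 6, length_um = 400, radius_box = 50) {
  vascular_network(
    tibble::tibble(node_id = 1:2,
                   x_um = radius_box, y_um = radius_box,
                   z_um = c(0, length_um), is_boundary = TRUE),
    tibble::tibble(segment_id = 1L, node_a = 1L, node_b = 2L,
                   diameter_um = diameter_um, length_um = length_um,
                   sma = FALSE)
  )
}
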