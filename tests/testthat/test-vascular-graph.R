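test_that("a minimal two-node network constructs and validates", {
  net <- two_node_net(d = 10, l = 100)
  expect_s3_class(net, "vasc_network")
  expect_equal(nrow(net$segments), 1L)
  expect_equal(sum(net$nodes$is_boundary), 2L)
  s <- summary(net)
  expect_equal(s$counts$n_segments, 1L)
  expect_equal(s$counts$n_boundary, 2L)
})

test_that("validation errors name the offending record", {
  nodes <- data.frame(node_id = 1:2, x_um = c(0, 100), y_um = 0, z_um = 0,
                      is_boundary = TRUE)
  segs <- data.frame(segment_id = 1, node_a = 1, node_b = 99,
                     diameter_um = 10, length_um = 100, sma = FALSE)
  expect_error(vascular_network(nodes, segs), "unknown node id")
  segs$node_b <- 2
  segs$diameter_um <- -1
  expect_error(vascular_network(nodes, segs), "non-positive diameter")
  segs$diameter_um <- 10
  segs2 <- rbind(segs, transform(segs, segment_id = 1))
  expect_error(vascular_network(nodes, segs2), "duplicate segment id")
  # boundary node of degree 2
  nodes3 <- rbind(nodes, data.frame(node_id = 3, x_um = 200, y_um = 0,
                                    z_um = 0, is_boundary = TRUE))
  segs3 <- rbind(segs, data.frame(segment_id = 2, node_a = 2, node_b = 3,
                                  diameter_um = 8, length_um = 100, sma = FALSE))
  nodes3$is_boundary[2] <- TRUE
  expect_error(vascular_network(nodes3, segs3), "degree != 1")
})

test_that("round-trips through csv, json and amira preserve the network", {
  net <- fx$cascade_toy
  for (fmt in c("csv", "json", "amira")) {
    path <- if (fmt == "csv") withr::local_tempdir() else
      withr::local_tempfile(fileext = paste0(".", fmt))
    write_network(net, path, format = fmt)
    back <- read_network(path, format = fmt)
    expect_equal(network_hash(back), network_hash(net), label = fmt)
    expect_equal(sort(back$segments$diameter_um), sort(net$segments$diameter_um),
                 tolerance = 1e-9)
    expect_equal(back$segments$sma[order(back$segments$segment_id)],
                 net$segments$sma[order(net$segments$segment_id)])
  }
})

test_that("json round-trip reparses with an identical topology hash", {
  net <- cached_network(1)
  f <- withr::local_tempfile(fileext = ".json")
  write_network(net, f, format = "json")
  expect_identical(network_hash(read_network(f)), network_hash(net))
})

test_that("format is guessed from the path and empty networks are refused", {
  net <- two_node_net()
  d <- withr::local_tempdir()
  write_network(net, d, format = "csv")
  expect_s3_class(read_network(d), "vasc_network")
  expect_error(read_network(file.path(d, "nope.json")), "no such file")
  empty <- net
  empty$segments <- empty$segments[0, ]
  expect_error(write_network(empty, tempfile()), "empty")
})

test_that("classification follows the SMA / diameter / boundary-tree rules", {
  toy <- fx$cascade_toy
  cls <- toy$segments$class
  expect_true(all(cls[toy$segments$sma] == "arteriole"))
  # non-SMA > 8 um tree touching a boundary -> venule
  expect_equal(cls[toy$segments$segment_id %in% c(11, 12)],
               c("venule", "venule"))
  # non-SMA 5-6 um -> capillary
  expect_equal(cls[toy$segments$segment_id %in% c(8, 9, 10)],
               rep("capillary", 3))
  # exactly at the 8 um threshold: strict ">" means capillary
  net <- two_node_net(d = 8, l = 100)
  net <- classify_vessels(net)
  expect_equal(net$segments$class, "capillary")
  # every segment gets exactly one class
  net1 <- cached_network(1)
  expect_true(all(net1$segments$class %in% c("arteriole", "capillary", "venule")))
  expect_false(anyNA(net1$segments$class))
})

test_that("a non-SMA wide tree not touching any boundary stays capillary", {
  # 3-segment wide non-SMA chain buried between two SMA feeders
  nodes <- data.frame(node_id = 1:6,
                      x_um = c(0, 100, 200, 300, 400, 500), y_um = 0, z_um = 0,
                      is_boundary = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))
  segs <- data.frame(segment_id = 1:5, node_a = 1:5, node_b = 2:6,
                     diameter_um = c(12, 10, 10, 10, 12),
                     length_um = 100,
                     sma = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  net <- classify_vessels(vascular_network(nodes, segs))
  expect_equal(net$segments$class, c("arteriole", "capillary", "capillary",
                                     "capillary", "arteriole"))
})

test_that("classification is idempotent and order-independent", {
  net <- cached_network(1)
  again <- classify_vessels(classify_vessels(net))
  expect_identical(again$segments$class, net$segments$class)
  perm <- sample.int(nrow(net$segments))
  shuffled <- net
  shuffled$segments <- net$segments[perm, ]
  shuffled <- classify_vessels(shuffled)
  expect_identical(shuffled$segments$class, net$segments$class[perm])
})

test_that("arteriole subtypes split at 10 um with >= tie-break and pial rule", {
  toy <- fx$cascade_toy
  sub <- toy$segments$subtype
  expect_equal(sub[3:5], rep("penetrating", 3))
  expect_equal(sub[6:7], rep("precapillary", 2))
  expect_equal(sub[1:2], rep("pial", 2))
  expect_true(all(is.na(sub[8:12])))
  # tie at exactly 10 um -> penetrating (on a segment deep enough that the
  # pial rule cannot fire: both its endpoints lie beyond one mean length)
  nodes <- data.frame(node_id = 1:3, x_um = 0, y_um = 0,
                      z_um = c(0, 100, 200),
                      is_boundary = c(TRUE, FALSE, TRUE))
  segs <- data.frame(segment_id = 1:2, node_a = 1:2, node_b = 2:3,
                     diameter_um = 10, length_um = 100, sma = TRUE)
  net <- classify_arteriole_subtype(classify_vessels(vascular_network(nodes, segs)))
  expect_equal(net$segments$subtype[2], "penetrating")
})

test_that("capillary branching order is a BFS from the precapillary interface", {
  toy <- fx$cascade_toy
  ord <- toy$segments$cap_order
  expect_equal(ord[8:10], 1:3)
  expect_true(all(is.na(ord[toy$segments$class != "capillary"])))
  # neighbouring capillaries differ by at most one order
  net <- cached_network(1)
  segs <- net$segments
  cap <- segs[segs$class == "capillary" & !is.na(segs$cap_order), ]
  # each capillary against capillaries sharing one of its nodes
  for (i in seq_len(min(nrow(cap), 200))) {
    touch <- cap$cap_order[cap$node_a %in% c(cap$node_a[i], cap$node_b[i]) |
                             cap$node_b %in% c(cap$node_a[i], cap$node_b[i])]
    expect_true(all(abs(touch - cap$cap_order[i]) <= 1))
  }
})

test_that("segment field export writes csv and vtk", {
  net <- fx$cascade_toy
  vals <- data.frame(segment_id = net$segments$segment_id,
                     flow = rnorm(nrow(net$segments)))
  f1 <- withr::local_tempfile(fileext = ".csv")
  export_segment_fields(net, vals, f1, format = "csv")
  expect_equal(nrow(utils::read.csv(f1)), nrow(net$segments))
  f2 <- withr::local_tempfile(fileext = ".vtk")
  export_segment_fields(net, vals, f2, format = "vtk")
  lines <- readLines(f2)
  expect_true(any(grepl("^DATASET POLYDATA", lines)))
  expect_true(any(grepl("^SCALARS flow", lines)))
})
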