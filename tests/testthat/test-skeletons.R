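test_that("read_swc parses a minimal chain and enforces structure", {
  f <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 0 0 0 0 1 -1",
               "2 0 1 0 0 1 1",
               "3 0 2 0 0 1 2"), f)
  sk <- read_swc(f)
  expect_s3_class(sk, "neuron_skeleton")
  expect_equal(nrow(sk$nodes), 3L)
  expect_equal(sum(is.na(sk$nodes$parent_id)), 1L)
  expect_equal(sk$nodes$x, c(0, 1, 2))

  writeLines(c("1 0 0 0 0 1 -1", "5 0 1 0 0 1 99"), f)
  expect_error(read_swc(f), "dangling")

  writeLines(c("1 0 0 0 0 1 -1", "2 0 1 0 0 1"), f)
  expect_error(read_swc(f), "line 2")
})

test_that("write_swc/read_swc round-trips node tables exactly", {
  f <- withr::local_tempfile(fileext = ".swc")
  one <- neuron_skeleton(data.frame(node_id = 1L, parent_id = NA,
                                    x = 1.5, y = -2, z = 0, radius = 1))
  write_swc(one, f)
  rows <- grep("^[^#]", readLines(f), value = TRUE)
  expect_length(rows, 1L)
  expect_match(rows, "-1$")

  for (seed in c(7L, 8L)) {
    sk <- random_tree_skeleton(200L, seed)
    write_swc(sk, f)
    back <- read_swc(f)
    expect_equal(back$nodes, sk$nodes, tolerance = 0)
  }

  bad <- one
  bad$nodes$x <- NaN
  expect_error(write_swc(bad, f), "finite")
})

test_that("skeleton validation rejects duplicates and cycles", {
  expect_error(neuron_skeleton(data.frame(
    node_id = c(1, 1), parent_id = c(NA, 1), x = 0:1, y = 0, z = 0)),
    "unique")
  expect_error(neuron_skeleton(data.frame(
    node_id = 1:2, parent_id = c(2, 1), x = 0:1, y = 0, z = 0)),
    "cycle")
})

test_that("resample_skeleton subdivides edges and conserves cable length", {
  seg <- neuron_skeleton(data.frame(node_id = 1:2, parent_id = c(NA, 1),
                                    x = c(0, 10), y = 0, z = 0))
  rs <- resample_skeleton(seg, 1)
  expect_equal(nrow(rs$nodes), 11L)
  expect_equal(sort(rs$nodes$x), 0:10)
  expect_true(all(rs$nodes$y == 0) && all(rs$nodes$z == 0))

  rs_big <- resample_skeleton(seg, 100)
  expect_equal(nrow(rs_big$nodes), 2L)

  for (seed in c(11L, 12L)) {
    sk <- random_tree_skeleton(60L, seed)
    rs <- resample_skeleton(sk, 1.5)
    expect_lt(abs(total_cable_length(rs) - total_cable_length(sk)), 1e-6)
    # every original node position survives (so branch/end points do)
    orig <- as.matrix(sk$nodes[, c("x", "y", "z")])
    new <- as.matrix(rs$nodes[, c("x", "y", "z")])
    for (i in seq_len(nrow(orig))) {
      expect_lt(min(colSums((t(new) - orig[i, ])^2)), 1e-18)
    }
    # all edges now <= step
    ed_child <- which(!is.na(rs$nodes$parent_id))
    ed_par <- match(rs$nodes$parent_id[ed_child], rs$nodes$node_id)
    lens <- sqrt(rowSums((new[ed_child, ] - new[ed_par, ])^2))
    expect_true(all(lens <= 1.5 + 1e-9))
  }
  expect_error(resample_skeleton(seg, 0), "positive")
})

test_that("to_dotprops recovers line directions with the sign convention", {
  line <- neuron_skeleton(data.frame(node_id = 1:20,
                                     parent_id = c(NA, 1:19),
                                     x = seq(0, 19), y = 0, z = 0))
  dp <- to_dotprops(line, 5)
  expect_equal(dp$tangents, matrix(rep(c(1, 0, 0), each = 20), ncol = 3,
                                   dimnames = list(NULL, c("tx", "ty",
                                                           "tz"))))
  neg <- neuron_skeleton(data.frame(node_id = 1:20,
                                    parent_id = c(NA, 1:19),
                                    x = seq(0, -19), y = 0, z = 0))
  expect_equal(to_dotprops(neg, 5)$tangents[, 1], rep(1, 20))

  # L-shape: tangents match a local-PCA oracle on each neighbourhood
  lshape <- neuron_skeleton(data.frame(
    node_id = 1:20, parent_id = c(NA, 1:19),
    x = c(seq(0, 9), rep(9, 10)), y = c(rep(0, 10), seq(1, 10)), z = 0))
  dp <- to_dotprops(lshape, 5)
  pts <- as.matrix(lshape$nodes[, c("x", "y", "z")])
  for (i in seq_len(20)) {
    d2 <- colSums((t(pts) - pts[i, ])^2)
    nb <- pts[order(d2)[1:5], ]
    ev <- eigen(cov(nb), symmetric = TRUE)$vectors[, 1]
    if (ev[1] < -1e-12 || (abs(ev[1]) < 1e-12 && ev[2] < 0)) ev <- -ev
    expect_lt(max(abs(dp$tangents[i, ] - ev)), 1e-6)
  }
  expect_error(to_dotprops(line, 25), "k_neighbors")
})

test_that("tangent estimation is rotation-equivariant up to sign", {
  sk <- random_tree_skeleton(80L, 21L)
  rot <- random_rotation(22L)
  pts <- as.matrix(sk$nodes[, c("x", "y", "z")]) %*% t(rot)
  sk_rot <- neuron_skeleton(data.frame(node_id = sk$nodes$node_id,
                                       parent_id = sk$nodes$parent_id,
                                       x = pts[, 1], y = pts[, 2],
                                       z = pts[, 3]))
  t1 <- to_dotprops(sk, 5)$tangents %*% t(rot)
  t2 <- to_dotprops(sk_rot, 5)$tangents
  mismatch <- pmin(rowSums((t1 - t2)^2), rowSums((t1 + t2)^2))
  expect_lt(max(mismatch), 1e-12)
})

test_that("dotprops CSV round-trips and validates", {
  dp <- random_dotprops(40L, 31L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_dotprops(dp, f)
  back <- read_dotprops(f)
  expect_equal(back$points, dp$points)
  expect_equal(back$tangents, dp$tangents)
  expect_error(dotprops(dp$points, dp$tangents * 2), "unit")
  expect_error(dotprops(dp$points[0, ], dp$tangents[0, ]), "at least one")
})
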