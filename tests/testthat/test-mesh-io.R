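test_that("tsi read/write round-trips a tetrahedron with marks", {
  mesh <- tetra_mesh()
  mesh$inclusions <- data.frame(type_id = 1L, vertex = 3L, dx = 1, dy = 0)
  mesh$exclusions <- data.frame(vertex = 2L, radius = 1.5)
  path <- withr::local_tempfile(fileext = ".tsi")
  write_tsi(mesh, path)
  back <- read_tsi(path)
  expect_equal(nrow(back$vertices), 4L)
  expect_equal(nrow(back$triangles), 4L)
  expect_lt(max(abs(back$vertices - mesh$vertices)), 1e-6)
  expect_identical(back$triangles, mesh$triangles)
  expect_equal(back$inclusions$vertex, 3L)
  expect_equal(back$inclusions$type_id, 1L)
  expect_equal(back$exclusions$radius, 1.5)
  # second round trip is a fixed point
  path2 <- withr::local_tempfile(fileext = ".tsi")
  write_tsi(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("tsi parser validates structure and indices", {
  path <- withr::local_tempfile(fileext = ".tsi")
  writeLines(c("version 1.1", "box 4 4 -1", "vertex 0", "triangle 0"), path)
  expect_error(read_tsi(path), "box")
  writeLines(c("version 1.1", "box 4 4 4", "vertex 1", "0 1 1 1",
               "triangle 1", "0 0 1 2"), path)
  expect_error(read_tsi(path), "index")
  writeLines(c("version 2.0", "box 4 4 4", "vertex 1", "0 1 1 1",
               "triangle 0"), path)
  expect_warning(read_tsi(path), "version")
})

test_that("obj reader handles triangulated meshes and rejects quads", {
  path <- withr::local_tempfile(fileext = ".obj")
  # cube, pre-triangulated: 8 vertices, 12 faces
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  quads <- rbind(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                 c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  tris <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i)
    rbind(quads[i, c(1, 2, 3)], quads[i, c(1, 3, 4)])))
  writeLines(c(sprintf("v %f %f %f", v[, 1], v[, 2], v[, 3]),
               sprintf("f %d %d %d", tris[, 1], tris[, 2], tris[, 3])), path)
  mesh <- read_obj(path)
  expect_equal(nrow(mesh$vertices), 8L)
  expect_equal(nrow(mesh$triangles), 12L)
  # obj -> tsi -> obj-vertices round trip
  tsi <- withr::local_tempfile(fileext = ".tsi")
  write_tsi(mesh, tsi)
  expect_lt(max(abs(read_tsi(tsi)$vertices - mesh$vertices)), 1e-6)
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0", "f 1 2 3 4"), path)
  expect_error(read_obj(path), "triangulate")
})

test_that("open-edge detection: closed, single triangle, grid perimeter", {
  expect_length(detect_open_edges(make_mesh("icosphere", subdiv = 1)), 0L)
  one <- tri_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                  rbind(c(1, 2, 3)), c(2, 2, 2))
  expect_equal(detect_open_edges(one), 1:3)
  for (n in c(5L, 9L)) {
    grid <- make_mesh("flat_grid", nx = n, ny = n)
    expect_length(detect_open_edges(grid), 4L * n - 4L)
  }
})

test_that("non-manifold edges are refused", {
  # three triangles sharing one edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  mesh <- tri_mesh(v, f, c(2, 2, 2))
  expect_error(detect_open_edges(mesh), "non-manifold")
  expect_error(orient_mesh(mesh), "non-manifold")
})

test_that("orientation: consistent meshes untouched, flips counted, volume positive", {
  om <- orient_mesh(make_mesh("icosphere", r = 10, subdiv = 1))
  expect_true(om$report$orientable)
  expect_equal(om$report$flipped, 0L)
  expect_equal(om$report$cut_vertices, 0L)
  expect_gt(signed_volume(om$mesh), 0)
  # two adjacent triangles, one reversed -> 1 flip
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 4, 3))  # second has same traversal of edge 1-3
  om2 <- orient_mesh(tri_mesh(v, f, c(2, 2, 2)))
  expect_equal(om2$report$flipped, 1L)
  expect_true(is_consistently_oriented(om2$mesh))
  # a fully inverted icosphere gets re-flipped outward (positive volume)
  ico <- make_mesh("icosphere", r = 5, subdiv = 1)
  ico$triangles <- ico$triangles[, c(1, 3, 2)]
  om3 <- orient_mesh(ico)
  expect_gt(signed_volume(om3$mesh), 0)
})

test_that("nonorientable Moebius mesh is cut into an orientable open surface", {
  mesh <- make_mesh("moebius", r = 10, nu = 40, nv = 5)
  om <- orient_mesh(mesh)
  expect_false(om$report$orientable)
  expect_gt(om$report$cut_vertices, 0L)
  expect_true(is_consistently_oriented(om$mesh))
  open <- detect_open_edges(om$mesh)
  expect_gt(length(open), 0L)
  # rerunning on the cut result is stable and reports orientable
  om2 <- orient_mesh(om$mesh)
  expect_true(om2$report$orientable)
  expect_equal(om2$report$cut_vertices, 0L)
  # deterministic cut
  om3 <- orient_mesh(mesh)
  expect_identical(om$mesh$triangles, om3$mesh$triangles)
})
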