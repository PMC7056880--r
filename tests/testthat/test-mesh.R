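# mesh generation: tessellation conservation, determinism, wall refinement

test_that("unit square mesh conserves area exactly", {
  sq <- NULL
  for (i in 0:9) sq <- rbind(sq, c(i / 10, 0))
  for (i in 0:9) sq <- rbind(sq, c(1, i / 10))
  for (i in 0:9) sq <- rbind(sq, c(1 - i / 10, 1))
  for (i in 0:9) sq <- rbind(sq, c(0, 1 - i / 10))
  m <- mesh_polygon(sq, rep("wall", 40), cell_size = 0.1)
  # areas in m^2; polygon is 1 mm^2 = 1e-6 m^2
  expect_equal(sum(m$cell_area), 1e-6, tolerance = 1e-6)
  expect_true(all(m$cell_area > 0))
})

test_that("meshing is deterministic", {
  g <- build_geometry("N-LV")
  cs <- generate_contours(g)
  m1 <- generate_mesh(g, cell_size = 1.5e-3, contour = cs)
  m2 <- generate_mesh(g, cell_size = 1.5e-3, contour = cs)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$tris, m2$tris)
})

test_that("first wall-layer height matches the configured value", {
  g <- build_geometry("DSS-LV")
  cs <- generate_contours(g)
  fl <- 4e-4
  m <- generate_mesh(g, cell_size = 1.2e-3, first_layer = fl, contour = cs)
  expect_gt(m$n_offset, 50)
  # offset nodes sit right after the boundary nodes; their wall distance
  # equals the configured first layer within 10%
  off_idx <- m$n_boundary + seq_len(m$n_offset)
  bnd <- m$nodes[seq_len(m$n_boundary), ] * 1000
  d <- lvotflow:::dist_to_polyline_cpp(m$nodes[off_idx, , drop = FALSE] * 1000, bnd)
  expect_lt(median(abs(d / 1000 - fl)) / fl, 0.1)
})

test_that("LV meshes carry tags, motion bindings and site coordinates", {
  g <- build_geometry("S-LV")
  cs <- generate_contours(g)
  m <- generate_mesh(g, cell_size = 1.4e-3, contour = cs)
  expect_true(all(c("septal_wall", "lv_wall", "inlet", "outlet") %in%
                  unique(m$face_tag)))
  expect_gt(sum(m$btype == 2L), 50)             # moving chamber nodes
  expect_true(all(!is.na(m$mov_seg[m$btype == 2L])))
  # septal arc coordinates cover the three site windows
  s <- m$s_face[!is.na(m$s_face)]
  cr <- locate_septal_crest(g)
  expect_lt(min(s), cr - 3)
  expect_gt(max(s), cr + 3)
  # DSS mesh has lesion-bound nodes
  gd <- build_geometry("DSS-LV")
  md <- generate_mesh(gd, cell_size = 1.4e-3, contour = generate_contours(gd))
  expect_gt(sum(md$btype == 3L), 10)
  expect_true("lesion" %in% md$face_tag)
})

test_that("degenerate polygons raise meshing errors", {
  # polygon too small for the cell size keeps no interior triangles
  tiny <- rbind(c(0, 0), c(0.05, 0), c(0.05, 0.05), c(0, 0.05))
  expect_error(mesh_polygon(tiny, rep("wall", 4), cell_size = 10),
               "meshing failure")
})
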