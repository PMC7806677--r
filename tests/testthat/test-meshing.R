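test_that("a unit square at target 2 triangulates into exactly 2 triangles", {
  o <- rect_outline(1, 1)
  m <- triangulate(o, 2)
  expect_equal(nrow(m$elements), 2L)
  expect_equal(sum(m$element_areas), 1.0, tolerance = 1e-12)
  expect_true(all(m$element_areas > 0))
})

test_that("tooth meshes hit the target count and conserve area exactly", {
  p <- otodontid_tooth_presets()
  o <- generate_outline(spec_from_row(p[p$label == "O. megalodon|anterior", ]))
  A <- polygon_area(o)
  for (target in c(1500, 35000)) {
    m <- triangulate(o, target)
    expect_lt(abs(nrow(m$elements) - target) / target, 0.15)
    expect_lt(abs(sum(m$element_areas) - A) / A, 1e-6)
    expect_true(all(m$element_areas > 0))
    # outline vertices are preserved on the mesh boundary
    d <- .mapply(function(x, y) min((m$coords[, 1] - x)^2 + (m$coords[, 2] - y)^2),
                 list(o$vertices[, 1], o$vertices[, 2]), NULL)
    expect_lt(max(unlist(d)), 1e-18)
  }
})

test_that("meshing is deterministic for identical inputs", {
  o <- generate_outline(tooth_spec(50, 30, cusplet_height_frac = 0.15,
                                   cusplet_width_frac = 0.15, root_width = 55))
  m1 <- triangulate(o, 3000)
  m2 <- triangulate(o, 3000)
  expect_identical(m1$coords, m2$coords)
  expect_identical(m1$elements, m2$elements)
})

test_that("root node set follows the y-threshold predicate, crown/root partition", {
  o <- rect_outline(2, 1, crown_root_y = 0.5)
  m <- identify_sets(triangulate(o, 200), o)
  expect_setequal(m$node_sets$root, which(m$coords[, 2] <= 0.5 + 1e-9))
  expect_gt(length(m$node_sets$root), 0)
  part <- sort(c(m$element_sets$crown, m$element_sets$root))
  expect_identical(part, seq_len(nrow(m$elements)))
  cy <- (m$coords[m$elements[, 1], 2] + m$coords[m$elements[, 2], 2] +
         m$coords[m$elements[, 3], 2]) / 3
  expect_true(all(cy[m$element_sets$crown] > 0.5))
  expect_true(all(cy[m$element_sets$root] <= 0.5))
})

test_that("apex ties on a flat-topped outline break deterministically to larger x", {
  o <- rect_outline(2, 1, crown_root_y = 0.4)  # two boundary nodes at max y
  m <- identify_sets(triangulate(o, 64), o)
  expect_length(m$node_sets$apex, 1L)
  top <- which(abs(m$coords[, 2] - 1) < 1e-9)
  expect_equal(m$coords[m$node_sets$apex, 1], max(m$coords[top, 1]))
})

test_that("distal edge nodes lie on the distal boundary chain above the crown base", {
  sc <- solved_tooth()
  m <- sc$mesh; o <- sc$outline
  chain <- o$vertices[o$spans$distal, , drop = FALSE]
  for (nd in m$node_sets$distal_edge) {
    expect_lt(oracle_dist_to_chain(m$coords[nd, ], chain), 1e-6)
    expect_gt(m$coords[nd, 2], o$crown_root_y)
  }
})

test_that("convergence study returns one deterministic row per target count", {
  o <- generate_outline(tooth_spec(40, 28, apex_offset_frac = 0.3,
                                   edge_curvature = 0.05))
  mat <- material()
  builder <- function(m) build_load_case("draw", m, 100)
  tb <- convergence_study(o, mat, builder, c(500, 500, 2000))
  expect_equal(nrow(tb), 3L)
  expect_identical(tb[1, ], tb[2, ], ignore_attr = TRUE)
  expect_equal(tb$mwam[3], tb$mwam[1], tolerance = 0.15)
  # geometry is mesh independent: summed areas agree across resolutions
  A <- polygon_area(o)
  m1 <- triangulate(o, 100)
  m2 <- triangulate(o, 20000)
  expect_equal(sum(m1$element_areas), sum(m2$element_areas), tolerance = 1e-9)
  expect_equal(sum(m1$element_areas), A, tolerance = 1e-9)
})

test_that("mesh CSV and VTK exports are written and readable", {
  sc <- solved_tooth()
  pref <- file.path(withr::local_tempdir(), "mesh")
  files <- write_mesh_csv(sc$mesh, pref)
  nodes <- read.csv(paste0(pref, "_nodes.csv"))
  expect_equal(nrow(nodes), nrow(sc$mesh$coords))
  vtk <- file.path(dirname(pref), "m.vtk")
  write_vtk(sc$mesh, vtk, cell_data = list(von_mises = sc$solution$element_vm))
  lines <- readLines(vtk)
  expect_true(any(grepl("^CELLS", lines)))
  expect_true(any(grepl("SCALARS von_mises", lines)))
})
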