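test_that("centred isosceles crowns are mirror-symmetric about the apex axis", {
  spec <- tooth_spec(crown_height = 100, crown_basal_width = 60,
                     apex_offset_frac = 0.5, edge_curvature = 0.06,
                     root_depth = 20, root_width = 80)
  o <- generate_outline(spec)
  v <- o$vertices
  xm <- spec$crown_basal_width / 2
  # every vertex must have a mirror partner across x = W/2
  mirrored <- cbind(2 * xm - v[, 1], v[, 2])
  for (i in seq_len(nrow(v))) {
    d <- sqrt((v[, 1] - mirrored[i, 1])^2 + (v[, 2] - mirrored[i, 2])^2)
    expect_lt(min(d), 1e-9)
  }
  expect_equal(unname(v[o$apex_index, ]), c(xm, 100))
})

test_that("cusplet spans exist exactly when cusplet fractions are positive", {
  o0 <- generate_outline(tooth_spec(50, 30, cusplet_height_frac = 0,
                                    cusplet_width_frac = 0))
  expect_length(o0$spans$cusplets, 0)
  o1 <- generate_outline(tooth_spec(50, 30, cusplet_height_frac = 0.2,
                                    cusplet_width_frac = 0.2, root_width = 60))
  expect_named(o1$spans$cusplets, c("distal", "mesial"))
  expect_true(all(lengths(o1$spans$cusplets) > 0))
})

test_that("invalid specs are rejected with the violated bound named", {
  expect_error(tooth_spec(-1, 30), "crown_height")
  expect_error(tooth_spec(50, 30, apex_offset_frac = 1.2), "apex_offset_frac")
  expect_error(tooth_spec(50, 30, cusplet_height_frac = 0.6,
                          cusplet_width_frac = 0.2), "cusplet_height_frac")
  expect_error(tooth_spec(50, 30, root_width = 10), "root_width")
  expect_error(generate_outline(tooth_spec(50, 30, cusplet_height_frac = 0.2,
                                           cusplet_width_frac = 0.45,
                                           root_width = 30.1)), "root_width")
})

test_that("all shipped preset outlines are simple polygons with positive area", {
  p <- otodontid_tooth_presets()
  expect_equal(nrow(p), 15L)
  for (i in seq_len(nrow(p))) {
    o <- generate_outline(spec_from_row(p[i, ]))
    expect_true(oracle_is_simple(o$vertices), label = p$label[i])
    expect_gt(polygon_area(o), 0)
    # apex is the global y maximum
    expect_equal(unname(o$vertices[o$apex_index, 2]), max(o$vertices[, 2]))
  }
})

test_that("polygon_area matches hand values and a decompose-and-sum oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(0, 1))), 0.5)
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1.0)
  # straight-edged isosceles tooth decomposes into crown triangle + root block
  o <- generate_outline(tooth_spec(crown_height = 100, crown_basal_width = 60,
                                   apex_offset_frac = 0.5, edge_curvature = 0,
                                   root_depth = 20, root_width = 70))
  expect_equal(polygon_area(o), 60 * 100 / 2 + 20 * 70, tolerance = 1e-12)
})

test_that("polygon_area is rigid-motion invariant and scales quadratically", {
  o <- generate_outline(tooth_spec(50, 30, apex_offset_frac = 0.3,
                                   edge_curvature = 0.05))
  v <- o$vertices
  a0 <- polygon_area(v)
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(polygon_area(sweep(v, 2, c(11.5, -3.2), "+")), a0,
               tolerance = 1e-9)
  expect_equal(polygon_area(v %*% R), a0, tolerance = 1e-9)
  expect_equal(polygon_area(2.5 * v), 2.5^2 * a0, tolerance = 1e-9)
})

test_that("read_outline_xy normalizes orientation and duplicates", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  o <- read_outline_xy(sq, crown_root_y = 0.5)
  expect_equal(polygon_area(o), 1.0)
  expect_equal(nrow(o$vertices), 4L)
  # clockwise input is reversed to counter-clockwise
  o_cw <- read_outline_xy(sq[4:1, ], crown_root_y = 0.5)
  expect_equal(polygon_area(o_cw), 1.0)
  expect_gt(sum(o_cw$vertices[, 1] * o_cw$vertices[c(2:4, 1), 2] -
                o_cw$vertices[c(2:4, 1), 1] * o_cw$vertices[, 2]), 0)
  expect_equal(o_cw$vertices[order(o_cw$vertices[, 1], o_cw$vertices[, 2]), ],
               o$vertices[order(o$vertices[, 1], o$vertices[, 2]), ])
  # explicit closing vertex is dropped
  o_closed <- read_outline_xy(rbind(sq, sq[1, , drop = FALSE]), crown_root_y = 0.5)
  expect_equal(nrow(o_closed$vertices), 4L)
  # degenerate and invalid inputs
  expect_error(read_outline_xy(sq[1:2, ], 0.5), "3")
  expect_error(read_outline_xy(rbind(c(0, 0), c(4, 0), c(4, 3), c(1, -1), c(0, 3)),
                               0.5),
               "self-intersecting")
})

test_that("outline CSV write/read round trip is the identity on vertices", {
  o <- generate_outline(tooth_spec(50, 30, apex_offset_frac = 0.4,
                                   edge_curvature = 0.05,
                                   cusplet_height_frac = 0.15,
                                   cusplet_width_frac = 0.15, root_width = 55))
  f <- withr::local_tempfile(fileext = ".csv")
  write_outline_xy(o, f)
  o2 <- read_outline_xy(f, crown_root_y = o$crown_root_y)
  expect_equal(unname(o2$vertices), unname(o$vertices), tolerance = 1e-12)
})
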