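test_that("cst_stiffness is symmetric, annihilates rigid modes, and scales with E and t", {
  tri <- rbind(c(0, 0), c(2, 0), c(0.4, 1.3))
  mat <- material(youngs_modulus = 2e9, poissons_ratio = 0.25, thickness = 3)
  K <- cst_stiffness(tri, mat)
  expect_equal(K, t(K), tolerance = 1e-12)
  # rigid translations and an infinitesimal rotation produce zero force
  rigid <- cbind(rep(c(1, 0), 3), rep(c(0, 1), 3),
                 as.numeric(t(cbind(-tri[, 2], tri[, 1]))))
  expect_lt(max(abs(K %*% rigid)), 1e-6 * max(abs(K)))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-6 * max(ev)), 3L)   # exactly 3 zero-energy modes
  expect_true(all(ev > -1e-6 * max(ev)))
  expect_equal(cst_stiffness(tri, material(4e9, 0.25, 3)), 2 * K,
               tolerance = 1e-12)
  expect_equal(cst_stiffness(tri, material(2e9, 0.25, 6)), 2 * K,
               tolerance = 1e-12)
  expect_error(cst_stiffness(tri[c(1, 3, 2), ], mat), "clockwise")
})

test_that("uniaxial patch test reproduces a uniform stress field exactly", {
  o <- rect_outline(4, 2, crown_root_y = 1)
  m <- identify_sets(triangulate(o, 400), o)
  left <- nodes_at_x(m, 0)
  right <- nodes_at_x(m, 4)
  corner <- left[which.min(m$coords[left, 2])]
  mat <- material(youngs_modulus = 10e9, poissons_ratio = 0.3, thickness = 2)
  # uniform traction sxx = 10 MPa on the right edge: F = 10 * h * t = 40 N
  lc <- build_load_case("draw", m, 40, nodes = right, direction = c(1, 0),
                        distribution = "consistent")
  sol <- fe_solve(m, mat, lc, constrained = list(ux = left, uy = corner))
  s <- sol$element_stress
  expect_lt(max(abs(s[, "sxx"] - 10)) / 10, 1e-3)
  expect_lt(max(abs(s[, "syy"])) / 10, 1e-3)
  expect_lt(max(abs(s[, "sxy"])) / 10, 1e-3)
  expect_equal(s[, "szz"], 0.3 * (s[, "sxx"] + s[, "syy"]), tolerance = 1e-9)
  # plane-strain axial strain and displacement field
  E <- 10e9 / 1e6; nu <- 0.3
  exx <- 10 * (1 - nu^2) / E
  expect_equal(sol$displacements[right, "ux"], rep(exx * 4, length(right)),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_lt(sol$residual, 1e-10)
})

test_that("tip-loaded cantilever deflection matches Timoshenko beam theory", {
  L <- 20; h <- 2; t <- 1; F <- 50
  o <- rect_outline(L, h, crown_root_y = h / 2)
  m <- identify_sets(triangulate(o, 20000), o)
  root <- nodes_at_x(m, 0)
  tip <- nodes_at_x(m, L)
  mat <- material(youngs_modulus = 1e9, poissons_ratio = 0.3, thickness = t)
  lc <- build_load_case("draw", m, F, nodes = tip, direction = c(0, -1),
                        distribution = "consistent")
  sol <- fe_solve(m, mat, lc, constrained = root)
  measured <- -mean(sol$displacements[tip, "uy"])
  E <- mat$E_mpa; nu <- mat$nu
  Ep <- E / (1 - nu^2)                      # plane-strain effective modulus
  G <- E / (2 * (1 + nu))
  I <- t * h^3 / 12
  kappa <- 10 * (1 + nu) / (12 + 11 * nu)   # Timoshenko shear coefficient
  delta <- F * L^3 / (3 * Ep * I) + F * L / (kappa * G * h * t)
  expect_lt(abs(measured - delta) / delta, 0.05)
})

test_that("reactions balance applied loads and the solution is linear in force", {
  sc <- solved_tooth()
  sol <- sc$solution
  expect_lt(max(abs(sol$reaction_sum + sol$applied_sum)) /
              max(abs(sol$applied_sum)), 1e-6)
  expect_equal(unname(sol$applied_sum), c(-500, 0), tolerance = 1e-9)
  expect_lt(sol$residual, 1e-6)
  # doubling the force exactly doubles displacements and stresses
  lc2 <- build_load_case("draw", sc$mesh, 1000)
  sol2 <- fe_solve(sc$mesh, sc$material, lc2)
  expect_equal(sol2$displacements, 2 * sol$displacements, tolerance = 1e-9)
  expect_equal(sol2$element_stress, 2 * sol$element_stress, tolerance = 1e-9)
  expect_equal(sol2$element_vm, 2 * sol$element_vm, tolerance = 1e-9)
})

test_that("von_mises matches hand-computed states and is invariant properties", {
  expect_equal(von_mises(0, 0, 0, 0), 0)
  expect_equal(von_mises(10, 0, 0, 0), 10)               # uniaxial
  expect_equal(von_mises(0, 0, 0, 5), 5 * sqrt(3))       # pure shear
  expect_equal(von_mises(7, 7, 7, 0), 0)                 # hydrostatic
  expect_equal(von_mises(3, -2, 1, 4),
               sqrt(0.5 * ((3 + 2)^2 + (-2 - 1)^2 + (1 - 3)^2) + 3 * 16))
  expect_error(von_mises(1, NA, 0, 0))
})

test_that("solver rejects unconstrained and fully constrained systems", {
  o <- rect_outline(1, 1)
  m <- identify_sets(triangulate(o, 50), o)
  mat <- material()
  f <- numeric(2 * nrow(m$coords)); f[1] <- 1
  expect_error(fe_solve(m, mat, f, constrained = integer(0)), "empty")
  # loading only fixed DOFs is rejected
  lc <- build_load_case("draw", m, 1, nodes = m$node_sets$root[1],
                        direction = c(1, 0))
  expect_error(fe_solve(m, mat, lc, constrained = m$node_sets$root),
               "constrained")
})

test_that("stress CSV export round-trips the solution fields", {
  sc <- solved_tooth()
  f <- withr::local_tempfile(fileext = ".csv")
  write_stress_csv(sc$solution, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), length(sc$solution$element_vm))
  expect_equal(tab$von_mises, unname(sc$solution$element_vm), tolerance = 1e-9)
  expect_equal(tab$sxx, unname(sc$solution$element_stress[, "sxx"]),
               tolerance = 1e-9)
})
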