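# Plane-strain linear elasticity on three-node (constant-strain) triangles.
# Units: geometry in mm, forces in N, Young's modulus supplied in Pa and held
# internally in MPa (= N/mm^2), so stresses come out in MPa with the section
# thickness in mm.

#' Isotropic linear-elastic material and section properties
#'
#' Defaults are the osteodentine properties used for lamniform shark teeth:
#' Young's modulus 28.44 GPa, Poisson's ratio 0.3, with a unit (1 mm)
#' out-of-plane section thickness.
#'
#' @param youngs_modulus Young's modulus in Pa.
#' @param poissons_ratio Poisson's ratio (0 <= nu < 0.5).
#' @param thickness Out-of-plane section thickness in mm.
#' @return An object of class `fe_material`.
#' @export
material <- function(youngs_modulus = 28.44e9, poissons_ratio = 0.3,
                     thickness = 1) {
  if (!is.numeric(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0", call. = FALSE)
  if (!is.numeric(poissons_ratio) || poissons_ratio < 0 || poissons_ratio >= 0.5)
    stop("poissons_ratio must lie in [0, 0.5)", call. = FALSE)
  if (!is.numeric(thickness) || thickness <= 0)
    stop("thickness must be > 0", call. = FALSE)
  structure(list(E = youngs_modulus, nu = poissons_ratio, thickness = thickness,
                 E_mpa = youngs_modulus / 1e6),
            class = "fe_material")
}

#' @export
print.fe_material <- function(x, ...) {
  cat(sprintf("<fe_material> E = %.4g GPa, nu = %.3g, thickness = %g mm (plane strain)\n",
              x$E / 1e9, x$nu, x$thickness))
  invisible(x)
}

# 3x3 plane-strain constitutive matrix in MPa
d_matrix <- function(material) {
  E <- material$E_mpa; nu <- material$nu
  k <- E / ((1 + nu) * (1 - 2 * nu))
  k * matrix(c(1 - nu, nu, 0,
               nu, 1 - nu, 0,
               0, 0, (1 - 2 * nu) / 2), 3, 3, byrow = TRUE)
}

#' Element stiffness matrix of a plane-strain constant-strain triangle
#'
#' Computes `K = A * t * B' D B` for one three-node triangle with the
#' plane-strain constitutive matrix `D(E, nu)`. Degrees of freedom are
#' ordered (u1, v1, u2, v2, u3, v3).
#'
#' @param triangle_coords 3 x 2 matrix of node coordinates (mm),
#'   counter-clockwise.
#' @param material An [fe_material][material()].
#' @return A symmetric 6 x 6 stiffness matrix (N/mm).
#' @export
cst_stiffness <- function(triangle_coords, material) {
  p <- as.matrix(triangle_coords)
  stopifnot(nrow(p) == 3, ncol(p) == 2)
  x <- p[, 1]; y <- p[, 2]
  A2 <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
  if (A2 <= 0) stop("degenerate or clockwise triangle (area <= 0)", call. = FALSE)
  b <- c(y[2] - y[3], y[3] - y[1], y[1] - y[2])
  cc <- c(x[3] - x[2], x[1] - x[3], x[2] - x[1])
  B <- matrix(0, 3, 6)
  B[1, c(1, 3, 5)] <- b
  B[2, c(2, 4, 6)] <- cc
  B[3, c(1, 3, 5)] <- cc
  B[3, c(2, 4, 6)] <- b
  B <- B / A2
  (A2 / 2) * material$thickness * t(B) %*% d_matrix(material) %*% B
}

# nodal force vector (length 2n) from a load_case or a raw vector
build_force_vector <- function(mesh, load) {
  n <- nrow(mesh$coords)
  if (is.numeric(load) && length(load) == 2 * n) return(as.numeric(load))
  stopifnot(inherits(load, "load_case"))
  f <- numeric(2 * n)
  idx <- load$loaded_nodes
  fn <- load$total_force * load$weights
  f[2 * idx - 1] <- f[2 * idx - 1] + fn * load$direction[1]
  f[2 * idx] <- f[2 * idx] + fn * load$direction[2]
  f
}

#' Solve plane-strain elasticity on a triangle mesh
#'
#' Assembles the global sparse stiffness matrix from constant-strain triangle
#' elements, fixes both translational degrees of freedom of the constrained
#' nodes, solves with a sparse Cholesky factorization, and recovers
#' per-element strain, stress (including the out-of-plane component
#' `szz = nu * (sxx + syy)`), and von Mises stress.
#'
#' @param mesh A `tri_mesh` (with node sets populated when `constrained` or
#'   a scenario load case refers to them).
#' @param material An [fe_material][material()].
#' @param load A `load_case` from [build_load_case()], or a raw numeric
#'   nodal force vector of length `2 * n_nodes` (N), ordered
#'   (u1, v1, u2, v2, ...).
#' @param constrained Node indices fixed in both translations (defaults to
#'   the mesh's `root` node set), or a list with elements `ux` and/or `uy`
#'   giving node sets fixed in one direction only (useful for symmetry and
#'   benchmark boundary conditions).
#' @return A `fem_solution`: `displacements` (n x 2, mm), `element_stress`
#'   (m x 4 matrix: sxx, syy, szz, sxy in MPa), `element_vm` (MPa),
#'   `element_areas` (mm^2), `reactions` (per-constrained-node 2-column
#'   matrix, N), `reaction_sum`, `applied_sum`, and the relative solver
#'   `residual`.
#' @export
fe_solve <- function(mesh, material, load, constrained = mesh$node_sets$root) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(material, "fe_material"))
  if (is.null(constrained) || !length(unlist(constrained)))
    stop("constrained node set is empty; fix at least one region (e.g. the root)",
         call. = FALSE)
  n <- nrow(mesh$coords)
  el <- mesh$elements
  m <- nrow(el)
  xy <- mesh$coords
  f <- build_force_vector(mesh, load)

  fixed <- if (is.list(constrained)) {
    sort(unique(c(2L * constrained$ux - 1L, 2L * constrained$uy)))
  } else {
    sort(unique(c(2L * constrained - 1L, 2L * constrained)))
  }
  loaded <- which(f != 0)
  if (length(loaded) && all(loaded %in% fixed))
    stop("all loaded degrees of freedom are constrained; nothing to solve",
         call. = FALSE)

  x1 <- xy[el[, 1], 1]; y1 <- xy[el[, 1], 2]
  x2 <- xy[el[, 2], 1]; y2 <- xy[el[, 2], 2]
  x3 <- xy[el[, 3], 1]; y3 <- xy[el[, 3], 2]
  A2 <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  if (any(A2 <= 0)) stop("mesh contains degenerate elements", call. = FALSE)
  A <- A2 / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2)
  cc <- cbind(x3 - x2, x1 - x3, x2 - x1)

  D <- d_matrix(material)
  d11 <- D[1, 1]; d12 <- D[1, 2]; d33 <- D[3, 3]
  th <- material$thickness
  scale <- th / (4 * A)

  # 36 stiffness entries per element, vectorized over elements
  nn <- 9L * 4L
  ii <- vector("list", nn); jj <- vector("list", nn); xx <- vector("list", nn)
  k <- 0L
  for (a in 1:3) for (bb in 1:3) {
    dof_ax <- 2L * el[, a] - 1L; dof_ay <- 2L * el[, a]
    dof_bx <- 2L * el[, bb] - 1L; dof_by <- 2L * el[, bb]
    ba <- b[, a]; bb_ <- b[, bb]; ca <- cc[, a]; cb <- cc[, bb]
    k <- k + 1L; ii[[k]] <- dof_ax; jj[[k]] <- dof_bx
    xx[[k]] <- scale * (d11 * ba * bb_ + d33 * ca * cb)
    k <- k + 1L; ii[[k]] <- dof_ax; jj[[k]] <- dof_by
    xx[[k]] <- scale * (d12 * ba * cb + d33 * ca * bb_)
    k <- k + 1L; ii[[k]] <- dof_ay; jj[[k]] <- dof_bx
    xx[[k]] <- scale * (d12 * ca * bb_ + d33 * ba * cb)
    k <- k + 1L; ii[[k]] <- dof_ay; jj[[k]] <- dof_by
    xx[[k]] <- scale * (d11 * ca * cb + d33 * ba * bb_)
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(2L * n, 2L * n))

  free <- setdiff(seq_len(2L * n), fixed)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  uf <- tryCatch(as.numeric(Matrix::solve(Kff, f[free])),
                 error = function(e)
                   stop("singular stiffness system (insufficient constraints ",
                        "leave a rigid-body mode): ", conditionMessage(e),
                        call. = FALSE))
  u <- numeric(2L * n)
  u[free] <- uf

  rhs <- f[free]
  res_num <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2))
  res_den <- sqrt(sum(rhs^2))
  residual <- if (res_den > 0) res_num / res_den else res_num

  ux1 <- u[2 * el[, 1] - 1]; uy1 <- u[2 * el[, 1]]
  ux2 <- u[2 * el[, 2] - 1]; uy2 <- u[2 * el[, 2]]
  ux3 <- u[2 * el[, 3] - 1]; uy3 <- u[2 * el[, 3]]
  exx <- (b[, 1] * ux1 + b[, 2] * ux2 + b[, 3] * ux3) / A2
  eyy <- (cc[, 1] * uy1 + cc[, 2] * uy2 + cc[, 3] * uy3) / A2
  gxy <- (cc[, 1] * ux1 + cc[, 2] * ux2 + cc[, 3] * ux3 +
          b[, 1] * uy1 + b[, 2] * uy2 + b[, 3] * uy3) / A2
  sxx <- d11 * exx + d12 * eyy
  syy <- d12 * exx + d11 * eyy
  sxy <- d33 * gxy
  szz <- material$nu * (sxx + syy)
  vm <- von_mises(sxx, syy, szz, sxy)

  r_all <- as.numeric(K %*% u) - f
  fx_d <- fixed[fixed %% 2L == 1L]
  fy_d <- fixed[fixed %% 2L == 0L]
  reactions <- list(nodes_x = (fx_d + 1L) %/% 2L, rx = r_all[fx_d],
                    nodes_y = fy_d %/% 2L, ry = r_all[fy_d])
  structure(list(displacements = matrix(u, ncol = 2, byrow = TRUE,
                                        dimnames = list(NULL, c("ux", "uy"))),
                 element_stress = cbind(sxx = sxx, syy = syy, szz = szz, sxy = sxy),
                 element_vm = vm,
                 element_areas = A,
                 reactions = reactions,
                 reaction_sum = c(fx = sum(reactions$rx), fy = sum(reactions$ry)),
                 applied_sum = c(fx = sum(f[seq(1, 2 * n, 2)]),
                                 fy = sum(f[seq(2, 2 * n, 2)])),
                 residual = residual,
                 constrained = constrained),
            class = "fem_solution")
}

#' @export
print.fem_solution <- function(x, ...) {
  cat(sprintf("<fem_solution> %d elements; max |u| = %.4g mm; von Mises: mean %.4g, max %.4g MPa\n",
              length(x$element_vm), max(abs(x$displacements)),
              mean(x$element_vm), max(x$element_vm)))
  cat(sprintf("  residual %.2e; reaction sum (%.6g, %.6g) N vs applied (%.6g, %.6g) N\n",
              x$residual, x$reaction_sum[1], x$reaction_sum[2],
              x$applied_sum[1], x$applied_sum[2]))
  invisible(x)
}

#' Von Mises equivalent stress from a plane-strain stress state
#'
#' `sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) + 3 * sxy^2)`.
#' All arguments are vectorized.
#'
#' @param sxx,syy,szz,sxy Stress components (MPa).
#' @return Von Mises stress (MPa), non-negative.
#' @export
von_mises <- function(sxx, syy, szz, sxy) {
  stopifnot(all(is.finite(c(sxx, syy, szz, sxy))))
  sqrt(0.5 * ((sxx - syy)^2 + (syy - szz)^2 + (szz - sxx)^2) + 3 * sxy^2)
}

#' Export per-element stress results as CSV
#'
#' @param solution A `fem_solution`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_stress_csv <- function(solution, file) {
  utils::write.csv(data.frame(element = seq_along(solution$element_vm),
                              solution$element_stress,
                              von_mises = solution$element_vm,
                              area = solution$element_areas),
                   file, row.names = FALSE)
  invisible(file)
}
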