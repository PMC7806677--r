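# Mesh generation: constrained Delaunay triangulation of a tooth outline at a
# target element count. All boundary vertices of the outline are kept (so the
# meshed domain is exactly the outline polygon and element areas sum to the
# polygon area); extra boundary points are inserted on the original edges and
# interior points are laid on a jittered hexagonal lattice sized to hit the
# requested element count through Euler's relation T = 2*I + B - 2.

# deterministic coordinate-hash jitter in (-1, 1); no RNG involved, so a mesh
# is a pure function of (outline, target_elements)
hash_unit <- function(ix, iy) {
  h <- sin(ix * 12.9898 + iy * 78.233) * 43758.5453
  2 * (h - floor(h)) - 1
}

# subdivide each polygon edge into ceil(L/spacing) equal pieces, keeping all
# original vertices; returns coords plus the closing segment list
resample_boundary <- function(vertices, spacing) {
  n <- nrow(vertices)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p0 <- vertices[i, ]
    p1 <- vertices[if (i == n) 1L else i + 1L, ]
    L <- sqrt(sum((p1 - p0)^2))
    k <- max(1L, ceiling(L / spacing - 1e-9))
    t <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    out[[i]] <- cbind(p0[1] + t * (p1[1] - p0[1]), p0[2] + t * (p1[2] - p0[2]))
  }
  coords <- do.call(rbind, out)
  B <- nrow(coords)
  seg <- cbind(seq_len(B), c(2:B, 1L))
  list(coords = coords, seg = seg)
}

# hexagonal interior lattice with deterministic jitter, clipped to the
# polygon interior with a clearance from the boundary
interior_points <- function(poly, spacing, clearance = 0.62, jitter = 0.15) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  rh <- spacing * sqrt(3) / 2
  iy <- seq_len(max(0L, floor((yr[2] - yr[1]) / rh)))
  if (!length(iy)) return(matrix(numeric(0), 0, 2))
  pts <- NULL
  for (r in iy) {
    y0 <- yr[1] + (r - 0.5) * rh
    off <- if (r %% 2 == 0) spacing / 2 else 0
    xs <- seq(xr[1] + off + spacing / 2, xr[2], by = spacing)
    if (!length(xs)) next
    ix <- seq_along(xs)
    jx <- jitter * spacing * hash_unit(ix, r)
    jy <- jitter * spacing * hash_unit(ix + 31L, r + 17L)
    pts <- rbind(pts, cbind(xs + jx, y0 + jy))
  }
  if (is.null(pts)) return(matrix(numeric(0), 0, 2))
  keep <- .points_in_polygon(pts, poly)
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) return(pts)
  chain <- rbind(poly, poly[1, , drop = FALSE])
  d <- .dist_to_polyline(pts, chain)
  pts[d >= clearance * spacing, , drop = FALSE]
}

#' Triangulate a tooth outline into linear triangles
#'
#' Produces a conforming constrained Delaunay triangulation of the outline's
#' interior whose element count approximates `target_elements`. The outline's
#' vertices are always preserved on the boundary, so the summed element area
#' equals the polygon area to floating-point accuracy. Meshing is fully
#' deterministic for a given outline and target.
#'
#' @param outline A `tooth_outline`.
#' @param target_elements Requested number of triangles (>= 1). The achieved
#'   count is typically within a few percent of the target (never worse than
#'   about 15 percent for targets well above the outline vertex count).
#' @return A `tri_mesh`: list with `coords` (n x 2, mm), `elements`
#'   (m x 3 node indices, counter-clockwise), `element_areas` (mm^2),
#'   `n_boundary` (boundary nodes come first in `coords`),
#'   `boundary_segments`, and empty `node_sets` / `element_sets` to be filled
#'   by [identify_sets()].
#' @export
triangulate <- function(outline, target_elements) {
  stopifnot(inherits(outline, "tooth_outline"))
  if (!is.numeric(target_elements) || length(target_elements) != 1 ||
      !is.finite(target_elements) || target_elements < 1)
    stop("target_elements must be a single number >= 1", call. = FALSE)
  target_elements <- as.integer(round(target_elements))
  A <- polygon_area(outline)
  v <- outline$vertices

  # joint boundary/interior spacing: solve T = B(s) + 2 I(s) - 2 for s
  s <- sqrt(4 * A / (sqrt(3) * max(target_elements, 1)))
  bd <- NULL
  for (iter in 1:5) {
    bd <- resample_boundary(v, s)
    B <- nrow(bd$coords)
    I_need <- max(0, ceiling((target_elements - B + 2) / 2))
    if (I_need == 0) break
    s_new <- sqrt(2 * A / (sqrt(3) * I_need))
    if (abs(s_new - s) < 1e-6 * s) { s <- s_new; break }
    s <- s_new
  }
  B <- nrow(bd$coords)
  I_need <- max(0, round((target_elements - B + 2) / 2))

  ip <- matrix(numeric(0), 0, 2)
  if (I_need > 0) {
    si <- s
    for (iter in 1:4) {
      ip <- interior_points(v, si)
      if (nrow(ip) >= I_need || nrow(ip) == 0) break
      si <- si * sqrt(max(nrow(ip), 1) / I_need) * 0.98
    }
    if (nrow(ip) > I_need) {
      keep <- unique(round(seq(1, nrow(ip), length.out = I_need)))
      ip <- ip[keep, , drop = FALSE]
    }
  }

  pts <- rbind(bd$coords, ip)
  tri <- .cdt_triangulate(pts, bd$seg)
  areas <- triangle_areas(pts, tri)
  if (any(areas <= 0)) stop("triangulation produced a degenerate element", call. = FALSE)
  if (abs(sum(areas) - A) > 1e-6 * A)
    stop("triangulation does not cover the outline polygon", call. = FALSE)

  structure(list(coords = pts,
                 elements = tri,
                 element_areas = areas,
                 n_boundary = nrow(bd$coords),
                 boundary_segments = bd$seg,
                 outline_area = A,
                 target_elements = target_elements,
                 node_sets = list(),
                 element_sets = list()),
            class = "tri_mesh")
}

triangle_areas <- function(coords, elements) {
  x1 <- coords[elements[, 1], 1]; y1 <- coords[elements[, 1], 2]
  x2 <- coords[elements[, 2], 1]; y2 <- coords[elements[, 2], 2]
  x3 <- coords[elements[, 3], 1]; y3 <- coords[elements[, 3], 2]
  0.5 * ((x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1))
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d nodes (%d on boundary), %d elements, area %.3f mm^2\n",
              nrow(x$coords), x$n_boundary, nrow(x$elements), sum(x$element_areas)))
  if (length(x$node_sets))
    cat("  node sets:", paste(sprintf("%s(%d)", names(x$node_sets),
                                      lengths(x$node_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Identify the node and element sets used for constraints and loads
#'
#' Populates the mesh's named sets: `root` nodes (all nodes, interior and
#' boundary, with y at or below the crown/root boundary), the single `apex`
#' node (boundary node of maximal y; ties broken towards larger x), and --
#' when the outline carries landmark spans -- the `distal_edge` and
#' `mesial_edge` boundary node chains above the crown/root line. Element sets
#' `crown` and `root` partition all elements by centroid y.
#'
#' @param mesh A `tri_mesh` generated from `outline`.
#' @param outline The `tooth_outline` the mesh was built from.
#' @param tol Vertical tolerance for the root predicate (mm).
#' @param chain_tol Distance tolerance for matching boundary nodes to the
#'   landmark polylines (mm).
#' @return The mesh with `node_sets` and `element_sets` filled in.
#' @export
identify_sets <- function(mesh, outline, tol = 1e-9, chain_tol = 1e-6) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(outline, "tooth_outline"))
  cry <- outline$crown_root_y
  xy <- mesh$coords
  root_nodes <- which(xy[, 2] <= cry + tol)
  if (!length(root_nodes))
    stop("configuration error: empty root node set", call. = FALSE)

  bidx <- seq_len(mesh$n_boundary)
  by <- xy[bidx, 2]
  ymax <- max(by)
  cand <- bidx[by > ymax - tol]
  apex_node <- cand[which.max(xy[cand, 1])]

  sets <- list(root = root_nodes, apex = apex_node)
  for (side in c("distal", "mesial")) {
    span <- outline$spans[[side]]
    if (is.null(span) || !length(span)) next
    chain <- outline$vertices[span, , drop = FALSE]
    d <- .dist_to_polyline(xy[bidx, , drop = FALSE], chain)
    nodes <- bidx[d <= chain_tol & xy[bidx, 2] > cry + tol]
    if (!length(nodes))
      stop("configuration error: empty ", side, "_edge node set", call. = FALSE)
    sets[[paste0(side, "_edge")]] <- nodes
  }

  cent_y <- (xy[mesh$elements[, 1], 2] + xy[mesh$elements[, 2], 2] +
             xy[mesh$elements[, 3], 2]) / 3
  crown_el <- which(cent_y > cry)
  mesh$node_sets <- sets
  mesh$element_sets <- list(crown = crown_el,
                            root = setdiff(seq_len(nrow(mesh$elements)), crown_el))
  mesh$crown_root_y <- cry
  mesh
}

#' Mesh-convergence study for the stress summary statistics
#'
#' Re-meshes the outline at each target count, solves the same load scenario,
#' and tabulates the mesh-weighted mean and maximum von Mises stress so the
#' user can judge convergence (the analysis analogue of choosing an optimal
#' element count before the comparative study).
#'
#' @param outline A `tooth_outline`.
#' @param material An [fe_material][material()].
#' @param loadcase_builder Function `(mesh) -> load_case` building the load
#'   for each mesh (e.g. a draw case via [build_load_case()]).
#' @param target_counts Numeric vector of target element counts.
#' @return A data frame with one row per mesh: `target`, `elements`, `nodes`,
#'   `mwam`, `mwam_crown`, `max_vm`.
#' @export
convergence_study <- function(outline, material, loadcase_builder, target_counts) {
  stopifnot(length(target_counts) >= 1, is.function(loadcase_builder))
  rows <- lapply(target_counts, function(tc) {
    mesh <- identify_sets(triangulate(outline, tc), outline)
    load <- loadcase_builder(mesh)
    sol <- fe_solve(mesh, material, load)
    s <- summarize_stress(sol, mesh$element_sets$crown)
    data.frame(target = tc, elements = nrow(mesh$elements),
               nodes = nrow(mesh$coords), mwam = s$mwam_whole,
               mwam_crown = s$mwam_crown, max_vm = s$max_vm)
  })
  do.call(rbind, rows)
}

#' Export mesh node and element tables as CSV
#'
#' @param mesh A `tri_mesh`.
#' @param prefix Path prefix; writes `<prefix>_nodes.csv` and
#'   `<prefix>_elements.csv`.
#' @return The two paths, invisibly.
#' @export
write_mesh_csv <- function(mesh, prefix) {
  nf <- paste0(prefix, "_nodes.csv")
  ef <- paste0(prefix, "_elements.csv")
  utils::write.csv(data.frame(node = seq_len(nrow(mesh$coords)),
                              x = mesh$coords[, 1], y = mesh$coords[, 2]),
                   nf, row.names = FALSE)
  utils::write.csv(data.frame(element = seq_len(nrow(mesh$elements)),
                              n1 = mesh$elements[, 1], n2 = mesh$elements[, 2],
                              n3 = mesh$elements[, 3], area = mesh$element_areas),
                   ef, row.names = FALSE)
  invisible(c(nf, ef))
}

#' Write a mesh (with optional per-element fields) as a legacy VTK file
#'
#' Plain-text VTK unstructured grid, readable by ParaView and friends, for
#' rendering stress distribution maps.
#'
#' @param mesh A `tri_mesh`.
#' @param file Output path (conventionally `.vtk`).
#' @param cell_data Named list of numeric per-element vectors (e.g.
#'   `list(von_mises = sol$element_vm)`).
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, file, cell_data = list()) {
  n <- nrow(mesh$coords); m <- nrow(mesh$elements)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "toothfea mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.10g %.10g 0", mesh$coords[, 1], mesh$coords[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4L * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.10g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}
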