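#' Parametric description of a labial-view tooth profile
#'
#' Bundles the geometric parameters of a synthetic tooth: a triangular crown
#' (optionally recurved and with concave edges), optional lateral cusplets on
#' the root shoulders, and a rectangular root block. Lengths are millimetres.
#'
#' @param crown_height Crown height above the crown/root boundary (mm).
#' @param crown_basal_width Width of the crown base (mm).
#' @param apex_offset_frac Apex position as a fraction of the basal width
#'   measured from the distal corner towards the mesial side: 0 puts the apex
#'   above the distal corner (right-triangle crown), 0.5 centres it
#'   (isosceles crown).
#' @param edge_curvature Dimensionless concavity of the mesial and distal
#'   crown edges; each straight edge of length L is bowed towards the crown
#'   interior by a quadratic arc of maximum depth `edge_curvature * L`.
#' @param cusplet_height_frac,cusplet_width_frac Height (fraction of crown
#'   height) and width (fraction of crown basal width) of the lateral
#'   cusplets; both 0 means no cusplets. Must be < 0.5.
#' @param root_depth Depth of the root block below the crown base (mm).
#' @param root_width Width of the root block (mm); at least the crown width.
#' @param label Free-text tag, typically "taxon|position".
#' @return An object of class `tooth_spec`.
#' @seealso [generate_outline()], [otodontid_tooth_presets()]
#' @export
tooth_spec <- function(crown_height, crown_basal_width,
                       apex_offset_frac = 0.5, edge_curvature = 0,
                       cusplet_height_frac = 0, cusplet_width_frac = 0,
                       root_depth = 0.4 * crown_height,
                       root_width = 1.25 * crown_basal_width,
                       label = "tooth") {
  spec <- list(crown_height = crown_height,
               crown_basal_width = crown_basal_width,
               apex_offset_frac = apex_offset_frac,
               edge_curvature = edge_curvature,
               cusplet_height_frac = cusplet_height_frac,
               cusplet_width_frac = cusplet_width_frac,
               root_depth = root_depth,
               root_width = root_width,
               label = as.character(label))
  validate_tooth_spec(spec)
  structure(spec, class = "tooth_spec")
}

validate_tooth_spec <- function(s) {
  chk <- function(ok, what) if (!isTRUE(ok)) stop("invalid tooth spec: ", what, call. = FALSE)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (f in c("crown_height", "crown_basal_width", "root_depth", "root_width"))
    chk(num1(s[[f]]) && s[[f]] > 0, paste(f, "must be a positive length"))
  chk(num1(s$apex_offset_frac) && s$apex_offset_frac >= 0 && s$apex_offset_frac <= 1,
      "apex_offset_frac must lie in [0, 1]")
  for (f in c("cusplet_height_frac", "cusplet_width_frac"))
    chk(num1(s[[f]]) && s[[f]] >= 0 && s[[f]] < 0.5,
        paste(f, "must lie in [0, 0.5)"))
  chk(xor(s$cusplet_height_frac == 0, s$cusplet_width_frac == 0) == FALSE,
      "cusplet fractions must be both zero or both positive")
  chk(num1(s$edge_curvature) && s$edge_curvature >= 0 && s$edge_curvature < 0.25,
      "edge_curvature must lie in [0, 0.25)")
  chk(s$root_width >= s$crown_basal_width,
      "root_width must be >= crown_basal_width")
  invisible(s)
}

#' @export
print.tooth_spec <- function(x, ...) {
  cat(sprintf("<tooth_spec '%s'> crown %.1f x %.1f mm, apex offset %.2f, root %.1f x %.1f mm",
              x$label, x$crown_basal_width, x$crown_height, x$apex_offset_frac,
              x$root_width, x$root_depth))
  if (x$cusplet_height_frac > 0)
    cat(sprintf(", cusplets %.0f%% h x %.0f%% w",
                100 * x$cusplet_height_frac, 100 * x$cusplet_width_frac))
  cat("\n")
  invisible(x)
}

# sample one boundary chain from p0 to p1 with k >= 2 points (both ends),
# bowing it towards the polygon interior (left of travel, CCW boundary)
sample_chain <- function(p0, p1, k, curvature = 0) {
  t <- seq(0, 1, length.out = max(2L, k))
  d <- p1 - p0
  L <- sqrt(sum(d^2))
  px <- p0[1] + t * d[1]
  py <- p0[2] + t * d[2]
  if (curvature > 0 && L > 0) {
    bow <- curvature * L * 4 * t * (1 - t)
    nx <- -d[2] / L
    ny <- d[1] / L
    px <- px + bow * nx
    py <- py + bow * ny
  }
  cbind(px, py)
}

#' Generate a synthetic tooth outline from a parametric spec
#'
#' Builds a counter-clockwise simple polygon in the package's coordinate
#' convention: y increases apically, the crown base sits on y = 0 (the
#' crown/root boundary), the mesial side is at small x and the distal side at
#' large x. The root block occupies y < 0.
#'
#' @param spec A [tooth_spec()].
#' @param n_vertices Approximate number of boundary vertices to sample
#'   (allocated across boundary chains in proportion to their length).
#' @return A `tooth_outline`: list with `vertices` (n x 2 matrix, mm, CCW),
#'   `apex_index`, `crown_root_y`, `spans` (named index ranges for the
#'   mesial edge, distal edge and cusplets) and `label`.
#' @export
generate_outline <- function(spec, n_vertices = 200) {
  if (!inherits(spec, "tooth_spec")) spec <- do.call(tooth_spec, as.list(spec))
  validate_tooth_spec(spec)
  H <- spec$crown_height; W <- spec$crown_basal_width
  f <- spec$apex_offset_frac; e <- spec$edge_curvature
  D <- spec$root_depth; Rw <- spec$root_width
  has_cusp <- spec$cusplet_height_frac > 0 && spec$cusplet_width_frac > 0
  cw <- spec$cusplet_width_frac * W
  ch <- spec$cusplet_height_frac * H
  gap <- 0.4 * cw
  xm_r <- (W - Rw) / 2          # mesial root corner x
  xd_r <- (W + Rw) / 2          # distal root corner x
  apex <- c(W - f * W, H)
  if (has_cusp) {
    if (W + gap + cw > xd_r - 1e-9 || -gap - cw < xm_r + 1e-9)
      stop("invalid tooth spec: root_width too small to carry the lateral cusplets",
           call. = FALSE)
  }

  # boundary chains in CCW order; named so landmark spans can be recovered
  chains <- list()
  add <- function(name, p0, p1, curv = 0)
    chains[[length(chains) + 1L]] <<- list(name = name, p0 = p0, p1 = p1, curv = curv)
  add("root_bottom", c(xm_r, -D), c(xd_r, -D))
  add("root_distal_side", c(xd_r, -D), c(xd_r, 0))
  if (has_cusp) {
    add("distal_shoulder", c(xd_r, 0), c(W + gap + cw, 0))
    add("cusplet_distal_up", c(W + gap + cw, 0), c(W + gap + cw / 2, ch))
    add("cusplet_distal_down", c(W + gap + cw / 2, ch), c(W + gap, 0))
    add("distal_notch", c(W + gap, 0), c(W, 0))
  } else {
    add("distal_shoulder", c(xd_r, 0), c(W, 0))
  }
  add("distal_edge", c(W, 0), apex, curv = e)
  add("mesial_edge", apex, c(0, 0), curv = e)
  if (has_cusp) {
    add("mesial_notch", c(0, 0), c(-gap, 0))
    add("cusplet_mesial_up", c(-gap, 0), c(-gap - cw / 2, ch))
    add("cusplet_mesial_down", c(-gap - cw / 2, ch), c(-gap - cw, 0))
    add("mesial_shoulder", c(-gap - cw, 0), c(xm_r, 0))
  } else {
    add("mesial_shoulder", c(0, 0), c(xm_r, 0))
  }
  add("root_mesial_side", c(xm_r, 0), c(xm_r, -D))

  lens <- vapply(chains, function(cc) sqrt(sum((cc$p1 - cc$p0)^2)), 0)
  per <- sum(lens)
  ks <- pmax(2L, as.integer(round(n_vertices * lens / per)))

  verts <- NULL
  spans <- list()
  cusplet_spans <- list()
  for (i in seq_along(chains)) {
    cc <- chains[[i]]
    pts <- sample_chain(cc$p0, cc$p1, ks[i], cc$curv)
    start_idx <- if (is.null(verts)) 1L else nrow(verts) + 1L
    # drop the first point (duplicate of previous chain's endpoint),
    # except for the very first chain
    if (!is.null(verts)) pts <- pts[-1, , drop = FALSE]
    idx <- seq.int(start_idx, length.out = nrow(pts))
    # span includes the junction vertex that starts the chain
    full_span <- c(if (!is.null(verts)) start_idx - 1L else integer(0), idx)
    if (cc$name == "distal_edge") spans$distal <- full_span
    if (cc$name == "mesial_edge") spans$mesial <- full_span
    if (grepl("^cusplet_distal", cc$name))
      cusplet_spans$distal <- c(cusplet_spans$distal, full_span)
    if (grepl("^cusplet_mesial", cc$name))
      cusplet_spans$mesial <- c(cusplet_spans$mesial, full_span)
    verts <- rbind(verts, pts)
  }
  # last chain ends at the first vertex; drop the duplicate closing point
  verts <- verts[-nrow(verts), , drop = FALSE]
  dimnames(verts) <- list(NULL, c("x", "y"))
  # spans are stored disjoint: the mesial edge yields the apex to the distal span
  spans$mesial <- setdiff(spans$mesial, spans$distal)
  if (length(cusplet_spans))
    cusplet_spans <- lapply(cusplet_spans, function(ix) sort(unique(ix)))

  apex_index <- which(abs(verts[, 2] - H) < 1e-12 & abs(verts[, 1] - apex[1]) < 1e-12)[1]
  out <- structure(list(vertices = verts,
                        apex_index = as.integer(apex_index),
                        crown_root_y = 0,
                        spans = list(mesial = spans$mesial,
                                     distal = spans$distal,
                                     cusplets = cusplet_spans),
                        label = spec$label,
                        spec = spec),
                   class = "tooth_outline")
  validate_outline(out)
  out
}

validate_outline <- function(o) {
  v <- o$vertices
  if (!is.matrix(v) || ncol(v) != 2 || nrow(v) < 3 || !all(is.finite(v)))
    stop("outline must be a numeric n x 2 matrix with n >= 3", call. = FALSE)
  a <- shoelace(v)
  if (a <= 0) stop("outline must be counter-clockwise with positive area", call. = FALSE)
  if (!.polygon_is_simple(v)) stop("outline is self-intersecting", call. = FALSE)
  ymax <- max(v[, 2])
  if (abs(v[o$apex_index, 2] - ymax) > 1e-9)
    stop("apex vertex must have maximal y", call. = FALSE)
  if (!(o$crown_root_y > min(v[, 2]) && o$crown_root_y < ymax))
    stop("crown_root_y must lie strictly between the outline's y extremes",
         call. = FALSE)
  invisible(o)
}

#' @export
print.tooth_outline <- function(x, ...) {
  cat(sprintf("<tooth_outline '%s'> %d vertices, area %.2f mm^2, crown/root y = %g mm\n",
              x$label, nrow(x$vertices), polygon_area(x), x$crown_root_y))
  invisible(x)
}

shoelace <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  0.5 * sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])
}

#' Polygon area of a tooth outline (shoelace formula)
#'
#' @param outline A `tooth_outline` or an n x 2 vertex matrix (mm).
#' @return Area in mm^2 (strictly positive for a valid CCW outline).
#' @export
polygon_area <- function(outline) {
  v <- if (inherits(outline, "tooth_outline")) outline$vertices else as.matrix(outline)
  abs(shoelace(v))
}

#' Read a digitized tooth outline from XY coordinates
#'
#' Accepts the two-column XY tables produced by digitizing labial-view
#' photographs (one vertex per row, mm). Clockwise input is reversed to
#' counter-clockwise and an explicitly repeated closing vertex is dropped.
#'
#' @param table A two-column numeric matrix/data frame, or a path to a CSV
#'   file with columns x, y (header optional).
#' @param crown_root_y y-coordinate of the crown/root boundary line (mm).
#' @param spans Optional named list of vertex index ranges (`mesial`,
#'   `distal`, `cusplets`) identifying boundary landmarks; indices refer to
#'   the vertex order after reorientation.
#' @param label Tag stored with the outline.
#' @return A `tooth_outline`.
#' @export
read_outline_xy <- function(table, crown_root_y, spans = NULL, label = "outline") {
  if (is.character(table) && length(table) == 1L) {
    first <- readLines(table, n = 1L)
    header <- grepl("[A-Za-z]", first)
    table <- utils::read.csv(table, header = header)
    if (!header) names(table) <- c("x", "y")[seq_len(ncol(table))]
  }
  v <- as.matrix(table)[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  if (nrow(v) < 3 || !all(is.finite(v)))
    stop("outline table must have >= 3 rows of finite x, y values", call. = FALSE)
  if (nrow(v) > 3 && all(abs(v[nrow(v), ] - v[1, ]) < 1e-12))
    v <- v[-nrow(v), , drop = FALSE]
  if (anyDuplicated(round(v, 9)))
    v <- v[!duplicated(round(v, 9)), , drop = FALSE]
  if (nrow(v) < 3) stop("fewer than 3 distinct vertices", call. = FALSE)
  a <- shoelace(v)
  if (a == 0) stop("outline has zero signed area", call. = FALSE)
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
  if (!.polygon_is_simple(v)) stop("outline is self-intersecting", call. = FALSE)
  ymax <- max(v[, 2])
  cand <- which(v[, 2] > ymax - 1e-12)
  apex_index <- cand[which.max(v[cand, 1])]
  dimnames(v) <- list(NULL, c("x", "y"))
  out <- structure(list(vertices = v,
                        apex_index = as.integer(apex_index),
                        crown_root_y = crown_root_y,
                        spans = if (is.null(spans)) list(mesial = NULL, distal = NULL,
                                                         cusplets = list())
                                else spans,
                        label = label,
                        spec = NULL),
                   class = "tooth_outline")
  validate_outline(out)
  out
}

#' Write a tooth outline's vertices to a two-column CSV
#'
#' @param outline A `tooth_outline`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_outline_xy <- function(outline, file) {
  v <- outline$vertices
  utils::write.csv(data.frame(x = v[, 1], y = v[, 2]), file, row.names = FALSE)
  invisible(file)
}
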