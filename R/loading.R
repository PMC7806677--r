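# Bite-force estimation and load-case construction.
#
# Life-size bite forces follow the allometric assumption that bite force
# scales with body mass to the 0.67 power, anchored at a 240 kg great white
# shark reference with anterior/posterior bite forces of 1602 N and 3131 N;
# the lateral jaw region takes the arithmetic mean of the two. Scaled forces
# instead keep a constant force-to-surface-area ratio across models so stress
# comparisons reflect shape only.

#' Allometric bite-force model
#'
#' @param reference_mass Reference body mass (kg).
#' @param f_anterior,f_posterior Anterior and posterior bite forces at the
#'   reference mass (N).
#' @param exponent Allometric exponent of bite force on body mass.
#' @return An object of class `bite_force_model`.
#' @export
bite_force_model <- function(reference_mass = 240, f_anterior = 1602,
                             f_posterior = 3131, exponent = 0.67) {
  vals <- c(reference_mass, f_anterior, f_posterior, exponent)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all bite-force model parameters must be positive", call. = FALSE)
  structure(list(reference_mass = reference_mass, f_anterior = f_anterior,
                 f_posterior = f_posterior, exponent = exponent),
            class = "bite_force_model")
}

#' Estimate a life-size bite force from body mass
#'
#' `F = F_ref_position * (M / M_ref)^b` for anterior and posterior positions;
#' the lateral position is the arithmetic mean of the two (jaws act as
#' third-class levers, so bite force rises towards the jaw joint).
#'
#' @param mass Body mass in kg (> 0); vectorized.
#' @param position One of "anterior", "lateral", "posterior".
#' @param model A [bite_force_model()].
#' @return Bite force in N.
#' @export
estimate_bite_force <- function(mass, position, model = bite_force_model()) {
  if (!all(is.finite(mass)) || any(mass <= 0))
    stop("mass must be > 0", call. = FALSE)
  position <- match.arg(position, c("anterior", "lateral", "posterior"))
  r <- (mass / model$reference_mass)^model$exponent
  switch(position,
         anterior = model$f_anterior * r,
         posterior = model$f_posterior * r,
         lateral = (model$f_anterior * r + model$f_posterior * r) / 2)
}

#' Scale a reference force to a model's surface area
#'
#' Keeps the force-to-surface-area (F/SA) ratio of the reference model, so
#' stress levels compare shapes rather than sizes:
#' `F = ref_force * area / ref_area`.
#'
#' @param area Model surface area (mm^2).
#' @param ref_area Reference model surface area (mm^2).
#' @param ref_force Force applied to the reference model (N).
#' @return Scaled force in N.
#' @export
scale_force_to_reference <- function(area, ref_area, ref_force) {
  if (!all(is.finite(c(area, ref_area, ref_force))) ||
      any(c(area, ref_area, ref_force) <= 0))
    stop("area, ref_area and ref_force must all be > 0", call. = FALSE)
  ref_force * area / ref_area
}

#' Build a puncture or draw load case on a mesh
#'
#' Puncture applies the total force at the single apex node, directed
#' apicobasally (0, -1). Draw distributes a horizontal force over the nodes
#' of a crown cutting edge; with the default distal edge the pull is mesially
#' directed (-1, 0). By default the total force is divided equally over the
#' loaded nodes; `distribution = "consistent"` instead weights nodes by the
#' half-lengths of their incident boundary segments (the work-equivalent
#' loading of a uniform edge traction, useful for analytic benchmarks).
#'
#' @param scenario "puncture" or "draw".
#' @param mesh A `tri_mesh` with node sets populated (see [identify_sets()]).
#' @param total_force Total applied force (N).
#' @param edge For draw: which cutting edge carries the load ("distal",
#'   the default, or "mesial").
#' @param distribution "equal" (divide the total by the number of loaded
#'   nodes) or "consistent" (boundary-segment-length weights).
#' @param nodes Optional explicit node index vector overriding the scenario's
#'   node set.
#' @param direction Optional explicit direction (2-vector, normalized
#'   internally).
#' @return A `load_case`: scenario, total force, loaded nodes, unit
#'   direction, normalized `weights` (summing to 1) and scalar
#'   `per_node_force` (N) for equal distribution.
#' @export
build_load_case <- function(scenario = c("puncture", "draw"), mesh, total_force,
                            edge = c("distal", "mesial"),
                            distribution = c("equal", "consistent"),
                            nodes = NULL, direction = NULL) {
  scenario <- match.arg(scenario)
  edge <- match.arg(edge)
  distribution <- match.arg(distribution)
  stopifnot(inherits(mesh, "tri_mesh"))
  if (!is.numeric(total_force) || length(total_force) != 1 || !is.finite(total_force))
    stop("total_force must be a single finite number", call. = FALSE)

  if (is.null(nodes)) {
    nodes <- switch(scenario,
                    puncture = mesh$node_sets$apex,
                    draw = mesh$node_sets[[paste0(edge, "_edge")]])
    if (is.null(nodes) || !length(nodes))
      stop("configuration error: empty loaded node set for scenario '",
           scenario, "'", call. = FALSE)
  }
  if (is.null(direction)) {
    direction <- switch(scenario,
                        puncture = c(0, -1),
                        draw = if (edge == "distal") c(-1, 0) else c(1, 0))
  }
  nd <- sqrt(sum(direction^2))
  if (nd == 0) stop("direction must be nonzero", call. = FALSE)
  direction <- direction / nd

  nL <- length(nodes)
  if (distribution == "equal") {
    weights <- rep(1 / nL, nL)
  } else {
    seg <- mesh$boundary_segments
    inset <- seg[, 1] %in% nodes & seg[, 2] %in% nodes
    if (!any(inset))
      stop("consistent distribution needs loaded nodes forming a boundary chain",
           call. = FALSE)
    seg <- seg[inset, , drop = FALSE]
    L <- sqrt(rowSums((mesh$coords[seg[, 1], , drop = FALSE] -
                       mesh$coords[seg[, 2], , drop = FALSE])^2))
    w <- setNames(numeric(nL), nodes)
    for (i in seq_len(nrow(seg))) {
      w[as.character(seg[i, 1])] <- w[as.character(seg[i, 1])] + L[i] / 2
      w[as.character(seg[i, 2])] <- w[as.character(seg[i, 2])] + L[i] / 2
    }
    weights <- as.numeric(w) / sum(w)
  }
  structure(list(scenario = scenario, total_force = total_force,
                 loaded_nodes = nodes, direction = direction,
                 weights = weights, per_node_force = total_force / nL,
                 distribution = distribution, edge = edge),
            class = "load_case")
}

#' @export
print.load_case <- function(x, ...) {
  cat(sprintf("<load_case '%s'> %g N over %d node(s), direction (%.3g, %.3g), %s weights\n",
              x$scenario, x$total_force, length(x$loaded_nodes),
              x$direction[1], x$direction[2], x$distribution))
  invisible(x)
}
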