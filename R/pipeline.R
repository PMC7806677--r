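# Study orchestration: 5 species x 3 tooth positions x three loading modes
# (life-size puncture, surface-area-scaled puncture, scaled draw), followed by
# age-resampled trend tests per (position, scenario), mirroring the structure
# of the comparative analysis the package implements.

#' Configuration for a comparative tooth-biomechanics study
#'
#' @param species Species metadata table (see [otodontid_species()]).
#' @param teeth Tooth-shape preset table (see [otodontid_tooth_presets()]);
#'   one row per model with `taxon`, `position` and [tooth_spec()] columns.
#' @param material An [fe_material][material()].
#' @param target_elements Target triangle count per mesh. The comparative
#'   study was designed around meshes of roughly 30-43 thousand elements;
#'   the default follows suit.
#' @param reference_puncture_force,reference_draw_force Forces (N) applied to
#'   the reference model in the scaled analyses; all other models receive
#'   forces keeping the same F/SA ratio.
#' @param reference_model Label `"taxon|position"` of the scaled-force
#'   reference model; defaults to the anterior tooth of the species flagged
#'   `is_reference` in `species`.
#' @param thresholds Named numeric: saturation thresholds (MPa) per scenario
#'   for stress maps and exceedance-area bookkeeping (defaults: 5 GPa for
#'   puncture, 10 MPa for draw).
#' @param draw_edge Which cutting edge carries the draw load ("distal", the
#'   default, or "mesial").
#' @param n_reps Number of age-resampling replicates for the trend tests.
#' @param seed Seed for the trend resampling.
#' @param bite_model A [bite_force_model()] for life-size forces.
#' @param out_dir Optional output directory for CSV/JSON exports.
#' @param keep_fields Keep meshes and full FEM solutions in the returned
#'   object (memory-heavy for large meshes).
#' @return A `study_config` list.
#' @export
study_config <- function(species = otodontid_species(),
                         teeth = otodontid_tooth_presets(),
                         material = toothfea::material(),
                         target_elements = 35000,
                         reference_puncture_force = 49051,
                         reference_draw_force = 500,
                         reference_model = NULL,
                         thresholds = c(puncture = 5000, draw = 10),
                         draw_edge = c("distal", "mesial"),
                         n_reps = 10000, seed = 1,
                         bite_model = bite_force_model(),
                         out_dir = NULL, keep_fields = FALSE) {
  draw_edge <- match.arg(draw_edge)
  if (is.null(reference_model)) {
    ref_taxon <- species$taxon[which(species$is_reference)[1]]
    if (is.na(ref_taxon)) ref_taxon <- species$taxon[nrow(species)]
    reference_model <- paste(ref_taxon, "anterior", sep = "|")
  }
  if (!reference_model %in% teeth$label)
    stop("reference model '", reference_model, "' not present in the teeth table",
         call. = FALSE)
  if (any(thresholds <= 0)) stop("thresholds must be > 0", call. = FALSE)
  structure(list(species = species, teeth = teeth, material = material,
                 target_elements = target_elements,
                 reference_puncture_force = reference_puncture_force,
                 reference_draw_force = reference_draw_force,
                 reference_model = reference_model,
                 thresholds = thresholds, draw_edge = draw_edge,
                 n_reps = n_reps, seed = seed, bite_model = bite_model,
                 out_dir = out_dir, keep_fields = keep_fields),
            class = "study_config")
}

#' Run the full comparative study
#'
#' For every tooth model: generates the outline, meshes it, solves the
#' life-size puncture, scaled puncture and scaled draw load cases, and
#' records a stress summary row. Then performs the age-resampled correlation
#' test per (position, scenario) on the scaled-force mesh-weighted means.
#' A failure in one model is logged and the remaining models proceed.
#'
#' @param config A [study_config()].
#' @return A `study_result`: `summary` (one data frame row per model and
#'   scenario), `trends` (named list of `trend_result`s per
#'   position/scenario), `areas`, `log` (per-stage messages), `failed`
#'   (labels of models that errored), and optionally `meshes`/`solutions`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  teeth <- config$teeth
  species <- config$species
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  # geometry pass: outlines, meshes, areas (reference area needed up front)
  models <- vector("list", nrow(teeth))
  names(models) <- teeth$label
  failed <- character(0)
  for (i in seq_len(nrow(teeth))) {
    lab <- teeth$label[i]
    models[i] <- list(tryCatch({
      outline <- generate_outline(spec_from_row(teeth[i, ]))
      mesh <- identify_sets(triangulate(outline, config$target_elements), outline)
      note("model %s: %d elements, %d nodes, area %.2f mm^2",
           lab, nrow(mesh$elements), nrow(mesh$coords), sum(mesh$element_areas))
      list(outline = outline, mesh = mesh, area = polygon_area(outline))
    }, error = function(e) {
      note("model %s FAILED in geometry/meshing: %s", lab, conditionMessage(e))
      NULL
    }))
  }
  ok <- !vapply(models, is.null, TRUE)
  failed <- c(failed, teeth$label[!ok])
  if (!any(ok)) stop("all models failed during meshing", call. = FALSE)
  ref_lab <- config$reference_model
  if (is.null(models[[ref_lab]]))
    stop("reference model failed; scaled forces undefined", call. = FALSE)
  ref_area <- models[[ref_lab]]$area

  scen_threshold <- function(scenario)
    unname(config$thresholds[[if (grepl("puncture", scenario)) "puncture" else "draw"]])

  rows <- list()
  solutions <- if (config$keep_fields) list() else NULL
  for (i in seq_len(nrow(teeth))) {
    if (!ok[i]) next
    lab <- teeth$label[i]
    mdl <- models[[i]]
    sp_row <- species[species$taxon == teeth$taxon[i], , drop = FALSE]
    mass <- if (nrow(sp_row)) sp_row$body_mass_kg[1] else NA_real_
    cases <- list(
      puncture_life = list(
        scenario = "puncture",
        force = if (is.finite(mass))
          estimate_bite_force(mass, teeth$position[i], config$bite_model)
        else NA_real_),
      puncture_scaled = list(
        scenario = "puncture",
        force = scale_force_to_reference(mdl$area, ref_area,
                                         config$reference_puncture_force)),
      draw_scaled = list(
        scenario = "draw",
        force = scale_force_to_reference(mdl$area, ref_area,
                                         config$reference_draw_force))
    )
    for (cs in names(cases)) {
      scen <- cases[[cs]]$scenario
      force <- cases[[cs]]$force
      if (!is.finite(force)) {
        note("model %s %s skipped: no body mass available", lab, cs)
        next
      }
      row <- tryCatch({
        load <- build_load_case(scen, mdl$mesh, force, edge = config$draw_edge)
        sol <- fe_solve(mdl$mesh, config$material, load)
        s <- summarize_stress(sol, mdl$mesh$element_sets$crown,
                              thresholds = scen_threshold(cs))
        if (config$keep_fields)
          solutions[[paste(lab, cs, sep = "@")]] <<- sol
        data.frame(taxon = teeth$taxon[i], position = teeth$position[i],
                   label = lab, mode = cs, scenario = scen,
                   total_force = force, loaded_nodes = length(load$loaded_nodes),
                   area = mdl$area, f_sa = force / mdl$area,
                   elements = nrow(mdl$mesh$elements),
                   mwam = s$mwam_whole, mwam_crown = s$mwam_crown,
                   max_vm = s$max_vm,
                   frac_area_above = unname(s$frac_area_above[1]),
                   threshold = scen_threshold(cs),
                   stringsAsFactors = FALSE)
      }, error = function(e) {
        note("model %s %s FAILED in solve: %s", lab, cs, conditionMessage(e))
        failed <<- unique(c(failed, lab))
        NULL
      })
      if (!is.null(row)) rows[[length(rows) + 1L]] <- row
    }
  }
  summary <- do.call(rbind, rows)

  # trend tests on scaled-force MWAMs per position x scenario
  trends <- list()
  for (pos in unique(summary$position)) {
    for (cs in c("puncture_scaled", "draw_scaled")) {
      sub <- summary[summary$position == pos & summary$mode == cs, ]
      recs <- merge(data.frame(taxon = sub$taxon, mwam = sub$mwam),
                    species, by = "taxon", sort = FALSE)
      if (nrow(recs) < 3) next
      trends[[paste(pos, cs, sep = ".")]] <-
        repeated_correlation(recs$mwam, recs, n_reps = config$n_reps,
                             seed = config$seed)
    }
  }

  result <- structure(list(summary = summary, trends = trends,
                           areas = vapply(models[ok], `[[`, 0, "area"),
                           config = config, log = log, failed = failed,
                           meshes = if (config$keep_fields)
                             lapply(models[ok], `[[`, "mesh") else NULL,
                           solutions = solutions),
                      class = "study_result")
  if (!is.null(config$out_dir)) export_study(result, config$out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d summary rows (%d models, %d failed), %d trend tests\n",
              nrow(x$summary), length(x$areas), length(x$failed), length(x$trends)))
  invisible(x)
}

export_study <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$summary, file.path(dir, "stress_summary.csv"),
                   row.names = FALSE)
  for (nm in names(result$trends))
    write_trend_result(result$trends[[nm]], file.path(dir, paste0("trend_", nm)))
  writeLines(result$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Classify crown elements into edge and central bands
#'
#' Crown elements within a mid-crown height window are split by the distance
#' of their centroid to the mesial/distal cutting-edge polylines: the closest
#' quantile forms the edge bands, the farthest the central band. Used for the
#' qualitative stress-pattern checks (edges load up under draw, the crown
#' centre behaves like a beam's neutral axis).
#'
#' @param mesh A `tri_mesh` with sets populated.
#' @param outline The corresponding `tooth_outline`.
#' @param height_window Crown-height fractions (low, high) selecting the band
#'   region between cusplets and apex.
#' @param edge_quantile Distance quantile bounding the edge bands.
#' @param central_quantile Distance quantile above which elements count as
#'   central.
#' @return List of element index vectors: `mesial_band`, `distal_band`,
#'   `edge` (union) and `central`.
#' @export
crown_bands <- function(mesh, outline, height_window = c(0.25, 0.7),
                        edge_quantile = 0.25, central_quantile = 0.55) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(outline, "tooth_outline"))
  v <- outline$vertices
  cry <- outline$crown_root_y
  H <- max(v[, 2]) - cry
  el <- mesh$elements
  cx <- (mesh$coords[el[, 1], 1] + mesh$coords[el[, 2], 1] + mesh$coords[el[, 3], 1]) / 3
  cy <- (mesh$coords[el[, 1], 2] + mesh$coords[el[, 2], 2] + mesh$coords[el[, 3], 2]) / 3
  win <- which(cy > cry + height_window[1] * H & cy < cry + height_window[2] * H)
  if (!length(win)) stop("empty crown band window", call. = FALSE)
  cen <- cbind(cx[win], cy[win])
  dm <- .dist_to_polyline(cen, v[outline$spans$mesial, , drop = FALSE])
  dd <- .dist_to_polyline(cen, v[outline$spans$distal, , drop = FALSE])
  d <- pmin(dm, dd)
  qe <- stats::quantile(d, edge_quantile)
  qc <- stats::quantile(d, central_quantile)
  list(mesial_band = win[dm <= qe],
       distal_band = win[dd <= qe],
       edge = win[d <= qe],
       central = win[d >= qc])
}

#' Render a von Mises stress map of a solved model
#'
#' Filled-element plot with stresses above the saturation threshold drawn in
#' grey, the convention used for puncture/draw stress distribution figures
#' (mesial left, distal right).
#'
#' @param mesh A `tri_mesh`.
#' @param element_vm Per-element von Mises stresses (MPa), e.g.
#'   `solution$element_vm`.
#' @param threshold Saturation threshold (MPa).
#' @param file Output file; the device is chosen from the extension
#'   (`.pdf` or `.png`). `NULL` draws on the current device.
#' @param palette Colour palette function for sub-threshold stresses.
#' @param title Plot title.
#' @return Invisibly, a list with `n_saturated` (elements above threshold)
#'   and `frac_area_saturated`.
#' @export
render_stress_map <- function(mesh, element_vm, threshold, file = NULL,
                              palette = grDevices::hcl.colors, title = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"), length(element_vm) == nrow(mesh$elements))
  sat <- element_vm > threshold
  if (!is.null(file)) {
    if (grepl("\\.png$", file, ignore.case = TRUE))
      grDevices::png(file, width = 900, height = 1100)
    else grDevices::pdf(file, width = 6, height = 7.5)
    on.exit(grDevices::dev.off())
  }
  ncol <- 64L
  cols <- palette(ncol, "Viridis")
  vmax <- max(min(threshold, max(element_vm)), .Machine$double.eps)
  idx <- pmin(ncol, pmax(1L, ceiling(element_vm / vmax * ncol)))
  fill <- ifelse(sat, "grey65", cols[idx])
  el <- mesh$elements
  xs <- rbind(mesh$coords[el[, 1], 1], mesh$coords[el[, 2], 1],
              mesh$coords[el[, 3], 1], NA)
  ys <- rbind(mesh$coords[el[, 1], 2], mesh$coords[el[, 2], 2],
              mesh$coords[el[, 3], 2], NA)
  graphics::plot(range(mesh$coords[, 1]), range(mesh$coords[, 2]),
                 type = "n", asp = 1, xlab = "mesial - distal (mm)",
                 ylab = "apicobasal (mm)", main = title)
  graphics::polygon(as.vector(xs), as.vector(ys), col = fill, border = NA)
  invisible(list(n_saturated = sum(sat),
                 frac_area_saturated = sum(mesh$element_areas[sat]) /
                   sum(mesh$element_areas)))
}
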