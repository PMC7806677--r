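# Stress field summaries. The comparison statistic across models is the
# mesh-weighted arithmetic mean (MWAM) of per-element von Mises stress,
# weighting each constant-stress element by its area so that non-uniform
# meshes do not bias the average.

#' Mesh-weighted arithmetic mean of a per-element field
#'
#' `sum(value_i * area_i) / sum(area_i)`. With a constant out-of-plane
#' thickness, area weights and volume weights coincide.
#'
#' @param element_vm Per-element values (e.g. von Mises stress, MPa).
#' @param element_areas Per-element areas (mm^2, > 0).
#' @return The weighted mean.
#' @export
mwam <- function(element_vm, element_areas) {
  if (length(element_vm) != length(element_areas))
    stop("element_vm and element_areas must have equal length", call. = FALSE)
  if (!length(element_vm)) stop("empty field", call. = FALSE)
  if (any(element_areas <= 0)) stop("element areas must be > 0", call. = FALSE)
  sum(element_vm * element_areas) / sum(element_areas)
}

#' Summarize a FEM solution's von Mises field
#'
#' Computes the whole-tooth and crown-only mesh-weighted means, the maximum
#' per-element von Mises stress, and the area fraction of the model exceeding
#' each threshold (the quantity rendered as saturated grey in stress maps).
#'
#' @param solution A `fem_solution`.
#' @param crown_elements Element indices of the crown set.
#' @param thresholds Named or unnamed numeric vector of thresholds (MPa).
#' @return A `stress_summary`: `mwam_whole`, `mwam_crown`, `max_vm` (MPa),
#'   `frac_area_above` (named by threshold), `element_count`.
#' @export
summarize_stress <- function(solution, crown_elements, thresholds = numeric(0)) {
  stopifnot(inherits(solution, "fem_solution"))
  vm <- solution$element_vm
  ar <- solution$element_areas
  if (is.null(crown_elements) || !length(crown_elements))
    stop("configuration error: empty crown element set", call. = FALSE)
  if (any(crown_elements < 1 | crown_elements > length(vm)))
    stop("crown element indices out of range", call. = FALSE)
  fr <- vapply(thresholds, function(tau) sum(ar[vm > tau]) / sum(ar), 0)
  names(fr) <- as.character(thresholds)
  structure(list(mwam_whole = mwam(vm, ar),
                 mwam_crown = mwam(vm[crown_elements], ar[crown_elements]),
                 max_vm = max(vm),
                 frac_area_above = fr,
                 element_count = length(vm)),
            class = "stress_summary")
}

#' @export
print.stress_summary <- function(x, ...) {
  cat(sprintf("<stress_summary> MWAM %.4g MPa (crown %.4g), max %.4g MPa, %d elements\n",
              x$mwam_whole, x$mwam_crown, x$max_vm, x$element_count))
  if (length(x$frac_area_above))
    cat("  area fraction above:",
        paste(sprintf("%s MPa: %.3g", names(x$frac_area_above),
                      x$frac_area_above), collapse = "; "), "\n")
  invisible(x)
}
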