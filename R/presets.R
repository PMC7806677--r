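# Shipped preset tables for the five otodontid chronospecies at three tooth
# positions. The tooth geometry parameters and species metadata (ages, body
# sizes) are ILLUSTRATIVE: they emulate the published morphological gradient
# (older species with tall narrow crowns and prominent lateral cusplets,
# younger species with broad triangular crowns and no cusplets; crowns more
# recurved towards lateral/posterior positions) but are not digitized from
# fossil specimens. Both tables are plain data frames that users can edit.

#' Illustrative species metadata for the five otodontid chronospecies
#'
#' Chronostratigraphic ranges (Mya, older >= younger) and body sizes are
#' round illustrative values consistent with the group's Paleocene-Pliocene
#' succession and its trend towards gigantism; they are config inputs, not
#' measurements. `is_reference` marks the taxon whose anterior tooth anchors
#' the scaled-force analyses.
#'
#' @return A data frame with columns `taxon`, `older_mya`, `younger_mya`,
#'   `body_length_m`, `body_mass_kg`, `is_reference`.
#' @export
otodontid_species <- function() {
  data.frame(
    taxon = c("O. obliquus", "O. auriculatus", "O. angustidens",
              "O. chubutensis", "O. megalodon"),
    older_mya = c(60, 45, 34, 22, 15),
    younger_mya = c(48, 34, 22, 13, 2.6),
    body_length_m = c(6.5, 9, 11, 13.5, 16),
    body_mass_kg = c(2800, 7900, 14800, 28600, 48700),
    is_reference = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Illustrative tooth-shape presets: 5 species x 3 tooth positions
#'
#' Parametric [tooth_spec()] rows emulating otodontid heterodonty: anterior
#' teeth are tall and nearly symmetric, lateral teeth recurved (apex shifted
#' distally), posterior teeth short and broad; the four older species carry
#' lateral cusplets that shrink towards the youngest, cusplet-free
#' O. megalodon, while crowns broaden through time.
#'
#' @return A data frame with one row per (taxon, position) and the
#'   [tooth_spec()] parameter columns.
#' @export
otodontid_tooth_presets <- function() {
  sp <- otodontid_species()$taxon
  crown_h_ant <- c(45, 65, 80, 100, 120)
  w_ratio_ant <- c(0.55, 0.65, 0.70, 0.78, 0.85)
  cusp_h <- c(0.22, 0.18, 0.14, 0.10, 0)
  cusp_w <- c(0.22, 0.20, 0.16, 0.12, 0)
  apex_ant <- c(0.35, 0.40, 0.42, 0.48, 0.50)
  apex_lat <- c(0.18, 0.22, 0.25, 0.30, 0.35)
  apex_post <- c(0.25, 0.28, 0.30, 0.32, 0.35)

  rows <- list()
  for (i in seq_along(sp)) {
    H <- crown_h_ant[i]
    W <- w_ratio_ant[i] * H
    base <- list(
      anterior = list(h = H, w = W, apex = apex_ant[i], curv = 0.05),
      lateral = list(h = 0.72 * H, w = 0.90 * W, apex = apex_lat[i], curv = 0.08),
      posterior = list(h = 0.45 * H, w = 0.95 * W, apex = apex_post[i], curv = 0.04)
    )
    for (pos in names(base)) {
      g <- base[[pos]]
      root_w <- g$w * max(1.25, 1.15 + 3.4 * cusp_w[i])
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = sp[i], position = pos,
        crown_height = g$h, crown_basal_width = g$w,
        apex_offset_frac = g$apex, edge_curvature = g$curv,
        cusplet_height_frac = cusp_h[i], cusplet_width_frac = cusp_w[i],
        root_depth = 0.40 * g$h, root_width = root_w,
        label = paste(sp[i], pos, sep = "|"),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Build a tooth_spec from one preset table row
#'
#' @param row A single-row data frame with [tooth_spec()] parameter columns.
#' @return A `tooth_spec`.
#' @export
spec_from_row <- function(row) {
  tooth_spec(crown_height = row$crown_height,
             crown_basal_width = row$crown_basal_width,
             apex_offset_frac = row$apex_offset_frac,
             edge_curvature = row$edge_curvature,
             cusplet_height_frac = row$cusplet_height_frac,
             cusplet_width_frac = row$cusplet_width_frac,
             root_depth = row$root_depth,
             root_width = row$root_width,
             label = row$label)
}
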