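## Marker panel and phenotype definitions shared across modules.

#' The 7-channel lymphocyte panel
#'
#' Fixed channel order used everywhere in the package: a nuclear stain
#' (DAPI), five phenotyping markers (CD3, FOXP3, CD20, CD45RO, CD8), and a
#' tumor marker (e.g. pan-cytokeratin or a melanoma cocktail).
#'
#' @return Character vector of the 7 channel names, in order.
#' @export
panel_channels <- function() {
  c("DAPI", "CD3", "FOXP3", "CD20", "CD45RO", "CD8", "tumor")
}

#' The five phenotyping markers
#'
#' The panel channels that carry per-cell Likert decorations and pseudomarker
#' predictions (everything except DAPI and the tumor marker).
#'
#' @return Character vector of 5 marker names.
#' @export
phenotyping_markers <- function() {
  c("CD3", "FOXP3", "CD20", "CD45RO", "CD8")
}

#' Simulated phenotypes and their marker expression profiles
#'
#' Defines which markers each simulated cell type expresses and where the
#' signal localizes (membrane or nucleus). Every phenotype expresses DAPI in
#' the nucleus; "background" cells express no panel marker and stand in for
#' tumor cells, stromal cells, or other unlabeled structures.
#'
#' * `B` - B cell: CD20 on the membrane.
#' * `Th` - helper T cell: CD3 on the membrane.
#' * `CTL` - cytotoxic T lymphocyte: CD3 and CD8 on the membrane.
#' * `Treg` - regulatory T cell: CD3 on the membrane, FOXP3 in the nucleus.
#' * `Tmem` - memory-phenotype helper T cell: CD3 and CD45RO on the membrane.
#' * `background` - no panel marker.
#'
#' @return Named list; each element is a named character vector mapping
#'   marker name to `"membrane"` or `"nuclear"`. Markers not listed are
#'   absent. DAPI is implied nuclear for every phenotype.
#' @export
phenotype_profiles <- function() {
  list(
    B          = c(CD20 = "membrane"),
    Th         = c(CD3 = "membrane"),
    CTL        = c(CD3 = "membrane", CD8 = "membrane"),
    Treg       = c(CD3 = "membrane", FOXP3 = "nuclear"),
    Tmem       = c(CD3 = "membrane", CD45RO = "membrane"),
    background = character(0)
  )
}

#' Default phenotype frequencies for the simulator
#'
#' A lymphocyte-dense composition loosely modeled on secondary lymphoid
#' tissue: B cells and helper T cells dominate, with smaller cytotoxic,
#' regulatory and memory compartments and a fifth of unlabeled background
#' cells.
#'
#' @return Named numeric probability vector over [phenotype_profiles()]
#'   names, summing to 1.
#' @export
default_phenotype_freqs <- function() {
  c(B = 0.20, Th = 0.25, CTL = 0.15, Treg = 0.10, Tmem = 0.10,
    background = 0.20)
}

#' Phenotypes counted as lymphocytes
#'
#' @return Character vector of the four called lymphocyte phenotypes.
#' @export
lymphocyte_phenotypes <- function() c("B", "Th", "CTL", "Treg")

## Pixel size used throughout (um per pixel / voxel side).
PIXEL_SIZE_UM <- 0.5
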