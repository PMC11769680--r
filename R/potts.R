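## 3D Cellular Potts simulator: state construction, relaxation, membranes.

## Mean target cell volume in voxels for diameters ~ U(7, 10) um at
## 0.5 um voxels: E[(pi/6) d^3] / 0.125 with E[d^3] = (10^4 - 7^4) / 12.
MEAN_CELL_VOLUME_VOX <- (pi / 6) * ((10^4 - 7^4) / (4 * 3)) / (0.5^3)

#' Default Cellular Potts model parameters
#'
#' Adhesion energies `J` (cytoplasm-medium, cytoplasm-cytoplasm between
#' cells, nucleus-own-cytoplasm, nucleus-anything-else), volume-constraint
#' strength `lambda_v`, and simulation temperature `temp`. The strongly
#' penalized nucleus-other contacts keep each nucleus enclosed in its own
#' cytoplasm; the remaining values are standard two-compartment CPM choices
#' that keep cells compact at `temp = 20`.
#'
#' @return Named list of CPM parameters.
#' @export
cpm_params <- function() {
  list(J_cm = 20, J_cc = 40, J_nc = 10, J_nx = 200, lambda_v = 50, temp = 20)
}

#' Seed a Cellular Potts simulation volume with cells
#'
#' Places `N = floor(density_fraction * N_confluent)` single-voxel cytoplasm
#' seeds uniformly at random (without collision) in a cubic lattice of
#' `side_um / 0.5` voxels per side, where `N_confluent = lattice volume /
#' mean target cell volume`. Each cell draws a diameter uniformly from
#' 7-10 um; its total target volume is the sphere volume at that diameter,
#' split 60% cytoplasm / 40% nucleus. Phenotypes are drawn i.i.d. from
#' `phenotype_freqs`.
#'
#' @param side_um Side length of the cubic volume in um; must be a multiple
#'   of 0.5. Default 128 (a 256^3 voxel lattice).
#' @param density_fraction Fraction of confluence in (0, 1].
#' @param phenotype_freqs Named probability vector over
#'   [phenotype_profiles()] names; must sum to 1.
#' @param rng_seed Integer seed; the same seed reproduces the same layout.
#' @param params CPM parameters, see [cpm_params()].
#' @return A `potts_state` object (see Details).
#' @details A `potts_state` is a list with elements `lattice` (3D integer
#'   array of spin ids, 0 = medium), `spin_cell`, `spin_comp` (0 cytoplasm /
#'   1 nucleus), `spin_target`, `spin_vol` (per-spin volumes in voxels),
#'   `cell_table` (one row per cell: id, phenotype, spin ids, diameter,
#'   targets, `alive`), `params`, `side_um`, `n_mcs` (steps run so far) and
#'   `energy` (incrementally tracked Hamiltonian).
#' @export
seed_cells <- function(side_um = 128, density_fraction = 0.5,
                       phenotype_freqs = default_phenotype_freqs(),
                       rng_seed = 1L, params = cpm_params()) {
  if (density_fraction <= 0 || density_fraction > 1)
    stop("`density_fraction` must be in (0, 1]")
  side_vox <- side_um / PIXEL_SIZE_UM
  if (abs(side_vox - round(side_vox)) > 1e-9)
    stop("`side_um` must be a multiple of 0.5")
  side_vox <- as.integer(round(side_vox))
  if (abs(sum(phenotype_freqs) - 1) > 1e-6)
    stop("`phenotype_freqs` must sum to 1")
  if (!all(names(phenotype_freqs) %in% names(phenotype_profiles())))
    stop("unknown phenotype in `phenotype_freqs`")

  set.seed(rng_seed)
  nvox <- side_vox^3
  n_confluent <- nvox / MEAN_CELL_VOLUME_VOX
  n <- floor(density_fraction * n_confluent)
  if (n < 1) stop("volume too small to hold a single cell")
  if (n > nvox) stop("cannot place ", n, " cells in ", nvox, " voxels")

  lattice <- array(0L, dim = c(side_vox, side_vox, side_vox))
  pos <- sample.int(nvox, n) # collision-free by construction
  lattice[pos] <- seq_len(n)

  phen <- sample(names(phenotype_freqs), n, replace = TRUE,
                 prob = phenotype_freqs)
  diam <- runif(n, 7, 10)
  v_total <- (pi / 6) * diam^3 / (PIXEL_SIZE_UM^3)
  cell_table <- data.frame(
    cell_id = seq_len(n), phenotype = phen, cyto_spin = seq_len(n),
    nucleus_spin = NA_integer_, diameter_um = diam,
    target_total = v_total, target_cyto = 0.6 * v_total,
    target_nucleus = 0.4 * v_total, alive = TRUE,
    stringsAsFactors = FALSE)

  st <- structure(list(
    lattice = lattice,
    spin_cell = seq_len(n),
    spin_comp = rep(0L, n),
    spin_target = 0.6 * v_total,
    spin_vol = rep(1, n),
    cell_table = cell_table,
    params = params, side_um = side_um, n_mcs = 0L,
    rng_seed = rng_seed, energy = NA_real_), class = "potts_state")
  st$energy <- potts_energy(st)
  st
}

#' Total Hamiltonian of a Potts state, recomputed from scratch
#'
#' Adhesion energy over 6-connected neighbor pairs (lattice boundary faces
#' pair with medium) plus the elastic volume penalty
#' `lambda_v * (v_s - V_s)^2` per spin. Matches the incremental bookkeeping
#' in [mcs_step()] exactly.
#'
#' @param state A `potts_state`.
#' @return Scalar energy (dimensionless).
#' @export
potts_energy <- function(state) {
  p <- state$params
  .cpm_total_energy(state$lattice, state$spin_cell, state$spin_comp,
                    state$spin_target, state$spin_vol,
                    p$J_cm, p$J_cc, p$J_nc, p$J_nx, p$lambda_v)
}

#' Run Monte Carlo steps on a Potts state
#'
#' One Monte Carlo step (MCS) performs as many copy attempts as there are
#' lattice voxels. Each attempt picks a random voxel and a random Moore
#' (26-connected) neighbor as copy source and accepts with Metropolis
#' probability `min(1, exp(-dH / temp))`. Adhesion energy is counted over
#' 6-connectivity.
#'
#' @param state A `potts_state`.
#' @param n Number of MCS to run (default 1).
#' @return The updated `potts_state` (with `n_mcs` and tracked `energy`
#'   advanced).
#' @export
mcs_step <- function(state, n = 1L) {
  stopifnot(inherits(state, "potts_state"), n >= 0)
  if (n == 0 || nrow(state$cell_table) == 0) return(state)
  p <- state$params
  res <- .cpm_run(state$lattice, state$spin_cell, state$spin_comp,
                  state$spin_target, state$spin_vol,
                  p$J_cm, p$J_cc, p$J_nc, p$J_nx, p$lambda_v, p$temp,
                  as.integer(n))
  state$lattice <- res$lattice
  state$spin_vol <- res$spin_vol
  state$energy <- state$energy + res$delta_energy
  state$n_mcs <- state$n_mcs + as.integer(n)
  state
}

#' Relax seeded cells and place nuclei
#'
#' Runs 25 MCS so the single-voxel seeds circularize, places one nucleus
#' seed voxel at each surviving cell's interior voxel nearest its centroid,
#' then runs 50 further MCS so cells settle into their final two-compartment
#' shape (75 MCS total). Cells annihilated during relaxation (volume 0) are
#' dropped from the cell table with a warning.
#'
#' @param state A freshly seeded `potts_state` (see [seed_cells()]).
#' @param mcs_circularize,mcs_settle MCS counts for the two phases.
#' @return The relaxed `potts_state`.
#' @export
grow_and_nucleate <- function(state, mcs_circularize = 25L, mcs_settle = 50L) {
  stopifnot(inherits(state, "potts_state"))
  state <- mcs_step(state, mcs_circularize)

  dead <- which(state$spin_vol[state$cell_table$cyto_spin] <= 0)
  if (length(dead) > 0) {
    warning(length(dead), " cell(s) annihilated during relaxation; dropped")
    state$cell_table$alive[dead] <- FALSE
  }

  ## nucleus seed: interior voxel nearest the cell centroid
  dims <- dim(state$lattice)
  live <- state$lattice > 0L
  idx <- which(live)
  cells <- state$spin_cell[state$lattice[idx]]
  co <- arrayInd(idx, dims)
  n_spins_old <- length(state$spin_cell)
  alive_ids <- state$cell_table$cell_id[state$cell_table$alive]
  new_spin <- n_spins_old
  for (cid in alive_ids) {
    sel <- which(cells == cid)
    xyz <- co[sel, , drop = FALSE]
    ctr <- colMeans(xyz)
    d2 <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 + (xyz[, 3] - ctr[3])^2
    vox <- idx[sel[which.min(d2)]]
    new_spin <- new_spin + 1L
    row <- which(state$cell_table$cell_id == cid)
    cyto <- state$cell_table$cyto_spin[row]
    state$spin_cell <- c(state$spin_cell, cid)
    state$spin_comp <- c(state$spin_comp, 1L)
    state$spin_target <- c(state$spin_target,
                           state$cell_table$target_nucleus[row])
    state$spin_vol <- c(state$spin_vol, 1)
    state$spin_vol[cyto] <- state$spin_vol[cyto] - 1
    state$lattice[vox] <- new_spin
    state$cell_table$nucleus_spin[row] <- new_spin
  }
  ## lattice edited outside MCS: re-baseline the tracked energy
  state$energy <- potts_energy(state)
  state <- mcs_step(state, mcs_settle)

  dead2 <- state$cell_table$alive &
    state$spin_vol[state$cell_table$cyto_spin] +
      ifelse(is.na(state$cell_table$nucleus_spin), 0,
             state$spin_vol[pmax(state$cell_table$nucleus_spin, 1L)]) <= 0
  if (any(dead2)) {
    warning(sum(dead2), " cell(s) annihilated while settling; dropped")
    state$cell_table$alive[dead2] <- FALSE
  }
  state
}

#' Simulate a relaxed tissue volume in one call
#'
#' Convenience wrapper: [seed_cells()] followed by [grow_and_nucleate()].
#'
#' @inheritParams seed_cells
#' @return A relaxed `potts_state`.
#' @export
simulate_tissue <- function(side_um = 128, density_fraction = 0.5,
                            phenotype_freqs = default_phenotype_freqs(),
                            rng_seed = 1L, params = cpm_params()) {
  grow_and_nucleate(seed_cells(side_um, density_fraction, phenotype_freqs,
                               rng_seed, params))
}

#' Membrane voxels of one cell
#'
#' The outer layer of a cell's cytoplasm compartment: cytoplasm voxels with
#' at least one 6-connected neighbor (out-of-lattice neighbors count as
#' medium) that does not belong to the same cell.
#'
#' @param state A `potts_state`.
#' @param cell_id Cell id (row of `state$cell_table`).
#' @return Integer matrix with one row per membrane voxel and columns
#'   `x, y, z` (1-based lattice indices).
#' @export
find_membrane_voxels <- function(state, cell_id) {
  stopifnot(inherits(state, "potts_state"))
  if (!cell_id %in% state$cell_table$cell_id)
    stop("unknown cell_id: ", cell_id)
  memb <- membrane_mask(state)
  idx <- which(memb & cell_map(state) == cell_id)
  co <- arrayInd(idx, dim(state$lattice))
  colnames(co) <- c("x", "y", "z")
  co
}

## Full-lattice membrane mask (logical array).
membrane_mask <- function(state) {
  m <- .cpm_membrane(state$lattice, state$spin_cell, state$spin_comp)
  array(m, dim = dim(state$lattice))
}

## Per-voxel cell id (0 = medium).
cell_map <- function(state) {
  cm <- state$lattice
  nz <- cm > 0L
  cm[nz] <- state$spin_cell[cm[nz]]
  cm
}

## Per-voxel compartment: 0 medium is coded -1; else 0 cyto / 1 nucleus.
comp_map <- function(state) {
  cm <- state$lattice
  out <- array(-1L, dim = dim(cm))
  nz <- cm > 0L
  out[nz] <- state$spin_comp[cm[nz]]
  out
}

## Test/fixture constructor: build a potts_state from an explicit lattice of
## spin ids plus spin lookups. Not exported.
potts_state_from_lattice <- function(lattice, spin_cell, spin_comp,
                                     spin_target, phenotype = NULL,
                                     params = cpm_params(), side_um = NULL) {
  spin_vol <- as.numeric(tabulate(lattice[lattice > 0L],
                                  nbins = length(spin_cell)))
  cells <- sort(unique(spin_cell))
  cyto <- vapply(cells, function(cid)
    which(spin_cell == cid & spin_comp == 0L)[1], integer(1))
  nucl <- vapply(cells, function(cid) {
    w <- which(spin_cell == cid & spin_comp == 1L)
    if (length(w)) w[1] else NA_integer_
  }, integer(1))
  if (is.null(phenotype)) phenotype <- rep("Th", length(cells))
  n_cells <- length(cells)
  ct <- data.frame(cell_id = cells, phenotype = phenotype, cyto_spin = cyto,
                   nucleus_spin = nucl,
                   diameter_um = rep(NA_real_, n_cells),
                   target_total = rep(NA_real_, n_cells),
                   target_cyto = as.numeric(spin_target[cyto]),
                   target_nucleus = ifelse(is.na(nucl), NA_real_,
                                           spin_target[pmax(nucl, 1L)]),
                   alive = rep(TRUE, n_cells), stringsAsFactors = FALSE)
  st <- structure(list(lattice = lattice, spin_cell = as.integer(spin_cell),
                       spin_comp = as.integer(spin_comp),
                       spin_target = as.numeric(spin_target),
                       spin_vol = spin_vol, cell_table = ct, params = params,
                       side_um = side_um %||%
                         dim(lattice)[1] * PIXEL_SIZE_UM,
                       n_mcs = 0L, rng_seed = NA_integer_,
                       energy = NA_real_), class = "potts_state")
  st$energy <- potts_energy(st)
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.potts_state <- function(x, ...) {
  d <- dim(x$lattice)
  cat(sprintf(
    "Cellular Potts state: %d x %d x %d voxels (%.0f um side), %d cells (%d alive), %d MCS run\n",
    d[1], d[2], d[3], x$side_um, nrow(x$cell_table),
    sum(x$cell_table$alive), x$n_mcs))
  invisible(x)
}
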