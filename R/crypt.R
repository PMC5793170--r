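# 3D individual cell-based model of the small-intestinal crypt. Cells are
# soft spheres constrained to a test-tube surface (hemisphere + cylinder),
# proliferation pushes the population towards the orifice (passive conveyor
# belt), and lineages self-organize from a Wnt gradient plus Notch lateral
# signalling from secretory neighbours.

LINEAGES <- c("ISC", "PC", "GC", "EC")
L_ISC <- 1L; L_PC <- 2L; L_GC <- 3L; L_EC <- 4L

#' Crypt geometry, signalling, and mechanics configuration
#'
#' Defaults are calibrated so that self-organized homeostatic crypts hold on
#' average about 9 intestinal stem cells (ISC), 32 Paneth cells (PC),
#' 59 Goblet cells (GC) and 222 enterocytes (EC). Lengths are in units of one
#' cell diameter, times in hours.
#'
#' Lineage rule given local Wnt and Notch levels: high Wnt & high Notch = ISC;
#' high Wnt & low Notch = PC; low Wnt & high Notch = EC; low Wnt & low Notch =
#' GC. Notch is induced by secretory (PC/GC) contact neighbours. Paneth and
#' Goblet cells are terminally differentiated and postmitotic; Paneth cells
#' are anchored at the crypt bottom (reduced mobility) and replaced after a
#' finite lifetime. Commitment of an uncovered stem cell to the Paneth fate
#' proceeds at rate `p_commit` per hour, which sets (together with
#' `pc_lifetime_days` and `notch_radius`) the steady-state Paneth/stem ratio.
#'
#' @param radius crypt radius (cell diameters).
#' @param orifice axial height of the crypt orifice; cells above it undergo
#'   anoikis (the only cell-loss mechanism besides Paneth cell turnover).
#' @param wnt_lambda exponential decay length of the Wnt gradient.
#' @param wnt_thr Wnt specification threshold; `hysteresis` is the relative
#'   margin applied when re-evaluating committed cells (prevents flickering).
#' @param notch_radius contact radius within which secretory neighbours
#'   induce Notch.
#' @param notch_thr Notch specification threshold on the saturating signal
#'   `n / (n + 0.5)` of `n` secretory contact neighbours.
#' @param p_commit per-hour probability that a stem cell without secretory
#'   contact commits to the Paneth fate.
#' @param p_gc probability that a newborn cell outside the niche without
#'   secretory contact commits to the Goblet fate (otherwise it stays an
#'   enterocyte and may be re-evaluated later); sets the standing
#'   Goblet/enterocyte ratio together with `notch_radius`.
#' @param pc_lifetime_days mean Paneth cell lifetime (days); individual
#'   lifetimes are uniform within `pc_jitter` relative spread.
#' @param pc_jitter,pc_mobility Paneth lifetime jitter and mobility factor.
#' @param cycle_isc,cycle_isc_jitter ISC cell-cycle mean (h) and relative
#'   uniform jitter.
#' @param cycle_ec range (h) of the uniform enterocyte-progenitor cell cycle.
#' @param z_prolif_frac fraction of the crypt height below which enterocytes
#'   keep proliferating (transit-amplifying band).
#' @param ec_reversion logical; may enterocytes revert to ISC when pushed
#'   into the niche (high Wnt + secretory contact)?
#' @param mechanics list: `rest` (sphere rest distance), `r_adh` (adhesion
#'   cutoff), `k_rep`, `k_adh` (spring constants), `eta` (mobility x time
#'   step per substep), `substeps` (mechanics substeps per hour).
#' @param n_init number of seed cells before burn-in.
#' @return An object of class `crypt_config`.
#' @export
crypt_config <- function(radius = 4,
                         orifice = 10.4,
                         wnt_lambda = 2.1,
                         wnt_thr = 0.82,
                         hysteresis = 0.1,
                         notch_radius = 0.95,
                         notch_thr = 0.5,
                         p_commit = 0.8,
                         p_gc = 0.33,
                         pc_lifetime_days = 22,
                         pc_jitter = 0.2,
                         pc_mobility = 0.02,
                         cycle_isc = 24,
                         cycle_isc_jitter = 0.2,
                         cycle_ec = c(18, 24),
                         z_prolif_frac = 0.55,
                         ec_reversion = TRUE,
                         mechanics = list(),
                         n_init = 150L) {
  mech_def <- list(rest = 1, r_adh = 1.3, k_rep = 10, k_adh = 0.5,
                   eta = 0.08, substeps = 10L)
  mechanics <- modifyList(mech_def, mechanics)
  cfg <- structure(list(
    radius = radius, orifice = orifice,
    wnt_lambda = wnt_lambda, wnt_thr = wnt_thr, hysteresis = hysteresis,
    notch_radius = notch_radius, notch_thr = notch_thr,
    p_commit = p_commit, p_gc = p_gc,
    pc_lifetime_days = pc_lifetime_days, pc_jitter = pc_jitter,
    pc_mobility = pc_mobility,
    cycle_isc = cycle_isc, cycle_isc_jitter = cycle_isc_jitter,
    cycle_ec = cycle_ec, z_prolif_frac = z_prolif_frac,
    ec_reversion = ec_reversion,
    mechanics = mechanics, n_init = as.integer(n_init)
  ), class = "crypt_config")
  stopifnot(cfg$radius > 0, cfg$orifice > cfg$radius,
            cfg$wnt_lambda > 0, cfg$wnt_thr > 0, cfg$wnt_thr < 1,
            cfg$p_commit >= 0, cfg$p_commit <= 1)
  cfg
}

#' Wnt signal at a given crypt height
#'
#' The Wnt gradient is provided by stroma cells around the crypt base:
#' maximal (1) at the bottom, decaying exponentially with height, effectively
#' zero at the orifice. Deterministic and non-increasing in height.
#'
#' @param height axial height(s), 0 at the crypt bottom (vectorised).
#' @param cfg a [crypt_config()].
#' @return Wnt level(s) in \[0, 1\].
#' @export
wnt_at <- function(height, cfg) {
  if (any(height < 0) || any(height > cfg$orifice))
    stop("height outside the crypt geometry", call. = FALSE)
  exp(-height / cfg$wnt_lambda)
}

notch_level <- function(n_secretory) n_secretory / (n_secretory + 0.5)

#' Notch input of a cell from its contact neighbours
#'
#' Notch signalling is induced by secretory neighbours (Paneth and Goblet
#' cells): zero without secretory contact, above threshold with a single
#' secretory neighbour, and saturating in the secretory-neighbour count.
#'
#' @param cell a list with at least a `lineage` field (unused, kept for
#'   interface symmetry).
#' @param neighbors list of neighbour cells, each with a `lineage` field
#'   (`"PC"`, `"GC"`, `"ISC"`, `"EC"`).
#' @return Notch level in \[0, 1).
#' @export
notch_input <- function(cell, neighbors) {
  n_sec <- sum(vapply(neighbors, function(nb) nb$lineage %in% c("PC", "GC"),
                      logical(1)))
  notch_level(n_sec)
}

#' Lineage specification rule
#'
#' @param wnt,notch local signal levels in \[0, 1\].
#' @param cfg a [crypt_config()].
#' @return One of `"ISC"`, `"PC"`, `"EC"`, `"GC"`.
#' @export
specify_lineage <- function(wnt, notch, cfg) {
  stopifnot(wnt >= 0, wnt <= 1, notch >= 0, notch <= 1)
  if (wnt >= cfg$wnt_thr) {
    if (notch >= cfg$notch_thr) "ISC" else "PC"
  } else {
    if (notch >= cfg$notch_thr) "EC" else "GC"
  }
}

#' One mechanical relaxation step of a cell population
#'
#' Overdamped pairwise repulsion/adhesion constrained to the crypt surface.
#' Positions are updated in place and returned.
#'
#' @param pos n x 3 matrix of positions.
#' @param cfg a [crypt_config()].
#' @param mobility per-cell mobility factors (default 1).
#' @param hours number of hours to relax.
#' @return The updated position matrix.
#' @export
mechanics_step <- function(pos, cfg, mobility = rep(1, nrow(pos)), hours = 1) {
  m <- cfg$mechanics
  cpp_mechanics_step(pos, seq_len(nrow(pos)) - 1L, mobility, cfg$radius,
                     m$rest, m$r_adh, m$k_rep, m$k_adh, m$eta,
                     as.integer(m$substeps * hours))
  pos
}

# uniform random point on the test-tube surface with z <= zmax
random_surface_points <- function(n, cfg, zmax) {
  r <- cfg$radius
  area_hemi <- 2 * pi * r * min(zmax, r)      # spherical cap area 2*pi*r*h
  area_cyl <- 2 * pi * r * max(0, zmax - r)
  pts <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    theta <- runif(1, 0, 2 * pi)
    if (runif(1) < area_hemi / (area_hemi + area_cyl)) {
      z <- runif(1, 0, min(zmax, r))          # cap area uniform in z
      rho <- sqrt(pmax(0, r^2 - (r - z)^2))
      pts[i, ] <- c(rho * cos(theta), rho * sin(theta), z)
    } else {
      z <- runif(1, r, zmax)
      pts[i, ] <- c(r * cos(theta), r * sin(theta), z)
    }
  }
  pts
}

draw_cycle_length <- function(lineage, cfg, n = 1L) {
  if (lineage == L_ISC)
    runif(n, cfg$cycle_isc * (1 - cfg$cycle_isc_jitter),
          cfg$cycle_isc * (1 + cfg$cycle_isc_jitter))
  else if (lineage == L_EC)
    runif(n, cfg$cycle_ec[1], cfg$cycle_ec[2])
  else rep(Inf, n)
}

random_tangent <- function(pos_row, cfg) {
  # random unit vector tangent to the surface at pos_row
  if (pos_row[3] < cfg$radius) {
    nrm <- c(pos_row[1], pos_row[2], pos_row[3] - cfg$radius)
  } else {
    nrm <- c(pos_row[1], pos_row[2], 0)
  }
  nl <- sqrt(sum(nrm^2))
  nrm <- if (nl > 1e-9) nrm / nl else c(0, 0, -1)
  v <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, -1, 1))
  v <- v - sum(v * nrm) * nrm
  vl <- sqrt(sum(v^2))
  if (vl < 1e-6) return(random_tangent(pos_row, cfg))
  v / vl
}
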