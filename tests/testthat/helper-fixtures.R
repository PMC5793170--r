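# Shared fixtures and independent oracles for the test suite.

# brute-force fixed-point oracle: sign-change scan of the methylation change
# on a fine grid (independent of the uniroot-based implementation)
oracle_fixed_points <- function(d_novo_value, p, step = 1e-4) {
  m <- seq(0, 1, by = step)
  f <- d_novo_value * (1 - m) - (1 - d_main(m, p)) * m
  s <- sign(f)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots <- (m[idx] + m[idx + 1L]) / 2
  if (any(f == 0)) roots <- sort(c(roots, m[f == 0]))
  roots
}

# minimal synthetic crypt_run for analysis-level tests: one lineage of cells
# with prescribed per-gene methylation tracks
synthetic_run <- function(times, mcpg_tracks, lineage = "ISC",
                          m4 = NULL, m27 = NULL,
                          params = epigenome_params(), cfg = crypt_config()) {
  G <- nrow(mcpg_tracks)
  if (is.null(m4)) m4 <- matrix(0, G, length(times))
  if (is.null(m27)) m27 <- matrix(0.8, G, length(times))
  snaps <- lapply(seq_along(times), function(s) {
    list(time = times[s],
         cells = data.frame(id = 1L, clone = 1L, lineage = lineage, z = 0,
                            stringsAsFactors = FALSE),
         epi = list(cell_id = 1L,
                    m4 = m4[, s, drop = FALSE],
                    m27 = m27[, s, drop = FALSE],
                    mcpg = mcpg_tracks[, s, drop = FALSE],
                    tlev = matrix(0, G, 1)))
  })
  pedigree <- data.frame(id = 1L, parent = NA_integer_, birth = 0,
                         end = max(times), fate = "alive", clone = 1L,
                         lineage = lineage, stringsAsFactors = FALSE)
  structure(list(counts = data.frame(time = times, ISC = 1L, PC = 0L,
                                     GC = 0L, EC = 0L, total = 1L),
                 snapshots = snaps, pedigree = pedigree,
                 repair_log = data.frame(cell = integer(0), gene = integer(0),
                                         start = numeric(0), end = numeric(0)),
                 genome = NULL, net = NULL, params = params, cfg = cfg,
                 ddr = NULL, seed = 0, t_end = max(times)),
            class = "crypt_run")
}

# small, fast crypt configuration for unit tests and the scaled-down
# neutral-drift experiment (not the calibrated full-size default): the wider
# Notch radius keeps the miniature niche stably populated (N_ISC ~ 12)
tiny_crypt <- function(...) {
  crypt_config(radius = 2.5, orifice = 6.5, n_init = 60, wnt_thr = 0.65,
               notch_radius = 1.15, p_commit = 0.8, pc_lifetime_days = 12, ...)
}

# memoized runs shared between tests in a file
.run_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .run_cache)) assign(key, expr, envir = .run_cache)
  get(key, envir = .run_cache)
}
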