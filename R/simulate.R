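# Main simulation loop: multiscale crypt dynamics with optional genome /
# epigenome payload and optional DNA damage repair.
#
# Cell state lives in fixed-capacity slot arrays (an `alive` mask plus a
# free-slot stack); divisions claim free slots and removals release them, so
# the large per-nucleosome mark matrices are never copied during the run.

project_surface_r <- function(v, r) {
  x <- v[1]; y <- v[2]; z <- v[3]
  if (z < r) {
    d <- c(x, y, z - r)
    L <- sqrt(sum(d^2))
    if (L < 1e-12) return(c(0, 0, 0))
    p <- c(0, 0, r) + r * d / L
    if (p[3] <= r) return(p)
    x <- p[1]; y <- p[2]; z <- p[3]
  }
  rxy <- sqrt(x^2 + y^2)
  if (rxy < 1e-12) { x <- r; y <- 0 } else { x <- x * r / rxy; y <- y * r / rxy }
  c(x, y, max(z, r))
}

epi_cols <- function(G, slots) as.vector(outer(seq_len(G), (slots - 1L) * G, `+`))

new_crypt_state <- function(cfg, genome, params, ddr, streams, epi_init) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg; st$genome <- genome; st$params <- params; st$ddr <- ddr
  st$streams <- streams
  n0 <- cfg$n_init
  cap <- as.integer(ceiling(n0 * 3.2))
  st$cap <- cap
  st$alive <- c(rep(TRUE, n0), rep(FALSE, cap - n0))
  st$free <- rev(seq.int(n0 + 1L, cap))
  st$pos <- matrix(0, cap, 3)
  st$pos[1:n0, ] <- with_stream(streams, "crypt",
                                random_surface_points(n0, cfg, 0.85 * cfg$orifice))
  st$lineage <- integer(cap)
  wnt <- wnt_at(st$pos[1:n0, 3], cfg)
  st$lineage[1:n0] <- ifelse(wnt >= cfg$wnt_thr, L_ISC, L_EC)
  st$id <- integer(cap); st$id[1:n0] <- seq_len(n0)
  st$clone <- integer(cap); st$clone[1:n0] <- seq_len(n0)
  st$birth <- numeric(cap)
  st$prolif <- logical(cap); st$prolif[1:n0] <- TRUE
  st$cyc_len <- rep(Inf, cap)
  st$cyc_len[1:n0] <- with_stream(streams, "crypt", vapply(seq_len(n0),
    function(i) draw_cycle_length(st$lineage[i], cfg), numeric(1)))
  st$cyc_clock <- numeric(cap)
  st$cyc_clock[1:n0] <- with_stream(streams, "crypt",
                                    runif(n0, 0, st$cyc_len[1:n0]))
  st$pc_death <- rep(Inf, cap)
  st$mobility <- rep(1, cap)
  st$next_id <- n0 + 1L
  # pedigree (row index == cell id)
  st$ped_parent <- rep(NA_integer_, n0)
  st$ped_birth <- rep(0, n0)
  st$ped_end <- rep(NA_real_, n0)
  st$ped_fate <- rep(NA_character_, n0)
  st$ped_clone <- seq_len(n0)
  st$ped_lineage <- LINEAGES[st$lineage[1:n0]]
  if (!is.null(genome)) {
    G <- length(genome$genes)
    nn <- genome$n_nucleosomes
    st$G <- G
    st$net <- build_tf_network(genome)
    W <- matrix(0, G, G)
    if (nrow(st$net$edges))
      W[cbind(st$net$edges$from, st$net$edges$to)] <-
        st$net$edges$sign * st$net$edges$weight
    st$tW <- t(W)
    st$basal_u <- 30 * (st$net$basal - 0.5)
    st$k4 <- matrix(0L, nn, G * cap)
    st$k27 <- matrix(0L, nn, G * cap)
    live_cols <- epi_cols(G, 1:n0)
    if (epi_init$m4 > 0)
      st$k4[, live_cols] <- with_stream(streams, "histone",
        rbinom(nn * G * n0, 1L, epi_init$m4))
    if (epi_init$m27 > 0)
      st$k27[, live_cols] <- with_stream(streams, "histone",
        rbinom(nn * G * n0, 1L, epi_init$m27))
    st$mcpg <- matrix(0, G, cap); st$mcpg[, 1:n0] <- epi_init$m_cpg
    st$m4m <- matrix(0, G, cap)
    st$m4m[, 1:n0] <- colMeans(st$k4[, live_cols, drop = FALSE])
    st$m27m <- matrix(0, G, cap)
    st$m27m[, 1:n0] <- colMeans(st$k27[, live_cols, drop = FALSE])
    st$tlev <- matrix(0, G, cap)
    st$repair_start <- matrix(Inf, G, cap)
    st$repair_end <- matrix(-Inf, G, cap)
    st$damage_cycle <- matrix(FALSE, G, cap)
  } else {
    st$G <- 0L
  }
  st$repair_chunks <- list()
  st
}

grow_state <- function(st, extra = NULL) {
  old_cap <- st$cap
  add <- if (is.null(extra)) max(64L, old_cap %/% 4L) else as.integer(extra)
  cap <- old_cap + add
  pad <- function(x, fill) c(x, rep(fill, add))
  st$alive <- pad(st$alive, FALSE)
  st$lineage <- pad(st$lineage, 0L)
  st$id <- pad(st$id, 0L)
  st$clone <- pad(st$clone, 0L)
  st$birth <- pad(st$birth, 0)
  st$prolif <- pad(st$prolif, FALSE)
  st$cyc_len <- pad(st$cyc_len, Inf)
  st$cyc_clock <- pad(st$cyc_clock, 0)
  st$pc_death <- pad(st$pc_death, Inf)
  st$mobility <- pad(st$mobility, 1)
  st$pos <- rbind(st$pos, matrix(0, add, 3))
  if (st$G > 0L) {
    G <- st$G; nn <- nrow(st$k4)
    st$k4 <- cbind(st$k4, matrix(0L, nn, G * add))
    st$k27 <- cbind(st$k27, matrix(0L, nn, G * add))
    st$mcpg <- cbind(st$mcpg, matrix(0, G, add))
    st$m4m <- cbind(st$m4m, matrix(0, G, add))
    st$m27m <- cbind(st$m27m, matrix(0, G, add))
    st$tlev <- cbind(st$tlev, matrix(0, G, add))
    st$repair_start <- cbind(st$repair_start, matrix(Inf, G, add))
    st$repair_end <- cbind(st$repair_end, matrix(-Inf, G, add))
    st$damage_cycle <- cbind(st$damage_cycle, matrix(FALSE, G, add))
  }
  st$free <- c(st$free, rev(seq.int(old_cap + 1L, cap)))
  st$cap <- cap
  invisible(st)
}

alloc_slots <- function(st, k) {
  if (length(st$free) < k) grow_state(st)
  slots <- st$free[seq.int(length(st$free), by = -1L, length.out = k)]
  st$free <- st$free[seq_len(length(st$free) - k)]
  slots
}

kill_slots <- function(st, slots, t, fate) {
  if (!length(slots)) return(invisible(st))
  ids <- st$id[slots]
  st$ped_end[ids] <- t
  st$ped_fate[ids] <- fate
  st$ped_lineage[ids] <- LINEAGES[st$lineage[slots]]
  st$alive[slots] <- FALSE
  st$prolif[slots] <- FALSE
  st$cyc_len[slots] <- Inf
  st$pc_death[slots] <- Inf
  st$mobility[slots] <- 1
  if (st$G > 0L) {
    st$repair_start[, slots] <- Inf
    st$repair_end[, slots] <- -Inf
    st$damage_cycle[, slots] <- FALSE
  }
  st$free <- c(st$free, slots)
  invisible(st)
}

grow_pedigree <- function(st, ids, parent, t, clone, lineage) {
  need <- max(ids) - length(st$ped_birth)
  if (need > 0) {
    pad_n <- max(need, 1024L)
    st$ped_parent <- c(st$ped_parent, rep(NA_integer_, pad_n))
    st$ped_birth <- c(st$ped_birth, rep(NA_real_, pad_n))
    st$ped_end <- c(st$ped_end, rep(NA_real_, pad_n))
    st$ped_fate <- c(st$ped_fate, rep(NA_character_, pad_n))
    st$ped_clone <- c(st$ped_clone, rep(NA_integer_, pad_n))
    st$ped_lineage <- c(st$ped_lineage, rep(NA_character_, pad_n))
  }
  st$ped_parent[ids] <- parent
  st$ped_birth[ids] <- t
  st$ped_clone[ids] <- clone
  st$ped_lineage[ids] <- LINEAGES[lineage]
  invisible(st)
}

# Notch coverage of arbitrary points given the current population
covered_at <- function(st, pts) {
  sec_idx <- which(st$alive & (st$lineage == L_PC | st$lineage == L_GC))
  if (!length(sec_idx)) return(rep(FALSE, nrow(pts)))
  sp <- st$pos[sec_idx, , drop = FALSE]
  r2 <- st$cfg$notch_radius^2
  vapply(seq_len(nrow(pts)), function(i) {
    d2 <- (sp[, 1] - pts[i, 1])^2 + (sp[, 2] - pts[i, 2])^2 +
      (sp[, 3] - pts[i, 3])^2
    any(d2 <= r2)
  }, logical(1))
}

make_postmitotic <- function(st, idx, lineage_code, t) {
  st$lineage[idx] <- lineage_code
  st$prolif[idx] <- FALSE
  st$cyc_len[idx] <- Inf
  st$cyc_clock[idx] <- 0
  if (lineage_code == L_PC) {
    cfg <- st$cfg
    st$mobility[idx] <- cfg$pc_mobility
    st$pc_death[idx] <- t + with_stream(st$streams, "crypt",
      runif(length(idx), 24 * cfg$pc_lifetime_days * (1 - cfg$pc_jitter),
            24 * cfg$pc_lifetime_days * (1 + cfg$pc_jitter)))
  }
  invisible(st)
}

# Batched division of all mothers that complete their cycle this hour.
divide_cells <- function(st, dividers, t) {
  cfg <- st$cfg
  ddr <- st$ddr
  G <- st$G
  M <- length(dividers)
  n2 <- 2L * M
  # crypt-stream draws: placement directions, fate commitments, cycle
  # lengths, Paneth lifetimes (fixed draw counts keep the stream replayable)
  tang <- u2 <- ucyc <- upcl <- NULL
  with_stream(st$streams, "crypt", {
    tang <- t(vapply(dividers, function(i) random_tangent(st$pos[i, ], cfg),
                     numeric(3)))
    u2 <- runif(n2)
    ucyc <- runif(n2)
    upcl <- runif(n2)
  })
  dpos <- matrix(0, n2, 3)
  for (k in seq_len(M)) {
    dpos[2 * k - 1L, ] <- project_surface_r(st$pos[dividers[k], ] +
                                              0.25 * tang[k, ], cfg$radius)
    dpos[2 * k, ] <- project_surface_r(st$pos[dividers[k], ] -
                                         0.25 * tang[k, ], cfg$radius)
  }
  wnt <- wnt_at(pmin(dpos[, 3], cfg$orifice), cfg)
  cov <- covered_at(st, dpos)
  # uncovered newborns commit to the secretory fate with the configured
  # probabilities, otherwise they take the default (ISC/EC) fate and are
  # re-evaluated on later steps
  high_wnt <- wnt >= cfg$wnt_thr
  lin <- integer(n2)
  lin[high_wnt] <- ifelse(cov[high_wnt] | u2[high_wnt] >= cfg$p_commit,
                          L_ISC, L_PC)
  lin[!high_wnt] <- ifelse(cov[!high_wnt] | u2[!high_wnt] >= cfg$p_gc,
                           L_EC, L_GC)
  lens <- rep(Inf, n2)
  isc <- lin == L_ISC
  lens[isc] <- cfg$cycle_isc * (1 - cfg$cycle_isc_jitter) +
    ucyc[isc] * cfg$cycle_isc * 2 * cfg$cycle_isc_jitter
  ec <- lin == L_EC
  lens[ec] <- cfg$cycle_ec[1] + ucyc[ec] * diff(cfg$cycle_ec)
  pcd <- rep(Inf, n2)
  pc <- lin == L_PC
  pcd[pc] <- t + 24 * cfg$pc_lifetime_days *
    (1 - cfg$pc_jitter + upcl[pc] * 2 * cfg$pc_jitter)
  ids <- st$next_id + seq_len(n2) - 1L
  st$next_id <- st$next_id + n2
  parents <- rep(st$id[dividers], each = 2)
  clones <- rep(st$clone[dividers], each = 2)
  grow_pedigree(st, ids, parents, t, clones, lin)
  epi_res <- NULL
  if (G > 0L) {
    src_cols <- epi_cols(G, dividers)
    dn0 <- rep(st$params$d_novo_0, G * M)
    if (!is.null(ddr)) {
      under_repair <- as.vector(st$damage_cycle[, dividers, drop = FALSE])
      dn0[under_repair] <- ddr$d_novo_0_repair
    }
    epi_res <- with_stream(st$streams, "histone",
      cpp_divide_promoters(st$k4[, src_cols, drop = FALSE],
                           st$k27[, src_cols, drop = FALSE],
                           as.vector(st$mcpg[, dividers, drop = FALSE]), dn0,
                           st$params$d_main_0, st$params$e_m_0,
                           st$params$e_m_1, st$params$e_cpg4,
                           st$params$e_cpg27, G))
    mother_tlev <- st$tlev[, dividers, drop = FALSE]
  }
  kill_slots(st, dividers, t, "divided")
  slots <- alloc_slots(st, n2)
  st$alive[slots] <- TRUE
  st$pos[slots, ] <- dpos
  st$lineage[slots] <- lin
  st$clone[slots] <- clones
  st$id[slots] <- ids
  st$birth[slots] <- t
  st$prolif[slots] <- isc | ec
  st$cyc_len[slots] <- lens
  st$cyc_clock[slots] <- 0
  st$pc_death[slots] <- pcd
  st$mobility[slots] <- ifelse(pc, cfg$pc_mobility, 1)
  if (G > 0L) {
    dst_cols <- epi_cols(G, slots)
    st$k4[, dst_cols] <- epi_res$k4
    st$k27[, dst_cols] <- epi_res$k27
    st$mcpg[, slots] <- matrix(epi_res$m_cpg, G)
    st$m4m[, slots] <- matrix(epi_res$m4, G)
    st$m27m[, slots] <- matrix(epi_res$m27, G)
    st$tlev[, slots] <- mother_tlev[, rep(seq_len(M), each = 2)]
    # repair matrices of the claimed slots were reset on release
    if (!is.null(ddr)) {
      ud <- us <- NULL
      with_stream(st$streams, "damage", {
        ud <- runif(G * n2)
        us <- runif(G * n2)
      })
      elig <- rep(isc | ec, each = G)
      dmg <- ud < ddr$p_damage & elig
      if (any(dmg)) {
        smax <- pmax(0, ifelse(is.finite(lens), lens, 0) -
                       ddr$repair_duration)
        start_all <- t + us * rep(smax, each = G)
        rs <- matrix(Inf, G, n2); re <- matrix(-Inf, G, n2)
        dc <- matrix(FALSE, G, n2)
        rs[dmg] <- start_all[dmg]
        re[dmg] <- start_all[dmg] + ddr$repair_duration
        dc[dmg] <- TRUE
        st$repair_start[, slots] <- rs
        st$repair_end[, slots] <- re
        st$damage_cycle[, slots] <- dc
        chunk <- list(cell = rep(ids, each = G)[dmg],
                      gene = rep(seq_len(G), n2)[dmg],
                      start = start_all[dmg],
                      end = start_all[dmg] + ddr$repair_duration)
        st$repair_chunks[[length(st$repair_chunks) + 1L]] <- chunk
      }
    }
  }
  invisible(st)
}

respecify <- function(st, t) {
  cfg <- st$cfg
  act <- which(st$alive)
  sec <- as.integer(st$lineage[act] == L_PC | st$lineage[act] == L_GC)
  nsec <- cpp_contact_counts(st$pos, act - 1L, sec, cfg$notch_radius)
  covered <- notch_level(nsec) >= cfg$notch_thr
  wnt <- wnt_at(pmin(st$pos[act, 3], cfg$orifice), cfg)
  thr_lo <- cfg$wnt_thr * (1 - cfg$hysteresis)
  thr_hi <- cfg$wnt_thr * (1 + cfg$hysteresis)
  is_isc <- st$lineage[act] == L_ISC
  # stem cells leaving the niche differentiate
  out <- act[is_isc & wnt < thr_lo]
  if (length(out)) {
    out_cov <- covered[match(out, act)]
    to_ec <- out[out_cov]
    to_gc <- out[!out_cov]
    if (length(to_ec)) {
      st$lineage[to_ec] <- L_EC
      st$cyc_len[to_ec] <- with_stream(st$streams, "crypt",
        draw_cycle_length(L_EC, cfg, length(to_ec)))
      st$cyc_clock[to_ec] <- pmin(st$cyc_clock[to_ec], st$cyc_len[to_ec] - 1)
    }
    if (length(to_gc)) make_postmitotic(st, to_gc, L_GC, t)
  }
  # stem cells without secretory contact commit to the Paneth fate
  cand <- act[is_isc & wnt >= thr_lo & !covered]
  if (length(cand)) {
    go <- cand[with_stream(st$streams, "crypt",
                           runif(length(cand))) < cfg$p_commit]
    if (length(go)) make_postmitotic(st, go, L_PC, t)
  }
  # enterocytes pushed back into the niche may revert
  if (cfg$ec_reversion) {
    back <- act[st$lineage[act] == L_EC & wnt >= thr_hi & covered]
    if (length(back)) {
      st$lineage[back] <- L_ISC
      st$prolif[back] <- TRUE
      st$cyc_len[back] <- with_stream(st$streams, "crypt",
        draw_cycle_length(L_ISC, cfg, length(back)))
      st$cyc_clock[back] <- pmin(st$cyc_clock[back], st$cyc_len[back] - 1)
    }
  }
  invisible(st)
}

epigenome_hour <- function(st, t) {
  p <- st$params
  act <- which(st$alive)
  cols <- epi_cols(st$G, act)
  m4a <- st$m4m[, act, drop = FALSE]
  m27a <- st$m27m[, act, drop = FALSE]
  drive <- plogis(st$basal_u + st$tW %*% st$tlev[, act, drop = FALSE])
  tla <- drive * (1 + p$hmt$beta4 * m4a) / (1 + p$hmt$beta27 * m27a)
  st$tlev[, act] <- tla
  cde4 <- rep(p$cde4, length(cols))
  if (!is.null(st$ddr)) {
    rs <- st$repair_start[, act, drop = FALSE]
    re <- st$repair_end[, act, drop = FALSE]
    active_rep <- as.vector(rs <= t & t < re)
    cde4[active_rep] <- p$cde4 * st$ddr$cde4_repair_factor
  }
  res <- with_stream(st$streams, "histone",
    cpp_histone_step(st$k4, st$k27, cols - 1L, as.vector(tla),
                     as.vector(st$mcpg[, act, drop = FALSE]),
                     cde4, p$cde27, p$hmt$q4_max, p$hmt$q27_max,
                     p$hmt$kt4, p$hmt$kt27, p$hmt$hill,
                     p$hmt$coop_basal, p$hmt$w4, p$hmt$w27))
  st$m4m[, act] <- matrix(res$m4, st$G)
  st$m27m[, act] <- matrix(res$m27, st$G)
  invisible(st)
}

take_snapshot <- function(st, t) {
  act <- which(st$alive)
  snap <- list(
    time = t,
    cells = data.frame(id = st$id[act], clone = st$clone[act],
                       lineage = LINEAGES[st$lineage[act]],
                       z = st$pos[act, 3], stringsAsFactors = FALSE)
  )
  if (st$G > 0L)
    snap$epi <- list(cell_id = st$id[act],
                     m4 = st$m4m[, act, drop = FALSE],
                     m27 = st$m27m[, act, drop = FALSE],
                     mcpg = st$mcpg[, act, drop = FALSE],
                     tlev = st$tlev[, act, drop = FALSE])
  snap
}

#' Simulate an intestinal crypt
#'
#' Runs the multiscale crypt model for `t_end_days` simulated days with a
#' fixed 1 h time step. Histone and transcription states are updated every
#' step; DNA methylation changes only at cell division. When `genome` is
#' `NULL` the epigenome payload is skipped entirely; crypt lineage dynamics
#' are bit-identical with the payload enabled or disabled under the same seed
#' because genome, crypt, histone and damage random draws use independent
#' streams.
#'
#' @param cfg a [crypt_config()].
#' @param genome optional [generate_genome()] object carried by every cell.
#' @param params an [epigenome_params()]; `n_nucleosomes` is taken from the
#'   genome when one is supplied.
#' @param ddr optional [damage_config()]; `NULL` simulates damage-free aging.
#' @param t_end_days simulated time (days).
#' @param seed master seed; all stream seeds derive from it.
#' @param snapshot_every_hours cadence of full state snapshots (0 disables).
#' @param epi_init list with initial mark probabilities `m4`, `m27` and the
#'   initial DNA-methylation level `m_cpg` (default all zero).
#' @param relabel_clones_at_days optional time at which every cell receives a
#'   fresh, distinct clone label (for neutral-drift experiments).
#' @param progress print a progress line every simulated week.
#' @return An object of class `crypt_run`: list with `counts` (hourly lineage
#'   counts), `snapshots`, `pedigree`, `repair_log`, `genome`, `net`,
#'   `params`, `cfg`, `ddr`, `seed`, `t_end`.
#' @export
simulate_crypt <- function(cfg = crypt_config(), genome = NULL,
                           params = epigenome_params(), ddr = NULL,
                           t_end_days = 90, seed = 1,
                           snapshot_every_hours = 24,
                           epi_init = list(m4 = 0, m27 = 0, m_cpg = 0),
                           relabel_clones_at_days = NULL,
                           progress = FALSE) {
  stopifnot(inherits(cfg, "crypt_config"), inherits(params, "epigenome_params"))
  if (!is.null(ddr)) stopifnot(inherits(ddr, "damage_config"))
  if (!is.null(genome))
    params$n_nucleosomes <- genome$n_nucleosomes
  epi_init <- modifyList(list(m4 = 0, m27 = 0, m_cpg = 0), epi_init)
  streams <- rng_streams(seed)
  st <- new_crypt_state(cfg, genome, params, ddr, streams, epi_init)
  t_end <- round(t_end_days * 24)
  relabel_at <- if (is.null(relabel_clones_at_days)) -1 else
    round(relabel_clones_at_days * 24)
  counts <- matrix(0L, t_end + 1L, 6L)
  colnames(counts) <- c("time", "ISC", "PC", "GC", "EC", "total")
  snapshots <- list()
  record_counts <- function(row, t) {
    tab <- tabulate(st$lineage[st$alive], nbins = 4L)
    counts[row, ] <<- c(t, tab, sum(tab))
  }
  record_counts(1L, 0)
  if (snapshot_every_hours > 0) snapshots[[1L]] <- take_snapshot(st, 0)
  mech <- cfg$mechanics
  for (t in seq_len(t_end)) {
    if (t == relabel_at) {
      act <- which(st$alive)
      st$clone[act] <- seq_along(act)
      st$ped_clone[st$id[act]] <- st$clone[act]
    }
    act <- which(st$alive)
    cpp_mechanics_step(st$pos, act - 1L, st$mobility, cfg$radius,
                       mech$rest, mech$r_adh, mech$k_rep, mech$k_adh,
                       mech$eta, as.integer(mech$substeps))
    # anoikis at the orifice
    act <- which(st$alive)
    kill_slots(st, act[st$pos[act, 3] > cfg$orifice], t, "anoikis")
    # Paneth cell turnover
    kill_slots(st, which(st$alive & st$pc_death <= t), t, "pc_death")
    # cell cycle and division
    act <- which(st$alive)
    st$cyc_clock[act] <- st$cyc_clock[act] + 1
    dividers <- act[st$prolif[act] & st$cyc_clock[act] >= st$cyc_len[act]]
    if (length(dividers)) {
      z_band <- cfg$z_prolif_frac * cfg$orifice
      halt <- dividers[st$lineage[dividers] == L_EC &
                         st$pos[dividers, 3] > z_band]
      if (length(halt)) {
        st$prolif[halt] <- FALSE
        st$cyc_len[halt] <- Inf
        dividers <- setdiff(dividers, halt)
      }
      if (length(dividers)) divide_cells(st, dividers, t)
    }
    if (!any(st$prolif[st$alive]))
      stop("crypt extinction: no proliferative cells left at t = ", t,
           " h", call. = FALSE)
    respecify(st, t)
    if (st$G > 0L) epigenome_hour(st, t)
    record_counts(t + 1L, t)
    if (snapshot_every_hours > 0 && t %% snapshot_every_hours == 0)
      snapshots[[length(snapshots) + 1L]] <- take_snapshot(st, t)
    if (progress && t %% 168 == 0) {
      tab <- tabulate(st$lineage[st$alive], nbins = 4L)
      message(sprintf("day %5.1f: %d cells (%d ISC, %d PC, %d GC, %d EC)",
                      t / 24, sum(tab), tab[1], tab[2], tab[3], tab[4]))
    }
  }
  # close pedigree records of surviving cells
  act <- which(st$alive)
  st$ped_end[st$id[act]] <- t_end
  st$ped_fate[st$id[act]] <- "alive"
  st$ped_lineage[st$id[act]] <- LINEAGES[st$lineage[act]]
  used <- which(!is.na(st$ped_birth))
  pedigree <- data.frame(
    id = used,
    parent = st$ped_parent[used],
    birth = st$ped_birth[used],
    end = st$ped_end[used],
    fate = st$ped_fate[used],
    clone = st$ped_clone[used],
    lineage = st$ped_lineage[used],
    stringsAsFactors = FALSE)
  repair_log <- if (length(st$repair_chunks)) {
    data.frame(
      cell = unlist(lapply(st$repair_chunks, `[[`, "cell")),
      gene = unlist(lapply(st$repair_chunks, `[[`, "gene")),
      start = unlist(lapply(st$repair_chunks, `[[`, "start")),
      end = unlist(lapply(st$repair_chunks, `[[`, "end")))
  } else {
    data.frame(cell = integer(0), gene = integer(0),
               start = numeric(0), end = numeric(0))
  }
  structure(list(
    counts = as.data.frame(counts),
    snapshots = snapshots,
    pedigree = pedigree,
    repair_log = repair_log,
    genome = genome, net = if (st$G > 0L) st$net else NULL,
    params = params, cfg = cfg, ddr = ddr,
    seed = seed, t_end = t_end
  ), class = "crypt_run")
}

#' @export
print.crypt_run <- function(x, ...) {
  n <- nrow(x$counts)
  cat(sprintf("crypt_run: %.0f days, final %d cells (%d ISC, %d PC, %d GC, %d EC)\n",
              x$t_end / 24, x$counts$total[n], x$counts$ISC[n],
              x$counts$PC[n], x$counts$GC[n], x$counts$EC[n]))
  cat(sprintf("  %d snapshots, %d pedigree records, %d repair events\n",
              length(x$snapshots), nrow(x$pedigree), nrow(x$repair_log)))
  invisible(x)
}

#' Time-averaged lineage composition of a crypt run
#'
#' @param run a `crypt_run`.
#' @param from_day average from this day onward (burn-in excluded).
#' @param to_day optional upper bound (days).
#' @return Named numeric vector of mean ISC/PC/GC/EC/total counts.
#' @export
composition_summary <- function(run, from_day = 30, to_day = Inf) {
  k <- run$counts$time >= from_day * 24 & run$counts$time <= to_day * 24
  colMeans(run$counts[k, c("ISC", "PC", "GC", "EC", "total")])
}
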