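# Post-processing of crypt runs: lineage-averaged epigenome tracks, histone
# state histograms, methylation switch detection, clonal fixation statistics,
# Newick phylogeny export, and multi-crypt aggregation.

#' Lineage-averaged epigenome tracks
#'
#' Per-gene time series of the arithmetic mean of `m4`, `m27`, `m_cpg` and
#' the transcription level over all cells of one lineage, one value per
#' snapshot. Time points at which the lineage is empty are `NA`.
#'
#' @param run a `crypt_run` with epigenome snapshots.
#' @param lineage one of `"ISC"`, `"PC"`, `"GC"`, `"EC"`.
#' @return A list with `time` (hours) and genes x time matrices `m4`, `m27`,
#'   `mcpg`, `tlev`, plus `n_cells` per time point.
#' @export
lineage_average_tracks <- function(run, lineage) {
  if (!lineage %in% LINEAGES) stop("unknown lineage: ", lineage, call. = FALSE)
  snaps <- Filter(function(s) !is.null(s$epi), run$snapshots)
  if (!length(snaps)) stop("run carries no epigenome snapshots", call. = FALSE)
  G <- nrow(snaps[[1]]$epi$mcpg)
  nt <- length(snaps)
  out <- list(time = vapply(snaps, `[[`, numeric(1), "time"),
              m4 = matrix(NA_real_, G, nt), m27 = matrix(NA_real_, G, nt),
              mcpg = matrix(NA_real_, G, nt), tlev = matrix(NA_real_, G, nt),
              n_cells = integer(nt))
  for (s in seq_len(nt)) {
    sel <- snaps[[s]]$cells$lineage == lineage
    out$n_cells[s] <- sum(sel)
    if (!any(sel)) next
    for (f in c("m4", "m27", "mcpg", "tlev"))
      out[[f]][, s] <- rowMeans(snaps[[s]]$epi[[f]][, sel, drop = FALSE])
  }
  out
}

#' Histone modification state histogram
#'
#' Normalized 2D frequency map of the `(m4, m27)` states of one gene over all
#' cells of a lineage within a time window. Bins have width
#' `1 / n_nucleosomes` (the resolution of the modified fractions).
#'
#' @param run a `crypt_run` with epigenome snapshots.
#' @param gene_index gene to tabulate.
#' @param lineage lineage selector.
#' @param time_window numeric length-2 vector (hours).
#' @return A `(n_nucleosomes + 1)` square matrix with `dimnames` giving the
#'   m4 (rows) and m27 (columns) levels; entries sum to 1.
#' @export
histone_state_histogram <- function(run, gene_index, lineage, time_window) {
  if (!lineage %in% LINEAGES) stop("unknown lineage: ", lineage, call. = FALSE)
  nn <- run$params$n_nucleosomes
  h <- matrix(0, nn + 1L, nn + 1L,
              dimnames = list(m4 = sprintf("%.3f", (0:nn) / nn),
                              m27 = sprintf("%.3f", (0:nn) / nn)))
  total <- 0L
  for (s in run$snapshots) {
    if (is.null(s$epi) || s$time < time_window[1] || s$time > time_window[2])
      next
    sel <- s$cells$lineage == lineage
    if (!any(sel)) next
    i4 <- round(s$epi$m4[gene_index, sel] * nn) + 1L
    i27 <- round(s$epi$m27[gene_index, sel] * nn) + 1L
    for (k in seq_along(i4)) h[i4[k], i27[k]] <- h[i4[k], i27[k]] + 1
    total <- total + length(i4)
  }
  if (total == 0L)
    stop("no cells of lineage ", lineage, " in the requested window",
         call. = FALSE)
  h / total
}

# Per-gene basin threshold: unstable fixed point of the methylation equation
# at the gene's prevailing histone state; 0.5 when mono-stable.
gene_basin_thresholds <- function(run, control_window = NULL) {
  snaps <- Filter(function(s) !is.null(s$epi), run$snapshots)
  if (!length(snaps)) stop("run carries no epigenome snapshots", call. = FALSE)
  if (!is.null(control_window))
    snaps <- Filter(function(s) s$time >= control_window[1] &&
                      s$time <= control_window[2], snaps)
  G <- nrow(snaps[[1]]$epi$mcpg)
  m4bar <- rowMeans(vapply(snaps, function(s) rowMeans(s$epi$m4),
                           numeric(G)))
  m27bar <- rowMeans(vapply(snaps, function(s) rowMeans(s$epi$m27),
                            numeric(G)))
  vapply(seq_len(G), function(g) {
    dn <- d_novo(m4bar[g], m27bar[g], run$params)
    fp <- fixed_points(dn, run$params)
    un <- fp$root[!fp$stable]
    if (length(un) == 1L) un else 0.5
  }, numeric(1))
}

descendants_alive_at <- function(children_of, pedigree, root_id, t) {
  # ids of root_id or its descendants whose lifetime covers time t
  out <- integer(0)
  stack <- root_id
  while (length(stack)) {
    cur <- stack[length(stack)]
    stack <- stack[-length(stack)]
    b <- pedigree$birth[cur]
    e <- pedigree$end[cur]
    if (!is.na(e) && e >= t && b <= t) out <- c(out, cur)
    if (b <= t) {
      kids <- children_of[[cur]]
      if (!is.null(kids)) stack <- c(stack, kids)
    }
  }
  out
}

#' Detect low-to-high DNA-methylation switches
#'
#' A switch is recorded when the methylation level of a (cell, gene) crosses
#' from the low into the high basin — classified against the unstable fixed
#' point of the methylation equation at the gene's prevailing histone state
#' (fallback 0.5 when mono-stable) — and the cell or its descendants remain
#' in the high basin for at least `k_cycles` cell cycles. Each switch is
#' linked to the most recent repair event on the switching cell or its
#' ancestors within a lookback window, and flagged `fixed` when all ISCs
#' carry the high state at some later snapshot.
#'
#' @param run a `crypt_run` with epigenome snapshots.
#' @param k_cycles persistence requirement (cell cycles; default 5).
#' @param lookback_cycles repair-attribution window (cell cycles).
#' @param thresholds optional per-gene basin thresholds (computed from the
#'   run itself by default; pass thresholds from a damage-free control run
#'   when available).
#' @return A data.frame of switch events: `cell_id`, `gene_index`, `time`,
#'   `repair_cell`, `repair_time`, `persisted`, `fixed`.
#' @export
detect_switches <- function(run, k_cycles = 5, lookback_cycles = 5,
                            thresholds = NULL) {
  snaps <- Filter(function(s) !is.null(s$epi), run$snapshots)
  if (!length(snaps)) stop("run carries no epigenome snapshots", call. = FALSE)
  if (is.null(thresholds)) thresholds <- gene_basin_thresholds(run)
  G <- nrow(snaps[[1]]$epi$mcpg)
  cycle_h <- run$cfg$cycle_isc
  persist_h <- k_cycles * cycle_h
  lookback_h <- lookback_cycles * cycle_h
  ped <- run$pedigree
  children_of <- split(ped$id, factor(ped$parent, levels = ped$id))
  empty <- data.frame(cell_id = integer(0), gene_index = integer(0),
                      time = numeric(0), repair_cell = integer(0),
                      repair_time = numeric(0), persisted = logical(0),
                      fixed = logical(0))
  # high/low basin state per snapshot
  high <- lapply(snaps, function(s) s$epi$mcpg > thresholds)
  times <- vapply(snaps, `[[`, numeric(1), "time")
  id_of <- lapply(snaps, function(s) s$epi$cell_id)
  res <- empty
  for (s in 2:length(snaps)) {
    prev_ids <- id_of[[s - 1L]]
    prev_high <- high[[s - 1L]]
    for (ci in seq_along(id_of[[s]])) {
      cid <- id_of[[s]][ci]
      # locate the cell (or its most recent ancestor) in the previous snapshot
      anc <- cid
      prev_ci <- match(anc, prev_ids)
      while (is.na(prev_ci) && !is.na(anc)) {
        anc <- ped$parent[anc]
        if (is.na(anc)) break
        prev_ci <- match(anc, prev_ids)
      }
      if (is.na(prev_ci)) next
      crossed <- which(high[[s]][, ci] & !prev_high[, prev_ci])
      for (g in crossed) {
        t_cross <- times[s]
        # persistence: some descendant still in the high basin k cycles later
        t_check <- t_cross + persist_h
        persisted <- FALSE
        s_chk <- which(times >= t_check)[1]
        if (!is.na(s_chk)) {
          alive <- descendants_alive_at(children_of, ped, cid, times[s_chk])
          cols <- match(alive, id_of[[s_chk]])
          cols <- cols[!is.na(cols)]
          persisted <- length(cols) > 0 && any(high[[s_chk]][g, cols])
        }
        # attribute to the most recent repair event on this lineage line
        rep_cell <- NA_integer_; rep_time <- NA_real_
        if (nrow(run$repair_log)) {
          line <- cid
          a <- cid
          while (!is.na(a)) { a <- ped$parent[a]; if (!is.na(a)) line <- c(line, a) }
          ev <- run$repair_log[run$repair_log$gene == g &
                                 run$repair_log$cell %in% line &
                                 run$repair_log$end <= t_cross &
                                 run$repair_log$end >= t_cross - lookback_h, ,
                               drop = FALSE]
          if (nrow(ev)) {
            k <- which.max(ev$end)
            rep_cell <- ev$cell[k]; rep_time <- ev$end[k]
          }
        }
        # fixation: all ISCs high for this gene at some later snapshot
        fixed <- FALSE
        for (s2 in seq(s, length(snaps))) {
          isc <- snaps[[s2]]$cells$lineage == "ISC"
          if (any(isc) && all(high[[s2]][g, isc])) { fixed <- TRUE; break }
        }
        res <- rbind(res, data.frame(
          cell_id = cid, gene_index = g, time = t_cross,
          repair_cell = rep_cell, repair_time = rep_time,
          persisted = persisted, fixed = fixed))
      }
    }
  }
  res
}

#' Clonal fixation statistics of methylation switches
#'
#' Estimates the probability that a low-to-high methylation switch occurring
#' in a stem cell becomes fixed in the crypt (all ISCs carry the high state),
#' with a binomial confidence interval. Under neutral drift roughly one out
#' of `N_ISC` stem-cell events fixes, where `N_ISC` is the time-averaged stem
#' cell count.
#'
#' @param switches a data.frame from [detect_switches()] (persistent switches
#'   are used).
#' @param run the `crypt_run` the switches came from.
#' @param from_day burn-in excluded from the `N_ISC` average.
#' @return A list with `n_isc`, `events`, `fixed`, `p_fix`, `ci` (95%
#'   binomial), `defined` (FALSE when no events were observed).
#' @export
fixation_statistics <- function(switches, run, from_day = 30) {
  n_isc <- composition_summary(run, from_day)[["ISC"]]
  # stem-cell events: the switching cell was an ISC when it crossed
  is_isc <- vapply(seq_len(nrow(switches)), function(i) {
    t <- switches$time[i]
    s <- Filter(function(x) x$time == t, run$snapshots)
    if (!length(s)) return(FALSE)
    k <- match(switches$cell_id[i], s[[1]]$cells$id)
    !is.na(k) && s[[1]]$cells$lineage[k] == "ISC"
  }, logical(1))
  ev <- switches[switches$persisted & is_isc, , drop = FALSE]
  if (!nrow(ev))
    return(list(n_isc = n_isc, events = 0L, fixed = 0L, p_fix = NA_real_,
                ci = c(NA_real_, NA_real_), defined = FALSE))
  bt <- binom.test(sum(ev$fixed), nrow(ev))
  list(n_isc = n_isc, events = nrow(ev), fixed = sum(ev$fixed),
       p_fix = sum(ev$fixed) / nrow(ev), ci = as.numeric(bt$conf.int),
       defined = TRUE)
}

#' Winning clone of the stem cell pool
#'
#' Returns the clone label once the ISC pool has become monoclonal
#' (`NA` if it never does within the run).
#'
#' @param run a `crypt_run`.
#' @param from_day search from this day onward.
#' @return Clone id or `NA`.
#' @export
winner_clone <- function(run, from_day = 0) {
  for (s in run$snapshots) {
    if (s$time < from_day * 24) next
    cl <- s$cells$clone[s$cells$lineage == "ISC"]
    if (length(cl) && length(unique(cl)) == 1L) return(cl[1])
  }
  NA_integer_
}

#' Export a cell pedigree as Newick trees
#'
#' Edges represent cells, vertices mitotic events; edge lengths are the
#' individual cell lifetimes (hours). One tree per founder cell (cells
#' without a recorded parent). Node labels are `c<id>`. Optional per-cell
#' annotation strings are emitted as Newick comments `[&...]` after the
#' label.
#'
#' @param pedigree a pedigree data.frame (`id`, `parent`, `birth`, `end`).
#' @param annotations optional character vector named by cell id.
#' @return Named character vector of Newick strings (one per founder).
#' @export
to_newick <- function(pedigree, annotations = NULL) {
  if (anyNA(pedigree$end))
    stop("pedigree has open-ended records", call. = FALSE)
  orphan <- !is.na(pedigree$parent) & !(pedigree$parent %in% pedigree$id)
  if (any(orphan))
    stop("orphaned record: cell ", pedigree$id[orphan][1], call. = FALSE)
  if (!any(is.na(pedigree$parent)))
    stop("pedigree has no founder cell", call. = FALSE)
  kids <- split(pedigree$id, factor(pedigree$parent, levels = pedigree$id))
  rows <- setNames(seq_len(nrow(pedigree)), pedigree$id)
  seen <- new.env(parent = emptyenv())
  fmt <- function(id) {
    key <- as.character(id)
    if (!is.na(rows[key]) && exists(key, envir = seen))
      stop("cyclic pedigree at cell ", id, call. = FALSE)
    assign(key, TRUE, envir = seen)
    r <- rows[[key]]
    if (is.null(r) || is.na(r)) stop("orphaned record: cell ", id, call. = FALSE)
    len <- pedigree$end[r] - pedigree$birth[r]
    ann <- if (!is.null(annotations) && key %in% names(annotations))
      sprintf("[&%s]", annotations[[key]]) else ""
    ch <- kids[[key]]
    if (is.null(ch) || !length(ch))
      sprintf("c%d%s:%g", id, ann, len)
    else
      sprintf("(%s)c%d%s:%g",
              paste(vapply(ch, fmt, character(1)), collapse = ","),
              id, ann, len)
  }
  founders <- pedigree$id[is.na(pedigree$parent)]
  setNames(vapply(founders, function(f) paste0(fmt(f), ";"), character(1)),
           paste0("c", founders))
}

#' Companion annotation table for exported phylogenies
#'
#' @param run a `crypt_run`.
#' @param gene_index optional gene whose final methylation level per cell is
#'   included (from the last snapshot covering the cell).
#' @return A data.frame keyed by cell id with fate, lineage, clone, number of
#'   repair events, and optionally `m_cpg`.
#' @export
newick_annotation_table <- function(run, gene_index = NULL) {
  ped <- run$pedigree
  out <- ped[, c("id", "fate", "lineage", "clone", "birth", "end")]
  if (nrow(run$repair_log)) {
    tab <- table(factor(run$repair_log$cell, levels = ped$id))
    out$n_repairs <- as.integer(tab)
  } else out$n_repairs <- 0L
  if (!is.null(gene_index)) {
    m <- rep(NA_real_, nrow(out))
    for (s in run$snapshots) {
      if (is.null(s$epi)) next
      k <- match(s$epi$cell_id, ped$id)
      m[k] <- s$epi$mcpg[gene_index, ]
    }
    out$m_cpg <- m
  }
  out
}

#' Population-average methylation across crypts
#'
#' Cell-weighted mean DNA methylation per gene and time across several runs,
#' emulating array-style measurements over many crypts: switch-like changes
#' in single crypts appear as long-term drifts because different crypts
#' switch at different times. Also reports the average over the ten most
#' methylated genes.
#'
#' @param runs list of >= 2 `crypt_run` objects with epigenome snapshots.
#' @return A list with `time`, `mcpg` (genes x time), `top10` (time series of
#'   the mean over the ten most methylated genes), `n_top`.
#' @export
multi_crypt_average <- function(runs) {
  stopifnot(length(runs) >= 2L)
  per_run <- lapply(runs, function(r) {
    snaps <- Filter(function(s) !is.null(s$epi), r$snapshots)
    list(time = vapply(snaps, `[[`, numeric(1), "time"),
         mean = vapply(snaps, function(s) rowMeans(s$epi$mcpg),
                       numeric(nrow(snaps[[1]]$epi$mcpg))),
         n = vapply(snaps, function(s) ncol(s$epi$mcpg), integer(1)))
  })
  grids <- lapply(per_run, `[[`, "time")
  common <- Reduce(intersect, grids)
  if (!length(common)) stop("runs share no snapshot times", call. = FALSE)
  if (!all(vapply(grids, function(g) identical(g, grids[[1]]), logical(1)))) {
    warning("snapshot grids differ; resampling to the common (coarsest) grid")
  }
  G <- nrow(per_run[[1]]$mean)
  num <- matrix(0, G, length(common))
  den <- numeric(length(common))
  for (pr in per_run) {
    k <- match(common, pr$time)
    num <- num + pr$mean[, k, drop = FALSE] * rep(pr$n[k], each = G)
    den <- den + pr$n[k]
  }
  avg <- num / rep(den, each = G)
  n_top <- min(10L, G)
  top <- order(avg[, ncol(avg)], decreasing = TRUE)[seq_len(n_top)]
  list(time = common, mcpg = avg,
       top10 = colMeans(avg[top, , drop = FALSE]), n_top = n_top)
}

#' Mann-Kendall trend test
#'
#' Kendall rank correlation of a series against time (normal approximation
#' through [stats::cor.test()]). Used to test lineage-mean methylation tracks
#' for stationarity after equilibration.
#'
#' @param x numeric series (NAs dropped).
#' @param times optional time points.
#' @return The p-value of the two-sided trend test.
#' @export
mk_trend_test <- function(x, times = seq_along(x)) {
  ok <- !is.na(x)
  x <- x[ok]; times <- times[ok]
  if (length(x) < 4L || length(unique(x)) == 1L) return(1)
  suppressWarnings(cor.test(times, x, method = "kendall"))$p.value
}
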