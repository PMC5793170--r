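# DNA damage and damage repair: random per-gene damage per cell cycle, and
# the transient epigenetic modulation applied while a gene is under repair.

#' DNA damage / repair configuration
#'
#' DNA damage occurs randomly with a constant probability per gene and cell
#' division. Damage is always fully repaired within a fixed time inside the
#' cell cycle in which it occurs; the cycle is not extended. While a gene is
#' under repair, its H3K4me3 demethylation constant `cde4` is reduced
#' (repression of the H3K4me3 demethylase by damage-induced fumarate) and the
#' maximum de novo DNA-methylation probability is raised to `d_novo_0_repair`
#' (loss of the demethylase's protective function). The elevated de novo
#' probability is carried into the methylation update at the division that
#' ends the damaged cycle, since DNMTs act only subsequent to division.
#'
#' @param p_damage probability of damage per gene per cell division
#'   (default 0.02, i.e. two repair events per 100 genes, cell and cycle).
#' @param repair_duration fixed repair time within the cycle (hours); must
#'   not exceed the shortest cell cycle.
#' @param cde4_repair_factor multiplicative reduction of `cde4` during
#'   repair, in (0, 1).
#' @param d_novo_0_repair maximum de novo methylation probability during
#'   repair (default 0.3; transitions to the high-methylation state vanish at
#'   0.2).
#' @return An object of class `damage_config`.
#' @export
damage_config <- function(p_damage = 0.02,
                          repair_duration = 12,
                          cde4_repair_factor = 0.1,
                          d_novo_0_repair = 0.3) {
  cfg <- structure(list(
    p_damage = p_damage,
    repair_duration = repair_duration,
    cde4_repair_factor = cde4_repair_factor,
    d_novo_0_repair = d_novo_0_repair
  ), class = "damage_config")
  stopifnot(cfg$p_damage >= 0, cfg$p_damage <= 1,
            cfg$repair_duration > 0,
            cfg$cde4_repair_factor > 0, cfg$cde4_repair_factor < 1,
            cfg$d_novo_0_repair > 0, cfg$d_novo_0_repair <= 1)
  cfg
}

#' Draw damage events for one cell cycle
#'
#' Called once per cell at the start of its cycle. Each of the `n_genes`
#' genes is damaged independently with probability `p_damage`; each event is
#' scheduled to start uniformly within the cycle such that repair completes
#' before the cycle ends.
#'
#' @param cell_id cell identifier attached to the events.
#' @param n_genes number of genes in the genome.
#' @param cycle_length length of the current cell cycle (hours).
#' @param cfg a [damage_config()].
#' @param t0 absolute start time of the cycle (hours).
#' @return A data.frame of repair events: `cell_id`, `gene_index`,
#'   `start_time`, `end_time`, `resolved`.
#' @export
draw_damage <- function(cell_id, n_genes, cycle_length, cfg, t0 = 0) {
  stopifnot(inherits(cfg, "damage_config"),
            cfg$repair_duration <= cycle_length)
  hit <- which(runif(n_genes) < cfg$p_damage)
  if (!length(hit))
    return(data.frame(cell_id = integer(0), gene_index = integer(0),
                      start_time = numeric(0), end_time = numeric(0),
                      resolved = logical(0)))
  smax <- cycle_length - cfg$repair_duration
  start <- t0 + runif(length(hit), 0, smax)
  data.frame(cell_id = cell_id, gene_index = hit,
             start_time = start, end_time = start + cfg$repair_duration,
             resolved = FALSE)
}

#' Effective epigenome parameters of a gene at a given time
#'
#' If an unresolved repair event of `cell_id` covers `gene_index` at time
#' `t`, returns the base parameters with `cde4` reduced and `d_novo_0`
#' elevated per the damage configuration; otherwise returns the base
#' parameters unchanged. The modulation is strictly per gene and per cell and
#' reverts exactly at the event's end time (the elevated de novo probability
#' additionally applies at the division ending the damaged cycle, which the
#' simulator handles through its per-cycle damage flags).
#'
#' @param gene_index,cell_id gene and cell to query.
#' @param t time (hours).
#' @param base an [epigenome_params()].
#' @param events a repair-event data.frame as from [draw_damage()].
#' @param cfg a [damage_config()].
#' @return An `epigenome_params` object.
#' @export
effective_params <- function(gene_index, cell_id, t, base, events, cfg) {
  stopifnot(inherits(base, "epigenome_params"), inherits(cfg, "damage_config"))
  if (nrow(events)) {
    act <- events$cell_id == cell_id & events$gene_index == gene_index &
      events$start_time <= t & t < events$end_time & !events$resolved
    if (any(act)) {
      base$cde4 <- base$cde4 * cfg$cde4_repair_factor
      base$d_novo_0 <- cfg$d_novo_0_repair
    }
  }
  base
}
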