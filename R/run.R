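# Reproducible experiment driver: validated run configurations, named
# experiments, output tables, and test fixtures.

EXPERIMENTS <- c("bistability", "crypt-homeostasis", "aging-nodamage",
                 "aging-ddr", "analyze")

#' Experiment run configuration
#'
#' A validated, JSON-serializable description of one experiment. Every
#' stochastic component draws from one of four independent streams (genome,
#' crypt, histone, damage) whose seeds derive from the single `seed` via a
#' fixed splitter, so identical configurations yield identical outputs.
#' Time is expressed in days here and in hours internally (1 h step).
#'
#' @param experiment one of `r paste(EXPERIMENTS, collapse=", ")`.
#' @param seed master seed.
#' @param t_end_days simulated days.
#' @param n_genes genome size (0 disables the genome payload).
#' @param snapshot_every_hours snapshot cadence.
#' @param epigenome,crypt,damage named lists of overrides for
#'   [epigenome_params()], [crypt_config()], [damage_config()]; `damage =
#'   NULL` disables DDR.
#' @param epi_init initial epigenome state (`m4`, `m27`, `m_cpg`).
#' @param genome_lengths gene region lengths passed to [generate_genome()].
#' @param out_dir output directory (created on demand).
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment,
                       seed = 1L,
                       t_end_days = 300,
                       n_genes = 100L,
                       snapshot_every_hours = 24,
                       epigenome = list(),
                       crypt = list(),
                       damage = NULL,
                       epi_init = list(m4 = 0, m27 = 0, m_cpg = 0),
                       genome_lengths = c(l_reg = 4000L, l_pro = 500L,
                                          l_cod = 900L),
                       out_dir = tempfile("cryptdrift-run-")) {
  if (!experiment %in% EXPERIMENTS)
    stop("config error at $experiment: must be one of ",
         paste(EXPERIMENTS, collapse = ", "), call. = FALSE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("config error at $seed: single integer required", call. = FALSE)
  if (t_end_days <= 0) stop("config error at $t_end_days: must be > 0",
                            call. = FALSE)
  structure(list(
    experiment = experiment, seed = as.integer(seed),
    t_end_days = t_end_days, n_genes = as.integer(n_genes),
    snapshot_every_hours = snapshot_every_hours,
    epigenome = epigenome, crypt = crypt, damage = damage,
    epi_init = epi_init,
    genome_lengths = as.list(genome_lengths),
    out_dir = out_dir
  ), class = "run_config")
}

#' Read / write a run configuration (JSON)
#' @param cfg a [run_config()].
#' @param path file path.
#' @return `write_run_config` returns `path`; `read_run_config` the config.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[setdiff(names(x), character(0))])
}

build_components <- function(cfg) {
  list(
    epi = do.call(epigenome_params, cfg$epigenome),
    crypt = do.call(crypt_config, cfg$crypt),
    ddr = if (is.null(cfg$damage)) NULL else do.call(damage_config, cfg$damage)
  )
}

tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tracks <- function(run, dir) {
  for (lin in LINEAGES) {
    tr <- lineage_average_tracks(run, lin)
    G <- nrow(tr$mcpg)
    long <- data.frame(
      time = rep(tr$time, each = G),
      gene = rep(seq_len(G), length(tr$time)),
      m4 = as.vector(tr$m4), m27 = as.vector(tr$m27),
      mcpg = as.vector(tr$mcpg), tlev = as.vector(tr$tlev))
    tsv(long, file.path(dir, sprintf("tracks_%s.tsv", lin)))
  }
}

#' Run a named experiment end-to-end
#'
#' Executes the experiment described by a [run_config()] and writes its
#' outputs (a copy of the configuration, tab-separated result tables, and a
#' log) to the configured output directory. Identical configurations and
#' seeds produce identical outputs.
#'
#' @param cfg a [run_config()].
#' @param keep_run return the in-memory run object(s) as well?
#' @return The output directory (invisibly), with attribute `"run"` holding
#'   the run object when `keep_run = TRUE`.
#' @export
run_experiment <- function(cfg, keep_run = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(cfg$out_dir, "config.json"))
  comp <- build_components(cfg)
  run <- NULL
  if (cfg$experiment == "bistability") {
    dn <- seq(0.002, 0.5, by = 0.002)
    tab <- do.call(rbind, lapply(dn, function(d) {
      fp <- fixed_points(d, comp$epi)
      data.frame(d_novo = d, root = fp$root, stable = fp$stable)
    }))
    tsv(tab, file.path(cfg$out_dir, "dnovo_roots.tsv"))
    bb <- bistability_boundary(comp$epi, 51L)
    tsv(bb$grid, file.path(cfg$out_dir, "bistability_grid.tsv"))
    tsv(bb$boundary, file.path(cfg$out_dir, "bistability_boundary.tsv"))
  } else if (cfg$experiment == "crypt-homeostasis") {
    run <- simulate_crypt(comp$crypt, genome = NULL, params = comp$epi,
                          ddr = NULL, t_end_days = cfg$t_end_days,
                          seed = cfg$seed,
                          snapshot_every_hours = cfg$snapshot_every_hours)
    tsv(run$counts, file.path(cfg$out_dir, "counts.tsv"))
    comp_tab <- t(composition_summary(run))
    tsv(as.data.frame(comp_tab), file.path(cfg$out_dir, "composition.tsv"))
    tsv(run$pedigree, file.path(cfg$out_dir, "pedigree.tsv"))
  } else if (cfg$experiment %in% c("aging-nodamage", "aging-ddr")) {
    streams <- rng_streams(cfg$seed)
    genome <- with_stream(streams, "genome",
                          generate_genome(cfg$n_genes, cfg$genome_lengths))
    ddr <- if (cfg$experiment == "aging-ddr") {
      if (is.null(comp$ddr)) damage_config() else comp$ddr
    } else NULL
    run <- simulate_crypt(comp$crypt, genome = genome, params = comp$epi,
                          ddr = ddr, t_end_days = cfg$t_end_days,
                          seed = cfg$seed,
                          snapshot_every_hours = cfg$snapshot_every_hours,
                          epi_init = cfg$epi_init)
    tsv(run$counts, file.path(cfg$out_dir, "counts.tsv"))
    tsv(run$pedigree, file.path(cfg$out_dir, "pedigree.tsv"))
    write_tracks(run, cfg$out_dir)
    write_genome_fasta(genome, file.path(cfg$out_dir, "genome.fasta"))
    write_tf_edges(run$net, file.path(cfg$out_dir, "tf_edges.tsv"))
    if (!is.null(ddr)) {
      tsv(run$repair_log, file.path(cfg$out_dir, "repair_events.tsv"))
      sw <- detect_switches(run)
      tsv(sw, file.path(cfg$out_dir, "switches.tsv"))
      nwk <- to_newick(run$pedigree)
      writeLines(nwk, file.path(cfg$out_dir, "phylogeny.nwk"))
      tsv(newick_annotation_table(run),
          file.path(cfg$out_dir, "phylogeny_annotations.tsv"))
    }
  } else if (cfg$experiment == "analyze") {
    analyze_run_dir(cfg$out_dir)
  }
  out <- invisible(cfg$out_dir)
  if (keep_run && !is.null(run)) attr(out, "run") <- run
  out
}

#' Summarize a stored run directory
#'
#' Recomputes composition statistics and per-gene methylation summaries from
#' the tab-separated tables written by [run_experiment()].
#'
#' @param dir a run directory.
#' @return A list of summary tables (also written to `summary_*.tsv`).
#' @export
analyze_run_dir <- function(dir) {
  out <- list()
  cf <- file.path(dir, "counts.tsv")
  if (file.exists(cf)) {
    counts <- read.table(cf, header = TRUE, sep = "\t")
    k <- counts$time >= max(counts$time) * 0.25
    out$composition <- colMeans(counts[k, c("ISC", "PC", "GC", "EC", "total")])
    tsv(as.data.frame(t(out$composition)), file.path(dir, "summary_composition.tsv"))
  }
  tf <- file.path(dir, "tracks_ISC.tsv")
  if (file.exists(tf)) {
    tr <- read.table(tf, header = TRUE, sep = "\t")
    last <- tr[tr$time == max(tr$time), ]
    out$final_mcpg <- last[order(-last$mcpg), c("gene", "m4", "m27", "mcpg", "tlev")]
    tsv(out$final_mcpg, file.path(dir, "summary_final_mcpg.tsv"))
  }
  invisible(out)
}

#' Generate small, seedable test fixtures
#'
#' @param kind one of `"tiny-genome"`, `"planted-motif-genome"`,
#'   `"pre-equilibrated-crypt"`, `"synthetic-tracks"`.
#' @param seed RNG seed.
#' @param dir output directory.
#' @return Paths of the written fixture files (invisibly); the constructed
#'   object as attribute `"object"`.
#' @export
generate_fixtures <- function(kind = c("tiny-genome", "planted-motif-genome",
                                       "pre-equilibrated-crypt",
                                       "synthetic-tracks"),
                              seed = 1L, dir = tempfile("fixture-")) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- NULL
  paths <- character(0)
  if (kind == "tiny-genome") {
    set.seed(seed)
    obj <- generate_genome(3L, c(l_reg = 400L, l_pro = 60L, l_cod = 40L))
    paths <- c(write_genome_fasta(obj, file.path(dir, "tiny_genome.fasta")),
               write_tf_edges(build_tf_network(obj),
                              file.path(dir, "tiny_edges.tsv")))
  } else if (kind == "planted-motif-genome") {
    set.seed(seed)
    obj <- generate_genome(2L, c(l_reg = 400L, l_pro = 60L, l_cod = 40L))
    # plant exactly one occurrence of gene 1's word in gene 2's regulatory
    # region and scrub accidental matches of either word elsewhere
    w1 <- tf_recognition(obj$genes[[1]]$cod_seq)$word
    scrub <- function(s, w) {
      while (grepl(w, s, fixed = TRUE)) {
        at <- regexpr(w, s, fixed = TRUE)
        substr(s, at, at) <- setdiff(BASES, substr(s, at, at))[1]
      }
      s
    }
    w2 <- tf_recognition(obj$genes[[2]]$cod_seq)$word
    for (i in 1:2) for (w in c(w1, w2))
      obj$genes[[i]]$reg_seq <- scrub(obj$genes[[i]]$reg_seq, w)
    substr(obj$genes[[2]]$reg_seq, 101, 108) <- w1
    paths <- write_genome_fasta(obj, file.path(dir, "planted_genome.fasta"))
  } else if (kind == "pre-equilibrated-crypt") {
    obj <- simulate_crypt(crypt_config(), genome = NULL, t_end_days = 40,
                          seed = seed, snapshot_every_hours = 0)
    final <- data.frame(
      time = obj$t_end,
      lineage = c("ISC", "PC", "GC", "EC"),
      count = as.integer(obj$counts[nrow(obj$counts), c("ISC", "PC", "GC", "EC")]))
    paths <- tsv(final, file.path(dir, "equilibrated_composition.tsv"))
  } else if (kind == "synthetic-tracks") {
    t <- seq(0, 200, by = 1)
    obj <- data.frame(
      time = t,
      step = ifelse(t >= 100, 0.9, 0.1),
      ramp = 0.1 + 0.8 * pmin(1, t / 200),
      flat = rep(0.1, length(t)))
    paths <- tsv(obj, file.path(dir, "synthetic_tracks.tsv"))
  }
  out <- invisible(paths)
  attr(out, "object") <- obj
  out
}
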