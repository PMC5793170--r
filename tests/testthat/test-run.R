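# Experiment driver: config validation and round-trip, experiment outputs,
# fixtures, CLI plumbing.

test_that("run configurations validate and round-trip through JSON", {
  cfg <- run_config("aging-ddr", seed = 5L, t_end_days = 10, n_genes = 12L,
                    damage = list(p_damage = 0.05),
                    crypt = list(radius = 2.5))
  path <- tempfile(fileext = ".json")
  write_run_config(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$seed, cfg$seed)
  expect_equal(cfg2$damage$p_damage, 0.05)
  expect_equal(cfg2$crypt$radius, 2.5)
  expect_equal(cfg2$experiment, "aging-ddr")
  expect_error(run_config("no-such-experiment"), "experiment")
  expect_error(run_config("bistability", seed = NA), "seed")
  expect_error(run_config("bistability", t_end_days = -1), "t_end_days")
  unlink(path)
})

test_that("the bistability experiment writes the advertised tables", {
  dir <- tempfile("bist-")
  run_experiment(run_config("bistability", out_dir = dir))
  roots <- read.table(file.path(dir, "dnovo_roots.tsv"), header = TRUE)
  expect_true(all(c("d_novo", "root", "stable") %in% names(roots)))
  grid <- read.table(file.path(dir, "bistability_grid.tsv"), header = TRUE)
  expect_true(all(grid$class %in% c("mono_low", "bistable", "mono_high")))
  expect_true(file.exists(file.path(dir, "config.json")))
  unlink(dir, recursive = TRUE)
})

test_that("aging experiments run end-to-end and are seed-deterministic", {
  base <- list(seed = 9L, t_end_days = 4, n_genes = 4L,
               crypt = list(radius = 2.5, orifice = 6.5, n_init = 60L,
                            wnt_thr = 0.6, p_commit = 0.2,
                            pc_lifetime_days = 12),
               genome_lengths = c(l_reg = 400L, l_pro = 60L, l_cod = 40L))
  d1 <- do.call(run_config, c(list("aging-nodamage", out_dir = tempfile()), base))
  d2 <- do.call(run_config, c(list("aging-nodamage", out_dir = tempfile()), base))
  o1 <- run_experiment(d1, keep_run = FALSE)
  o2 <- run_experiment(d2, keep_run = FALSE)
  c1 <- readLines(file.path(o1, "counts.tsv"))
  expect_identical(c1, readLines(file.path(o2, "counts.tsv")))
  expect_identical(readLines(file.path(o1, "tracks_ISC.tsv")),
                   readLines(file.path(o2, "tracks_ISC.tsv")))
  expect_true(file.exists(file.path(o1, "genome.fasta")))
  dd <- do.call(run_config, c(list("aging-ddr", out_dir = tempfile(),
                                   damage = list(p_damage = 0.05)), base))
  od <- run_experiment(dd, keep_run = TRUE)
  expect_true(file.exists(file.path(od, "repair_events.tsv")))
  expect_true(file.exists(file.path(od, "switches.tsv")))
  expect_true(file.exists(file.path(od, "phylogeny.nwk")))
  run <- attr(od, "run")
  expect_s3_class(run, "crypt_run")
  # analyze recomputes composition from the stored tables
  sm <- analyze_run_dir(o1)
  expect_true("composition" %in% names(sm))
  for (d in c(o1, o2, od)) unlink(d, recursive = TRUE)
})

test_that("fixture generator produces the advertised kinds", {
  fx <- generate_fixtures("tiny-genome", seed = 2)
  expect_true(all(file.exists(fx)))
  g <- attr(fx, "object")
  expect_length(g$genes, 3L)
  tr <- generate_fixtures("synthetic-tracks", seed = 2)
  tab <- read.table(tr, header = TRUE)
  expect_true(all(c("step", "ramp", "flat") %in% names(tab)))
  expect_equal(unique(tab$flat), 0.1)
  unlink(dirname(fx[1]), recursive = TRUE)
  unlink(dirname(tr[1]), recursive = TRUE)
})

test_that("RNG streams are independent and reproducible", {
  s1 <- rng_streams(123)
  s2 <- rng_streams(123)
  a1 <- with_stream(s1, "crypt", runif(5))
  # drawing on one stream does not advance another
  h_before <- with_stream(s2, "histone", runif(5))
  a2 <- with_stream(s2, "crypt", runif(5))
  expect_identical(a1, a2)
  s3 <- rng_streams(123)
  expect_identical(h_before, with_stream(s3, "histone", runif(5)))
  # different streams give different draws
  expect_false(identical(a1, h_before))
})

test_that("the CLI parses flags and drives an experiment", {
  out <- tempfile("cli-")
  expect_invisible(cryptdrift_cli(c("bistability", "--out", out, "--seed", "3")))
  expect_true(file.exists(file.path(out, "dnovo_roots.tsv")))
  expect_output(cryptdrift_cli("--help"), "usage")
  expect_error(cryptdrift_cli(c("bistability", "--seed")), "missing value")
  unlink(out, recursive = TRUE)
})
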