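# Crypt model: signalling fields, lineage rule, mechanics, proliferation,
# homeostasis and pedigree accounting.

test_that("Wnt gradient is maximal at the bottom and vanishes at the orifice", {
  cfg <- crypt_config()
  expect_equal(wnt_at(0, cfg), 1)
  expect_lt(wnt_at(cfg$orifice, cfg), 0.02)
  h <- seq(0, cfg$orifice, length.out = 200)
  expect_true(all(diff(wnt_at(h, cfg)) <= 0))
  expect_error(wnt_at(cfg$orifice + 1, cfg), "geometry")
  expect_error(wnt_at(-0.1, cfg), "geometry")
})

test_that("Notch requires secretory contact and saturates", {
  cfg <- crypt_config()
  mk <- function(lin) list(lineage = lin)
  expect_equal(notch_input(mk("ISC"), list()), 0)
  expect_equal(notch_input(mk("ISC"), list(mk("EC"), mk("ISC"))), 0)
  one_pc <- notch_input(mk("ISC"), list(mk("PC")))
  expect_gt(one_pc, cfg$notch_thr) # a single Paneth neighbour suffices
  three <- notch_input(mk("ISC"), list(mk("PC"), mk("GC"), mk("PC")))
  expect_gte(three, one_pc)
  expect_lt(three, 1)
})

test_that("lineage rule table matches the Wnt/Notch logic", {
  cfg <- crypt_config()
  expect_equal(specify_lineage(1, 1, cfg), "ISC")
  expect_equal(specify_lineage(1, 0, cfg), "PC")
  expect_equal(specify_lineage(0, 1, cfg), "EC")
  expect_equal(specify_lineage(0, 0, cfg), "GC")
})

test_that("mechanics separates overlapping cells and fixes a single cell", {
  # fine relaxation steps expose the force law: distance grows monotonically
  # to the rest length (production runs use coarser, calibrated steps)
  cfg <- crypt_config(mechanics = list(eta = 0.01))
  pos <- matrix(c(cfg$radius, 0, 6, cfg$radius * cos(0.1),
                  cfg$radius * sin(0.1), 6), 2, 3, byrow = TRUE)
  d0 <- sqrt(sum((pos[1, ] - pos[2, ])^2))
  dists <- d0
  for (i in 1:100) {
    mechanics_step(pos, cfg)
    dists <- c(dists, sqrt(sum((pos[1, ] - pos[2, ])^2)))
  }
  expect_true(all(diff(dists) > -1e-9))
  expect_equal(tail(dists, 1), cfg$mechanics$rest, tolerance = 0.05)
  # single cell does not move
  single <- matrix(c(0, 0, 0), 1, 3)
  mechanics_step(single, cfg)
  expect_equal(single, matrix(c(0, 0, 0), 1, 3))
})

test_that("a small crypt reaches homeostasis with full pedigree accounting", {
  run <- cached("tiny20", simulate_crypt(tiny_crypt(), genome = NULL,
                                         t_end_days = 20, seed = 5,
                                         snapshot_every_hours = 24))
  cc <- composition_summary(run, from_day = 10)
  expect_gt(cc[["ISC"]], 1)
  expect_gt(cc[["PC"]], 5)
  expect_gt(cc[["EC"]], 30)
  # stationarity of the total cell number (no trend in the second half)
  k <- run$counts$time >= 10 * 24
  halves <- split(run$counts$total[k], cut(seq_len(sum(k)), 2))
  expect_lt(abs(mean(halves[[1]]) - mean(halves[[2]])) / mean(halves[[1]]),
            0.15)
  ped <- run$pedigree
  # every record closed with an explicit fate; no silent disappearance
  expect_false(anyNA(ped$end))
  expect_true(all(ped$fate %in% c("divided", "anoikis", "pc_death", "alive")))
  expect_equal(sum(ped$fate == "alive"),
               run$counts$total[nrow(run$counts)])
  # conservation: every record is a founder or a daughter of one division
  expect_equal(nrow(ped), run$cfg$n_init + 2L * sum(ped$fate == "divided"))
  # postmitotic lineages never divide
  expect_false(any(ped$fate == "divided" & ped$lineage %in% c("PC", "GC")))
  # anoikis only at the orifice: all other removals are Paneth turnover
  expect_true(all(ped$fate[!ped$fate %in% c("divided", "alive")] %in%
                    c("anoikis", "pc_death")))
})

test_that("division counts match the cell cycle and cells move upward", {
  run <- cached("tiny20", simulate_crypt(tiny_crypt(), genome = NULL,
                                         t_end_days = 20, seed = 5,
                                         snapshot_every_hours = 24))
  ped <- run$pedigree
  # dividing cells complete a cycle of roughly the configured length
  div <- ped[ped$fate == "divided" & ped$birth > 0, ]
  expect_equal(mean(div$end - div$birth),
               mean(c(run$cfg$cycle_isc, mean(run$cfg$cycle_ec))),
               tolerance = 0.25)
  # passive conveyor belt: cells born low end higher just before extrusion
  ano <- ped[ped$fate == "anoikis", ]
  expect_gt(nrow(ano), 20)
  # mean height of extruded cells is the orifice by construction; check
  # instead that EC-lineage snapshots drift upward between snapshots
  zs <- sapply(run$snapshots, function(s) mean(s$cells$z[s$cells$lineage == "EC"]))
  expect_gt(mean(zs[-1]), 2) # ECs populate the upper crypt
})

test_that("trajectories are reproducible and decoupled from the genome layer", {
  set.seed(1); g <- generate_genome(4L, c(l_reg = 400L, l_pro = 60L, l_cod = 40L))
  r1 <- simulate_crypt(tiny_crypt(), genome = NULL, t_end_days = 6, seed = 11,
                       snapshot_every_hours = 48)
  r2 <- simulate_crypt(tiny_crypt(), genome = g, t_end_days = 6, seed = 11,
                       snapshot_every_hours = 48)
  # identical lineage/pedigree trajectory with the payload enabled
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$pedigree, r2$pedigree)
  # bit-identical rerun including the epigenome
  r3 <- simulate_crypt(tiny_crypt(), genome = g, t_end_days = 6, seed = 11,
                       snapshot_every_hours = 48)
  expect_identical(r2$snapshots, r3$snapshots)
})

test_that("epigenome state stays in bounds and conserves marks in the crypt", {
  set.seed(2); g <- generate_genome(4L, c(l_reg = 400L, l_pro = 60L, l_cod = 40L))
  run <- simulate_crypt(tiny_crypt(), genome = g, t_end_days = 6, seed = 12,
                        snapshot_every_hours = 12)
  for (s in run$snapshots) {
    expect_true(all(s$epi$m4 >= 0 & s$epi$m4 <= 1))
    expect_true(all(s$epi$m27 >= 0 & s$epi$m27 <= 1))
    expect_true(all(s$epi$mcpg >= 0 & s$epi$mcpg <= 1))
    expect_true(all(s$epi$tlev >= 0))
  }
})
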