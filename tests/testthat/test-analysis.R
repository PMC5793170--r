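# Analysis operators: lineage averages, histone histograms, switch detection,
# fixation statistics, Newick export, multi-crypt aggregation, trend test.

test_that("lineage averages match hand arithmetic on a built fixture", {
  times <- c(0, 24, 48)
  snaps <- lapply(seq_along(times), function(s) {
    list(time = times[s],
         cells = data.frame(id = 1:3, clone = 1:3,
                            lineage = c("ISC", "ISC", "EC"), z = c(0, 0, 5),
                            stringsAsFactors = FALSE),
         epi = list(cell_id = 1:3,
                    m4 = matrix(c(0.2, 0.4, 0.9) + (s - 1) * 0.01, 1),
                    m27 = matrix(c(0.5, 0.7, 0.1), 1),
                    mcpg = matrix(c(0.1, 0.3, 0.0), 1),
                    tlev = matrix(c(0.2, 0.2, 1.4), 1)))
  })
  run <- synthetic_run(times, matrix(0.1, 1, 3))
  run$snapshots <- snaps
  tr <- lineage_average_tracks(run, "ISC")
  expect_equal(tr$mcpg[1, ], rep(0.2, 3))                 # mean of 0.1, 0.3
  expect_equal(tr$m4[1, ], 0.3 + (0:2) * 0.01)
  expect_equal(tr$n_cells, rep(2L, 3))
  tre <- lineage_average_tracks(run, "EC")
  expect_equal(tre$tlev[1, ], rep(1.4, 3))                # single cell track
  # empty lineage -> NA with zero count
  trp <- lineage_average_tracks(run, "PC")
  expect_true(all(is.na(trp$mcpg)))
  expect_error(lineage_average_tracks(run, "XX"), "unknown lineage")
})

test_that("histone histograms are normalized with the mark-level bin width", {
  times <- c(0, 24)
  run <- synthetic_run(times, matrix(0.1, 1, 2),
                       m4 = matrix(0.5, 1, 2), m27 = matrix(0.25, 1, 2),
                       params = epigenome_params(n_nucleosomes = 20L))
  h <- histone_state_histogram(run, 1L, "ISC", c(0, 48))
  expect_equal(sum(h), 1)
  expect_equal(dim(h), c(21L, 21L))
  # all cells identical: a single nonzero bin at (0.5, 0.25)
  expect_equal(h[11, 6], 1)
  expect_error(histone_state_histogram(run, 1L, "EC", c(0, 48)), "no cells")
})

test_that("a permanent jump yields exactly one persistent switch", {
  times <- seq(0, 480, by = 24)
  track <- matrix(ifelse(times >= 240, 0.95, 0.05), 1, length(times))
  run <- synthetic_run(times, track)
  sw <- detect_switches(run, thresholds = 0.5)
  expect_equal(nrow(sw), 1L)
  expect_equal(sw$time, 240)
  expect_true(sw$persisted)
  expect_true(sw$fixed) # the only ISC carries the high state
  # a transient excursion shorter than the persistence window is not persistent
  track2 <- matrix(ifelse(times == 240, 0.95, 0.05), 1, length(times))
  sw2 <- detect_switches(synthetic_run(times, track2), thresholds = 0.5)
  expect_equal(nrow(sw2), 1L)
  expect_false(sw2$persisted)
})

test_that("switch detection is insensitive to doubling the snapshot cadence", {
  times <- seq(0, 480, by = 12)
  track <- matrix(ifelse(times >= 252, 0.95, 0.05), 1, length(times))
  run_fine <- synthetic_run(times, track)
  keep <- seq(1, length(times), by = 2)
  run_coarse <- synthetic_run(times[keep], track[, keep, drop = FALSE])
  sw_f <- detect_switches(run_fine, thresholds = 0.5)
  sw_c <- detect_switches(run_coarse, thresholds = 0.5)
  expect_equal(sum(sw_f$persisted), 1L)
  expect_equal(sum(sw_c$persisted), 1L)
  expect_equal(sw_f$gene_index[sw_f$persisted], sw_c$gene_index[sw_c$persisted])
})

test_that("fixation statistics flag undefined and all-fixed cases", {
  times <- seq(0, 480, by = 24)
  run <- synthetic_run(times, matrix(0.05, 1, length(times)))
  none <- fixation_statistics(detect_switches(run, thresholds = 0.5), run,
                              from_day = 0)
  expect_false(none$defined)
  expect_true(is.na(none$p_fix))
  jump <- synthetic_run(times, matrix(ifelse(times >= 240, 0.95, 0.05), 1,
                                      length(times)))
  sw <- detect_switches(jump, thresholds = 0.5)
  fs <- fixation_statistics(sw, jump, from_day = 0)
  expect_true(fs$defined)
  expect_equal(fs$p_fix, 1)
  expect_equal(fs$n_isc, 1)
})

test_that("Newick export has correct shape and round-trips through ape", {
  # one division, both daughters surviving: (A:x,B:y)R:z;
  ped <- data.frame(id = 1:3, parent = c(NA, 1L, 1L), birth = c(0, 30, 30),
                    end = c(30, 100, 80), fate = c("divided", "alive", "alive"),
                    clone = 1L, lineage = "ISC", stringsAsFactors = FALSE)
  nwk <- to_newick(ped)
  expect_match(unname(nwk["c1"]), "^\\(c2:70,c3:50\\)c1:30;$")
  # annotations appear as comments
  ann <- to_newick(ped, annotations = c("2" = "fate=alive"))
  expect_match(unname(ann["c1"]), "c2\\[&fate=alive\\]:70")
  # orphaned and open-ended records are rejected
  expect_error(to_newick(data.frame(id = 2L, parent = 9L, birth = 0, end = 1)),
               "orphan")
  # round-trip a simulated pedigree through an independent parser
  run <- cached("tiny20", simulate_crypt(tiny_crypt(), genome = NULL,
                                         t_end_days = 20, seed = 5,
                                         snapshot_every_hours = 24))
  founder_ids <- run$pedigree$id[is.na(run$pedigree$parent)]
  f <- founder_ids[which.max(tabulate(match(run$pedigree$clone,
                                            run$pedigree$clone[founder_ids])))]
  nwk2 <- to_newick(run$pedigree)
  tree <- ape::read.tree(text = nwk2[[paste0("c", f)]])
  # leaf count equals the number of terminated-or-surviving childless cells
  kids <- run$pedigree$id[!is.na(run$pedigree$parent)]
  desc <- function(id) {
    out <- id
    ch <- run$pedigree$id[!is.na(run$pedigree$parent) &
                            run$pedigree$parent %in% id]
    if (length(ch)) out <- c(out, desc(ch))
    out
  }
  clan <- desc(f)
  leaves <- setdiff(clan, unique(run$pedigree$parent))
  expect_equal(ape::Ntip(tree), length(leaves))
  # branch lengths preserved to 1e-6: compare total tree length
  lens <- run$pedigree$end - run$pedigree$birth
  expect_equal(sum(tree$edge.length) +
                 lens[run$pedigree$id == f],
               sum(lens[match(clan, run$pedigree$id)]), tolerance = 1e-6)
})

test_that("multi-crypt averages reproduce single runs and staggered drifts", {
  times <- seq(0, 240, by = 24)
  flat <- synthetic_run(times, matrix(0.1, 2, length(times)))
  # identical runs: the average equals any single run
  avg <- multi_crypt_average(list(flat, flat, flat))
  expect_equal(avg$mcpg, flat$snapshots[[1]]$epi$mcpg[, rep(1, length(times))],
               ignore_attr = TRUE)
  # crypts switching a gene at staggered times: steps aggregate to a ramp
  mk_step <- function(t_on) {
    m <- matrix(0.1, 2, length(times))
    m[1, times >= t_on] <- 0.9
    synthetic_run(times, m)
  }
  runs <- lapply(c(48, 96, 144, 192), mk_step)
  agg <- multi_crypt_average(runs)
  ramp <- agg$mcpg[1, ]
  expect_true(all(diff(ramp) >= 0))
  expect_gt(length(unique(round(ramp, 6))), 4) # graded, not a step
  expect_equal(ramp[1], 0.1)
  expect_equal(ramp[length(ramp)], 0.9)
  # the untouched gene stays flat
  expect_equal(agg$mcpg[2, ], rep(0.1, length(times)), ignore_attr = TRUE)
  expect_error(multi_crypt_average(list(flat)), "length")
})

test_that("the trend test detects ramps and passes stationary noise", {
  set.seed(9)
  expect_lt(mk_trend_test(seq(0, 1, length.out = 30)), 1e-6)
  flat_p <- replicate(50, mk_trend_test(rnorm(30)))
  expect_gt(mean(flat_p > 0.01), 0.9)
  expect_equal(mk_trend_test(rep(0.5, 20)), 1) # constant series
})
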