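# Promoter epigenome model: methylation equations, fixed points, histone
# kinetics, division dilution.

test_that("maintenance and de novo probabilities follow the binding model", {
  p <- epigenome_params()
  # boundary evaluations collapse to closed forms
  expect_equal(d_main(0, p), p$d_main_0 / (1 + exp(p$e_m_0)))
  expect_equal(d_main(1, p), p$d_main_0 / (1 + exp(p$e_m_0 + p$e_m_1)))
  # positive auto-feedback under the sign convention
  expect_gt(d_main(1, p), d_main(0, p))
  m <- seq(0, 1, by = 0.01)
  expect_true(all(diff(d_main(m, p)) >= 0))
  # unmodified promoter: numerator equals denominator
  expect_equal(d_novo(0, 0, p), p$d_novo_0)
  expect_equal(d_novo(0, 0.73, p), p$d_novo_0) # m4 = 0 cancels exactly
  # ceiling and monotonicity on a grid
  grid <- expand.grid(m4 = m, m27 = m)
  dn <- d_novo(grid$m4, grid$m27, p)
  expect_true(all(dn <= p$d_novo_0 + 1e-12))
  expect_equal(max(dn), p$d_novo_0) # homeostasis grid maximum = 0.1
  expect_true(all(diff(d_novo(m, 0.4, p)) <= 0))        # non-increasing in m4
  expect_true(all(diff(d_novo(0.8, m, p)) >= 0))        # non-decreasing in m27
  # domain errors
  expect_error(d_main(1.2, p), "\\[0, 1\\]")
  expect_error(d_novo(-0.1, 0, p), "\\[0, 1\\]")
  # sign convention is enforced
  expect_error(epigenome_params(e_m_1 = 5))
})

test_that("methylation change vanishes at fixed points and is bounded", {
  p <- epigenome_params()
  expect_equal(delta_m_cpg(0, 0.3, 0.6, p), d_novo(0.3, 0.6, p))
  expect_equal(delta_m_cpg(1, 0.3, 0.6, p), -(1 - d_main(1, p)))
  fp <- fixed_points(0.05, p)
  for (r in fp$root)
    expect_equal(delta_m_cpg(r, 0, 0, epigenome_params(d_novo_0 = 0.05)), 0,
                 tolerance = 1e-8)
  # m + delta stays in [0, 1] everywhere
  g <- expand.grid(m = seq(0, 1, 0.05), m4 = seq(0, 1, 0.2),
                   m27 = seq(0, 1, 0.2))
  mm <- g$m + delta_m_cpg(g$m, g$m4, g$m27, p)
  expect_true(all(mm >= 0 & mm <= 1))
})

test_that("fixed points agree with the brute-force oracle", {
  set.seed(421)
  for (i in 1:100) {
    p <- epigenome_params(
      d_main_0 = runif(1, 0.9, 0.999),
      e_m_0 = runif(1, 6, 14),
      e_m_1 = -runif(1, 20, 50))
    dn <- runif(1, 0.005, 0.9)
    fp <- fixed_points(dn, p)
    orc <- oracle_fixed_points(dn, p)
    expect_equal(length(fp$root), length(orc),
                 info = sprintf("draw %d: dn=%.4f", i, dn))
    expect_true(all(abs(sort(fp$root) - sort(orc)) < 1e-4))
    expect_true(length(fp$root) %in% c(1L, 3L))
    if (length(fp$root) == 3L)
      expect_identical(fp$stable, c(TRUE, FALSE, TRUE))
  }
})

test_that("bistable window, hysteresis and boundary map match the model", {
  p <- epigenome_params() # D_main,0 = 0.99
  # a d_novo interval below 0.1 with exactly 3 roots
  n_roots <- vapply(seq(0.02, 0.09, by = 0.01),
                    function(d) nrow(fixed_points(d, p)), integer(1))
  expect_true(all(n_roots == 3L))
  # d_novo close to 1: single stable root near 1
  fp <- fixed_points(0.95, p)
  expect_equal(nrow(fp), 1L)
  expect_true(fp$stable && fp$root > 0.9)
  # hysteresis: follow the nearest stable branch up, then down
  dns <- seq(0.005, 0.4, by = 0.005)
  follow <- function(dns) {
    m <- fixed_points(dns[1], p)
    m <- m$root[m$stable][1]
    vapply(dns, function(d) {
      fp <- fixed_points(d, p)
      st <- fp$root[fp$stable]
      m <<- st[which.min(abs(st - m))]
      m
    }, numeric(1))
  }
  up <- follow(dns)
  down <- rev(follow(rev(dns)))
  expect_gt(max(abs(up - down)), 0.5) # branches differ inside the window
  # classification map
  bb <- bistability_boundary(p, 21L)
  k4_quadrant <- bb$grid$m4 > 0.5 & bb$grid$m27 < 0.5
  expect_true(all(bb$grid$class[k4_quadrant] == "mono_low"))
  expect_false(any(bb$grid$class == "mono_high")) # none at D_novo,0 = 0.1
  bb3 <- bistability_boundary(epigenome_params(d_novo_0 = 0.3), 21L)
  expect_gt(sum(bb3$grid$class == "mono_high"), 0) # appears during repair
  expect_gt(nrow(bb$boundary), 0)
})

test_that("histone step realizes the stated couplings", {
  p <- epigenome_params(cde4 = 0, cde27 = 0,
                        hmt = list(q4_max = 1, q27_max = 1, coop_basal = 1,
                                   w4 = 0, w27 = 0, kt4 = 1e-6, kt27 = 1e6))
  # no demodification + saturating recruitment: all-marked absorbing state
  s <- promoter_state(rep(TRUE, 20), rep(TRUE, 20))
  s2 <- histone_step(s, tf_input = 1, p)
  expect_equal(s2$m4, 1)
  expect_equal(s2$m27, 1)
  # zero recruitment: marks decay geometrically at rates cde4/cde27
  pdec <- epigenome_params(cde4 = 0.3, cde27 = 0.1,
                           hmt = list(q4_max = 0, q27_max = 0))
  set.seed(99)
  n_rep <- 2000L
  left <- replicate(n_rep, {
    s1 <- histone_step(promoter_state(rep(TRUE, 20), rep(TRUE, 20)), 0, pdec)
    c(s1$m4, s1$m27)
  })
  expect_equal(mean(left[1, ]), 1 - 0.3, tolerance = 0.02)
  expect_equal(mean(left[2, ]), 1 - 0.1, tolerance = 0.02)
  # DNA methylation weakens mark gain (paired Monte-Carlo)
  pw <- epigenome_params()
  gain <- function(mcpg, seed) {
    set.seed(seed)
    mean(replicate(400, {
      s0 <- promoter_state(rep(FALSE, 20), rep(FALSE, 20), m_cpg = mcpg)
      histone_step(s0, tf_input = 1, pw)$m4
    }))
  }
  expect_lt(gain(1, 7), gain(0, 7))
})

test_that("transcription is modulated by marks but never by DNA methylation", {
  p <- epigenome_params()
  bare <- promoter_state(rep(FALSE, 20), rep(FALSE, 20))
  expect_equal(transcription_update(bare, 0.7, p), 0.7) # bare TF drive
  for (mc in c(0, 0.5, 1)) {
    s <- promoter_state(rep(c(TRUE, FALSE), 10), rep(FALSE, 20), m_cpg = mc)
    expect_equal(transcription_update(s, 0.7, p),
                 0.7 * (1 + p$hmt$beta4 * 0.5)) # identical for all m_cpg
  }
  rep27 <- promoter_state(rep(FALSE, 20), rep(TRUE, 20))
  expect_lt(transcription_update(rep27, 0.7, p), 0.7) # impeded Pol II
})

test_that("division conserves marks and applies the deterministic update", {
  p <- epigenome_params()
  set.seed(5)
  for (i in 1:25) {
    k4 <- runif(20) < 0.6
    k27 <- runif(20) < 0.4
    s <- promoter_state(k4, k27, m_cpg = runif(1))
    d <- divide_promoter_state(s, p)
    expect_equal(sum(d[[1]]$k4_marks) + sum(d[[2]]$k4_marks), sum(k4))
    expect_equal(sum(d[[1]]$k27_marks) + sum(d[[2]]$k27_marks), sum(k27))
    for (k in 1:2) expect_true(d[[k]]$m_cpg >= 0 && d[[k]]$m_cpg <= 1)
  }
  # fully marked mother: expected daughter fraction 1/2
  set.seed(6)
  m4d <- replicate(800, {
    s <- promoter_state(rep(TRUE, 20), rep(FALSE, 20))
    divide_promoter_state(s, p)[[1]]$m4
  })
  expect_equal(mean(m4d), 0.5, tolerance = 0.01)
  # unmodified, unmethylated mother: daughters get exactly D_novo,0 = 0.1
  s0 <- promoter_state(rep(FALSE, 20), rep(FALSE, 20), m_cpg = 0)
  d0 <- divide_promoter_state(s0, p)
  expect_equal(d0[[1]]$m_cpg, 0.1)
  expect_equal(d0[[2]]$m_cpg, 0.1)
  # methylation update is deterministic given the daughter state
  s1 <- promoter_state(rep(FALSE, 20), rep(TRUE, 20), m_cpg = 0.2)
  reps <- replicate(20, divide_promoter_state(s1, p)[[1]]$m_cpg)
  # all daughters have m4 = 0, m27 diluted; same (m4, m27, m) -> identical m
  m27s <- replicate(20, {
    d <- divide_promoter_state(s1, p)[[1]]
    c(d$m27, d$m_cpg)
  })
  same <- split(m27s[2, ], m27s[1, ])
  for (v in same) expect_length(unique(v), 1L)
})
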