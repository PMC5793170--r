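#!/usr/bin/env Rscript
# Calibration checks behind the shipped defaults. Verifies (and documents)
# that the default parameter set realizes the qualitative structure the model
# is built around; run after changing any default.
#
# 1. Methylation equation (epigenome_params defaults):
#    - bistable window of d_novo at D_main,0 = 0.99 with a 3-root interval
#      below the homeostatic D_novo,0 = 0.1,
#    - no mono-stable-high histone state at D_novo,0 = 0.1, a non-empty
#      mono-stable-high region at the repair value 0.3,
#    - H3K4me3-dominated promoters (m4 > 0.5, m27 < 0.5) mono-stable-low,
#    - division-map escape logic: single repair divisions at 0.3 are
#      transient, consecutive ones escape; sustained 0.2 divisions never do.
# 2. Crypt model (crypt_config defaults): time-averaged lineage composition
#    of 10 replicate 90-day crypts close to 9 ISC / 32 PC / 59 GC / 222 EC.
#
# Usage: Rscript scripts/calibrate.R [--replicates N]

suppressMessages(library(cryptdrift))
args <- commandArgs(trailingOnly = TRUE)
n_rep <- {
  i <- match("--replicates", args)
  if (is.na(i)) 10L else as.integer(args[i + 1L])
}

p <- epigenome_params()
cat("== methylation equation ==\n")
win <- vapply(seq(0.005, 0.5, by = 0.005), function(d)
  nrow(fixed_points(d, p)) == 3L, logical(1))
dns <- seq(0.005, 0.5, by = 0.005)[win]
cat(sprintf("bistable d_novo window: [%.3f, %.3f]\n", min(dns), max(dns)))
stopifnot(min(dns) < 0.1, max(dns) > 0.1, max(dns) < 0.3)

bb1 <- bistability_boundary(p, 21L)
bb3 <- bistability_boundary(epigenome_params(d_novo_0 = 0.3), 21L)
k4q <- bb1$grid$m4 > 0.5 & bb1$grid$m27 < 0.5
cat(sprintf("classes at 0.1: %s | mono-high at 0.3: %d points\n",
            paste(names(table(bb1$grid$class)), table(bb1$grid$class),
                  collapse = " ", sep = "="),
            sum(bb3$grid$class == "mono_high")))
stopifnot(all(bb1$grid$class[k4q] == "mono_low"),
          !any(bb1$grid$class == "mono_high"),
          any(bb3$grid$class == "mono_high"))

# division-map escape logic for a pure H3K27me3 target (m4 = 0, m27 = 0.8)
step <- function(m, dn0) m + delta_m_cpg(m, 0, 0.8,
                                         epigenome_params(d_novo_0 = dn0))
fp <- fixed_points(0.1, p)
m_low <- min(fp$root); m_u <- fp$root[!fp$stable]
m1 <- step(m_low, 0.3)
m2 <- step(m1, 0.3)
m02 <- m_low; for (i in 1:50) m02 <- step(m02, 0.2)
cat(sprintf("low root %.3f, unstable %.3f; repair jumps: single %.3f, double %.3f, sustained 0.2 -> %.3f\n",
            m_low, m_u, m1, m2, m02))
stopifnot(m1 < m_u, m2 > m_u, m02 < m_u)

cat("== crypt composition (", n_rep, "x 90 d) ==\n", sep = "")
comp <- sapply(seq_len(n_rep), function(sd) {
  run <- simulate_crypt(crypt_config(), genome = NULL, t_end_days = 90,
                        seed = sd, snapshot_every_hours = 0)
  composition_summary(run, from_day = 30, to_day = 90)
})
means <- rowMeans(comp)
cat(sprintf("ISC %.2f (target 9+-4) | PC %.2f (32+-3) | GC %.2f (59+-6) | EC %.2f (222+-10)\n",
            means[["ISC"]], means[["PC"]], means[["GC"]], means[["EC"]]))
stopifnot(abs(means[["ISC"]] - 9) < 4, abs(means[["PC"]] - 32) < 3,
          abs(means[["GC"]] - 59) < 6, abs(means[["EC"]] - 222) < 10)
cat("calibration checks passed\n")
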