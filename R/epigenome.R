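# Promoter-level epigenome model: histone (de-)modification kinetics,
# transcription feedback, and the DNA-methylation difference equation.

#' Parameters of the promoter epigenome model
#'
#' Bundles all constants of the DNA-methylation difference equation and of
#' the stochastic histone (de-)modification kinetics.
#'
#' The maintenance methylation probability per division is
#' \deqn{D_{main}(m) = D_{main,0} / (1 + \exp(E_{m,0} + E_{m,1} m)),}
#' the effective de novo probability is
#' \deqn{D_{novo}(m_4, m_{27}) = D_{novo,0}\,
#'   \frac{1 + \exp(-E_{CpG27} m_{27})}{1 + \exp(E_{CpG4} m_4 - E_{CpG27} m_{27})}.}
#' Positive auto-feedback of maintenance methylation (non-decreasing
#' \eqn{D_{main}} in \eqn{m}) requires `e_m_1 <= 0`; the constructor enforces
#' this sign convention.
#'
#' @param d_novo_0 maximum de novo methylation probability per division,
#'   in (0, 1]. 0.1 under homeostasis; elevated during DNA damage repair.
#' @param d_main_0 maximum maintenance probability per division, in (0, 1].
#' @param e_m_0 accessibility energy constant of maintenance-DNMT binding.
#' @param e_m_1 methylation-coupling energy constant (must be <= 0 so that
#'   maintenance activity increases with the methylation level).
#' @param e_cpg4 energy constant of H3K4me3 suppression of de novo DNMT
#'   binding (>= 0).
#' @param e_cpg27 energy constant of H3K27me3 recruitment of de novo DNMTs
#'   (>= 0).
#' @param cde4,cde27 demethylation probabilities per nucleosome per time step
#'   for H3K4me3 and H3K27me3.
#' @param hmt named list of histone-methyltransferase recruitment constants:
#'   `q4_max`, `q27_max` (maximal modification probabilities per nucleosome
#'   and time step), `kt4`, `kt27`, `hill` (Hill constants/exponent of the
#'   transcription gates: the H3K4me3 HMT gate increases with transcription
#'   level T, the H3K27me3 HMT gate decreases with T), `coop_basal` (basal
#'   recruitment relative to full neighbour cooperativity), `w4`, `w27`
#'   (multiplicative weakening of HMT binding by DNA methylation, in [0, 1]),
#'   and `beta4`, `beta27` (transcription modulation: T is multiplied by
#'   `(1 + beta4 * m4) / (1 + beta27 * m27)`).
#' @param n_nucleosomes number of cooperative nucleosomes per promoter
#'   (regulatory-region length / 200; 20 for the default 4 kb region).
#'
#' @return An object of class `epigenome_params` (a validated list).
#' @examples
#' p <- epigenome_params()
#' d_novo(0, 0, p)    # equals d_novo_0
#' d_main(1, p) > d_main(0, p)  # positive auto-feedback
#' @export
epigenome_params <- function(d_novo_0 = 0.1,
                             d_main_0 = 0.99,
                             e_m_0 = 11.2,
                             e_m_1 = -40,
                             e_cpg4 = 20,
                             e_cpg27 = 10,
                             cde4 = 0.05,
                             cde27 = 0.05,
                             hmt = list(),
                             n_nucleosomes = 20L) {
  hmt_def <- list(q4_max = 0.35, q27_max = 0.35,
                  kt4 = 0.5, kt27 = 0.25, hill = 4,
                  coop_basal = 0.3, w4 = 0.9, w27 = 0.9,
                  beta4 = 0.5, beta27 = 1.5)
  hmt <- modifyList(hmt_def, hmt)
  p <- structure(list(
    d_novo_0 = d_novo_0, d_main_0 = d_main_0,
    e_m_0 = e_m_0, e_m_1 = e_m_1,
    e_cpg4 = e_cpg4, e_cpg27 = e_cpg27,
    cde4 = cde4, cde27 = cde27,
    hmt = hmt,
    n_nucleosomes = as.integer(n_nucleosomes)
  ), class = "epigenome_params")
  validate_epigenome_params(p)
  p
}

validate_epigenome_params <- function(p) {
  stopifnot(
    p$d_novo_0 > 0, p$d_novo_0 <= 1,
    p$d_main_0 > 0, p$d_main_0 <= 1,
    p$e_m_1 <= 0,                       # positive auto-feedback sign convention
    p$e_cpg4 >= 0, p$e_cpg27 >= 0,
    p$cde4 >= 0, p$cde4 <= 1, p$cde27 >= 0, p$cde27 <= 1,
    p$n_nucleosomes >= 1L,
    p$hmt$w4 >= 0, p$hmt$w4 <= 1, p$hmt$w27 >= 0, p$hmt$w27 <= 1
  )
  invisible(p)
}

#' @export
print.epigenome_params <- function(x, ...) {
  cat("Promoter epigenome parameters\n")
  cat(sprintf("  D_novo,0 = %.3g  D_main,0 = %.3g\n", x$d_novo_0, x$d_main_0))
  cat(sprintf("  E_m,0 = %.3g  E_m,1 = %.3g  E_CpG4 = %.3g  E_CpG27 = %.3g\n",
              x$e_m_0, x$e_m_1, x$e_cpg4, x$e_cpg27))
  cat(sprintf("  Cde4 = %.3g  Cde27 = %.3g  nucleosomes = %d\n",
              x$cde4, x$cde27, x$n_nucleosomes))
  invisible(x)
}

#' Promoter epigenetic state
#'
#' Per-gene, per-cell epigenetic state: boolean H3K4me3/H3K27me3 marks per
#' nucleosome, the derived modified fractions `m4` and `m27`, the promoter
#' DNA-methylation level `m_cpg`, and the gene's transcription level `t_level`.
#'
#' @param k4_marks,k27_marks logical vectors of length `n_nucleosomes`.
#' @param m_cpg DNA-methylation level in \[0, 1\].
#' @param t_level non-negative transcription level.
#' @return An object of class `promoter_state`.
#' @export
promoter_state <- function(k4_marks, k27_marks, m_cpg = 0, t_level = 0) {
  k4_marks <- as.logical(k4_marks)
  k27_marks <- as.logical(k27_marks)
  stopifnot(length(k4_marks) == length(k27_marks),
            length(k4_marks) >= 1L,
            !anyNA(k4_marks), !anyNA(k27_marks),
            m_cpg >= 0, m_cpg <= 1, t_level >= 0)
  structure(list(
    k4_marks = k4_marks, k27_marks = k27_marks,
    m4 = mean(k4_marks), m27 = mean(k27_marks),
    m_cpg = m_cpg, t_level = t_level
  ), class = "promoter_state")
}

check_unit <- function(x, name) {
  if (anyNA(x) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  x
}

#' Maintenance DNA-methylation probability
#'
#' Methylation-dependent binding of maintenance DNMTs:
#' `d_main_0 / (1 + exp(e_m_0 + e_m_1 * m_cpg))`. With `e_m_1 < 0` this is
#' non-decreasing in `m_cpg` (positive auto-feedback).
#'
#' @param m_cpg DNA-methylation level(s) in \[0, 1\] (vectorised).
#' @param p an [epigenome_params()] object.
#' @return Maintenance probabilities in (0, `d_main_0`).
#' @export
d_main <- function(m_cpg, p) {
  check_unit(m_cpg, "m_cpg")
  p$d_main_0 / (1 + exp(p$e_m_0 + p$e_m_1 * m_cpg))
}

#' Effective de novo DNA-methylation probability
#'
#' Histone-state dependent binding of de novo DNMTs:
#' `d_novo_0 * (1 + exp(-e_cpg27 * m27)) / (1 + exp(e_cpg4 * m4 - e_cpg27 * m27))`.
#' H3K4me3 suppresses, H3K27me3 recruits de novo DNMTs; the value never
#' exceeds `d_novo_0` (attained whenever `m4 = 0`).
#'
#' @param m4,m27 modified nucleosome fractions in \[0, 1\] (vectorised).
#' @param p an [epigenome_params()] object.
#' @return De novo probabilities in (0, `d_novo_0`\].
#' @export
d_novo <- function(m4, m27, p) {
  check_unit(m4, "m4"); check_unit(m27, "m27")
  p$d_novo_0 * (1 + exp(-p$e_cpg27 * m27)) /
    (1 + exp(p$e_cpg4 * m4 - p$e_cpg27 * m27))
}

#' Post-division change of the promoter DNA-methylation level
#'
#' Deterministic balance between de novo methylation of unmethylated CpGs and
#' loss of methylation not maintained through replication:
#' `d_novo(m4, m27) * (1 - m_cpg) - (1 - d_main(m_cpg)) * m_cpg`.
#' `m_cpg + delta_m_cpg(...)` always remains in \[0, 1\].
#'
#' @inheritParams d_novo
#' @param m_cpg DNA-methylation level(s) in \[0, 1\].
#' @return Signed methylation change(s).
#' @export
delta_m_cpg <- function(m_cpg, m4, m27, p) {
  check_unit(m_cpg, "m_cpg")
  d_novo(m4, m27, p) * (1 - m_cpg) - (1 - d_main(m_cpg, p)) * m_cpg
}

#' Fixed points of the DNA-methylation difference equation
#'
#' Finds all roots of `delta_m_cpg(m) = 0` in \[0, 1\] with the de novo
#' probability held at a fixed value, and classifies their stability by the
#' sign of the derivative of the methylation change at the root (central
#' difference, step 1e-6; a root is stable iff the derivative is negative).
#' For the default parameterisation the equation has one or three roots
#' (two stable and one unstable in the bistable regime).
#'
#' @param d_novo_value de novo methylation probability in (0, 1\].
#' @param p an [epigenome_params()] object.
#' @param tol root acceptance tolerance on `|delta_m_cpg|`.
#' @return A data.frame with columns `root` and `stable`.
#' @export
fixed_points <- function(d_novo_value, p, tol = 1e-9) {
  stopifnot(d_novo_value > 0, d_novo_value <= 1)
  f <- function(m) d_novo_value * (1 - m) - (1 - d_main(m, p)) * m
  # bracket roots on a fine grid, then polish by bisection
  grid <- seq(0, 1, length.out = 4001L)
  fg <- f(grid)
  roots <- numeric(0)
  exact <- which(fg == 0)
  roots <- c(roots, grid[exact])
  sgn <- sign(fg)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in idx) {
    r <- tryCatch(
      stats::uniroot(f, lower = grid[i], upper = grid[i + 1L],
                     tol = .Machine$double.eps^0.75)$root,
      error = function(e) stop("fixed-point search failed to converge in [",
                               grid[i], ", ", grid[i + 1L], "]: ",
                               conditionMessage(e), call. = FALSE))
    roots <- c(roots, r)
  }
  roots <- sort(unique(roots))
  if (length(roots) && any(abs(f(roots)) >= tol)) {
    bad <- roots[abs(f(roots)) >= tol]
    stop("fixed-point residual above tolerance at m = ",
         paste(signif(bad, 6), collapse = ", "), call. = FALSE)
  }
  h <- 1e-6
  stable <- vapply(roots, function(r) {
    lo <- max(0, r - h); hi <- min(1, r + h)
    (f(hi) - f(lo)) / (hi - lo) < 0
  }, logical(1))
  data.frame(root = roots, stable = stable)
}

#' Bistability map over histone modification states
#'
#' Classifies every point of a regular (m4, m27) grid by the number and
#' location of the stable fixed points of the methylation equation at the
#' corresponding effective de novo probability `d_novo(m4, m27, p)`:
#' `"mono_low"` (single stable root below 0.5), `"bistable"` (two stable
#' roots), or `"mono_high"` (single stable root above 0.5). Also returns the
#' grid segments where the classification changes (boundary polyline).
#'
#' @param p an [epigenome_params()] object.
#' @param grid_resolution number of grid points per axis (>= 10).
#' @return A list with `grid` (data.frame `m4`, `m27`, `d_novo`, `class`) and
#'   `boundary` (data.frame of midpoints between differently classified
#'   neighbouring grid points).
#' @export
bistability_boundary <- function(p, grid_resolution = 51L) {
  stopifnot(grid_resolution >= 10L)
  v <- seq(0, 1, length.out = grid_resolution)
  g <- expand.grid(m4 = v, m27 = v)
  g$d_novo <- d_novo(g$m4, g$m27, p)
  cls <- vapply(g$d_novo, function(dn) {
    fp <- fixed_points(dn, p)
    st <- fp$root[fp$stable]
    if (length(st) >= 2L) "bistable"
    else if (st[1] < 0.5) "mono_low"
    else "mono_high"
  }, character(1))
  g$class <- cls
  m <- matrix(cls, nrow = grid_resolution)
  bnd <- list()
  # horizontal and vertical class changes -> boundary midpoints
  dh <- which(m[-1, ] != m[-grid_resolution, ], arr.ind = TRUE)
  if (nrow(dh)) bnd[[1]] <- data.frame(m4 = (v[dh[, 1]] + v[dh[, 1] + 1L]) / 2,
                                       m27 = v[dh[, 2]])
  dv <- which(m[, -1] != m[, -grid_resolution], arr.ind = TRUE)
  if (nrow(dv)) bnd[[2]] <- data.frame(m4 = v[dv[, 1]],
                                       m27 = (v[dv[, 2]] + v[dv[, 2] + 1L]) / 2)
  boundary <- if (length(bnd)) do.call(rbind, bnd) else
    data.frame(m4 = numeric(0), m27 = numeric(0))
  list(grid = g, boundary = boundary)
}

#' One stochastic histone (de-)modification step for a single promoter
#'
#' Advances the per-nucleosome H3K4me3/H3K27me3 marks of one promoter by one
#' time step (1 h by default scheduling). Transcription facilitates H3K4me3-HMT
#' and suppresses H3K27me3-HMT recruitment (Hill gates); modification is
#' cooperative in like-modified nearest-neighbour nucleosomes; DNA methylation
#' multiplicatively weakens both HMT bindings; demodification occurs with
#' probabilities `cde4`/`cde27` per marked nucleosome. The transcription level
#' is first recomputed from `tf_input` via [transcription_update()].
#'
#' @param s a [promoter_state()].
#' @param tf_input non-negative regulatory drive from the TF network.
#' @param p an [epigenome_params()] object.
#' @param cde4 optional override of the H3K4me3 demethylation constant (used
#'   during DNA damage repair).
#' @return The updated `promoter_state`.
#' @export
histone_step <- function(s, tf_input, p, cde4 = p$cde4) {
  stopifnot(inherits(s, "promoter_state"), tf_input >= 0)
  tl <- transcription_update(s, tf_input, p)
  k4 <- matrix(as.integer(s$k4_marks), ncol = 1)
  k27 <- matrix(as.integer(s$k27_marks), ncol = 1)
  cpp_histone_step(k4, k27, 0L, tl, s$m_cpg, cde4, p$cde27,
                   p$hmt$q4_max, p$hmt$q27_max,
                   p$hmt$kt4, p$hmt$kt27, p$hmt$hill,
                   p$hmt$coop_basal, p$hmt$w4, p$hmt$w27)
  promoter_state(as.logical(k4[, 1]), as.logical(k27[, 1]),
                 m_cpg = s$m_cpg, t_level = tl)
}

#' Transcription level of a promoter
#'
#' Returns the TF-network drive modulated upward by H3K4me3 and downward by
#' H3K27me3: `tf_input * (1 + beta4 * m4) / (1 + beta27 * m27)`. The value is
#' completely independent of the DNA-methylation level (transcriptional
#' silencing precedes promoter DNA methylation, not vice versa).
#'
#' @param s a [promoter_state()] (only `m4` and `m27` are used).
#' @param tf_input non-negative regulatory drive.
#' @param p an [epigenome_params()] object.
#' @return The transcription level (non-negative scalar).
#' @export
transcription_update <- function(s, tf_input, p) {
  stopifnot(tf_input >= 0)
  tf_input * (1 + p$hmt$beta4 * s$m4) / (1 + p$hmt$beta27 * s$m27)
}

#' Division of a promoter state into two daughters
#'
#' Each modified nucleosome of the mother is assigned to exactly one daughter
#' uniformly at random and placed at a random position along the daughter
#' promoter; remaining positions are unmodified (random distribution of
#' parental histones with complementation by unmodified ones). Both mark types
#' of a nucleosome travel together. Subsequent to the division, the
#' deterministic DNA-methylation update is applied per daughter with its
#' post-dilution `(m4, m27)`: `m_cpg <- m_cpg + delta_m_cpg(m_cpg, m4, m27)`
#' (DNMTs act only subsequent to cell division).
#'
#' @param s the mother [promoter_state()].
#' @param p an [epigenome_params()] object.
#' @param d_novo_0 optional override of the maximum de novo probability for
#'   this division (elevated during DNA damage repair).
#' @return A list of two `promoter_state` daughters.
#' @export
divide_promoter_state <- function(s, p, d_novo_0 = p$d_novo_0) {
  stopifnot(inherits(s, "promoter_state"))
  res <- cpp_divide_promoters(
    matrix(as.integer(s$k4_marks), ncol = 1),
    matrix(as.integer(s$k27_marks), ncol = 1),
    s$m_cpg, d_novo_0,
    p$d_main_0, p$e_m_0, p$e_m_1, p$e_cpg4, p$e_cpg27, 1L)
  lapply(1:2, function(i) {
    promoter_state(as.logical(res$k4[, i]), as.logical(res$k27[, i]),
                   m_cpg = res$m_cpg[i], t_level = s$t_level)
  })
}
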