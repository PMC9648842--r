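test_that("dilution profile realises the square wave geometry", {
  # low-frequency experimental regime: 2 h on, ~5.14 h off
  fp <- feed_program("pulsed", D = 0.1, w = 0.14, s = 0.28)
  expect_equal(fp$s / fp$w, 2)
  expect_equal((1 - fp$s) / fp$w, 1 / 0.14 - 2)
  expect_equal(dilution_profile(c(0, 1.99), fp), c(0.1, 0.1))
  expect_equal(dilution_profile(c(2.01, 7.13), fp), c(0, 0))
  expect_equal(dilution_profile(1 / 0.14 + 0.5, fp), 0.1) # next period
  # high-frequency regime: 1 h on, ~2 h off
  fp2 <- feed_program("pulsed", D = 0.1, w = 0.33, s = 0.33)
  expect_equal(fp2$s / fp2$w, 1)
  expect_equal(dilution_profile(c(0.5, 1.5, 2.5, 3.5), fp2),
               c(0.1, 0, 0, 0.1))
  # s = 1 is a chemostat
  fp3 <- feed_program("pulsed", D = 0.2, w = 0.5, s = 1)
  expect_equal(dilution_profile(seq(0, 10, 0.3), fp3),
               rep(0.2, length(seq(0, 10, 0.3))))
  # batch is identically zero
  expect_equal(dilution_profile(c(0, 5, 50), feed_program("batch")),
               c(0, 0, 0))
  # time average over one full period is s * D_on
  tt <- seq(0, 1 / 0.14, length.out = 100001)[-1]
  expect_equal(mean(dilution_profile(tt, fp)), 0.28 * 0.1, tolerance = 1e-3)
  # average-dilution parameterisation
  fp4 <- feed_program("pulsed", D = 0.028, w = 0.14, s = 0.28,
                      D_is_average = TRUE)
  expect_equal(fp4$D_on, 0.1)
})

test_that("the joint RHS vanishes at the classical chemostat fixed point", {
  sp <- mono_species()
  D <- 0.1
  S_star <- sp$pathways$Ks * D / (sp$pathways$mu_max - D)
  X_star <- sp$pathways$Yx * (30 - S_star)
  fp <- feed_program("chemostat", D = D, feed = c(GLU = 30, ACE = 0, ETH = 0))
  d <- coculture_rhs(5, list(X = c(mono = X_star),
                             M = c(GLU = S_star, ACE = 0, ETH = 0),
                             psi = list(mono = 1)),
                     sp, fp)
  expect_equal(unname(d$dX), 0, tolerance = 1e-10)
  expect_equal(unname(d$dM["GLU"]), 0, tolerance = 1e-10)
  # batch with no biomass: only the enzyme pools move
  d0 <- coculture_rhs(0, list(X = c(mono = 0),
                              M = c(GLU = 10, ACE = 0, ETH = 0),
                              psi = list(mono = 0.3)),
                      sp, feed_program("batch"))
  expect_equal(unname(d0$dX), 0)
  expect_equal(unname(d0$dM), c(0, 0, 0))
  expect_gt(abs(d0$dpsi$mono), 0)
  # two identical species and equal biomass: identical derivative blocks
  spA <- mono_species("A")
  spB <- mono_species("B")
  d2 <- coculture_rhs(0, list(X = c(A = 0.4, B = 0.4),
                              M = c(GLU = 5, ACE = 0, ETH = 0),
                              psi = list(A = 0.5, B = 0.5)),
                      list(spA, spB), feed_program("batch"))
  expect_equal(unname(d2$dX["A"]), unname(d2$dX["B"]))
  expect_equal(unname(d2$dpsi$A), unname(d2$dpsi$B))
})

test_that("integration reaches the classical chemostat steady state", {
  sp <- mono_species()
  D <- 0.1
  fp <- feed_program("chemostat", D = D, feed = c(GLU = 30, ACE = 0, ETH = 0))
  init <- reactor_init(sp, X0 = 0.5, M0 = c(GLU = 5, ACE = 0, ETH = 0))
  traj <- simulate_reactor(sp, fp, init, t_end = 400, dt = 1,
                           dynamic_enzymes = FALSE)
  S_star <- sp$pathways$Ks * D / (sp$pathways$mu_max - D)
  X_star <- sp$pathways$Yx * (30 - S_star)
  expect_rel_equal(dplyr::last(traj$GLU), S_star, 1e-3)
  expect_rel_equal(dplyr::last(traj$X_mono), X_star, 1e-3)
  # at steady state the realised growth rate equals the dilution rate
  expect_rel_equal(dplyr::last(traj$mu_mono), D, 1e-3)
})

test_that("batch mass accounting closes when yields saturate the bound", {
  # one pathway, byproduct takes all non-biomass mass: strict closure
  sp <- species_model("closed", list(
    pathway("GLU", "GLU", mu_max = 0.4, Ks = 0.1, q_max = 2.0, Yx = 0.2,
            Yp = c(ACE = 0.8))))
  traj <- run_batch(sp, S0 = 10, X0 = 0.05, t_end = 25, dt = 0.25)
  consumed <- traj$GLU[1] - traj$GLU
  gained <- (traj$X_closed - traj$X_closed[1]) + (traj$ACE - traj$ACE[1])
  expect_lt(max(abs(gained - consumed)), 1e-6)
  # full organism: production never exceeds consumption
  ec <- ecoli_k12()
  tr2 <- run_batch(ec, S0 = 20, X0 = 0.05, t_end = 30, dt = 0.25)
  consumed2 <- tr2$GLU[1] - tr2$GLU + (pmax(tr2$ACE[1] - tr2$ACE, 0))
  gained2 <- (tr2$X_ecoli - tr2$X_ecoli[1]) + pmax(tr2$ACE - tr2$ACE[1], 0)
  expect_true(all(gained2 <= consumed2 + 1e-8))
})

test_that("pulsed trajectories settle onto a periodic orbit", {
  # a regime where both species are robustly persistent
  w <- 0.2
  traj <- run_pulsed(default_pair(),
                     feed_program("pulsed", D = 0.05, w = w, s = 0.2),
                     t_end = 300, dt = 0.25)
  period <- 1 / w
  # compare phase-aligned biomasses one period apart across the last 5
  # periods (interpolated, since the reporting grid is incommensurate with
  # the period); differences are scaled by each signal's window maximum
  for (col in c("X_ecoli", "X_scerevisiae")) {
    scale <- max(traj[[col]][traj$t >= 240])
    for (t1 in seq(300 - 6 * period, 300 - 2 * period, length.out = 5)) {
      v1 <- approx(traj$t, traj[[col]], xout = t1)$y
      v2 <- approx(traj$t, traj[[col]], xout = t1 + period)$y
      expect_lt(abs(v2 - v1) / scale, 0.01)
    }
  }
})

test_that("fast pulsing converges to the equivalent chemostat", {
  sp <- mono_species()
  # s * D_on fixed at 0.1 while the period shrinks
  ch <- run_chemostat(sp, D = 0.1, t_end = 60, batch_phase = 0, S0 = 10,
                      X_total = 0.5, dt = 0.5)
  fp <- feed_program("pulsed", D = 0.2, w = 4, s = 0.5)
  pu <- run_pulsed(sp, fp, t_end = 60, S0 = 10, X_total = 0.5, dt = 0.5)
  expect_rel_equal(dplyr::last(pu$X_mono), dplyr::last(ch$X_mono), 0.02)
  expect_lt(abs(dplyr::last(pu$GLU) - dplyr::last(ch$GLU)), 0.05)
})

test_that("refining integrator tolerances leaves the final state unchanged", {
  pair <- default_pair()
  fp <- feed_program("pulsed", D = 0.1, w = 0.33, s = 0.33)
  a <- run_pulsed(pair, fp, t_end = 40, dt = 0.5, rtol = 1e-8, atol = 1e-10)
  b <- run_pulsed(pair, fp, t_end = 40, dt = 0.5, rtol = 5e-9, atol = 5e-11)
  fa <- unlist(a[nrow(a), c("X_ecoli", "X_scerevisiae", "GLU", "ACE", "ETH")])
  fb <- unlist(b[nrow(b), c("X_ecoli", "X_scerevisiae", "GLU", "ACE", "ETH")])
  expect_lt(max(abs(fa - fb) / pmax(abs(fa), 1e-6)), 1e-4)
})

test_that("dilution above every attainable growth rate washes the culture out", {
  traj <- run_chemostat(default_pair(), D = 0.5, t_end = 140,
                        batch_phase = 0, dt = 0.5)
  total0 <- traj$X_ecoli[1] + traj$X_scerevisiae[1]
  total <- dplyr::last(traj$X_ecoli) + dplyr::last(traj$X_scerevisiae)
  expect_lt(total, total0 * 1e-3)
})

test_that("compiled and R integration engines agree", {
  pair <- default_pair()
  fp <- feed_program("pulsed", D = 0.1, w = 0.33, s = 0.33)
  a <- run_pulsed(pair, fp, t_end = 15, dt = 0.5, engine = "compiled")
  b <- run_pulsed(pair, fp, t_end = 15, dt = 0.5, engine = "R")
  expect_lt(max(abs(as.matrix(a[-1]) - as.matrix(b[-1]))), 1e-6)
})

test_that("a decaying resting culture relaxes to the constitutive baseline", {
  sp <- mono_species()
  init <- reactor_init(sp, X0 = 0.2, M0 = c(GLU = 0, ACE = 0, ETH = 0),
                       psi0 = list(mono = 0.9))
  # enzyme decay relaxes at rate delta = 0.05/h, so give it ~12 timescales
  traj <- simulate_reactor(sp, feed_program("batch"), init, t_end = 250,
                           dt = 2)
  # no substrate: biomass constant, enzymes decay towards eps_c/delta level
  expect_equal(dplyr::last(traj$X_mono), 0.2, tolerance = 1e-8)
  resting <- unname(comonod:::resting_psi_rel(sp))
  expect_equal(dplyr::last(traj$psi_rel_mono_GLU), resting,
               tolerance = 1e-4)
})
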