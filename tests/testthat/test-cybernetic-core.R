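test_that("Monod fraction is a saturating hyperbola with half-point at Ks", {
  expect_identical(monod_fraction(0.112, 0.112), 0.5)
  expect_identical(monod_fraction(0, 1), 0)
  expect_lt(abs(monod_fraction(1e6, 1) - 1), 1e-6)
  # strictly increasing, bounded below 1
  S <- sort(runif(50, 0, 100))
  H <- monod_fraction(S, 0.3)
  expect_true(all(diff(H) > 0))
  expect_true(all(H >= 0 & H < 1))
  expect_error(monod_fraction(-1, 1), class = "comonod_domain_error")
  expect_error(monod_fraction(1, 0), class = "comonod_domain_error")
})

test_that("pathway growth returns are yield-scaled gated uptake rates", {
  ec <- ecoli_k12()
  sc <- scerevisiae_cenpk()
  # saturating glucose, fully expressed enzymes: mu = Yx * q_max
  mu <- pathway_growth_returns(c(GLU = 1e6, ACE = 0, ETH = 0),
                               rep(1, 3), ec)
  expect_equal(unname(mu["GLU_ferm"]), 0.165 * 2.640, tolerance = 1e-6)
  mu_sc <- pathway_growth_returns(c(GLU = 1e9, ACE = 0, ETH = 0),
                                  rep(1, 4), sc)
  expect_equal(unname(mu_sc["GLU_ox"]), 0.070 * 3.175, tolerance = 1e-6)
  # no enzyme, no flux
  expect_equal(unname(pathway_growth_returns(c(GLU = 20, ACE = 1, ETH = 1),
                                             rep(0, 3), ec)),
               rep(0, 3))
  # bounded by mu_max within the table's consistency slack
  psi <- runif(3)
  M <- c(GLU = runif(1, 0, 50), ACE = runif(1, 0, 5), ETH = 0)
  mu_r <- pathway_growth_returns(M, psi, ec)
  expect_true(all(mu_r <= ec$pathways$mu_max * 1.03))
  # malformed pool rejected
  expect_error(pathway_growth_returns(c(GLU = 1), rep(1, 3), ec),
               class = "comonod_config_error")
})

test_that("matching-law weights normalise and declare degeneracy safely", {
  w <- cybernetic_weights(c(0.3, 0.1))
  expect_equal(w$u, c(0.75, 0.25))
  expect_equal(w$v, c(1, 1 / 3))
  w1 <- cybernetic_weights(0.437)
  expect_equal(w1$u, 1)
  expect_equal(w1$v, 1)
  w0 <- cybernetic_weights(c(0, 0, 0))
  expect_equal(w0$u, rep(1 / 3, 3))
  expect_equal(w0$v, rep(1, 3))
  expect_error(cybernetic_weights(c(0.1, -0.1)),
               class = "comonod_domain_error")
  # property: normalisation over random draws
  set.seed(11)
  for (i in 1:25) {
    mu <- runif(sample(2:6, 1), 0, 0.5)
    w <- cybernetic_weights(mu)
    expect_equal(sum(w$u), 1)
    expect_equal(max(w$v), 1)
    expect_true(all(w$u >= 0 & w$u <= 1 & w$v >= 0 & w$v <= 1))
  }
})

test_that("enzyme dynamics hold their designed fixed point and stay bounded", {
  sp <- mono_species()
  pw <- sp$pathways
  # fixed point: fully allocated, saturating substrate, growing at mu_max
  d <- enzyme_odes(1, c(GLU = 1e9, ACE = 0, ETH = 0), mu_total = pw$mu_max,
                   u = 1, sp)
  expect_equal(unname(d), 0, tolerance = 1e-6)
  # constitutive baseline at zero substrate and zero growth
  psi <- 0.3
  d0 <- enzyme_odes(psi, c(GLU = 0, ACE = 0, ETH = 0), 0, u = 1, sp)
  pmx <- (pw$eps_c + pw$eps_i) / (pw$delta + pw$mu_max)
  expect_equal(unname(d0), pw$eps_c / pmx - pw$delta * psi)
  # synthesis-only at psi = 0: strictly positive
  expect_gt(enzyme_odes(0, c(GLU = 0, ACE = 0, ETH = 0), 0, u = 0, sp), 0)

  # property: along simulated trajectories with admissible random parameters
  # (eps_c * mu_max <= eps_i * delta), psi_rel stays in [0, 1 + 1e-6]
  set.seed(7)
  for (i in 1:8) {
    mu_max <- runif(1, 0.05, 0.8)
    delta <- runif(1, max(0.05, 0.02 * mu_max / 1), 0.2)
    spr <- mono_species(mu_max = mu_max, Ks = runif(1, 0.01, 2),
                        Yx = runif(1, 0.05, 0.6),
                        eps_c = 0.01, eps_i = 1, delta = delta)
    traj <- run_batch(spr, S0 = runif(1, 1, 30), X0 = 0.05, t_end = 40,
                      dt = 0.2)
    psi_col <- traj[[grep("^psi_rel_", names(traj), value = TRUE)]]
    expect_true(all(psi_col >= 0 & psi_col <= 1 + 1e-6))
  }
})

test_that("species flux assembles stoichiometry and conserves mass", {
  ec <- ecoli_k12()
  # no biomass, no flux
  f0 <- species_flux(c(GLU = 20, ACE = 1, ETH = 0), rep(1, 3), rep(1, 3),
                     X = 0, ec)
  expect_equal(unname(f0), rep(0, 4))
  # single pathway collapses to the scalar stoichiometric vector
  sp <- mono_species()
  f <- species_flux(c(GLU = 1e6, ACE = 0, ETH = 0), 1, 1, X = 2, sp)
  expect_equal(unname(f["GLU"]), -sp$pathways$q_max * 2, tolerance = 1e-6)
  expect_equal(unname(f["X"]), sp$pathways$Yx * sp$pathways$q_max * 2,
               tolerance = 1e-6)
  # brute-force elementwise evaluation vs matrix product, 3-pathway species
  M <- c(GLU = 20, ACE = 0, ETH = 0)
  psi <- c(0.7, 0.2, 0.4)
  mu <- pathway_growth_returns(M, psi, ec)
  v <- cybernetic_weights(unname(mu))$v
  X <- 0.8
  got <- species_flux(M, psi, v, X, ec)
  pw <- ec$pathways
  rate <- v * pw$q_max * psi * (M[pw$substrate] / (pw$Ks + M[pw$substrate])) * X
  manual <- c(X = sum(pw$Yx * rate),
              GLU = -rate[1] - rate[3],
              ACE = pw$Yp[[1]][["ACE"]] * rate[1] - rate[2],
              ETH = 0)
  expect_equal(unname(got), unname(manual), tolerance = 1e-12)
  # the acetate pathway contributes nothing without acetate
  expect_equal(unname(got["X"]),
               sum(pw$Yx[c(1, 3)] * rate[c(1, 3)]), tolerance = 1e-12)
  # flux conservation: produced / consumed = Yx + sum(Yp) <= 1 per pathway
  for (j in seq_len(nrow(pw))) {
    produced <- pw$Yx[j] + sum(pw$Yp[[j]])
    expect_lte(produced, 1 + 1e-9)
  }
})

test_that("packaged parameter tables load, validate and report violations", {
  expect_message(
    ec <- load_species(system.file("extdata", "species",
                                   "ecoli_k12_table1.yml",
                                   package = "comonod")),
    "negative q_max")
  expect_equal(ec$pathways$id, c("GLU_ferm", "ACE", "GLU_ox"))
  expect_equal(ec$pathways$mu_max, c(0.437, 0.077, 0.234))
  expect_true(all(ec$pathways$q_max > 0))
  sc <- scerevisiae_cenpk()
  expect_equal(nrow(sc$pathways), 4)
  expect_equal(sc$pathways$mu_max[sc$pathways$id == "ETH"], 0.080)
  # mass-bound violation is rejected with pathway identity
  bad <- tempfile(fileext = ".yml")
  writeLines(c("name: bad", "pathways:", "  P:", "    substrate: GLU",
               "    mu_max: 0.4", "    Ks: 0.1", "    q_max: 2.0",
               "    Yx: 0.5", "    Yp:", "      ACE: 0.6"), bad)
  expect_error(load_species(bad), "mass bound",
               class = "comonod_config_error")
  # unknown keys are fatal
  bad2 <- tempfile(fileext = ".yml")
  writeLines(c("name: bad2", "pathwayz: {}"), bad2)
  expect_error(load_species(bad2), class = "comonod_config_error")
  # own-substrate byproduct is impossible
  expect_error(
    species_model("x", list(pathway("P", "GLU", 0.4, 0.1, 2, 0.2,
                                    Yp = c(GLU = 0.1)))),
    class = "comonod_config_error")
})

test_that("a single-pathway culture reduces to classical Monod kinetics", {
  sp <- mono_species()
  S0 <- 8
  X0 <- 0.05
  # independent oracle: hand-coded Monod batch integrator
  oracle <- deSolve::ode(
    y = c(X = X0, S = S0), times = seq(0, 30, 0.1),
    func = function(t, y, p) {
      mu <- p$mu_max * max(y["S"], 0) / (p$Ks + max(y["S"], 0))
      list(c(mu * y["X"], -mu / p$Yx * y["X"]))
    },
    parms = list(mu_max = 0.4, Ks = 0.1, Yx = 0.2),
    rtol = 1e-10, atol = 1e-12)
  traj <- run_batch(sp, S0 = S0, X0 = X0, t_end = 30, dt = 0.1,
                    dynamic_enzymes = FALSE)
  expect_equal(traj$X_mono, unname(oracle[, "X"]), tolerance = 1e-6)
  expect_equal(traj$GLU, pmax(unname(oracle[, "S"]), 0), tolerance = 1e-5)
  # and the cybernetic weights are trivially 1
  expect_true(all(traj$u_mono_GLU == 1))
  expect_true(all(traj$v_mono_GLU == 1))
})
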