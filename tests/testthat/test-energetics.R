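# Pair potentials, group sums with decomposition, tail averaging.

test_that("LJ pair energy has its analytic zero and minimum", {
  expect_equal(lj_pair_energy(0.34, 0.34, 0.2), 0)
  expect_equal(lj_pair_energy(2^(1 / 6) * 0.34, 0.34, 0.2), -0.2,
               tolerance = 1e-12)
  expect_error(lj_pair_energy(0, 0.3, 0.1), "r must be > 0")
  # random parameters against an independently coded form of the potential
  set.seed(5)
  for (i in 1:50) {
    r <- runif(1, 0.2, 2); s <- runif(1, 0.2, 0.5); e <- runif(1, 0, 1)
    alt <- 4 * e * exp(12 * (log(s) - log(r))) -
      4 * e * exp(6 * (log(s) - log(r)))
    expect_equal(lj_pair_energy(r, s, e), alt, tolerance = 1e-12)
  }
})

test_that("Coulomb energy has the right constant and 1/r scaling", {
  expect_equal(coulomb_pair_energy(1, 1, 1), 138.935458 / 4.184,
               tolerance = 1e-12)
  expect_equal(round(coulomb_pair_energy(1, 1, 1), 3), 33.206)
  expect_equal(coulomb_pair_energy(0.7, 0, 0.5), 0)
  set.seed(6)
  for (i in 1:20) {
    r <- runif(1, 0.1, 3)
    expect_equal(coulomb_pair_energy(2 * r, 1, 1),
                 coulomb_pair_energy(r, 1, 1) / 2, tolerance = 1e-12)
  }
})

make_random_energy_system <- function(seed, n_a = 12, n_b = 18) {
  set.seed(seed)
  top <- topology(
    name = c(rep("CA", n_a), rep("MO", n_b)),
    resid = c(sample(1:4, n_a, replace = TRUE), rep(99L, n_b)),
    resname = c(rep("ALA", n_a), rep("MOS", n_b)),
    element = c(sample(c("C", "N", "O"), n_a, replace = TRUE),
                sample(c("Mo", "S"), n_b, replace = TRUE)),
    charge = round(runif(n_a + n_b, -0.5, 0.5), 3))
  top$lj_type <- top$element
  xyz <- matrix(runif((n_a + n_b) * 3, 0, 1.6), n_a + n_b, 3)
  list(top = top, frame = make_frame(xyz), n_a = n_a, n_b = n_b)
}

brute_energy <- function(sys, params, rc) {
  e_vdw <- e_elec <- 0
  kq <- 138.935458 / 4.184
  for (i in seq_len(sys$n_a)) {
    for (j in sys$n_a + seq_len(sys$n_b)) {
      dv <- sys$frame$xyz[i, ] - sys$frame$xyz[j, ]
      r <- sqrt(sum(dv^2))
      if (r > rc) next
      pi_ <- params$species[[sys$top$lj_type[i]]]
      pj <- params$species[[sys$top$lj_type[j]]]
      s <- (pi_$sigma + pj$sigma) / 2
      e <- sqrt(pi_$epsilon * pj$epsilon)
      e_vdw <- e_vdw + 4 * e * ((s / r)^12 - (s / r)^6)
      e_elec <- e_elec + kq * sys$top$charge[i] * sys$top$charge[j] / r
    }
  }
  list(vdw = e_vdw, elec = e_elec)
}

test_that("group energies match the exhaustive double sum over 100 seeds", {
  params <- read_nonbonded_params()
  for (seed in 1:100) {
    sys <- make_random_energy_system(seed)
    got <- interaction_energy(sys$frame, sys$top, 1:sys$n_a,
                              sys$n_a + 1:sys$n_b, params = params, rc = 1.0)
    want <- brute_energy(sys, params, rc = 1.0)
    expect_equal(got$E_vdw, want$vdw, tolerance = 1e-10)
    expect_equal(got$E_elec, want$elec, tolerance = 1e-10)
  }
})

test_that("per-residue terms partition the totals and the sum is symmetric", {
  params <- read_nonbonded_params()
  sys <- make_random_energy_system(404)
  a <- 1:sys$n_a; b <- sys$n_a + 1:sys$n_b
  e_ab <- interaction_energy(sys$frame, sys$top, a, b, params = params)
  expect_equal(sum(e_ab$per_residue_vdw), e_ab$E_vdw, tolerance = 1e-6)
  expect_equal(sum(e_ab$per_residue_elec), e_ab$E_elec, tolerance = 1e-6)
  e_ba <- interaction_energy(sys$frame, sys$top, b, a, params = params)
  expect_equal(e_ba$E_vdw, e_ab$E_vdw, tolerance = 1e-10)
  expect_equal(e_ba$E_elec, e_ab$E_elec, tolerance = 1e-10)
})

test_that("doubling charges quadruples electrostatics and leaves vdW alone", {
  params <- read_nonbonded_params()
  sys <- make_random_energy_system(77)
  a <- 1:sys$n_a; b <- sys$n_a + 1:sys$n_b
  e1 <- interaction_energy(sys$frame, sys$top, a, b, params = params)
  top2 <- sys$top
  top2$charge <- 2 * top2$charge
  e2 <- interaction_energy(sys$frame, top2, a, b, params = params)
  expect_equal(e2$E_elec, 4 * e1$E_elec, tolerance = 1e-10)
  expect_equal(e2$E_vdw, e1$E_vdw, tolerance = 1e-12)
})

test_that("energies vanish beyond the cutoff and at large gaps", {
  params <- read_nonbonded_params()
  top <- topology(c("CA", "MO"), c(1L, 2L), c("ALA", "MOS"),
                  element = c("C", "Mo"), charge = c(0.3, -0.3))
  far <- make_frame(rbind(c(0, 0, 0), c(0, 0, 1.5)))
  e <- interaction_energy(far, top, 1L, 2L, params = params, rc = 1.0)
  expect_identical(e$E_vdw, 0)
  expect_identical(e$E_elec, 0)
  # whole system at gap = 5 * rc
  sheet <- build_monolayer(lattice_spec(nx = 6L, ny = 4L))
  bundle <- build_ideal_bundle()
  sys <- suppressWarnings(place_protein(bundle, sheet, gap = 5.0))
  st <- sheet_as_structure(sheet)
  full_top <- rbind(as.data.frame(sys$protein$topology),
                    as.data.frame(st$topology))
  class(full_top) <- class(sys$protein$topology)
  fr <- make_frame(rbind(sys$protein$frame$xyz, st$frame$xyz))
  np <- nrow(sys$protein$topology)
  e5 <- interaction_energy(fr, full_top, 1:np, np + 1:nrow(st$topology),
                           params = params, rc = 1.0)
  expect_identical(e5$E_vdw, 0)
  expect_identical(e5$E_elec, 0)
})

test_that("energy series are per-frame consistent and monotone on approach", {
  params <- read_nonbonded_params()
  sheet <- build_monolayer(lattice_spec(nx = 8L, ny = 5L))
  bundle <- build_ideal_bundle()
  gaps <- seq(0.95, 0.55, by = -0.05)
  frames <- lapply(gaps, function(g) {
    sys <- suppressWarnings(place_protein(bundle, sheet, gap = g))
    rbind(sys$protein$frame$xyz, sheet_xyz(sheet))
  })
  st <- sheet_as_structure(sheet)
  full_top <- rbind(as.data.frame(bundle$topology),
                    as.data.frame(st$topology))
  class(full_top) <- class(bundle$topology)
  traj <- trajectory(full_top, frames, seq_along(gaps) * 20)
  np <- nrow(bundle$topology)
  es <- energy_series(traj, 1:np, np + 1:nrow(st$topology), params = params)
  expect_identical(nrow(es$summary), length(gaps))
  # vdW attraction deepens monotonically as the gap closes
  expect_true(all(diff(es$summary$E_vdw) <= 1e-9))
  expect_lt(es$summary$E_vdw[length(gaps)], es$summary$E_vdw[1])
  # per-frame values equal single-frame calls
  e3 <- interaction_energy(traj_frame(traj, 3), full_top, 1:np,
                           np + 1:nrow(st$topology), params = params)
  expect_equal(es$summary$E_vdw[3], e3$E_vdw, tolerance = 1e-12)
  expect_equal(as.numeric(es$per_residue_vdw[3, ]),
               as.numeric(e3$per_residue_vdw), tolerance = 1e-12)
  # a static trajectory gives a constant series
  static <- trajectory(full_top, frames[c(1, 1, 1)], c(0, 20, 40))
  ess <- energy_series(static, 1:np, np + 1:nrow(st$topology),
                       params = params)
  expect_equal(diff(ess$summary$E_vdw), c(0, 0))
})

test_that("tail averages handle constants, boundaries and Gaussian noise", {
  t <- seq(0, 200, by = 2)
  const <- tail_average(t, rep(3.5, length(t)), window_ns = 100)
  expect_equal(const$mean, 3.5)
  expect_equal(const$uncertainty, 0)
  full <- tail_average(t, seq_along(t), window_ns = 200)
  expect_equal(full$mean, mean(seq_along(t)))
  expect_error(tail_average(t, seq_along(t), window_ns = 300), "window")
  # sampling check: mean of iid Gaussians lands within 4 sd/sqrt(n)
  set.seed(8)
  hits <- vapply(1:100, function(i) {
    v <- rnorm(length(t), mean = -10, sd = 2)
    ta <- tail_average(t, v, window_ns = 200)
    abs(ta$mean + 10) <= 4 * 2 / sqrt(length(t))
  }, TRUE)
  expect_gte(mean(hits), 0.99)
})

test_that("favorable-residue filtering equals a comparison oracle", {
  expect_identical(nrow(favorable_residues(c(`1` = 0, `2` = 0))), 0L)
  out <- favorable_residues(c(`42` = -25, `43` = -5))
  expect_identical(out$resid, 42L)
  set.seed(123)
  for (i in 1:20) {
    v <- stats::setNames(runif(30, -40, 5), 1:30)
    got <- favorable_residues(v, threshold = -20)
    want <- sort(v[v < -20])
    expect_identical(got$resid, as.integer(names(want)))
    expect_equal(got$energy, as.numeric(want))
    expect_true(all(diff(got$energy) >= 0))
  }
})
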