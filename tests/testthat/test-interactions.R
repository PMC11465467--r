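# Hamiltonian assembly, unit conversions, trajectories, driven geometry

test_that("empty interaction set assembles to the zero operator", {
  fix <- bare_pair()
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  expect_lt(max(abs(dense_of(H))), 1e-15)
})

test_that("Zeeman splitting matches the closed form from physical constants", {
  fix <- bare_pair(field_mT = c(0, 0, 1))
  H <- dense_of(assemble_hamiltonian(fix$ops, fix$interactions))
  ev <- sort(Re(eigen(H, only.values = TRUE)$values))
  # g mu_B B / hbar for g = 2.0023, B = 1 mT, in rad/us
  expected <- 2.0023 * (9.2740100783e-24 / 1.054571817e-34) * 1e-9
  expect_equal(ev[4] - ev[1], 2 * expected, tolerance = 1e-9)  # |aa> vs |bb>
  expect_equal(max(abs(H - Conj(t(H)))), 0)
})

test_that("isotropic hyperfine gives the two-spin coupling spectrum", {
  fix <- one_nucleus_pair(a_mT = 1)
  H <- dense_of(assemble_hamiltonian(fix$ops, fix$interactions))
  a_rad <- 2 * pi * rpsse:::.mT_to_MHz(1)
  ev <- sort(unique(round(Re(eigen(H, only.values = TRUE)$values) / a_rad, 9)))
  # a S.I for two spins 1/2: triplet a/4, singlet -3a/4
  expect_equal(ev, c(-0.75, 0.25))
})

test_that("exchange convention puts the singlet-triplet gap at 2J", {
  fix <- bare_pair()
  ints <- interaction_set(exchange = exchange_term(twoJ_mT = 6.4))
  H <- dense_of(assemble_hamiltonian(fix$ops, ints))
  st <- rpsse:::.electronic_states()
  gap <- Re(t(Conj(st$S)) %*% H %*% st$S) -
    Re(t(Conj(st$T0)) %*% H %*% st$T0)
  expect_equal(as.numeric(gap), 2 * pi * rpsse:::.mT_to_MHz(6.4),
               tolerance = 1e-12)
  # J and 2J keys agree
  h1 <- assemble_hamiltonian(fix$ops,
                             interaction_set(exchange = exchange_term(J_MHz = 5)))
  h2 <- assemble_hamiltonian(fix$ops,
                             interaction_set(exchange = exchange_term(twoJ_MHz = 10)))
  expect_zspm_equal(h1, h2, 1e-12)
  expect_error(exchange_term(J_MHz = 1, twoJ_MHz = 2), "exactly one")
})

test_that("unit conversions round-trip to 1 part in 1e9", {
  a_mT <- 0.731
  a_MHz <- rpsse:::.mT_to_MHz(a_mT)
  direct <- rpsse:::.mT_to_radus() * a_mT
  via_MHz <- rpsse:::.MHz_to_radus(a_MHz)
  expect_equal(direct, via_MHz, tolerance = 1e-9)
  h1 <- assemble_hamiltonian(one_nucleus_pair(a_mT = a_mT)$ops,
    interaction_set(hyperfine = list(hyperfine_term("H1", a_mT = a_mT))))
  h2 <- assemble_hamiltonian(one_nucleus_pair()$ops,
    interaction_set(hyperfine = list(hyperfine_term("H1", a_MHz = a_MHz))))
  expect_zspm_equal(h1, h2, 1e-9)
})

test_that("assembled Hamiltonians are Hermitian for randomized systems", {
  for (seed in 1:6) {
    fix <- random_small_system(seed)
    H <- assemble_hamiltonian(fix$ops, fix$interactions)
    expect_true(rpsse:::zspm_is_hermitian(H, tol = 1e-9))
  }
})

test_that("dipolar input validation enforces symmetry and zero trace", {
  D <- diag(c(1, 1, -2))
  expect_silent(interaction_set(dipolar = D))
  expect_error(interaction_set(dipolar = diag(c(1, 1, 1))), "traceless")
  Dns <- D; Dns[1, 2] <- 0.5
  expect_error(interaction_set(dipolar = Dns), "symmetric")
  expect_error(
    assemble_hamiltonian(bare_pair()$ops,
      interaction_set(hyperfine = list(hyperfine_term("nope", a_mT = 1)))),
    "undeclared")
})

test_that("trajectory lookup is zero-order hold with hard boundaries", {
  tens <- lapply(1:5, function(i) diag(i * 1.0, 3))
  traj <- trajectory_series(seq(0, 0.2, by = 0.05), list(hf = tens))
  expect_equal(trajectory_value(traj, "hf", 0.05)[1, 1], 2)   # on grid point
  expect_equal(trajectory_value(traj, "hf", 0.07)[1, 1], 2)   # held
  expect_equal(trajectory_value(traj, "hf", 0.2)[1, 1], 5)
  expect_error(trajectory_value(traj, "hf", 0.3), "outside")
  expect_error(trajectory_value(traj, "zz", 0.1), "no series")
})

test_that("time-dependent assembly equals re-assembled static Hamiltonian", {
  sys <- spin_system(data.frame(label = c("N1", "H1"), radical = c(1, 2),
                                I = c(1, 0.5)))
  ops <- build_operators(sys)
  set.seed(8)
  tensors <- lapply(1:9, function(i) matrix(rnorm(9, 0, 5), 3, 3))
  traj <- trajectory_series(seq(0, 4, by = 0.5), list(nhf = tensors))
  ints_dyn <- interaction_set(field_mT = c(0, 0, 0.3),
    hyperfine = list(hyperfine_term("N1", A_MHz = diag(3), dynamic = "nhf"),
                     hyperfine_term("H1", a_mT = 0.2)))
  for (t in c(0, 0.5, 1.7, 3.99, 4)) {
    Ht <- hamiltonian_at_time(ops, ints_dyn, traj, t)
    held <- trajectory_value(traj, "nhf", t)
    ints_sta <- interaction_set(field_mT = c(0, 0, 0.3),
      hyperfine = list(hyperfine_term("N1", A_MHz = held),
                       hyperfine_term("H1", a_mT = 0.2)))
    expect_zspm_equal(Ht, assemble_hamiltonian(ops, ints_sta), 1e-9)
  }
  # constant trajectory reproduces the static assembly exactly
  const <- trajectory_series(c(0, 1), list(nhf = lapply(1:2, function(i) diag(3))))
  ints_const <- interaction_set(field_mT = c(0, 0, 0.3),
    hyperfine = list(hyperfine_term("N1", A_MHz = diag(3)),
                     hyperfine_term("H1", a_mT = 0.2)))
  expect_zspm_equal(hamiltonian_at_time(ops, ints_dyn, const, 0.5),
                    assemble_hamiltonian(ops, ints_const), 1e-12)
})

test_that("trajectory text format round-trips", {
  traj <- generate_fluctuating_tensor(diag(c(-2.6, -2.6, 49.2)), 4, 100,
                                      step_ps = 50, length_ns = 1, seed = 2,
                                      tag = "n5")
  path <- tempfile(fileext = ".tsv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$time_ns, traj$time_ns, tolerance = 1e-9)
  expect_equal(back$tensors$n5, traj$tensors$n5, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(path)
})

test_that("driven geometry follows the exponential distance laws", {
  # static limit
  g0 <- driven_geometry(c(0, 13, 512), v_d_MHz = 0, J0_MHz = 10, k_b0 = 2)
  expect_equal(g0$r_A, rep(17.8, 3))
  expect_equal(g0$J_MHz, rep(10, 3))
  expect_equal(g0$k_b, rep(2, 3))
  # shared exponential factor: J/J0 == k_b/k_b0 at all times
  tt <- seq(0, 400, by = 7)
  g <- driven_geometry(tt, v_d_MHz = 5, J0_MHz = 10, k_b0 = 2)
  expect_equal(g$J_MHz / 10, g$k_b / 2, tolerance = 1e-12)
  # peak-to-peak modulation over one period: exp(beta * delta_d) = e^4.2
  tt <- seq(0, 200, length.out = 4001)             # one period at 5 MHz
  g <- driven_geometry(tt, v_d_MHz = 5, delta_d = 3, beta = 1.4)
  expect_equal(max(g$k_b) / min(g$k_b), exp(1.4 * 3), tolerance = 1e-5)
  expect_equal(max(g$r_A), 17.8, tolerance = 1e-12)
  expect_equal(min(g$r_A), 17.8 - 3, tolerance = 1e-6)
  # period 1/v_d
  expect_equal(g$r_A[1], g$r_A[4001], tolerance = 1e-9)
  expect_error(driven_geometry(0, delta_d = -1), "delta_d")
})
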