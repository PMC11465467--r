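# Exponential-action stepping: dense, Arnoldi and Lanczos paths

test_that("zero generator leaves the state unchanged", {
  psi <- complex(real = rnorm(8), imaginary = rnorm(8))
  om <- rpsse:::zspm_zero(8)
  for (m in c("expm_action", "krylov_arnoldi")) {
    out <- step_state(psi, om, propagator_config(dt_ns = 5, method = m))
    expect_equal(out, psi, tolerance = 1e-14)
  }
})

test_that("Krylov steps match the dense matrix exponential", {
  fix <- random_small_system(5)
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  K <- haberkorn_operator(rate_scheme(k_S = 2, k_T = 0.5), fix$ops)
  om <- effective_generator(H, K)
  psi <- initial_state(fix$ops, "S", sample_su_z(fix$ops$Z, 1, 1))
  dense <- step_state(psi, om, propagator_config(dt_ns = 4,
                                                 method = "expm_action"))
  arn <- step_state(psi, om, propagator_config(dt_ns = 4, eps = 1e-10,
                                               method = "krylov_arnoldi"))
  expect_lt(sqrt(sum(Mod(arn - dense)^2)), 1e-8)
  # Lanczos on the unitary part only
  omu <- effective_generator(H, NULL)
  dense_u <- step_state(psi, omu, propagator_config(dt_ns = 4,
                                                    method = "expm_action"))
  lan <- step_state(psi, omu, propagator_config(dt_ns = 4, eps = 1e-10,
                                                method = "krylov_lanczos"))
  expect_lt(sqrt(sum(Mod(lan - dense_u)^2)), 1e-8)
  # Lanczos refuses a reactive generator and falls back
  expect_warning(step_state(psi, om, propagator_config(dt_ns = 1,
                                                       method = "krylov_lanczos")),
                 "anti-Hermitian")
})

test_that("unitary propagation preserves the norm over many steps", {
  fix <- one_nucleus_pair(a_mT = 1, B_mT = 0.5)
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  om <- effective_generator(H, NULL)
  psi <- initial_state(fix$ops, "S", 1)
  ev <- evolve_state(psi, om, 1000,
                     propagator_config(dt_ns = 1, method = "krylov_arnoldi",
                                       eps = 1e-12))
  expect_lt(max(abs(ev$survival[, 1] - 1)), 1e-10)
})

test_that("field-free symmetric kinetics give the closed-form populations", {
  fix <- one_nucleus_pair(a_mT = 0)
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  K <- haberkorn_operator(rate_scheme(k_S = 0.8, k_T = 0.8), fix$ops)
  om <- effective_generator(H, K)
  psi <- initial_state(fix$ops, "S", 1)
  ev <- evolve_state(psi, om, 500, propagator_config(dt_ns = 2),
                     observables = fix$ops$P)
  t_us <- ev$time_ns / 1000
  expect_lt(max(abs(ev$pops[, "S", 1] - exp(-0.8 * t_us))), 1e-6)
  expect_lt(max(abs(ev$pops[, "T0", 1])), 1e-12)
})

test_that("coherent singlet-triplet oscillation matches the dense oracle", {
  fix <- one_nucleus_pair(a_mT = 1)
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  om <- effective_generator(H, NULL)
  psi0 <- matrix(vapply(1:fix$ops$Z,
                        function(j) initial_state(fix$ops, "S", j),
                        complex(fix$ops$dim)), ncol = fix$ops$Z)
  ev <- evolve_state(psi0, om, 200, propagator_config(dt_ns = 1),
                     observables = fix$ops$P)
  p_sse <- rowMeans(ev$pops[, "S", ])
  ref <- dense_trajectory(fix$ops, fix$interactions, rate_scheme(), "S",
                          times_ns = ev$time_ns)
  expect_lt(max(abs(p_sse - ref$p_S)), 1e-6)
  # the two-spin oscillation revisits p_S = 1 with angular frequency a
  a_rad <- 2 * pi * rpsse:::.mT_to_MHz(1)
  period_ns <- 2 * pi / a_rad * 1000
  idx <- which.min(abs(ev$time_ns - period_ns))
  expect_gt(p_sse[idx], 0.99)
})

test_that("step halving shows the expected Magnus convergence orders", {
  # start-of-step hold is globally first order (Richardson ratio ~ 2);
  # midpoint evaluation is second order (ratio ~ 4).  A static generator is
  # exact in dt, so the check needs a genuinely time-dependent one.
  b <- builtin_system("driven_n5")
  ops <- build_operators(b$system)
  p <- b$params; p$v_d_MHz <- 20
  run <- function(dt, ev) {
    driven_yield(ops, b$interactions, p, theta_deg = 30, T_ns = 400,
                 config = propagator_config(dt_ns = dt,
                                            time_eval = ev))$phi[["S"]]
  }
  y <- vapply(c(0.5, 0.25, 0.125), run, numeric(1), ev = "start")
  ratio <- (y[1] - y[2]) / (y[2] - y[3])
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
  # midpoint evaluation is higher order: at equal step it beats the hold
  # rule by a large factor (reference: Richardson limit of the hold rule)
  ref <- y[3] + (y[3] - y[2])            # extrapolated dt -> 0 value
  ym <- run(0.5, "midpoint")
  expect_lt(abs(ym - ref), abs(y[1] - ref) / 5)
})

test_that("symmetric-rate evolution factorizes into decay times unitary", {
  fix <- random_small_system(3)
  H <- assemble_hamiltonian(fix$ops, fix$interactions)
  k <- 1.3
  psi <- initial_state(fix$ops, "S", sample_su_z(fix$ops$Z, 2, 1))
  cfg <- propagator_config(dt_ns = 2)
  omK <- effective_generator(H, haberkorn_operator(rate_scheme(k_S = k, k_T = k),
                                                   fix$ops))
  om0 <- effective_generator(H, NULL)
  evK <- evolve_state(psi, omK, 250, cfg, observables = fix$ops$P)
  ev0 <- evolve_state(psi, om0, 250, cfg, observables = fix$ops$P)
  w <- exp(-k * ev0$time_ns / 1000)
  expect_lt(max(abs(evK$pops[, "S", 1] - w * ev0$pops[, "S", 1])), 1e-8)
})

test_that("uniform-grid quadrature integrates smooth functions accurately", {
  h <- 0.01
  x <- seq(0, 2, by = h)
  expect_equal(rpsse:::quad_uniform(exp(-x), h), 1 - exp(-2),
               tolerance = 1e-9)
  expect_equal(rpsse:::quad_uniform(sin(3 * x), h), (1 - cos(6)) / 3,
               tolerance = 1e-8)
  # odd number of intervals handled
  x2 <- seq(0, 2 - h, by = h)
  expect_equal(rpsse:::quad_uniform(exp(-x2), h), 1 - exp(-(2 - h)),
               tolerance = 1e-7)
})
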