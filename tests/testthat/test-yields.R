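# Quantum yields: direct, stochastic, tail correction, scans, anisotropy

test_that("a field-free singlet-born pair reacts only through the singlet", {
  fix <- one_nucleus_pair(a_mT = 0)
  y <- yield_direct(fix$ops, fix$interactions, rate_scheme(k_S = 1), "S",
                    T_ns = 8000, config = propagator_config(dt_ns = 4),
                    correction = "off")
  expect_equal(y$phi[["S"]], 1, tolerance = 1e-3)
  expect_equal(y$phi[["T0"]], 0)
  expect_equal(y$phi[["Tp"]], 0)
})

test_that("direct yields match the dense Liouville oracle", {
  fix <- one_nucleus_pair(a_mT = 1)
  rates <- rate_scheme(k_S = 1, k_T = 1)
  yd <- yield_direct(fix$ops, fix$interactions, rates, "S", T_ns = 3000,
                     config = propagator_config(dt_ns = 0.25))
  yo <- dense_yield(fix$ops, fix$interactions, rates, "S", T_ns = 3000)
  expect_lt(max(abs(yd$phi - yo$phi)), 1e-6)
})

test_that("stochastic yields agree with direct within Monte-Carlo error", {
  sys <- spin_system(data.frame(label = paste0("H", 1:4),
                                radical = c(1, 1, 2, 2), I = rep(0.5, 4)))
  ops <- build_operators(sys)
  ints <- interaction_set(field_mT = c(0, 0, 0.5),
    hyperfine = list(hyperfine_term("H1", a_mT = 0.4),
                     hyperfine_term("H2", a_mT = -0.2),
                     hyperfine_term("H3", a_mT = 0.3),
                     hyperfine_term("H4", a_mT = 0.15)))
  rates <- rate_scheme(k_S = 1, k_T = 1)
  cfg <- propagator_config(dt_ns = 1)
  yd <- yield_direct(ops, ints, rates, "S", T_ns = 2000, config = cfg)
  ys <- yield_stochastic(ops, ints, rates, "S", T_ns = 2000, M = 10,
                         seed = 7, config = cfg)
  expect_lt(abs(ys$phi[["S"]] - yd$phi[["S"]]), 3 * ys$stderr[["S"]])
  expect_warning(
    yield_stochastic(ops, ints, rates, "S", T_ns = 100, M = 20, seed = 1,
                     config = propagator_config(dt_ns = 4)),
    "exceeds the nuclear dimension")
})

test_that("stochastic sampling is unbiased across many independent seeds", {
  sys <- spin_system(data.frame(label = c("H1", "H2", "H3"),
                                radical = c(1, 1, 2), I = rep(0.5, 3)))
  ops <- build_operators(sys)
  ints <- interaction_set(field_mT = c(0, 0, 0.3),
    hyperfine = list(hyperfine_term("H1", a_mT = 0.5),
                     hyperfine_term("H2", a_mT = 0.2),
                     hyperfine_term("H3", a_mT = -0.3)))
  rates <- rate_scheme(k_S = 1, k_T = 1)
  cfg <- propagator_config(dt_ns = 2)
  yd <- yield_direct(ops, ints, rates, "S", T_ns = 1000, config = cfg)
  ests <- vapply(1:50, function(r)
    yield_stochastic(ops, ints, rates, "S", T_ns = 1000, M = 4,
                     seed = 101 + 13 * r, config = cfg)$phi[["S"]],
    numeric(1))
  pooled_se <- stats::sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - yd$phi[["S"]]), 3 * pooled_se)
})

test_that("tail correction is exact for constant populations", {
  for (T_ns in c(50, 500, 3000)) {
    tt <- seq(0, T_ns, by = 1)
    expect_equal(corrected_yield(rep(0.4, length(tt)), tt, k_sym = 1), 0.4,
                 tolerance = 1e-9)
  }
})

test_that("corrected short-time estimate matches the long uncorrected one", {
  fix <- one_nucleus_pair(a_mT = 1)
  k <- 1
  om <- effective_generator(assemble_hamiltonian(fix$ops, fix$interactions),
                            NULL)
  psi0 <- matrix(vapply(1:fix$ops$Z,
                        function(j) initial_state(fix$ops, "S", j),
                        complex(fix$ops$dim)), ncol = fix$ops$Z)
  cfg <- propagator_config(dt_ns = 0.5)
  ev <- evolve_state(psi0, om, 32000, cfg, observables = fix$ops$P)
  p <- rowMeans(ev$pops[, "S", ])
  n_short <- 2000                                   # T = 1/k
  corr_short <- corrected_yield(p[1:(n_short + 1)],
                                ev$time_ns[1:(n_short + 1)], k)
  t_us <- ev$time_ns / 1000
  n10 <- 20001                                      # T = 10/k
  uncorr_long <- rpsse:::quad_uniform(k * exp(-k * t_us[1:n10]) * p[1:n10],
                                      0.5 / 1000)
  expect_lt(abs(corr_short - uncorr_long), 1e-3)
  # corrected and uncorrected converge to the same value at large T (16/k)
  corr_T <- corrected_yield(p, ev$time_ns, k)
  uncorr_T <- rpsse:::quad_uniform(k * exp(-k * t_us) * p, 0.5 / 1000)
  expect_lt(abs(corr_T - uncorr_T), 1e-6)
})

test_that("corrected yields conserve probability for symmetric rates", {
  for (seed in c(1, 4)) {
    fix <- random_small_system(seed)
    y <- yield_direct(fix$ops, fix$interactions,
                      rate_scheme(k_S = 1, k_T = 1), "S", T_ns = 2000,
                      config = propagator_config(dt_ns = 1))
    expect_lt(abs(sum(y$phi) - 1), 1e-4)
  }
})

test_that("relative yield is 1 at zero field and at zero observation time", {
  b <- builtin_system("wire_toy")
  ops <- build_operators(b$system)
  expect_equal(relative_yield(ops, b$interactions, b$rates, 0, 50), 1,
               tolerance = 1e-12)
  expect_equal(relative_yield(ops, b$interactions, b$rates, 5, 0), 1)
  r <- relative_yield(ops, b$interactions, b$rates, 6.4, 50)
  expect_lt(r, 1)          # resonant loss of radical pairs
})

test_that("anisotropy chi is a signed normalized difference", {
  expect_equal(anisotropy_chi(0.3, 0.3), 0)
  expect_equal(anisotropy_chi(0.4, 0.2), -anisotropy_chi(0.2, 0.4))
  expect_error(anisotropy_chi(0, 0), "zero")
  expect_error(anisotropy_chi(-0.1, 0.2), "non-negative")
})

test_that("isotropic systems give orientation-independent yields", {
  sys <- spin_system(data.frame(label = c("H1", "H2"), radical = c(1, 2),
                                I = c(0.5, 0.5)))
  ops <- build_operators(sys)
  ints <- interaction_set(field_mT = c(0, 0, 0.5),
    hyperfine = list(hyperfine_term("H1", a_mT = 0.5),
                     hyperfine_term("H2", a_mT = 0.3)))
  rates <- rate_scheme(k_S = 1, k_T = 1)
  sc <- orientation_scan(ops, ints, rates, seq(0, 180, by = 45),
                         T_ns = 500, config = propagator_config(dt_ns = 2))
  expect_lt(scan_amplitude(sc), 1e-10)
})

test_that("z-x-plane scans are symmetric about theta = 90 degrees", {
  sys <- spin_system(data.frame(label = "N1", radical = 1, I = 1))
  ops <- build_operators(sys)
  ints <- interaction_set(field_mT = c(0, 0, 0.5),
    hyperfine = list(hyperfine_term("N1", A_MHz = diag(c(-2.6, -2.6, 49.2)))))
  rates <- rate_scheme(k_S = 1, k_T = 1)
  th <- c(30, 150)                     # theta and 180 - theta
  sc <- orientation_scan(ops, ints, rates, th, T_ns = 1000,
                         config = propagator_config(dt_ns = 1))
  expect_equal(sc$phi_S[1], sc$phi_S[2], tolerance = 1e-8)
})

test_that("electron-electron coupling attenuates the orientation contrast", {
  # anisotropic pair with and without exchange+dipolar coupling
  sys <- spin_system(data.frame(label = c("N1", "H1"), radical = c(1, 2),
                                I = c(1, 0.5)))
  ops <- build_operators(sys)
  hfs <- list(hyperfine_term("N1", A_MHz = diag(c(-2.6, -2.6, 49.2))),
              hyperfine_term("H1", a_mT = 0.3))
  rates <- rate_scheme(k_S = 1, k_T = 1)
  th <- seq(0, 180, by = 30)
  cfg <- propagator_config(dt_ns = 1)
  free <- orientation_scan(ops,
    interaction_set(field_mT = c(0, 0, 0.05), hyperfine = hfs),
    rates, th, T_ns = 2000, config = cfg)
  coupled <- orientation_scan(ops,
    interaction_set(field_mT = c(0, 0, 0.05), hyperfine = hfs,
                    exchange = exchange_term(J_MHz = 5),
                    dipolar = diag(c(5, 5, -10))),
    rates, th, T_ns = 2000, config = cfg)
  expect_lt(scan_amplitude(coupled), scan_amplitude(free))
})
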