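# Quantum yields of spin-selective radical-pair reactions.
#
# The yield of electronic channel Theta is
#   Phi_Theta = int_0^T k_Theta(t) <P_Theta>(t) dt
# with <P_Theta>(t) averaged over the initial nuclear configuration:
# either exactly, propagating all Z nuclear basis states (direct method),
# or by Monte-Carlo trace sampling with M SU(Z) coherent states
# (stochastic method).  For a time-independent symmetric rate
# k_sym = k_S = k_T the survival factor exp(-k_sym t) factorizes out of the
# spin dynamics, and because the reaction-free population p(t) is
# quasi-stationary on the 1/k_sym scale the missing tail of the yield
# integral is, to excellent accuracy, a geometric completion:
#   Phi(inf) ~ [int_0^T k e^(-kt) p(t) dt] / (1 - e^(-k T)).
# The completion is exact for constant p at any T and lets T be of order
# 1/k_sym instead of the ~ 6/k_sym a plain truncation needs for comparable
# accuracy.

# ---- generator construction ---------------------------------------------

# Build the propagation generator for a system.  Returns either a static
# zspm/dense matrix or a function of time (ns).  Dense precomputation is
# used below dense_cap for speed.
#' @keywords internal
make_generator <- function(ops, interactions, rates, trajectory = NULL,
                           config = propagator_config()) {
  terms <- hamiltonian_terms(ops, interactions)
  has_dyn_h <- length(terms$dynamic) > 0
  if (has_dyn_h && is.null(trajectory))
    stop("interaction set has dynamic tags but no trajectory was supplied")
  time_dep <- has_dyn_h || rates$time_dependent
  dense <- ops$dim <= config$dense_cap
  if (!time_dep) {
    H <- assemble_hamiltonian(ops, interactions)
    K <- haberkorn_operator(rates, ops)
    return(effective_generator(H, K))
  }
  if (dense) {
    Hs <- zspm_dense(terms$static)
    dyn <- lapply(terms$dynamic, function(d)
      lapply(d$ops, zspm_dense))
    Pd <- lapply(ops$P, zspm_dense)
    Id <- diag(1 + 0i, ops$dim)
    function(t_ns) {
      H <- Hs
      for (tag in names(dyn)) {
        vals <- as.vector(t(trajectory_value(trajectory, tag, t_ns)))
        for (j in seq_along(vals))
          if (vals[j] != 0)
            H <- H + .MHz_to_radus(vals[j]) * dyn[[tag]][[j]]
      }
      k <- rates_at(rates, t_ns)
      K <- matrix(0 + 0i, ops$dim, ops$dim)
      for (nm in names(k)) if (k[[nm]] != 0) K <- K + (k[[nm]] / 2) * Pd[[nm]]
      -1i * H - K
    }
  } else {
    function(t_ns) {
      H <- terms$static
      for (tag in names(terms$dynamic)) {
        d <- terms$dynamic[[tag]]
        vals <- as.vector(t(trajectory_value(trajectory, tag, t_ns)))
        for (j in seq_along(vals))
          if (vals[j] != 0)
            H <- zspm_add(H, zspm_scale(d$ops[[j]], .MHz_to_radus(vals[j])))
      }
      effective_generator(H, haberkorn_operator(rates, ops, t_ns))
    }
  }
}

# ---- yield containers ----------------------------------------------------

new_yield_result <- function(phi, stderr = rep(NA_real_, 4), meta = list()) {
  names(phi) <- c("S", "T0", "Tp", "Tm")
  names(stderr) <- names(phi)
  structure(list(phi = phi, stderr = stderr, meta = meta),
            class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("Quantum yields (%s method, T = %g ns, dt = %g ns)\n",
              x$meta$mode %||% "?", x$meta$T_ns %||% NA,
              x$meta$dt_ns %||% NA))
  for (nm in names(x$phi)) {
    if (is.na(x$stderr[[nm]]))
      cat(sprintf("  Phi_%-3s = %.6f\n", nm, x$phi[[nm]]))
    else
      cat(sprintf("  Phi_%-3s = %.6f (se %.2g)\n", nm, x$phi[[nm]],
                  x$stderr[[nm]]))
  }
  if (!is.null(x$meta$M)) cat(sprintf("  M = %d samples\n", x$meta$M))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# integrate per-state yields from recorded populations
# pops: array (steps+1) x 4 x ncols ; returns ncols x 4 matrix
.integrate_yields <- function(pops, time_ns, rates, correction,
                              channel_rates = NULL) {
  h_us <- diff(time_ns[1:2]) / 1000
  nsteps <- length(time_ns)
  kmat <- if (is.null(channel_rates)) {
    t(vapply(time_ns, function(t) rates_at(rates, t), numeric(4)))
  } else {
    t(vapply(time_ns, channel_rates, numeric(4)))
  }
  symmetric <- is_symmetric_scheme(rates) && is.null(channel_rates)
  k_sym <- if (symmetric) kmat[1, 1] else NA_real_
  T_us <- (time_ns[nsteps] - time_ns[1]) / 1000
  ncols <- dim(pops)[3]
  out <- matrix(NA_real_, ncols, 4)
  for (j in seq_len(ncols)) {
    for (o in 1:4) {
      y <- kmat[, o] * pops[, o, j]
      phi <- quad_uniform(y, h_us)
      if (symmetric && correction && k_sym > 0)
        phi <- phi / (1 - exp(-k_sym * T_us))
      out[j, o] <- phi
    }
  }
  colnames(out) <- c("S", "T0", "Tp", "Tm")
  out
}

# ---- direct method -------------------------------------------------------

#' Quantum yields by the direct method
#'
#' Propagates all Z nuclear basis states under the stochastic Schrodinger
#' equation and evaluates the trace exactly:
#' Phi_Theta = k_Theta int (1/Z) sum_M <Theta,M;t|P_Theta|Theta,M;t> dt
#' (composite quadrature on the step grid).  With symmetric
#' time-independent rates the tail correction is applied by default, making
#' the result essentially independent of the truncation time once T covers
#' a few oscillation periods.
#'
#' @param ops \code{operator_set}.
#' @param interactions \code{interaction_set}.
#' @param rates \code{rate_scheme}.
#' @param electronic initial electronic state, "S", "T0", "Tp" or "Tm".
#' @param T_ns integration time (ns).
#' @param config \code{propagator_config}.
#' @param trajectory optional \code{trajectory_series} for dynamic tags.
#' @param correction apply the symmetric-rate tail correction ("auto": yes
#'   whenever the scheme is symmetric and time-independent).
#' @param channel_rates optional function(t_ns) -> numeric(4) replacing the
#'   scheme rates in the yield integrand (channel-resolved yields for
#'   schemes where a state reacts through several channels).
#' @param z_cap refuse direct propagation above this nuclear dimension.
#' @return \code{yield_result}.
#' @export
yield_direct <- function(ops, interactions, rates, electronic = "S",
                         T_ns = 1000, config = propagator_config(),
                         trajectory = NULL, correction = c("auto", "on", "off"),
                         channel_rates = NULL, z_cap = 4096) {
  correction <- match.arg(correction)
  if (ops$Z > z_cap)
    stop("nuclear dimension Z = ", ops$Z, " exceeds the direct-method cap; ",
         "use yield_stochastic()")
  gen <- make_generator(ops, interactions, rates, trajectory, config)
  psi0 <- vapply(seq_len(ops$Z),
                 function(j) initial_state(ops, electronic, j),
                 complex(ops$dim))
  psi0 <- matrix(psi0, nrow = ops$dim)
  n_steps <- round(T_ns / config$dt_ns)
  ev <- evolve_state(psi0, gen, n_steps, config, observables = ops$P)
  do_corr <- correction == "on" ||
    (correction == "auto" && is_symmetric_scheme(rates))
  per_state <- .integrate_yields(ev$pops, ev$time_ns, rates, do_corr,
                                 channel_rates)
  phi <- colMeans(per_state)
  new_yield_result(phi, meta = list(mode = "direct", T_ns = T_ns,
                                    dt_ns = config$dt_ns, Z = ops$Z,
                                    corrected = do_corr,
                                    electronic = electronic))
}

# ---- stochastic method ---------------------------------------------------

#' Quantum yields by SU(Z) trace sampling
#'
#' Monte-Carlo estimate of the nuclear trace: M initial states
#' |Theta_init> (x) |Z_m> with Z_m uniform on the complex unit hypersphere.
#' The estimator averages the per-sample yields (the SU(Z) resolution of the
#' identity makes each sample unbiased) and reports their sample standard
#' error.  Sampling is counter-based, so sample m is reproducible
#' independently of M.
#'
#' @inheritParams yield_direct
#' @param M number of SU(Z) samples.
#' @param seed base seed for the sampler.
#' @return \code{yield_result} with per-state standard errors (NA at M = 1).
#' @export
yield_stochastic <- function(ops, interactions, rates, electronic = "S",
                             T_ns = 1000, M = 10, seed = 1,
                             config = propagator_config(),
                             trajectory = NULL,
                             correction = c("auto", "on", "off"),
                             channel_rates = NULL) {
  correction <- match.arg(correction)
  if (M < 1) stop("M must be >= 1")
  if (M > ops$Z)
    warning("M = ", M, " exceeds the nuclear dimension Z = ", ops$Z,
            ": trace sampling brings no gain over the direct method here")
  gen <- make_generator(ops, interactions, rates, trajectory, config)
  psi0 <- vapply(seq_len(M), function(m)
    initial_state(ops, electronic, sample_su_z(ops$Z, seed, m)),
    complex(ops$dim))
  psi0 <- matrix(psi0, nrow = ops$dim)
  n_steps <- round(T_ns / config$dt_ns)
  ev <- evolve_state(psi0, gen, n_steps, config, observables = ops$P)
  do_corr <- correction == "on" ||
    (correction == "auto" && is_symmetric_scheme(rates))
  per_sample <- .integrate_yields(ev$pops, ev$time_ns, rates, do_corr,
                                  channel_rates)
  phi <- colMeans(per_sample)
  se <- if (M > 1) apply(per_sample, 2, stats::sd) / sqrt(M)
        else rep(NA_real_, 4)
  new_yield_result(phi, se, meta = list(mode = "stochastic", T_ns = T_ns,
                                        dt_ns = config$dt_ns, Z = ops$Z,
                                        M = M, seed = seed,
                                        corrected = do_corr,
                                        electronic = electronic,
                                        per_sample = per_sample))
}

# ---- tail-corrected yield from a reaction-free population series ---------

#' Tail-corrected yield for symmetric rates
#'
#' Given the reaction-free (unitary) population p(t) = <P_Theta>(t) sampled
#' on [0, T] and a symmetric rate k_sym, estimates the infinite-time yield
#'   Phi ~ [k_sym int_0^T e^(-k_sym t) p(t) dt] / (1 - e^(-k_sym T)).
#' The completion factor extends the exponentially weighted average of p
#' over [0, T] to the whole time axis; it is exact for constant p at any T,
#' and for oscillatory p its error decays as e^(-k_sym T) times the residual
#' phase imbalance, so a truncation time of order 1/k_sym already gives
#' accuracy that a plain truncated integral only reaches near 6/k_sym.
#'
#' @param p population series (unitary evolution, reaction excluded).
#' @param time_ns uniform sample times (ns) matching \code{p}.
#' @param k_sym symmetric rate constant (1/us, > 0); the correction is only
#'   valid when k_S = k_T.
#' @return yield estimate.
#' @export
corrected_yield <- function(p, time_ns, k_sym) {
  if (length(p) != length(time_ns)) stop("p and time_ns lengths differ")
  if (k_sym <= 0) stop("k_sym must be > 0")
  t_us <- time_ns / 1000
  h_us <- diff(t_us[1:2])
  if (length(time_ns) > 2 &&
      max(abs(diff(t_us) - h_us)) > 1e-9 * h_us)
    stop("time grid must be uniform")
  integ <- quad_uniform(k_sym * exp(-k_sym * t_us) * p, h_us)
  integ / (1 - exp(-k_sym * (t_us[length(t_us)] - t_us[1])))
}

# ---- survival-based relative yield (MARY-type scans) ---------------------

# mean radical-pair survival probability Tr rho(t) at a single time
.survival_at <- function(ops, interactions, rates, electronic, t_obs_ns,
                         config, mode = "direct", M = 1, seed = 1) {
  gen <- make_generator(ops, interactions, rates, NULL, config)
  cols <- if (mode == "direct") {
    vapply(seq_len(ops$Z), function(j) initial_state(ops, electronic, j),
           complex(ops$dim))
  } else {
    vapply(seq_len(M), function(m)
      initial_state(ops, electronic, sample_su_z(ops$Z, seed, m)),
      complex(ops$dim))
  }
  psi0 <- matrix(cols, nrow = ops$dim)
  n_steps <- max(1, round(t_obs_ns / config$dt_ns))
  cfg <- config
  cfg$dt_ns <- t_obs_ns / n_steps
  ev <- evolve_state(psi0, gen, n_steps, cfg)
  mean(ev$survival[n_steps + 1, ])
}

#' Relative radical-pair yield at a fixed observation time
#'
#' Phi_RP(B, t) / Phi_RP(0, t): the surviving radical-pair population
#' (both electronic manifolds) at time t under field strength B, normalized
#' by its zero-field value.  The dip of this quantity as a function of B
#' locates the 2J resonance of an exchange-coupled pair.
#'
#' @param ops,interactions,rates system pieces; the field direction stored
#'   in \code{interactions} is kept, only its magnitude is set to B.
#' @param B_mT field strength (mT).
#' @param t_obs_ns observation time (ns, > 0 unless exactly 0 for the
#'   trivial ratio 1).
#' @param electronic initial electronic state.
#' @param config \code{propagator_config}.
#' @return ratio Phi_RP(B, t) / Phi_RP(0, t).
#' @export
relative_yield <- function(ops, interactions, rates, B_mT, t_obs_ns,
                           electronic = "S", config = propagator_config()) {
  if (t_obs_ns < 0) stop("t_obs_ns must be >= 0")
  if (t_obs_ns == 0) return(1)
  dir <- interactions$field_mT
  if (sum(dir^2) == 0) dir <- c(0, 0, 1)
  dir <- dir / sqrt(sum(dir^2))
  int_B <- interactions; int_B$field_mT <- B_mT * dir
  int_0 <- interactions; int_0$field_mT <- c(0, 0, 0)
  s_B <- .survival_at(ops, int_B, rates, electronic, t_obs_ns, config)
  s_0 <- .survival_at(ops, int_0, rates, electronic, t_obs_ns, config)
  s_B / s_0
}

#' Field-strength scan of the relative radical-pair yield
#'
#' @inheritParams relative_yield
#' @param B_grid_mT strictly increasing field strengths (mT).
#' @return \code{scan_result} with columns \code{B_mT}, \code{rel_yield};
#'   the grid argmin and grid resolution are stored as attributes and
#'   reported by \code{print}.
#' @export
field_scan <- function(ops, interactions, rates, B_grid_mT, t_obs_ns,
                       electronic = "S", config = propagator_config()) {
  if (any(diff(B_grid_mT) <= 0)) stop("B grid must be strictly increasing")
  dir <- interactions$field_mT
  if (sum(dir^2) == 0) dir <- c(0, 0, 1)
  dir <- dir / sqrt(sum(dir^2))
  int_0 <- interactions; int_0$field_mT <- c(0, 0, 0)
  s_0 <- .survival_at(ops, int_0, rates, electronic, t_obs_ns, config)
  rel <- vapply(B_grid_mT, function(B) {
    int_B <- interactions; int_B$field_mT <- B * dir
    .survival_at(ops, int_B, rates, electronic, t_obs_ns, config) / s_0
  }, numeric(1))
  df <- data.frame(B_mT = B_grid_mT, rel_yield = rel)
  res <- if (length(B_grid_mT) > 1) stats::median(diff(B_grid_mT)) else NA
  structure(df, class = c("scan_result", "data.frame"),
            axis = "B_mT", value = "rel_yield",
            argmin = B_grid_mT[which.min(rel)], grid_resolution = res)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("Scan over %s (%d points)\n", attr(x, "axis"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...\n")
  if (!is.null(attr(x, "argmin")))
    cat(sprintf("grid argmin of %s: %s = %g (grid resolution %g)\n",
                attr(x, "value"), attr(x, "axis"), attr(x, "argmin"),
                attr(x, "grid_resolution")))
  invisible(x)
}

#' @export
plot.scan_result <- function(x, ...) {
  ax <- attr(x, "axis"); val <- attr(x, "value")
  graphics::plot(x[[ax]], x[[val]], type = "b", xlab = ax, ylab = val, ...)
  invisible(x)
}

# ---- anisotropy ----------------------------------------------------------

#' Relative anisotropy of the singlet yield
#'
#' chi = (Phi_par - Phi_perp) / mean(Phi_par, Phi_perp): the normalized
#' difference of the yields for a field parallel and perpendicular to the
#' reference (hyperfine z) axis.  chi = 0 exactly when the two yields are
#' equal, and swapping the arguments flips its sign.
#'
#' @param phi_par,phi_perp singlet yields for parallel/perpendicular field.
#' @export
anisotropy_chi <- function(phi_par, phi_perp) {
  if (phi_par < 0 || phi_perp < 0) stop("yields must be non-negative")
  m <- (phi_par + phi_perp) / 2
  if (m == 0) stop("both yields are zero; anisotropy undefined")
  (phi_par - phi_perp) / m
}

# ---- orientation scan ----------------------------------------------------

#' Singlet yield versus magnetic field direction
#'
#' Rotates the field in the molecular z-x plane (theta measured from the
#' z-axis) with all tensors fixed and computes the quantum yields at each
#' angle, by the direct or the stochastic method.
#'
#' @inheritParams yield_direct
#' @param theta_deg angles in degrees.
#' @param B_mT field magnitude; default: magnitude stored in
#'   \code{interactions}.
#' @param mode "direct" or "stochastic".
#' @param M,seed trace-sampling settings (stochastic mode).
#' @return \code{scan_result} with columns \code{theta_deg}, \code{phi_S},
#'   \code{phi_T0}, \code{phi_Tp}, \code{phi_Tm} (and \code{stderr_S} etc.
#'   in stochastic mode).
#' @export
orientation_scan <- function(ops, interactions, rates, theta_deg,
                             electronic = "S", T_ns = 1000,
                             mode = c("direct", "stochastic"), M = 5,
                             seed = 1, B_mT = NULL,
                             config = propagator_config(),
                             trajectory = NULL) {
  mode <- match.arg(mode)
  rows <- lapply(theta_deg, function(th) {
    ints <- set_field_direction(interactions, th, B_mT)
    yr <- if (mode == "direct")
      yield_direct(ops, ints, rates, electronic, T_ns, config, trajectory)
    else
      yield_stochastic(ops, ints, rates, electronic, T_ns, M, seed, config,
                       trajectory)
    c(theta_deg = th, phi_S = unname(yr$phi["S"]),
      phi_T0 = unname(yr$phi["T0"]), phi_Tp = unname(yr$phi["Tp"]),
      phi_Tm = unname(yr$phi["Tm"]),
      stderr_S = unname(yr$stderr["S"]), stderr_T0 = unname(yr$stderr["T0"]),
      stderr_Tp = unname(yr$stderr["Tp"]), stderr_Tm = unname(yr$stderr["Tm"]))
  })
  df <- as.data.frame(do.call(rbind, rows))
  if (mode == "direct") df <- df[, 1:5]
  structure(df, class = c("scan_result", "data.frame"),
            axis = "theta_deg", value = "phi_S",
            argmin = df$theta_deg[which.min(df$phi_S)],
            grid_resolution = if (length(theta_deg) > 1)
              stats::median(diff(theta_deg)) else NA)
}

#' Peak-to-peak amplitude of a scan
#'
#' max - min of the scanned value column; the standard summary of how
#' anisotropic (or field-sensitive) a yield curve is.
#'
#' @param scan a \code{scan_result}.
#' @param column value column; default: the scan's primary value.
#' @export
scan_amplitude <- function(scan, column = NULL) {
  if (is.null(column)) column <- attr(scan, "value")
  v <- scan[[column]]
  max(v) - min(v)
}

# ---- driven radical pair -------------------------------------------------

#' Singlet recombination yield of the harmonically driven radical pair
#'
#' One nitrogen-like nucleus, time-dependent exchange J(t) and singlet
#' recombination rate k_b(t) following the exponential distance laws of the
#' driven geometry, a uniform forward rate k_f on all four states, and a
#' static field of magnitude B at angle theta from the hyperfine z-axis.
#' The reported singlet yield is the backward-recombination channel
#' Phi_S = int k_b(t) <P_S>(t) dt.
#'
#' @param ops,interactions system with the static parts (field magnitude
#'   and direction are overridden by \code{theta_deg}/\code{B_mT}).
#' @param params driven-geometry parameters: list with r0, delta_d,
#'   v_d_MHz, beta, J0_MHz, k_b0, k_f.
#' @param theta_deg field angle from the z-axis (z-x plane).
#' @param B_mT field magnitude (mT).
#' @param T_ns integration time (ns).
#' @param electronic initial electronic state.
#' @param config \code{propagator_config}.
#' @return \code{yield_result} (phi["S"] is the recombination-channel yield).
#' @export
driven_yield <- function(ops, interactions, params, theta_deg = 0,
                         B_mT = 0.05, T_ns = 10000, electronic = "S",
                         config = propagator_config(dt_ns = 0.5)) {
  ints <- set_field_direction(interactions, theta_deg, B_mT)
  ints$exchange <- NULL                     # J(t) handled below
  kb_fun <- function(t_ns)
    driven_geometry(t_ns, r0 = params$r0, delta_d = params$delta_d,
                    v_d_MHz = params$v_d_MHz, beta = params$beta,
                    J0_MHz = params$J0_MHz, k_b0 = params$k_b0)$k_b
  rates <- rate_scheme(k_S = kb_fun, k_f = params$k_f)
  # dense precomputation: static H, exchange basis operator, projectors
  Hs <- zspm_dense(assemble_hamiltonian(ops, ints))
  opJ <- zspm_dense(zspm_add(zspm_scale(.dot_product(ops$S[[1]], ops$S[[2]]), 2),
                             zspm_scale(ops$identity, 0.5)))
  Pd <- lapply(ops$P, zspm_dense)
  Id <- diag(1 + 0i, ops$dim)
  kf <- params$k_f
  gen <- function(t_ns) {
    g <- driven_geometry(t_ns, r0 = params$r0, delta_d = params$delta_d,
                         v_d_MHz = params$v_d_MHz, beta = params$beta,
                         J0_MHz = params$J0_MHz, k_b0 = params$k_b0)
    H <- Hs - .MHz_to_radus(g$J_MHz) * opJ
    K <- (kf / 2) * Id + (g$k_b / 2) * Pd$S
    -1i * H - K
  }
  psi0 <- matrix(vapply(seq_len(ops$Z),
                        function(j) initial_state(ops, electronic, j),
                        complex(ops$dim)), nrow = ops$dim)
  n_steps <- round(T_ns / config$dt_ns)
  cfg <- config
  if (cfg$method == "auto" && ops$dim <= cfg$dense_cap)
    cfg$method <- "expm_action"
  ev <- evolve_state(psi0, gen, n_steps, cfg, observables = ops$P)
  channel <- function(t_ns) c(kb_fun(t_ns), 0, 0, 0)
  per_state <- .integrate_yields(ev$pops, ev$time_ns, rates, FALSE, channel)
  phi <- colMeans(per_state)
  new_yield_result(phi, meta = list(mode = "direct", T_ns = T_ns,
                                    dt_ns = config$dt_ns, Z = ops$Z,
                                    driven = TRUE, theta_deg = theta_deg,
                                    v_d_MHz = params$v_d_MHz,
                                    J0_MHz = params$J0_MHz,
                                    electronic = electronic))
}

#' Driven-model anisotropy
#'
#' chi for the driven radical pair: singlet recombination yields for the
#' field parallel (theta = 0) and perpendicular (theta = 90 degrees) to the
#' hyperfine symmetry axis, combined with \code{anisotropy_chi}.
#'
#' @inheritParams driven_yield
#' @param v_d_MHz driving frequency; overrides \code{params$v_d_MHz}.
#' @return list with \code{chi}, \code{phi_par}, \code{phi_perp}.
#' @export
driven_chi <- function(ops, interactions, params, v_d_MHz = NULL,
                       B_mT = 0.05, T_ns = 10000,
                       config = propagator_config(dt_ns = 0.5)) {
  if (!is.null(v_d_MHz)) params$v_d_MHz <- v_d_MHz
  par_ <- driven_yield(ops, interactions, params, 0, B_mT, T_ns,
                       config = config)
  perp <- driven_yield(ops, interactions, params, 90, B_mT, T_ns,
                       config = config)
  list(chi = anisotropy_chi(par_$phi[["S"]], perp$phi[["S"]]),
       phi_par = par_$phi[["S"]], phi_perp = perp$phi[["S"]])
}
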