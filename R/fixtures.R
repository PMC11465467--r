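# Built-in model systems and a synthetic fluctuating-tensor generator.
#
# The generator stands in for tensors extracted along an MD trajectory and
# recomputed quantum-chemically every 50 ps: each tensor component follows
# a stationary Ornstein-Uhlenbeck process, the minimal Gaussian model with
# a single correlation time that reproduces the visual character of such
# data and is sufficient to induce hyperfine-fluctuation-driven spin
# relaxation.

#' Synthetic fluctuating interaction tensor (Ornstein-Uhlenbeck)
#'
#' Each of the nine tensor components evolves independently as
#' x_{n+1} = mu + (x_n - mu) e^(-dt/tau) + sigma sqrt(1 - e^(-2 dt/tau)) xi_n
#' with xi standard normal, started from the stationary distribution
#' N(mu, sigma^2).  The series is stationary with mean mu, standard
#' deviation sigma and autocorrelation e^(-lag/tau).
#'
#' @param mean_MHz 3x3 mean tensor (MHz).
#' @param sigma_MHz fluctuation standard deviation per component: scalar or
#'   3x3 matrix (MHz, >= 0).
#' @param tau_ps correlation time (ps, > 0).
#' @param step_ps sampling interval (ps, default 50).
#' @param length_ns trajectory length (ns).
#' @param seed RNG seed (restored afterwards).
#' @param tag interaction tag carried by the returned series.
#' @return \code{trajectory_series} with one tagged tensor series.
#' @export
generate_fluctuating_tensor <- function(mean_MHz, sigma_MHz, tau_ps,
                                        step_ps = 50, length_ns = 1000,
                                        seed = 1, tag = "hf") {
  mu <- as.vector(t(as.matrix(mean_MHz)))
  if (length(mu) != 9) stop("mean_MHz must be a 3x3 matrix")
  sig <- if (length(sigma_MHz) == 1) rep(sigma_MHz, 9)
         else as.vector(t(as.matrix(sigma_MHz)))
  if (any(sig < 0)) stop("sigma_MHz must be >= 0")
  if (tau_ps <= 0) stop("tau_ps must be > 0")
  if (step_ps <= 0) stop("step_ps must be > 0")
  n <- floor(length_ns * 1000 / step_ps) + 1
  decay <- exp(-step_ps / tau_ps)
  innov <- sqrt(1 - decay^2)
  m <- local_seed(seed, {
    out <- matrix(NA_real_, n, 9)
    out[1, ] <- mu + sig * stats::rnorm(9)
    if (n > 1) for (i in 2:n)
      out[i, ] <- mu + (out[i - 1, ] - mu) * decay +
        sig * innov * stats::rnorm(9)
    out
  })
  tensors <- list(m)
  names(tensors) <- tag
  trajectory_series(seq(0, by = step_ps / 1000, length.out = n), tensors)
}

#' Built-in radical-pair model systems
#'
#' \describe{
#'   \item{driven_n5}{One axial I = 1 nucleus (principal hyperfine
#'     components -2.6, -2.6, 49.2 MHz, the N5 nitrogen of a flavin
#'     radical), field 50 uT, and the driven-geometry parameter set
#'     r0 = 17.8 A, delta_d = 3 A, beta = 1.4 /A, k_b0 = 2 /us,
#'     k_f = 0.5 /us, J0 = 10 MHz.}
#'   \item{wire_toy}{Reduced donor-bridge-acceptor radical pair: three
#'     isotropic proton hyperfine couplings (0.45, 0.25 mT on radical 1,
#'     0.15 mT on radical 2), exchange splitting 2J = 6.4 mT, asymmetric
#'     rates k_T = 350 /us, k_S = 2.45 /us, singlet-born.}
#'   \item{fad_trp_12}{Flavin/tryptophan roster with 12 nuclei: N5, N10,
#'     H6, 3 x H8, H-beta in the flavin radical and N1, H1, H2, H4, H6 in
#'     the tryptophan radical (Hilbert dimension 55,296).  Hyperfine
#'     tensors are not built in (they originate in quantum-chemistry data);
#'     supply them via \code{hyperfine_tensors} or request seeded synthetic
#'     stand-ins with \code{synthetic = TRUE}.}
#'   \item{fad_trp_14}{As above with H7 and H-beta-1 of tryptophan added
#'     (14 nuclei, dimension 221,184).}
#'   \item{fad_trp_20}{The 20-nucleus roster (4 x I = 1, 16 x I = 1/2;
#'     dimension 21,233,664), for dimension accounting; operators of this
#'     size are not constructed.}
#' }
#'
#' @param name one of "driven_n5", "wire_toy", "fad_trp_12", "fad_trp_14",
#'   "fad_trp_20".
#' @param hyperfine_tensors named list label -> 3x3 MHz tensor for the
#'   fad_trp rosters.
#' @param synthetic generate seeded synthetic hyperfine tensors for the
#'   fad_trp rosters (clearly a stand-in for quantum-chemistry values, for
#'   exercising the machinery only).
#' @param seed seed for the synthetic tensors.
#' @return list with \code{system}, \code{interactions}, \code{rates} and,
#'   for driven_n5, \code{params} (driven-geometry parameters).
#' @export
builtin_system <- function(name = c("driven_n5", "wire_toy", "fad_trp_12",
                                    "fad_trp_14", "fad_trp_20"),
                           hyperfine_tensors = NULL, synthetic = FALSE,
                           seed = 1) {
  name <- match.arg(name)
  if (name == "driven_n5") {
    sys <- spin_system(data.frame(label = "N5", radical = 1, I = 1))
    ints <- interaction_set(
      field_mT = c(0, 0, 0.05),
      hyperfine = list(hyperfine_term("N5",
                                      A_MHz = diag(c(-2.6, -2.6, 49.2)))))
    params <- list(r0 = 17.8, delta_d = 3, v_d_MHz = 0, beta = 1.4,
                   J0_MHz = 10, k_b0 = 2, k_f = 0.5)
    rates <- rate_scheme(k_S = params$k_b0, k_f = params$k_f)
    return(list(system = sys, interactions = ints, rates = rates,
                params = params))
  }
  if (name == "wire_toy") {
    sys <- spin_system(data.frame(label = c("H1", "H2", "H3"),
                                  radical = c(1, 1, 2),
                                  I = c(0.5, 0.5, 0.5)))
    ints <- interaction_set(
      field_mT = c(0, 0, 0),
      hyperfine = list(hyperfine_term("H1", a_mT = 0.45),
                       hyperfine_term("H2", a_mT = 0.25),
                       hyperfine_term("H3", a_mT = 0.15)),
      exchange = exchange_term(twoJ_mT = 6.4))
    rates <- rate_scheme(k_S = 2.45, k_T = 350)
    return(list(system = sys, interactions = ints, rates = rates))
  }
  roster <- switch(name,
    fad_trp_12 = data.frame(
      label = c("N5", "N10", "H6", "H8a", "H8b", "H8c", "Hbeta",
                "N1", "H1", "H2", "H4", "H6w"),
      radical = c(rep(1, 7), rep(2, 5)),
      I = c(1, 1, rep(0.5, 5), 1, rep(0.5, 4))),
    fad_trp_14 = data.frame(
      label = c("N5", "N10", "H6", "H8a", "H8b", "H8c", "Hbeta",
                "N1", "H1", "H2", "H4", "H6w", "H7w", "Hbeta1"),
      radical = c(rep(1, 7), rep(2, 7)),
      I = c(1, 1, rep(0.5, 5), 1, rep(0.5, 6))),
    fad_trp_20 = data.frame(
      label = c("N5", "N10", "H6", "H8a", "H8b", "H8c", "Hbeta1f",
                "Hbeta2f", "H7a", "H7b",
                "N1", "Nstar", "H1", "H2", "H4", "H6w", "H7w",
                "Hbeta1", "Hbeta2", "Halpha"),
      radical = c(rep(1, 10), rep(2, 10)),
      I = c(1, 1, rep(0.5, 8), 1, 1, rep(0.5, 8))))
  sys <- spin_system(roster)
  hfs <- list()
  if (!is.null(hyperfine_tensors)) {
    for (lab in names(hyperfine_tensors))
      hfs[[length(hfs) + 1]] <-
        hyperfine_term(lab, A_MHz = hyperfine_tensors[[lab]])
  } else if (synthetic) {
    hfs <- local_seed(seed, lapply(seq_len(nrow(roster)), function(k) {
      scale <- if (roster$I[k] == 1) 15 else 1
      ax <- stats::rnorm(3, 0, scale)
      r <- .random_rotation()
      hyperfine_term(roster$label[k], A_MHz = r %*% diag(ax) %*% t(r))
    }))
  }
  ints <- interaction_set(field_mT = c(0, 0, 0.05), hyperfine = hfs)
  rates <- rate_scheme(k_S = 1, k_T = 1)
  list(system = sys, interactions = ints, rates = rates)
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  d <- sign(diag(qr.R(qr_)))
  q <- q %*% diag(d)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
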