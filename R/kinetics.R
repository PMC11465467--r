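# Spin-selective reaction kinetics in the Haberkorn form.
#
# K(t) = sum_Theta k_Theta(t)/2 * P_Theta, entering the master equation as
# -{K, rho} and the stochastic Schrodinger equation through the generator
# Omega = -iH - K.  The factor 1/2 lives inside K so that a uniform rate k
# across all four electronic states gives exact population decay exp(-k t).

#' Spin-state-selective rate scheme
#'
#' Rates are in 1/us and may be numbers or functions of time (ns), e.g. the
#' driven singlet recombination coefficient.  A uniform forward rate
#' \code{k_f} is added to every electronic state on top of the
#' state-selective rates.
#'
#' @param k_S,k_T0,k_Tp,k_Tm rate coefficient per electronic state (1/us);
#'   number or function(t_ns).
#' @param k_T convenience: sets all three triplet rates at once.
#' @param k_f uniform forward rate applied to all four states (1/us).
#' @return object of class \code{rate_scheme}.
#' @export
rate_scheme <- function(k_S = 0, k_T = NULL, k_T0 = 0, k_Tp = 0, k_Tm = 0,
                        k_f = 0) {
  if (!is.null(k_T)) {
    k_T0 <- k_T; k_Tp <- k_T; k_Tm <- k_T
  }
  ks <- list(S = k_S, T0 = k_T0, Tp = k_Tp, Tm = k_Tm)
  for (nm in names(ks)) {
    k <- ks[[nm]]
    if (is.numeric(k) && k < 0) stop("negative rate for state ", nm)
    if (!is.numeric(k) && !is.function(k))
      stop("rates must be numbers or functions of time")
  }
  if (is.numeric(k_f) && k_f < 0) stop("negative forward rate")
  time_dep <- any(vapply(ks, is.function, logical(1))) || is.function(k_f)
  structure(list(k = ks, k_f = k_f, time_dependent = time_dep),
            class = "rate_scheme")
}

#' @export
print.rate_scheme <- function(x, ...) {
  fmt <- function(k) if (is.function(k)) "f(t)" else sprintf("%g", k)
  cat(sprintf("Rate scheme (1/us): k_S=%s k_T0=%s k_T+=%s k_T-=%s k_f=%s%s\n",
              fmt(x$k$S), fmt(x$k$T0), fmt(x$k$Tp), fmt(x$k$Tm), fmt(x$k_f),
              if (x$time_dependent) " [time-dependent]" else ""))
  invisible(x)
}

# numeric rates at a time point (including the uniform forward part)
rates_at <- function(rates, t_ns = 0) {
  ev <- function(k) if (is.function(k)) k(t_ns) else k
  kf <- ev(rates$k_f)
  out <- vapply(rates$k, ev, numeric(1)) + kf
  if (any(out < 0)) stop("negative rate encountered at t = ", t_ns, " ns")
  out
}

# state-selective part only (no k_f), for channel-resolved yields
selective_rates_at <- function(rates, t_ns = 0) {
  vapply(rates$k, function(k) if (is.function(k)) k(t_ns) else k, numeric(1))
}

is_symmetric_scheme <- function(rates) {
  if (rates$time_dependent) return(FALSE)
  k <- rates_at(rates, 0)
  max(k) - min(k) < 1e-12 * max(1, max(k))
}

#' Haberkorn reaction operator
#'
#' K(t) = sum_Theta k_Theta(t)/2 P_Theta; Hermitian and positive
#' semidefinite, with eigenvalues between 0 and max(k)/2.
#'
#' @param rates a \code{rate_scheme}.
#' @param ops an \code{operator_set} (supplies the projectors).
#' @param t_ns evaluation time for time-dependent rates (default 0).
#' @return sparse Hermitian operator (class \code{zspm}).
#' @export
haberkorn_operator <- function(rates, ops, t_ns = 0) {
  k <- rates_at(rates, t_ns)
  K <- zspm_zero(ops$dim)
  for (nm in names(k))
    if (k[[nm]] != 0)
      K <- zspm_add(K, zspm_scale(ops$P[[nm]], k[[nm]] / 2))
  K
}

#' Effective non-Hermitian generator
#'
#' Omega = -iH - K: the anti-Hermitian part carries the coherent spin
#' dynamics, the (negative semidefinite) Hermitian part the reaction losses,
#' so the norm of any propagated state is non-increasing.
#'
#' @param H Hamiltonian (\code{zspm}, rad/us).
#' @param K Haberkorn operator (\code{zspm}, 1/us), or NULL for none.
#' @return \code{zspm} generator; attribute \code{unitary} records K == 0.
#' @export
effective_generator <- function(H, K = NULL) {
  if (!is.null(K) && zspm_dim(H) != zspm_dim(K))
    stop("Hamiltonian and reaction operator dimensions differ")
  omega <- zspm_scale(H, -1i)
  unitary <- TRUE
  if (!is.null(K) && zspm_nnz(K) > 0) {
    omega <- zspm_add(omega, zspm_scale(K, -1))
    unitary <- FALSE
  }
  attr(omega, "unitary") <- unitary
  omega
}
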