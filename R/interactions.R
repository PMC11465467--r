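# Static and time-dependent spin Hamiltonians.
#
# Internal energy unit: angular frequency in rad/us.  Conversions:
#   A [MHz]  -> 2*pi*A  rad/us
#   B [mT]   -> g * (mu_B / hbar) * B  (electron Zeeman / hyperfine in field
#               units), i.e. 2.0023 mT ~ 2*pi*28.02 rad/us
# Times are nanoseconds at the user surface and microseconds internally.

.MU_B <- 9.2740100783e-24      # J/T
.HBAR <- 1.054571817e-34       # J s
.G_E <- 2.0023                 # default electron g-value

# rad/us per mT for a given g-value
.mT_to_radus <- function(g = .G_E) g * (.MU_B / .HBAR) * 1e-9

.MHz_to_radus <- function(a) 2 * pi * a

# mT -> MHz using the free-electron gyromagnetic ratio (the standard field
# unit for hyperfine/exchange couplings in spin chemistry)
.mT_to_MHz <- function(b, g = .G_E) .mT_to_radus(g) * b / (2 * pi)

#' Hyperfine coupling term
#'
#' @param nucleus label of a declared nucleus.
#' @param a_mT,a_MHz isotropic coupling constant (give one).
#' @param A_MHz full 3x3 real coupling tensor in MHz (alternative to the
#'   isotropic forms).
#' @param dynamic optional trajectory tag: the tensor is replaced by the
#'   trajectory values at run time (zero-order hold).
#' @return list describing the term, for \code{interaction_set}.
#' @export
hyperfine_term <- function(nucleus, a_mT = NULL, a_MHz = NULL, A_MHz = NULL,
                           dynamic = NULL) {
  ngiven <- sum(!is.null(a_mT), !is.null(a_MHz), !is.null(A_MHz))
  if (ngiven != 1)
    stop("give exactly one of a_mT, a_MHz, A_MHz for nucleus ", nucleus)
  if (!is.null(a_mT)) A <- diag(.mT_to_MHz(a_mT), 3)
  if (!is.null(a_MHz)) A <- diag(a_MHz, 3)
  if (!is.null(A_MHz)) {
    A <- as.matrix(A_MHz)
    if (!all(dim(A) == c(3, 3)) || !is.numeric(A))
      stop("A_MHz must be a real 3x3 matrix")
  }
  list(kind = "hyperfine", nucleus = nucleus, A_MHz = A, dynamic = dynamic)
}

#' Electron exchange term
#'
#' The exchange Hamiltonian is -J (2 S1.S2 + 1/2), which places the singlet
#' at +J and the triplet at -J: the singlet-triplet gap is 2J.  Because much
#' of the literature quotes 2J rather than J, both keys are accepted, in MHz
#' or in mT (converted with the free-electron gyromagnetic ratio).
#'
#' @param J_MHz,J_mT,twoJ_MHz,twoJ_mT the coupling; give exactly one.
#' @export
exchange_term <- function(J_MHz = NULL, J_mT = NULL, twoJ_MHz = NULL,
                          twoJ_mT = NULL) {
  vals <- list(J_MHz = J_MHz, J_mT = J_mT, twoJ_MHz = twoJ_MHz,
               twoJ_mT = twoJ_mT)
  given <- !vapply(vals, is.null, logical(1))
  if (sum(given) != 1)
    stop("give exactly one of J_MHz, J_mT, twoJ_MHz, twoJ_mT")
  J <- switch(names(vals)[given],
              J_MHz = J_MHz,
              J_mT = .mT_to_MHz(J_mT),
              twoJ_MHz = twoJ_MHz / 2,
              twoJ_mT = .mT_to_MHz(twoJ_mT) / 2)
  list(kind = "exchange", J_MHz = J)
}

#' Assemble the declared interactions of a radical pair
#'
#' @param field_mT external magnetic field vector (mT), molecular frame.
#' @param hyperfine list of \code{hyperfine_term}s.
#' @param exchange an \code{exchange_term}, or NULL.
#' @param dipolar 3x3 traceless symmetric electron-electron coupling tensor
#'   (MHz), or a list \code{list(D_MHz = , dynamic = tag)}.
#' @param ee_tensor alternative combined electron-electron tensor
#'   C = D - 2 J I (MHz), used as S1 . C . S2; exclusive with
#'   \code{exchange}/\code{dipolar}.
#' @return object of class \code{interaction_set}.
#' @export
interaction_set <- function(field_mT = c(0, 0, 0), hyperfine = list(),
                            exchange = NULL, dipolar = NULL,
                            ee_tensor = NULL) {
  stopifnot(length(field_mT) == 3, is.numeric(field_mT))
  if (length(hyperfine) > 0 && !is.null(hyperfine$kind))
    hyperfine <- list(hyperfine)          # single bare term
  for (h in hyperfine)
    if (!identical(h$kind, "hyperfine"))
      stop("hyperfine entries must come from hyperfine_term()")
  if (!is.null(exchange) && !identical(exchange$kind, "exchange"))
    stop("exchange must come from exchange_term()")
  dip <- NULL
  if (!is.null(dipolar)) {
    if (is.matrix(dipolar)) dipolar <- list(D_MHz = dipolar, dynamic = NULL)
    D <- as.matrix(dipolar$D_MHz)
    if (!all(dim(D) == c(3, 3))) stop("dipolar tensor must be 3x3")
    if (max(abs(D - t(D))) > 1e-9) stop("dipolar tensor must be symmetric")
    if (abs(sum(diag(D))) > 1e-6 * max(1, max(abs(D))))
      stop("dipolar tensor must be traceless")
    dip <- list(D_MHz = D, dynamic = dipolar$dynamic)
  }
  if (!is.null(ee_tensor)) {
    if (!is.null(exchange) || !is.null(dip))
      stop("give either ee_tensor or exchange/dipolar, not both")
    C <- as.matrix(ee_tensor)
    if (!all(dim(C) == c(3, 3))) stop("ee_tensor must be 3x3")
  } else C <- NULL
  structure(list(field_mT = as.numeric(field_mT), hyperfine = hyperfine,
                 exchange = exchange, dipolar = dip, ee_tensor = C),
            class = "interaction_set")
}

#' @export
print.interaction_set <- function(x, ...) {
  cat("Interaction set\n")
  cat(sprintf("  B = (%g, %g, %g) mT\n", x$field_mT[1], x$field_mT[2],
              x$field_mT[3]))
  cat(sprintf("  hyperfine terms: %d (%d dynamic)\n", length(x$hyperfine),
              sum(vapply(x$hyperfine, function(h) !is.null(h$dynamic),
                         logical(1)))))
  if (!is.null(x$exchange))
    cat(sprintf("  exchange: J = %g MHz (singlet-triplet gap 2J = %g MHz)\n",
                x$exchange$J_MHz, 2 * x$exchange$J_MHz))
  if (!is.null(x$dipolar)) cat("  dipolar tensor present\n")
  if (!is.null(x$ee_tensor)) cat("  combined electron-electron tensor present\n")
  invisible(x)
}

#' Rotate the field of an interaction set in the molecular z-x plane
#'
#' theta is the angle between the molecular z-axis and B; the scan plane is
#' z-x, so B(theta) = |B| (sin theta, 0, cos theta).  Tensors stay fixed in
#' the molecular frame.
#'
#' @param interactions an \code{interaction_set}.
#' @param theta_deg angle in degrees.
#' @param B_mT optional field magnitude; default: magnitude of the stored
#'   field vector.
#' @export
set_field_direction <- function(interactions, theta_deg, B_mT = NULL) {
  if (is.null(B_mT)) B_mT <- sqrt(sum(interactions$field_mT^2))
  th <- theta_deg * pi / 180
  interactions$field_mT <- B_mT * c(sin(th), 0, cos(th))
  interactions
}

# two-spin coupled term sum_ab T_ab * Op1_a Op2_b, T in MHz, result rad/us
.coupling_term <- function(T_MHz, op1, op2) {
  acc <- NULL
  ax <- c("x", "y", "z")
  for (a in 1:3) for (b in 1:3) {
    w <- .MHz_to_radus(T_MHz[a, b])
    if (w == 0) next
    prod_re <- op1[[ax[a]]]$re %*% op2[[ax[b]]]$re -
      op1[[ax[a]]]$im %*% op2[[ax[b]]]$im
    prod_im <- op1[[ax[a]]]$re %*% op2[[ax[b]]]$im +
      op1[[ax[a]]]$im %*% op2[[ax[b]]]$re
    term <- zspm_scale(zspm(prod_re, prod_im), w)
    acc <- if (is.null(acc)) term else zspm_add(acc, term)
  }
  if (is.null(acc)) zspm_zero(zspm_dim(op1$x)) else acc
}

# product of two zspm operators (needed for S.A.I style bilinear terms)
.zspm_mult <- function(a, b) {
  zspm(a$re %*% b$re - a$im %*% b$im, a$re %*% b$im + a$im %*% b$re)
}

#' Assemble the static spin Hamiltonian
#'
#' H = sum_i [ Zeeman(g_i, B) + sum_k S_i . A_ik . I_ik ]
#'     - J (2 S1.S2 + 1/2) + S1 . D . S2
#' in angular frequency units (rad/us).  Terms tagged as dynamic use the
#' static tensor stored in the interaction set; \code{hamiltonian_at_time}
#' substitutes trajectory values.
#'
#' @param ops \code{operator_set} from \code{build_operators}.
#' @param interactions an \code{interaction_set}.
#' @return Hermitian sparse operator (class \code{zspm}).
#' @export
assemble_hamiltonian <- function(ops, interactions) {
  terms <- hamiltonian_terms(ops, interactions)
  H <- terms$static
  for (d in terms$dynamic) {
    vals <- d$static_MHz
    for (j in seq_along(d$ops))
      if (vals[j] != 0)
        H <- zspm_add(H, zspm_scale(d$ops[[j]], .MHz_to_radus(vals[j])))
  }
  if (!zspm_is_hermitian(H, tol = 1e-8))
    stop("assembled Hamiltonian is not Hermitian; check tensor inputs")
  H
}

# Decompose the Hamiltonian into a static part and, per dynamic tag, the 9
# elementary bilinear operators whose coefficients come from a trajectory.
# This is the workhorse behind both static assembly and trajectory feeding.
#' @keywords internal
hamiltonian_terms <- function(ops, interactions) {
  sys <- ops$system
  n <- zspm_dim(ops$identity)
  H <- zspm_zero(n)
  B <- interactions$field_mT
  for (i in 1:2) {
    w <- .mT_to_radus(sys$g[i])
    for (a in seq_along(c("x", "y", "z"))) {
      ax <- c("x", "y", "z")[a]
      if (B[a] != 0) H <- zspm_add(H, zspm_scale(ops$S[[i]][[ax]], w * B[a]))
    }
  }
  dynamic <- list()
  for (h in interactions$hyperfine) {
    k <- match(h$nucleus, sys$nuclei$label)
    if (is.na(k)) stop("hyperfine term refers to undeclared nucleus ", h$nucleus)
    i <- sys$nuclei$radical[k]
    if (is.null(h$dynamic)) {
      H <- zspm_add(H, .coupling_term(h$A_MHz, ops$S[[i]], ops$I[[k]]))
    } else {
      dynamic[[h$dynamic]] <- list(
        ops = .bilinear_basis(ops$S[[i]], ops$I[[k]]),
        static_MHz = as.vector(t(h$A_MHz)))  # row-major: xx xy xz yx ...
    }
  }
  if (!is.null(interactions$exchange)) {
    J <- .MHz_to_radus(interactions$exchange$J_MHz)
    if (J != 0) {
      s1s2 <- .dot_product(ops$S[[1]], ops$S[[2]])
      H <- zspm_add(H, zspm_scale(zspm_add(zspm_scale(s1s2, 2),
                                           zspm_scale(ops$identity, 0.5)),
                                  -J))
    }
  }
  if (!is.null(interactions$dipolar)) {
    d <- interactions$dipolar
    if (is.null(d$dynamic)) {
      H <- zspm_add(H, .coupling_term(d$D_MHz, ops$S[[1]], ops$S[[2]]))
    } else {
      dynamic[[d$dynamic]] <- list(
        ops = .bilinear_basis(ops$S[[1]], ops$S[[2]]),
        static_MHz = as.vector(t(d$D_MHz)))
    }
  }
  if (!is.null(interactions$ee_tensor))
    H <- zspm_add(H, .coupling_term(interactions$ee_tensor,
                                    ops$S[[1]], ops$S[[2]]))
  list(static = H, dynamic = dynamic)
}

.dot_product <- function(op1, op2) {
  zspm_add(zspm_add(.zspm_mult(op1$x, op2$x), .zspm_mult(op1$y, op2$y)),
           .zspm_mult(op1$z, op2$z))
}

# the 9 operators Op1_a Op2_b in row-major (xx, xy, xz, yx, ...) order
.bilinear_basis <- function(op1, op2) {
  ax <- c("x", "y", "z")
  out <- vector("list", 9)
  idx <- 1
  for (a in ax) for (b in ax) {
    out[[idx]] <- .zspm_mult(op1[[a]], op2[[b]])
    idx <- idx + 1
  }
  out
}

#' Hamiltonian at a given time from a tensor trajectory
#'
#' Tagged interactions are replaced by their trajectory value at time t
#' (zero-order hold: the sample covering t is used; no extrapolation beyond
#' the final sample).
#'
#' @param ops \code{operator_set}.
#' @param interactions \code{interaction_set} with dynamic tags.
#' @param trajectory a \code{trajectory_series} carrying every tag.
#' @param t_ns time in ns.
#' @export
hamiltonian_at_time <- function(ops, interactions, trajectory, t_ns) {
  terms <- hamiltonian_terms(ops, interactions)
  H <- terms$static
  for (tag in names(terms$dynamic)) {
    d <- terms$dynamic[[tag]]
    vals <- trajectory_value(trajectory, tag, t_ns)
    vals <- as.vector(t(vals))
    for (j in seq_along(d$ops))
      if (vals[j] != 0)
        H <- zspm_add(H, zspm_scale(d$ops[[j]], .MHz_to_radus(vals[j])))
  }
  H
}

#' Tensor trajectory series
#'
#' A uniform time series of 3x3 interaction tensors (MHz), one set of nine
#' columns per tag, emulating tensors extracted along an MD trajectory.
#'
#' @param time_ns strictly increasing sample times (ns).
#' @param tensors named list: per tag either a T x 9 matrix (columns xx, xy,
#'   xz, yx, ..., zz in MHz) or a T-long list of 3x3 matrices.
#' @export
trajectory_series <- function(time_ns, tensors) {
  time_ns <- as.numeric(time_ns)
  if (any(diff(time_ns) <= 0)) stop("trajectory times must be strictly increasing")
  tensors <- lapply(tensors, function(m) {
    if (is.list(m)) m <- t(vapply(m, function(x) as.vector(t(x)), numeric(9)))
    m <- as.matrix(m)
    if (ncol(m) != 9) stop("each tensor series needs 9 components per sample")
    if (nrow(m) != length(time_ns)) stop("tensor series length mismatch")
    if (!all(is.finite(m))) stop("non-finite values in trajectory")
    m
  })
  structure(list(time_ns = time_ns, tensors = tensors),
            class = "trajectory_series")
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat(sprintf("Tensor trajectory: %d samples, %g to %g ns, tags: %s\n",
              length(x$time_ns), min(x$time_ns), max(x$time_ns),
              paste(names(x$tensors), collapse = ", ")))
  invisible(x)
}

#' Trajectory value at a time (zero-order hold)
#' @param trajectory a \code{trajectory_series}.
#' @param tag interaction tag.
#' @param t_ns query time; must lie within the sampled span.
#' @return 3x3 matrix in MHz.
#' @export
trajectory_value <- function(trajectory, tag, t_ns) {
  m <- trajectory$tensors[[tag]]
  if (is.null(m)) stop("trajectory has no series tagged '", tag, "'")
  tt <- trajectory$time_ns
  if (t_ns < tt[1] - 1e-9 || t_ns > tt[length(tt)] + 1e-9)
    stop(sprintf("time %g ns outside trajectory span [%g, %g]",
                 t_ns, tt[1], tt[length(tt)]))
  idx <- findInterval(t_ns + 1e-9, tt)
  idx <- max(1L, min(idx, length(tt)))
  matrix(m[idx, ], 3, 3, byrow = TRUE)
}

#' Write / read the trajectory text format
#'
#' Tab-separated text, first column \code{time_ns}, then columns
#' \code{<tag>.<xx|xy|...|zz>} in MHz; a header line is required.
#'
#' @param trajectory a \code{trajectory_series}.
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  comp <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")
  df <- data.frame(time_ns = trajectory$time_ns)
  for (tag in names(trajectory$tensors)) {
    m <- trajectory$tensors[[tag]]
    colnames(m) <- paste(tag, comp, sep = ".")
    df <- cbind(df, m)
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (names(df)[1] != "time_ns")
    stop("trajectory file must start with a 'time_ns' column")
  tags <- unique(sub("\\.[a-z]{2}$", "", names(df)[-1]))
  comp <- c("xx", "xy", "xz", "yx", "yy", "yz", "zx", "zy", "zz")
  tensors <- lapply(tags, function(tag) {
    cols <- paste(tag, comp, sep = ".")
    if (!all(cols %in% names(df)))
      stop("trajectory tag '", tag, "' is missing tensor components")
    as.matrix(df[, cols])
  })
  names(tensors) <- tags
  trajectory_series(df$time_ns, tensors)
}

#' Harmonically driven inter-radical geometry
#'
#' The inter-radical distance oscillates between r0 and r0 - delta_d with
#' frequency v_d: r(t) = r0 - (delta_d/2) (1 - cos(2 pi v_d t)).  The
#' singlet recombination rate and the exchange coupling follow exponential
#' distance laws with a shared decay constant beta:
#' k_b(t) = k_b0 exp(-beta (r - r0)),  J(t) = J0 exp(-beta (r - r0)),
#' so both are smallest at r = r0 and grow by exp(beta delta_d) at closest
#' approach.
#'
#' @param t_ns time(s) in ns.
#' @param r0 equilibrium distance (Angstrom).
#' @param delta_d oscillation amplitude (Angstrom, >= 0).
#' @param v_d_MHz driving frequency (MHz; 0 gives the static geometry).
#' @param beta exponential decay constant (1/Angstrom, > 0).
#' @param J0_MHz exchange coupling at r0 (MHz).
#' @param k_b0 singlet recombination rate at r0 (1/us).
#' @return list with vectors \code{r_A}, \code{J_MHz}, \code{k_b} (1/us).
#' @export
driven_geometry <- function(t_ns, r0 = 17.8, delta_d = 3, v_d_MHz = 0,
                            beta = 1.4, J0_MHz = 10, k_b0 = 2) {
  if (delta_d < 0) stop("delta_d must be >= 0")
  if (v_d_MHz < 0) stop("driving frequency must be >= 0")
  if (beta <= 0) stop("beta must be > 0")
  t_us <- t_ns / 1000
  r <- r0 - (delta_d / 2) * (1 - cos(2 * pi * v_d_MHz * t_us))
  fac <- exp(-beta * (r - r0))
  list(r_A = r, J_MHz = J0_MHz * fac, k_b = k_b0 * fac)
}
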