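# Hilbert-space structure of a two-electron radical pair with an arbitrary
# set of spin-1/2 and spin-1 nuclei.
#
# Basis ordering (fixed throughout the package):
#   electron 1  (x)  electron 2  (x)  nuclei of radical 1 (declaration order)
#   (x)  nuclei of radical 2 (declaration order)
# with m_s = +1/2 ("alpha") listed before m_s = -1/2 within each spin-1/2
# factor and m = +I, ..., -I within each nuclear factor.  This makes the
# nuclear subspace contiguous: a full-space index is
# (electronic index - 1) * Z + nuclear index.

#' Declare a radical-pair spin system
#'
#' A radical pair consists of exactly two electron spins (one per radical)
#' and any number of nuclear spins, each attached to radical 1 or 2.
#' Only nuclear spin quantum numbers I = 1/2 and I = 1 are supported
#' (protons and nitrogen-14, which cover the usual flavin/tryptophan and
#' molecular-wire systems).
#'
#' @param nuclei data frame (or NULL for a bare pair) with columns
#'   \code{label} (character), \code{radical} (1 or 2) and \code{I}
#'   (spin quantum number, 0.5 or 1).
#' @param g length-2 numeric, electron g-values; default free-electron
#'   value 2.0023 for both radicals.
#' @return object of class \code{spin_system}.
#' @examples
#' sys <- spin_system(data.frame(label = "N5", radical = 1, I = 1))
#' hilbert_dimension(sys)  # 4 * 3 = 12
#' @export
spin_system <- function(nuclei = NULL, g = c(2.0023, 2.0023)) {
  if (length(g) != 2 || !is.numeric(g))
    stop("exactly two electron g-values are required")
  if (is.null(nuclei)) {
    nuclei <- data.frame(label = character(), radical = integer(),
                         I = numeric(), stringsAsFactors = FALSE)
  }
  nuclei <- as.data.frame(nuclei, stringsAsFactors = FALSE)
  req <- c("label", "radical", "I")
  if (!all(req %in% names(nuclei)))
    stop("'nuclei' must have columns label, radical, I")
  if (nrow(nuclei) > 0) {
    if (!all(nuclei$radical %in% c(1, 2)))
      stop("every nucleus must be assigned to radical 1 or 2")
    bad <- !(abs(nuclei$I - 0.5) < 1e-12 | abs(nuclei$I - 1) < 1e-12)
    if (any(bad))
      stop("unsupported nuclear spin quantum number: only I = 1/2 and I = 1 ",
           "are supported (offending: ",
           paste(nuclei$label[bad], collapse = ", "), ")")
  }
  # order: radical 1 nuclei first (declaration order), then radical 2
  ord <- order(nuclei$radical, seq_len(nrow(nuclei)))
  nuclei <- nuclei[ord, , drop = FALSE]
  rownames(nuclei) <- NULL
  structure(list(g = as.numeric(g), nuclei = nuclei), class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  cat("Radical-pair spin system\n")
  cat(sprintf("  electrons: 2 (g = %.4f, %.4f)\n", x$g[1], x$g[2]))
  n <- nrow(x$nuclei)
  cat(sprintf("  nuclei: %d (%d in radical 1, %d in radical 2)\n", n,
              sum(x$nuclei$radical == 1), sum(x$nuclei$radical == 2)))
  if (n > 0) {
    lab <- paste0(x$nuclei$label, "(I=", format(x$nuclei$I), ",r",
                  x$nuclei$radical, ")")
    cat("   ", paste(lab, collapse = " "), "\n")
  }
  cat(sprintf("  Hilbert dimension: %s (nuclear subspace Z = %s)\n",
              format(hilbert_dimension(x), big.mark = ","),
              format(nuclear_dimension(x), big.mark = ",")))
  invisible(x)
}

#' Dimension of the full Hilbert space
#'
#' The full space is the tensor product of the two electron spin-1/2 spaces
#' and every nuclear spin space, so its dimension is
#' 4 x prod(2 I_k + 1).
#'
#' @param system a \code{spin_system}.
#' @return numeric dimension (numeric, not integer, because realistic
#'   rosters exceed 2^31 only slightly less often than one would like).
#' @export
hilbert_dimension <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  4 * nuclear_dimension(system)
}

#' Dimension Z of the nuclear spin subspace
#' @rdname hilbert_dimension
#' @export
nuclear_dimension <- function(system) {
  stopifnot(inherits(system, "spin_system"))
  if (nrow(system$nuclei) == 0) return(1)
  prod(2 * system$nuclei$I + 1)
}

# single-spin angular momentum matrices (dense, multiplicity n = 2s+1),
# basis ordered m = s, s-1, ..., -s
.spin_matrices <- function(s) {
  n <- as.integer(round(2 * s + 1))
  m <- seq(s, -s, by = -1)
  jz <- diag(m, n, n)
  jp <- matrix(0, n, n)  # raising: J+ |s,m> = sqrt(s(s+1)-m(m+1)) |s,m+1>
  for (k in seq_len(n - 1)) {
    mm <- m[k + 1]
    jp[k, k + 1] <- sqrt(s * (s + 1) - mm * (mm + 1))
  }
  jm <- t(jp)
  list(x = (jp + jm) / 2,
       y = matrix(complex(real = 0, imaginary = -(jp - jm) / 2), n, n),
       z = jz)
}

# Embed a single-spin dense operator at slot 'pos' of the factor list 'dims'.
.embed_op <- function(op, pos, dims) {
  left <- prod(dims[seq_len(pos - 1)])
  right <- prod(dims[seq_along(dims) > pos])
  a <- zspm_from_dense(op)
  out <- if (left > 1) zspm_kron(zspm_identity(left), a) else a
  if (right > 1) out <- zspm_kron(out, zspm_identity(right))
  out
}

#' Build spin operators and electronic projectors
#'
#' Constructs sparse Cartesian spin operators for every spin, embedded in the
#' full Hilbert space, together with the four electronic projection operators
#' onto the singlet and triplet states.  The two-electron states are defined
#' in the product basis as T+1 = |aa>, T-1 = |bb>,
#' T0/S = (|ab> +/- |ba>)/sqrt(2).
#'
#' @param system a \code{spin_system}.
#' @param max_dim guard on the full dimension (default 2^20); exceeding it is
#'   an error rather than a silent attempt to exhaust memory.
#' @return object of class \code{operator_set}: electron operators
#'   \code{S[[i]]$x/y/z}, nuclear operators \code{I[[k]]$x/y/z}, projectors
#'   \code{P$S, P$T0, P$Tp, P$Tm}, the identity, and dimensions.
#' @export
build_operators <- function(system, max_dim = 2^20) {
  stopifnot(inherits(system, "spin_system"))
  dim_full <- hilbert_dimension(system)
  if (dim_full > max_dim)
    stop(sprintf("Hilbert dimension %s exceeds the operator-construction cap %s",
                 format(dim_full, big.mark = ","), format(max_dim, big.mark = ",")))
  z_dim <- nuclear_dimension(system)
  nn <- nrow(system$nuclei)
  dims <- c(2, 2, if (nn > 0) 2 * system$nuclei$I + 1)
  dims <- as.integer(round(dims))

  half <- .spin_matrices(0.5)
  S <- lapply(1:2, function(i)
    lapply(half, .embed_op, pos = i, dims = dims))
  I <- if (nn > 0) lapply(seq_len(nn), function(k) {
    sm <- .spin_matrices(system$nuclei$I[k])
    lapply(sm, .embed_op, pos = 2 + k, dims = dims)
  }) else list()
  if (nn > 0) names(I) <- system$nuclei$label

  # electronic states in the 4-dim two-electron space (|aa>,|ab>,|ba>,|bb>)
  st <- .electronic_states()
  proj <- lapply(st, function(v) {
    p4 <- v %*% Conj(t(v))
    p <- zspm_from_dense(p4)
    if (z_dim > 1) p <- zspm_kron(p, zspm_identity(z_dim)) else p
  })

  structure(list(system = system, S = S, I = I, P = proj,
                 identity = zspm_identity(dim_full),
                 dim = dim_full, Z = z_dim),
            class = "operator_set")
}

# electronic basis vectors, order |aa>, |ab>, |ba>, |bb>
.electronic_states <- function() {
  s2 <- 1 / sqrt(2)
  list(S  = c(0, s2, -s2, 0) + 0i,
       T0 = c(0, s2,  s2, 0) + 0i,
       Tp = c(1, 0, 0, 0) + 0i,
       Tm = c(0, 0, 0, 1) + 0i)
}

#' @export
print.operator_set <- function(x, ...) {
  cat(sprintf("Operator set: dim %d (Z = %d), %d nuclear spins\n",
              x$dim, x$Z, length(x$I)))
  invisible(x)
}

#' Initial full-space state vector
#'
#' Kronecker product of a pure electronic state (singlet or one of the three
#' triplet states) with a nuclear state, either a computational basis state
#' (by index) or a sampled SU(Z) coherent state.  Mixed electronic initial
#' states are handled by combining the results of separate runs, not here.
#'
#' @param ops an \code{operator_set}.
#' @param electronic one of "S", "T0", "Tp", "Tm".
#' @param nuclear either a single 1-based basis index or a complex vector of
#'   length Z with unit norm (e.g. from \code{sample_su_z}).
#' @return complex vector of length 4Z with unit norm.
#' @export
initial_state <- function(ops, electronic = c("S", "T0", "Tp", "Tm"),
                          nuclear = 1L) {
  stopifnot(inherits(ops, "operator_set"))
  electronic <- match.arg(electronic)
  z_dim <- ops$Z
  if (length(nuclear) == 1 && is.numeric(nuclear) && nuclear == round(nuclear)) {
    idx <- as.integer(nuclear)
    if (idx < 1 || idx > z_dim) stop("nuclear basis index out of range")
    nuc <- rep(0 + 0i, z_dim); nuc[idx] <- 1 + 0i
  } else {
    if (inherits(nuclear, "su_z_state")) nuclear <- nuclear$amplitudes
    nuc <- as.complex(nuclear)
    if (length(nuc) != z_dim) stop("nuclear state has wrong dimension")
    nrm <- sqrt(sum(Mod(nuc)^2))
    if (abs(nrm - 1) > 1e-8) stop("nuclear state must be normalized")
  }
  el <- .electronic_states()[[electronic]]
  # full-space index is (e - 1) * Z + n: electronic factor slowest, so
  # column-major flattening of outer(nuc, el)[n, e] gives the right order
  as.vector(outer(nuc, el))
}

#' Sample an SU(Z) coherent state
#'
#' Draws a random unit vector uniformly distributed on the unit hypersphere
#' of the Z-dimensional nuclear subspace: amplitudes Z_n = X_n + i Y_n with
#' X, Y independent standard normal deviates, then normalized.  The outer
#' product of such states averages to identity/Z, which is what makes them
#' unbiased trace estimators.  Sampling is counter-based: sample \code{index}
#' under base \code{seed} is identical no matter how many other samples are
#' drawn or in what order.
#'
#' @param Z nuclear subspace dimension (>= 1).
#' @param seed integer base seed.
#' @param index sample counter (>= 1).
#' @return object of class \code{su_z_state} with fields \code{amplitudes}
#'   (complex, unit norm) and \code{index}.
#' @export
sample_su_z <- function(Z, seed = 1L, index = 1L) {
  if (Z < 1) stop("Z must be >= 1")
  mix <- (as.double(seed) %% 2147483647) * 48271 + as.double(index) * 16807
  mix <- as.integer(mix %% 2147483647)
  amp <- local_seed(mix, {
    complex(real = stats::rnorm(Z), imaginary = stats::rnorm(Z))
  })
  amp <- amp / sqrt(sum(Mod(amp)^2))
  structure(list(amplitudes = amp, index = as.integer(index)),
            class = "su_z_state")
}

# Evaluate 'expr' under a temporary RNG seed, restoring the caller's RNG
# state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
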