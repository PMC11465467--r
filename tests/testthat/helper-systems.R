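# shared fixture builders: all fixtures are constructed in code

# one proton coupled to electron 1, optionally with a field
one_nucleus_pair <- function(a_mT = 1, B_mT = 0) {
  sys <- spin_system(data.frame(label = "H1", radical = 1, I = 0.5))
  list(system = sys,
       ops = build_operators(sys),
       interactions = interaction_set(
         field_mT = c(0, 0, B_mT),
         hyperfine = list(hyperfine_term("H1", a_mT = a_mT))))
}

# bare electron pair (no nuclei)
bare_pair <- function(field_mT = c(0, 0, 0)) {
  sys <- spin_system()
  list(system = sys, ops = build_operators(sys),
       interactions = interaction_set(field_mT = field_mT))
}

# randomized small radical pair for oracle cross-checks; dimension <= 64
random_small_system <- function(seed) {
  rosters <- list(
    data.frame(label = "H1", radical = 1, I = 0.5),                    # dim 8
    data.frame(label = c("H1", "H2"), radical = c(1, 2),
               I = c(0.5, 0.5)),                                       # dim 16
    data.frame(label = c("N1", "H1"), radical = c(1, 2),
               I = c(1, 0.5)),                                         # dim 24
    data.frame(label = c("H1", "H2", "H3"), radical = c(1, 1, 2),
               I = c(0.5, 0.5, 0.5)),                                  # dim 32
    data.frame(label = c("N1", "H1", "H2"), radical = c(1, 2, 2),
               I = c(1, 0.5, 0.5)))                                    # dim 48
  roster <- rosters[[((seed - 1) %% length(rosters)) + 1]]
  sys <- spin_system(roster)
  set.seed(seed)
  hfs <- lapply(seq_len(nrow(roster)), function(k) {
    if (stats::runif(1) < 0.5) {
      hyperfine_term(roster$label[k], a_mT = stats::runif(1, -0.5, 0.5))
    } else {
      A <- matrix(stats::rnorm(9, 0, 6), 3, 3)
      A <- (A + t(A)) / 2
      hyperfine_term(roster$label[k], A_MHz = A)
    }
  })
  ex <- if (stats::runif(1) < 0.5) exchange_term(J_MHz = stats::runif(1, -4, 4))
  ints <- interaction_set(field_mT = c(0, 0, stats::runif(1, 0, 1)),
                          hyperfine = hfs, exchange = ex)
  list(system = sys, ops = build_operators(sys), interactions = ints)
}

dense_of <- function(a) rpsse:::zspm_dense(a)

expect_zspm_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(dense_of(a) - dense_of(b))), tol)
}
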