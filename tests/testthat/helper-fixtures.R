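# Small trees and quick configs shared across test files.

tiny_tree <- function(G = 3) build_tree(G)

# dense nodal-admittance oracle for the tree input impedance: unknowns are
# the pressures at every airway's distal node; the inlet is driven at P = 1
# and the input impedance is 1 / (inlet current). Independent of the
# recursive collapse used by input_resistance().
nodal_impedance <- function(tree, radii, frequency, compliances,
                            viscosity = 1.81e-5) {
  n <- tree$n_airways
  omega <- 2 * pi * frequency
  Cu <- rep_len(compliances, tree$n_terminal)
  Rres <- airway_resistance(radii, tree$airways$length, viscosity)
  A <- matrix(0 + 0i, n, n)
  b <- complex(n)
  for (j in seq_len(n)) {
    g <- 1 / Rres[j]
    # airway j connects its top node (parent's distal node, or the driven
    # inlet for the root) to its own distal node j
    A[j, j] <- A[j, j] + g
    if (j == 1L) b[j] <- b[j] + g * 1 else {
      p <- tree$airways$parent[j]
      A[j, p] <- A[j, p] - g
      A[p, p] <- A[p, p] + g
      A[p, j] <- A[p, j] - g
    }
    u <- tree$airways$terminal_unit[j]
    if (!is.na(u)) {
      Zc <- -1i / (omega * Cu[u])
      A[j, j] <- A[j, j] + 1 / Zc
    }
  }
  P <- solve(A, b)
  I_in <- (1 - P[1L]) / Rres[1L]
  1 / I_in
}

quick_config <- function(G = 5, T_r = 1, n_breaths = 20,
                         schedule = di_schedule(25, 1), seed = 1, ...) {
  sim_config(generations = G, T_r = T_r, n_breaths = n_breaths,
             schedule = schedule, seed = seed, n_trace = 8L, ...)
}
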