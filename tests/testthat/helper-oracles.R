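# Independent oracles kept deliberately separate from the implementation.

# closed-form ordinary least squares (textbook sums formulation)
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y); syy <- sum(y^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  r <- (n * sxy - sx * sy) /
    sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  list(slope = slope, intercept = intercept, pearson_r = r, cod = r^2)
}

# all-pairs distance table by explicit loops
brute_force_distances <- function(structure) {
  xyz <- structure$coordinates
  n <- nrow(xyz)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) d[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    }
  }
  d
}

# random rigid transform drawn from the current RNG state
random_rigid <- function(structure) {
  transform_structure(structure,
                      axis = stats::rnorm(3),
                      angle_deg = stats::runif(1, -180, 180),
                      translation = stats::rnorm(3, sd = 5))
}

# rotate a subset of atoms about an axis through two points (test-side
# rotation construction, independent of the package's placement code)
rotate_atoms_about_bond <- function(structure, idx, p_from, p_to, angle_deg) {
  u <- (p_to - p_from) / sqrt(sum((p_to - p_from)^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  for (i in idx) {
    structure$coordinates[i, ] <- p_from +
      as.vector(R %*% (structure$coordinates[i, ] - p_from))
  }
  structure
}

# the published benchmark panel, frozen digit-for-digit as printed
published_pka_ref <- c(
  "Benzoic Acid" = 4.20, "4-Cyanobenzoic Acid" = 3.55,
  "2,6-Dimethylbenzoic Acid" = 3.24, "4-Bromobenzoic Acid" = 3.96,
  "2-Bromobenzoic Acid" = 2.96, "2-Chlorobenzoic Acid" = 2.96,
  "3-Chlorobenzoic Acid" = 3.83, "4-Chlorobenzoic Acid" = 3.99,
  "2-Methoxybenzoic Acid" = 4.09, "3-Methoxybenzoic Acid" = 4.10,
  "4-Methoxybenzoic Acid" = 4.50
)

# a minimal synthetic result for parser fixtures
fixture_result <- function(kind = "water", energy = -229.123456,
                           frequencies = NULL, converged = TRUE,
                           wall_time = 51.5) {
  st <- build_species(kind)
  if (is.null(frequencies)) {
    frequencies <- seq(50, 3600, length.out = 3 * length(st$elements) - 6)
  }
  qm_result(st, energy, frequencies = frequencies, converged = converged,
            wall_time = wall_time)
}
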