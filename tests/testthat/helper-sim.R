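# Shared fixtures and small independent oracles for the test suite.

# Frozen reference values, each recomputed from first principles
# (k = 1.380649e-23 J/K, T = 298.15 K, eta = 8.9e-4 Pa s, n0 = 1.33,
# lambda0 = 660 nm, theta = 90 deg) with plain arithmetic:
D_100NM <- 2.453731095e-12      # kT / (6 pi eta 1e-7), m^2/s
Q_REF <- 1.790616457e7          # (4 pi 1.33 / 660e-9) sin(45 deg), 1/m
GAMMA_100NM <- 786.7415913      # q^2 D, 1/s
D_ROD_400_20 <- 4.093108436e-12 # Tirado-Garcia de la Torre, m^2/s

# Rand index between two partitions (vectors of labels over the same
# items); brute-force contingency-table formula, independent of the
# linker under test.
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  s2 <- function(x) sum(choose(x, 2))
  (choose(n, 2) + 2 * s2(tab) - s2(rowSums(tab)) - s2(colSums(tab))) /
    choose(n, 2)
}

# Pool per-track MSD curves (equal-length tracks) into one mean curve.
pooled_msd <- function(ts, max_lag, dt) {
  curves <- vapply(ts$tracks, function(tr) msd_curve(tr, max_lag, dt)$msd,
                   numeric(max_lag))
  rowMeans(curves)
}

# All lag-1 squared 2-D displacements across the tracks of a set
# (consecutive frames only).
lag1_sqdisp <- function(ts) {
  unlist(lapply(ts$tracks, function(tr) {
    ok <- which(diff(tr$frames) == 1L)
    (tr$x[ok + 1L] - tr$x[ok])^2 + (tr$y[ok + 1L] - tr$y[ok])^2
  }))
}

# density (per mL) giving `n` expected particles in a detection volume
density_for_count <- function(n, detection_volume = 15e-12) {
  n / (detection_volume * 1e3)
}
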