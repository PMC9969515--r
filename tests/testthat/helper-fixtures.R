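## shared fixtures, built in code at test time

## formamide-like planar 6-atom geometry (C, O, N, H-on-C, two H-on-N)
make_formamide <- function() {
  geometry(c("C", "O", "N", "H", "H", "H"),
           rbind(c(0, 0, 0), c(1.22, 0, 0), c(-0.68, 1.18, 0),
                 c(-0.55, -0.93, 0), c(-0.35, 2.05, 0.1),
                 c(-1.68, 1.25, -0.1)))
}

## a seeded proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## apply a rigid motion to a geometry
rigid_move <- function(geom, rot, shift = c(0, 0, 0)) {
  geometry(geom$elements, t(rot %*% t(geom$coords)) +
             rep(shift, each = n_atoms(geom)),
           molecule = geom$molecule, comment = geom$comment)
}

## dimer of two surrogate monomers at a given offset
make_surrogate_dimer <- function(spec, seed, offset = c(4.5, 0.6, 0.3),
                                 temperature = 0.6) {
  g1 <- sample_pool(spec, 1, temperature, seed = seed)[[1]]
  g2 <- sample_pool(spec, 1, temperature, seed = seed + 1000)[[1]]
  g2$coords <- g2$coords + rep(offset, each = n_atoms(g2))
  geometry(c(g1$elements, g2$elements), rbind(g1$coords, g2$coords),
           molecule = rep(1:2, each = n_atoms(g1)))
}

## small trained bundle shared across test files (built once per run)
.fixture_cache <- new.env(parent = emptyenv())

get_small_bundle <- function() {
  if (is.null(.fixture_cache$bundle)) {
    spec <- surrogate_spec()
    pool <- sample_pool(spec, 260, 1, seed = 11)
    props <- surrogate_property_table(pool, spec)
    .fixture_cache$spec <- spec
    .fixture_cache$bundle <- run_training(
      pool, props,
      list(n_final = 120, n_valid = 80, batch = 42, n_starts = 3,
           seed = 2, refit_every = 100,
           moment_columns = c("Q00", "Q1m1", "Q10", "Q11")))
  }
  list(spec = .fixture_cache$spec, bundle = .fixture_cache$bundle)
}

## LJ table used for surrogate dimers in tests
test_lj_table <- function() {
  lj_params(c("C", "O", "N", "H"),
            epsilon = c(0.4, 0.6, 0.5, 0.06),
            sigma = c(3.4, 3.0, 3.3, 2.2))
}

## unit component vector for one (l, m) slot of a 25-long moment row
unit_moment <- function(l, m, value = 1) {
  q <- numeric(25)
  off <- if (l == 0) 0L else sum(2 * (0:(l - 1)) + 1)
  q[off + m + l + 1L] <- value
  q
}
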