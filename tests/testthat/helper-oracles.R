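# Independent oracles used across tests. These deliberately avoid the
# package's own code paths (SVD Kabsch, mixture shortcuts) so agreement is
# meaningful.

# rotation matrix from an (unnormalized) quaternion
quat_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# brute-force minimum superposed RMSD: numeric optimization over rotations
# parameterized by unit quaternions, multi-start
quaternion_rmsd_oracle <- function(mobile, reference, n_starts = 12) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  obj <- function(q) {
    R <- quat_rotation(q)
    sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    q0 <- stats::rnorm(4)
    fit <- stats::optim(q0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

random_point_cloud <- function(n, seed, scale = 10) {
  withr::with_seed(seed, matrix(stats::runif(n * 3, -scale, scale), n, 3))
}

random_rotation <- function(seed) {
  withr::with_seed(seed, quat_rotation(stats::rnorm(4)))
}

# direct per-atom RMSD formula, written out independently
direct_rmsd <- function(a, b) {
  sqrt(sum((a - b)^2) / nrow(a))
}

# shared desk-scale planted world: 30-residue helix, motif = its own
# residues 13-17, so design length == world length and all native geometry
# is consistent
planted_test_world <- function(L = 30, seed = 42, window = 2) {
  stopifnot(L >= 9)
  src <- make_fixture("helix", L, seed = seed)
  lead <- (L - 5) %/% 2
  spec <- parse_contigs(sprintf("%d,A%d-%d,%d", lead, lead + 1, lead + 5,
                                L - lead - 5))
  placement <- sample_placement(spec, seed = 1)
  motif <- extract_motif(spec, src)
  list(world = planted_landscape(src, window = window),
       placement = placement, motif = motif,
       context = loss_context(placement = placement, native_motif = motif))
}

# random sequence distribution with rows on the simplex
random_seqdist <- function(L, seed) {
  withr::with_seed(seed, {
    P <- matrix(stats::runif(L * 20), L, 20)
    P / rowSums(P)
  })
}

# central finite differences of a composite loss w.r.t. every entry of P
finite_diff_gradient <- function(config, P, world, context, h = 1e-5) {
  f <- function(Q) composite_loss(toy_predict(Q, world), config, context)$total
  out <- matrix(0, nrow(P), 20)
  for (i in seq_len(nrow(P))) {
    for (t in seq_len(20)) {
      Pp <- P; Pp[i, t] <- Pp[i, t] + h
      Pm <- P; Pm[i, t] <- Pm[i, t] - h
      out[i, t] <- (f(Pp) - f(Pm)) / (2 * h)
    }
  }
  out
}

max_relative_error <- function(a, b, floor = 1e-6) {
  max(abs(a - b) / pmax(abs(a), abs(b), floor))
}
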