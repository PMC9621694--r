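# Idealized backbone generation by sequential internal-coordinate placement
# (NeRF). Bond lengths/angles are standard peptide values; secondary
# structure is set purely by the (phi, psi) torsions.

ideal_geom <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
  a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
  omega = 180
)

# place atom D from A-B-C with |C-D| = r, angle(B,C,D) = theta (deg),
# dihedral(A,B,C,D) = chi (deg)
nerf_place <- function(A, B, C, r, theta, chi) {
  theta <- theta * pi / 180; chi <- chi * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-r * cos(theta), r * sin(theta) * cos(chi), r * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * n
}

# build an n-residue backbone from per-residue (phi, psi) torsions
build_backbone_coords <- function(phi, psi, g = ideal_geom) {
  n <- length(phi)
  stopifnot(length(psi) == n, n >= 1)
  N <- CA <- C <- matrix(0, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  C[1, ] <- nerf_place(c(0, 1, 0), N[1, ], CA[1, ], g$b_ca_c, g$a_n_ca_c,
                       phi[1])
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], g$b_c_n, g$a_ca_c_n,
                               psi[i])
      CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], g$b_n_ca,
                                g$a_c_n_ca, g$omega)
      C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_ca_c,
                               g$a_n_ca_c, phi[i + 1])
    }
  }
  list(N = N, CA = CA, C = C)
}

fixture_torsions <- list(
  helix = c(phi = -57, psi = -47),
  strand = c(phi = -139, psi = 135)
)

#' Generate an idealized synthetic test structure
#'
#' Builds ideal-geometry backbones with canonical secondary-structure
#' torsions: an alpha helix, a beta strand, or a two-chain complex of two
#' antiparallel helices packed about 10 Angstrom apart (chains A and B).
#' The sequence is sampled from the default mutation alphabet under the
#' seed, so fixtures are fully deterministic.
#'
#' @param kind `"helix"`, `"strand"` or `"two_chain_complex"`.
#' @param n Residues per chain, `n >= 1`.
#' @param seed Integer seed controlling the sampled sequence.
#' @param chain Chain id (single-chain kinds).
#' @return A [backbone] structure.
#' @export
make_fixture <- function(kind = c("helix", "strand", "two_chain_complex"),
                         n = 15, seed = 1, chain = "A") {
  kind <- match.arg(kind)
  if (n < 1) stop("n must be >= 1")
  if (kind == "two_chain_complex") {
    a <- make_fixture("helix", n, seed, chain = "A")
    b <- make_fixture("helix", n, seed + 1, chain = "B")
    # antiparallel: flip about x, offset perpendicular to the helical axis
    flip <- diag(c(1, -1, -1))
    b <- transform_structure(b, rotation = flip)
    axis_a <- helix_axis(a)
    offset <- perpendicular_unit(axis_a) * 10
    shift <- colMeans(a$CA) + offset - colMeans(b$CA)
    b <- transform_structure(b, translation = shift)
    return(bind_chains(a, b))
  }
  t <- fixture_torsions[[kind]]
  coords <- build_backbone_coords(rep(t["phi"], n), rep(t["psi"], n))
  backbone(chain = chain, resno = seq_len(n),
           aa = random_sequence(n, seed),
           N = coords$N, CA = coords$CA, C = coords$C)
}

# principal axis of the CA trace (unit vector)
helix_axis <- function(x) {
  ca <- sweep(x$CA, 2, colMeans(x$CA))
  v <- svd(ca)$v[, 1]
  v / sqrt(sum(v^2))
}

perpendicular_unit <- function(v) {
  u <- c(-v[2], v[1], 0)
  if (sum(u^2) < 1e-8) u <- c(1, 0, 0)
  u / sqrt(sum(u^2))
}

#' Rise per residue along the helical axis
#'
#' Fits the principal axis of the CA trace and returns the mean projected
#' advance between consecutive residues, the standard helical-rise estimate.
#'
#' @param x A [backbone] structure (a single helix).
#' @return Rise in Angstrom per residue.
#' @export
helix_rise <- function(x) {
  v <- helix_axis(x)
  proj <- as.numeric(x$CA %*% v)
  mean(abs(diff(proj)))
}
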