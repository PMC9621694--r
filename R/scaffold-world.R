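#' Build a planted design world around a motif
#'
#' Constructs the toy optimization target for a placement: a full-length
#' backbone in which each motif segment keeps its native coordinates
#' exactly (grafted rigidly onto the growing chain) and scaffold gaps are
#' ideal helix, plus a planted target sequence carrying the native motif
#' letters at motif positions and seeded random letters elsewhere.
#' Optimizers run against the returned [planted_landscape]; recovering its
#' sequence is the toy analog of a design whose sequence strongly encodes
#' its backbone. Each segment's internal geometry is exact; the relative
#' orientation of different segments is set by the helical linkers, not by
#' the native inter-segment arrangement.
#'
#' @param placement A `motif_placement`.
#' @param motif Native motif [backbone] (from [extract_motif]).
#' @param seed Integer seed for the scaffold letters.
#' @param window,max_pae Passed to [planted_landscape].
#' @param chain Chain id of the built design.
#' @return A [planted_landscape] of length `placement$total_length`.
#' @export
scaffold_world <- function(placement, motif, seed = 1, window = 2,
                           max_pae = 30, chain = "A") {
  L <- placement$total_length
  stopifnot(nrow(motif) == sum(placement$motif_mask))
  g <- ideal_geom
  th <- fixture_torsions$helix
  N <- CA <- C <- matrix(NA_real_, L, 3)
  seg_of <- integer(L)                      # 0 = scaffold
  seg_of[placement$index_map$position] <- placement$index_map$segment
  motif_row <- integer(L)
  motif_row[placement$index_map$position] <- seq_len(nrow(motif))

  place_gap_residue <- function(i, prev) {
    Ni <- nerf_place(prev$N, prev$CA, prev$C, g$b_c_n, g$a_ca_c_n, th["psi"])
    CAi <- nerf_place(prev$CA, prev$C, Ni, g$b_n_ca, g$a_c_n_ca, g$omega)
    Ci <- nerf_place(prev$C, Ni, CAi, g$b_ca_c, g$a_n_ca_c, th["phi"])
    list(N = Ni, CA = CAi, C = Ci)
  }

  prev <- NULL
  i <- 1
  while (i <= L) {
    if (seg_of[i] == 0) {
      res <- if (is.null(prev)) {
        list(N = c(0, 0, 0), CA = c(g$b_n_ca, 0, 0),
             C = nerf_place(c(0, 1, 0), c(0, 0, 0), c(g$b_n_ca, 0, 0),
                            g$b_ca_c, g$a_n_ca_c, th["phi"]))
      } else {
        place_gap_residue(i, prev)
      }
      N[i, ] <- res$N; CA[i, ] <- res$CA; C[i, ] <- res$C
      prev <- res
      i <- i + 1
    } else {
      s <- seg_of[i]
      run <- which(seg_of == s)
      rows <- motif_row[run]
      seg <- motif[rows, ]
      if (is.null(prev)) {
        fit <- list(rotation = diag(3), translation = c(0, 0, 0))
      } else {
        # frame the segment's first residue would occupy on an ideal chain,
        # then graft the whole native segment rigidly onto that frame
        anchor <- place_gap_residue(i, prev)
        fit <- kabsch_superpose(rbind(seg$N[1, ], seg$CA[1, ], seg$C[1, ]),
                                rbind(anchor$N, anchor$CA, anchor$C))
      }
      for (atom in c("N", "CA", "C")) {
        placed <- transform_structure(seg[[atom]], fit$rotation,
                                      fit$translation)
        for (k in seq_along(run)) {
          if (atom == "N") N[run[k], ] <- placed[k, ]
          if (atom == "CA") CA[run[k], ] <- placed[k, ]
          if (atom == "C") C[run[k], ] <- placed[k, ]
        }
      }
      last <- run[length(run)]
      prev <- list(N = N[last, ], CA = CA[last, ], C = C[last, ])
      i <- last + 1
    }
  }

  seq <- random_sequence(L, seed)
  seq[placement$index_map$position] <- motif$aa
  design <- backbone(chain = chain, resno = seq_len(L), aa = seq,
                     N = N, CA = CA, C = C)
  planted_landscape(design, window = window, max_pae = max_pae)
}
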