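# mixture-form geometry with a chosen uniform confidence, sharing the toy
# world's reference bins
geometry_at_conf <- function(world, conf) {
  motifscaffold:::mixture_geometry(
    matrix(conf, nrow(world$structure), nrow(world$structure)),
    world$ref_bins, world$bins)
}

prediction_at_conf <- function(world, conf) {
  L <- nrow(world$structure)
  prediction_result(world$structure, geometry_at_conf(world, conf),
                    plddt = rep(100 * sqrt(conf), L),
                    pae = world$max_pae * (1 - matrix(conf, L, L)),
                    chain_boundary = world$chain_boundary)
}

test_that("motif cross-entropy is at the epsilon floor for a correct one-hot prediction", {
  tw <- planted_test_world()
  pred <- prediction_at_conf(tw$world, 1)
  val <- composite_loss(pred, loss_config("motif_ce"), tw$context)
  expect_lt(abs(val$total), 1e-7)
})

test_that("uniform predictions contribute ln(B) per channel to the motif CE", {
  tw <- planted_test_world()
  pred <- prediction_at_conf(tw$world, 0)
  val <- composite_loss(pred, loss_config("motif_ce"), tw$context)$total
  expected <- mean(log(c(37, 25, 25, 13)))
  expect_equal(val, expected, tolerance = 1e-6)  # eps floor shifts ln B slightly
})

test_that("the planted sequence beats a uniform one on motif CE in any world", {
  for (s in 1:5) {
    src <- make_fixture("helix", 24, seed = 600 + s)
    spec <- parse_contigs("8,A9-16,8")
    placement <- sample_placement(spec, seed = 1)
    motif <- extract_motif(spec, src)
    world <- planted_landscape(src)
    ctx <- loss_context(placement = placement, native_motif = motif)
    cfg <- loss_config("motif_ce")
    good <- composite_loss(toy_predict(one_hot_sequence(world$sequence),
                                       world), cfg, ctx)$total
    flat <- composite_loss(toy_predict(matrix(1 / 20, 24, 20), world),
                           cfg, ctx)$total
    expect_lt(good, flat)
  }
})

test_that("motif coordinate RMSD matches the direct-formula oracle", {
  tw <- planted_test_world()
  cfg <- loss_config("motif_rmsd")
  pred <- toy_predict(one_hot_sequence(tw$world$sequence), tw$world)
  expect_equal(composite_loss(pred, cfg, tw$context)$total, 0,
               tolerance = 1e-12)

  # rigid motion of the whole prediction leaves the superposed RMSD at 0
  R <- random_rotation(44)
  moved <- transform_structure(tw$world$structure, R, c(4, -1, 2))
  pred_moved <- prediction_result(moved, pred$geometry, pred$plddt, pred$pae)
  expect_lt(composite_loss(pred_moved, cfg, tw$context)$total, 1e-9)

  # seeded Gaussian perturbation: compare against an independent Kabsch+RMSD
  noisy <- tw$world$structure
  pos <- tw$placement$index_map$position
  withr::with_seed(17, {
    for (atom in c("N", "CA", "C")) {
      noisy[[atom]][pos, ] <- noisy[[atom]][pos, ] +
        matrix(stats::rnorm(length(pos) * 3, sd = 0.5), length(pos), 3)
    }
  })
  pred_noisy <- prediction_result(noisy, pred$geometry, pred$plddt, pred$pae)
  got <- composite_loss(pred_noisy, cfg, tw$context)$total
  a <- backbone_coords(noisy, rows = pos)
  b <- backbone_coords(tw$motif)
  fit <- kabsch_superpose(a, b)
  oracle <- direct_rmsd(sweep(a %*% t(fit$rotation), 2, fit$translation, "+"),
                        b)
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("certainty loss has its analytic values at the distribution extremes", {
  tw <- planted_test_world()
  lnB <- log(c(dist = 37, omega = 25, theta = 25, phi = 13))

  flat <- prediction_at_conf(tw$world, 0)
  cfg_H <- loss_config(loss_term("certainty", mode = "entropy"))
  expect_equal(composite_loss(flat, cfg_H, tw$context)$total,
               mean(lnB), tolerance = 1e-12)

  sharp <- prediction_at_conf(tw$world, 1)
  expect_equal(composite_loss(sharp, cfg_H, tw$context)$total, 0,
               tolerance = 1e-12)

  cfg_KL <- loss_config(loss_term("certainty", mode = "kl_background"))
  expect_equal(composite_loss(sharp, cfg_KL, tw$context)$total,
               -mean(lnB), tolerance = 1e-12)
  expect_equal(composite_loss(flat, cfg_KL, tw$context)$total, 0,
               tolerance = 1e-12)

  lam <- seq(0, 1, by = 0.1)
  H <- vapply(lam, function(l) {
    composite_loss(prediction_at_conf(tw$world, l), cfg_H, tw$context)$total
  }, numeric(1))
  expect_true(all(diff(H) < 0))
})

test_that("mixture and dense geometry representations agree on every statistic", {
  tw <- planted_test_world()
  pred <- toy_predict(random_seqdist(30, seed = 55), tw$world)
  dense_pred <- pred
  dense_pred$geometry <- as_dense_geometry(pred$geometry)
  ctx <- tw$context
  cfg <- loss_config(loss_term("certainty"), loss_term("motif_ce"),
                     loss_term("pae"))
  a <- composite_loss(pred, cfg, ctx)
  b <- composite_loss(dense_pred, cfg, ctx)
  expect_equal(a$total, b$total, tolerance = 1e-9)
  expect_equal(a$breakdown$value, b$breakdown$value, tolerance = 1e-9)
})

test_that("repulsion loss matches brute-force enumeration of contact mass", {
  complex <- make_fixture("two_chain_complex", 10, seed = 12)
  world <- planted_landscape(complex)
  P <- random_seqdist(20, seed = 13)
  pred <- toy_predict(P, world)
  allowed <- rbind(c(3, 14), c(14, 3))
  ctx <- loss_context(allowed_pairs = allowed)
  got <- composite_loss(pred, loss_config(loss_term("repulsion",
                                                    cutoff = 8)),
                        ctx)$total

  # brute force: enumerate all cross-chain ordered pairs over the dense
  # distogram, summing mass of distance bins entirely below the cutoff
  dense <- as_dense_geometry(pred$geometry)
  breaks <- dense$bins$dist$breaks
  below <- which(breaks[-1] <= 8)
  vals <- c()
  for (i in 1:20) {
    for (j in 1:20) {
      cross <- (i <= 10 && j >= 11) || (i >= 11 && j <= 10)
      if (!cross) next
      if (any(allowed[, 1] == i & allowed[, 2] == j)) next
      vals <- c(vals, sum(dense$channels$dist[i, j, below]))
    }
  }
  expect_equal(got, mean(vals), tolerance = 1e-9)
  expect_true(got >= 0 && got <= 1)
})

test_that("repulsion loss hits its extremes and rejects single chains", {
  complex <- make_fixture("two_chain_complex", 10, seed = 12)
  world <- planted_landscape(complex)
  ctx <- loss_context()
  cfg <- loss_config("repulsion")

  # force every cross-chain reference bin beyond the cutoff: zero loss
  far <- world
  far$ref_bins$dist[1:10, 11:20] <- 37L
  far$ref_bins$dist[11:20, 1:10] <- 37L
  pred0 <- toy_predict(one_hot_sequence(world$sequence), far)
  expect_equal(composite_loss(pred0, cfg, ctx)$total, 0)

  # force every cross-chain pair fully in contact: loss 1
  near <- world
  near$ref_bins$dist[1:10, 11:20] <- 1L
  near$ref_bins$dist[11:20, 1:10] <- 1L
  pred1 <- toy_predict(one_hot_sequence(world$sequence), near)
  expect_equal(composite_loss(pred1, cfg, ctx)$total, 1)

  single <- planted_test_world()
  pred <- toy_predict(one_hot_sequence(single$world$sequence), single$world)
  expect_error(composite_loss(pred, cfg, ctx), "two-chain")
})

test_that("radius-of-gyration loss matches hand computations", {
  one <- backbone(chain = "A", resno = 1, aa = "A",
                  N = rbind(c(-1.4, 0, 0)), CA = rbind(c(0, 0, 0)),
                  C = rbind(c(1.2, 1, 0)))
  pred1 <- list(coords = one)
  expect_equal(motifscaffold:::term_rog(pred1, NULL, list(rg_max = 0)), 0)

  helix <- make_fixture("helix", 15, seed = 2)
  predh <- list(coords = helix)
  expect_equal(motifscaffold:::term_rog(predh, NULL, list(rg_max = 50)), 0)

  # four CA atoms at the corners of a 2 A square: Rg = sqrt(2), loss = 2
  sq <- backbone(chain = "A", resno = 1:4, aa = "AAAA",
                 N = matrix(0, 4, 3) + c(0, 0, 1),
                 CA = rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0)),
                 C = matrix(0, 4, 3) + c(0, 1, 0))
  predsq <- list(coords = sq)
  expect_equal(radius_of_gyration(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(motifscaffold:::term_rog(predsq, NULL, list(rg_max = 0)), 2,
               tolerance = 1e-12)
})

test_that("composite loss combines weighted terms and keeps the breakdown", {
  tw <- planted_test_world()
  pred <- toy_predict(random_seqdist(30, seed = 77), tw$world)

  zero <- composite_loss(pred, loss_config(loss_term("certainty", weight = 0),
                                           loss_term("motif_ce", weight = 0)),
                         tw$context)
  expect_equal(zero$total, 0)
  expect_equal(nrow(zero$breakdown), 2)
  expect_true(all(zero$breakdown$value > 0))

  single <- composite_loss(pred, loss_config(loss_term("certainty",
                                                       weight = 1)),
                           tw$context)
  expect_equal(single$total, single$breakdown$value[1])

  t1 <- composite_loss(pred, loss_config("certainty"), tw$context)$total
  t2 <- composite_loss(pred, loss_config("motif_ce"), tw$context)$total
  both <- composite_loss(pred, loss_config(loss_term("certainty", weight = 2),
                                           loss_term("motif_ce",
                                                     weight = 0.5)),
                         tw$context)
  expect_equal(both$total, 2 * t1 + 0.5 * t2, tolerance = 1e-12)
})

test_that("loss bounds hold on random mixture distributions", {
  tw <- planted_test_world()
  for (s in 1:10) {
    pred <- toy_predict(random_seqdist(30, seed = 700 + s), tw$world)
    ce <- composite_loss(pred, loss_config("motif_ce"), tw$context)$total
    expect_gte(ce, -1e-7)
    H <- composite_loss(pred, loss_config(loss_term("certainty")),
                        tw$context)$total
    expect_true(H >= 0 && H <= log(37))
    kl <- -composite_loss(pred,
                          loss_config(loss_term("certainty",
                                                mode = "kl_background")),
                          tw$context)$total
    expect_gte(kl, -1e-12)   # Gibbs: KL to background is non-negative
  }
})

test_that("loss configs validate and round-trip through YAML", {
  expect_error(loss_config(), "at least one")
  expect_error(loss_term("nope"), "unknown loss term")
  expect_error(loss_term("certainty", weight = Inf), "is.finite")

  cfg <- loss_config(loss_term("certainty", weight = 2, mode = "entropy"),
                     loss_term("motif_ce", weight = 0.5, eps = 1e-8))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_loss_config(cfg, path)
  cfg2 <- read_loss_config(path)
  expect_equal(vapply(cfg2, `[[`, character(1), "name"),
               vapply(cfg, `[[`, character(1), "name"))
  expect_equal(vapply(cfg2, `[[`, numeric(1), "weight"),
               vapply(cfg, `[[`, numeric(1), "weight"))

  tw <- planted_test_world()
  pred <- toy_predict(random_seqdist(30, seed = 3), tw$world)
  expect_equal(composite_loss(pred, cfg2, tw$context)$total,
               composite_loss(pred, cfg, tw$context)$total)
})
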