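test_that("metropolis criterion accepts improvements and obeys the Boltzmann rate", {
  expect_true(metropolis_accept(-1, 1e-9))
  expect_true(metropolis_accept(-1, 100))
  expect_error(metropolis_accept(1, 0), "positive")
  expect_error(metropolis_accept(1, -2), "positive")

  # T -> 0+: worsening moves essentially never accepted
  withr::with_seed(1, {
    expect_false(any(vapply(1:200, function(i) {
      metropolis_accept(1, 1e-6)
    }, logical(1))))
  })

  # delta = 1, T = 1: acceptance fraction ~ exp(-1) within 3 binomial SEs
  withr::with_seed(2, {
    acc <- vapply(1:10000, function(i) metropolis_accept(1, 1), logical(1))
  })
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(mean(acc) - p), 3 * se)
})

make_mcmc_setup <- function(L = 20, seed = 42) {
  src <- make_fixture("helix", L, seed = seed)
  spec <- parse_contigs(sprintf("6,A7-11,%d", L - 11))
  placement <- sample_placement(spec, seed = 1)
  motif <- extract_motif(spec, src)
  list(world = planted_landscape(src), placement = placement,
       motif = motif,
       context = loss_context(placement = placement, native_motif = motif))
}

test_that("mcmc_design trajectories are deterministic and contract-obeying", {
  s <- make_mcmc_setup()
  predictor <- toy_predictor(s$world)
  cfg <- loss_config("certainty")
  init <- init_design_sequence(s$placement, s$motif, seed = 5)

  t1 <- mcmc_design(predictor, cfg, s$context, s$placement, init,
                    schedule = anneal_schedule(150), seed = 7)
  t2 <- mcmc_design(predictor, cfg, s$context, s$placement, init,
                    schedule = anneal_schedule(150), seed = 7)
  expect_identical(t1$steps, t2$steps)

  # best-so-far loss is non-increasing
  expect_true(all(diff(t1$steps$best_loss) <= 1e-12))
  # motif letters never mutate
  pos <- s$placement$index_map$position
  for (sq in t1$steps$sequence[c(1, 50, 150)]) {
    expect_identical(strsplit(sq, "")[[1]][pos], s$motif$aa)
  }
  # recorded best matches the trajectory minimum
  expect_equal(t1$best$loss, min(t1$steps$loss))
})

test_that("mcmc_design with zero steps returns only the initial state", {
  s <- make_mcmc_setup()
  t0 <- mcmc_design(toy_predictor(s$world), loss_config("certainty"),
                    s$context, s$placement,
                    init_design_sequence(s$placement, s$motif, seed = 2),
                    schedule = anneal_schedule(0, T0 = 0.1), seed = 1)
  expect_equal(nrow(t0$steps), 1)
  expect_equal(t0$steps$step, 0L)
  expect_error(
    mcmc_design(toy_predictor(s$world), loss_config("certainty"),
                s$context,
                sample_placement(parse_contigs("A7-11"), 1),
                s$motif$aa, schedule = anneal_schedule(5), seed = 1),
    "no mutable positions")
})

test_that("the cold final phase accepts no worsening moves", {
  s <- make_mcmc_setup()
  tr <- mcmc_design(toy_predictor(s$world), loss_config("certainty"),
                    s$context, s$placement,
                    init_design_sequence(s$placement, s$motif, seed = 3),
                    schedule = anneal_schedule(400, T0 = 0.05, Tf = 1e-9),
                    seed = 11)
  st <- tr$steps
  late <- st[st$step > 360 & !is.na(st$accepted) & st$accepted, ]
  if (nrow(late) > 0) {
    deltas <- st$loss[match(late$step, st$step)] -
      st$loss[match(late$step, st$step) - 1]
    expect_true(all(deltas <= 1e-9))
  }
  succeed()
})

test_that("gradient_design honors trivial limits and determinism", {
  s <- make_mcmc_setup()
  predictor <- toy_predictor(s$world)
  cfg <- loss_config("pae")

  t0 <- gradient_design(predictor, cfg, s$context, s$placement, steps = 0,
                        seed = 4)
  expect_equal(nrow(t0$steps), 1)

  tlr0 <- gradient_design(predictor, cfg, s$context, s$placement,
                          steps = 10, learning_rate = 0, seed = 4)
  expect_length(unique(tlr0$steps$sequence), 1)

  ta <- gradient_design(predictor, cfg, s$context, s$placement, steps = 25,
                        seed = 6)
  tb <- gradient_design(predictor, cfg, s$context, s$placement, steps = 25,
                        seed = 6)
  expect_identical(ta$steps, tb$steps)
  expect_true(all(diff(ta$steps$best_loss) <= 1e-12))

  pos <- s$placement$index_map$position
  final <- strsplit(ta$steps$sequence[nrow(ta$steps)], "")[[1]]
  expect_identical(final[pos], s$motif$aa)

  no_grad <- structure(list(predict = predictor$predict, gradient = NULL),
                       class = "predictor")
  expect_error(gradient_design(no_grad, cfg, s$context, s$placement),
               "gradient capability")
})

test_that("a single stage reproduces the direct optimizer call exactly", {
  s <- make_mcmc_setup()
  predictor <- toy_predictor(s$world)
  cfg <- loss_config("certainty")
  init <- init_design_sequence(s$placement, s$motif, seed = 1)

  staged <- staged_protocol(
    list(list(optimizer = "mcmc", config = cfg, steps = 100)),
    predictor, s$context, s$placement, init = init, seed = 9)
  direct <- mcmc_design(predictor, cfg, s$context, s$placement, init,
                        schedule = anneal_schedule(100), seed = 9)
  expect_identical(staged$stages[[1]]$steps, direct$steps)
})

test_that("stage two starts from stage one's best design", {
  s <- make_mcmc_setup()
  predictor <- toy_predictor(s$world)
  cfg <- loss_config("certainty")
  staged <- staged_protocol(
    list(list(optimizer = "mcmc", config = cfg, steps = 120),
         list(optimizer = "mcmc", config = cfg, steps = 120)),
    predictor, s$context, s$placement, seed = 10)
  s1_best <- staged$stages[[1]]$best$sequence
  s2_init <- strsplit(staged$stages[[2]]$steps$sequence[1], "")[[1]]
  expect_identical(s2_init, s1_best)
  expect_error(staged_protocol(list(), predictor, s$context, s$placement),
               "at least one stage")
})

test_that("a staged mcmc-then-gradient run refines the motif reconstruction", {
  s <- make_mcmc_setup()
  predictor <- toy_predictor(s$world)
  staged <- staged_protocol(
    list(list(optimizer = "mcmc", config = loss_config("certainty"),
              steps = 250),
         list(optimizer = "gradient",
              config = loss_config(loss_term("certainty"),
                                   loss_term("motif_ce")),
              steps = 60, learning_rate = 1)),
    predictor, s$context, s$placement, seed = 12)
  expect_equal(vapply(staged$stages, function(t) t$method, character(1)),
               c("mcmc", "gradient"))
  bd <- staged$stages[[2]]$breakdown
  expect_true(all(c("certainty", "motif_ce") %in% names(bd)))
  expect_lte(min(bd$motif_ce), bd$motif_ce[1] + 1e-12)
  expect_true(all(diff(staged$stages[[2]]$steps$best_loss) <= 1e-12))
})

test_that("trajectory tidiers and plots expose the run", {
  s <- make_mcmc_setup()
  tr <- mcmc_design(toy_predictor(s$world), loss_config("certainty"),
                    s$context, s$placement,
                    init_design_sequence(s$placement, s$motif, seed = 2),
                    schedule = anneal_schedule(50), seed = 2)
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 51)
  tdb <- tidy(tr, breakdown = TRUE)
  expect_true("certainty" %in% names(tdb))
  g <- glance(tr)
  expect_equal(g$n_steps, 50)
  expect_equal(g$best_loss, tr$best$loss)
  expect_s3_class(autoplot(tr), "ggplot")
})
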