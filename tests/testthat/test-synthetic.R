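test_that("degenerate mixtures respect the basin guarantees", {
  cfg1 <- synthetic_config(n_runs = 1, n_frames = 4,
                           molecules_per_frame = 10, bias_fraction = 1,
                           seed = 3)
  gt1 <- generate_toy_ensemble(cfg1)$ground_truth
  expect_true(all(gt1$basin == "closed"))
  expect_true(all(gt1$r_ha < 2.5))

  cfg0 <- synthetic_config(n_runs = 1, n_frames = 4,
                           molecules_per_frame = 10, bias_fraction = 0,
                           seed = 3)
  gt0 <- generate_toy_ensemble(cfg0)$ground_truth
  expect_true(all(gt0$basin == "open"))
  expect_true(all(gt0$r_ha > 4))
})

test_that("the planted closed fraction obeys the binomial bound", {
  cfg <- synthetic_config(n_runs = 1, n_frames = 40,
                          molecules_per_frame = 25, bias_fraction = 0.4,
                          seed = 19)
  gt <- generate_toy_ensemble(cfg)$ground_truth
  n <- nrow(gt)
  expect_equal(n, 1000)
  expect_lt(abs(mean(gt$basin == "closed") - 0.4),
            4 * sqrt(0.4 * 0.6 / n))
})

test_that("generation is reproducible under the seed", {
  cfg <- synthetic_config(n_runs = 1, n_frames = 2,
                          molecules_per_frame = 6, seed = 8)
  e1 <- generate_toy_ensemble(cfg)
  e2 <- generate_toy_ensemble(cfg)
  expect_identical(e1$ground_truth, e2$ground_truth)
  expect_identical(e1$frames[[2]]$atoms, e2$frames[[2]]$atoms)
  e3 <- generate_toy_ensemble(synthetic_config(n_runs = 1, n_frames = 2,
                                               molecules_per_frame = 6,
                                               seed = 9))
  expect_false(identical(e1$ground_truth$r_ha, e3$ground_truth$r_ha))
})

test_that("molecules are placed without center overlap", {
  cfg <- synthetic_config(n_runs = 1, n_frames = 3,
                          molecules_per_frame = 25, seed = 5)
  ens <- generate_toy_ensemble(cfg)
  for (fr in ens$frames) {
    A <- fr$atoms
    centers <- t(vapply(sort(unique(A$molecule)), function(m)
      colMeans(as.matrix(A[A$molecule == m, c("x", "y", "z")])), double(3)))
    for (i in 1:(nrow(centers) - 1)) for (j in (i + 1):nrow(centers)) {
      expect_gte(min_image_distance(centers[i, ], centers[j, ], fr$cell),
                 cfg$min_center_distance - 1e-6)
    }
  }
})

test_that("surrogate shifts follow the documented closed form", {
  cfg <- synthetic_config(noise_sigma = 0)
  # open geometry: H-bond term decayed to ~0 at r ~ 8 A
  fr_open <- toy_frame(c(180, 180, 180, 180))
  s_open <- surrogate_shifts(fr_open, 1, cfg, noise = FALSE)
  r_open <- sqrt(sum((build_toy_geometry(c(180, 180, 180, 180))[8, ] -
                        build_toy_geometry(c(180, 180, 180, 180))[7, ])^2))
  expect_equal(unname(s_open["H1"]),
               unname(cfg$delta0["H1"]) + cfg$a_hb * exp(-r_open / cfg$r0),
               tolerance = 1e-12)
  expect_lt(abs(s_open["H1"] - cfg$delta0["H1"]), 0.01)

  # closed geometry: the full closed form for H1, N7 and the ring carbons
  tau <- c(-60, 4, 105, -28)
  fr_cl <- toy_frame(tau)
  X <- build_toy_geometry(tau)
  r <- sqrt(sum((X[8, ] - X[7, ])^2))
  s_cl <- surrogate_shifts(fr_cl, 1, cfg, noise = FALSE)
  expect_equal(unname(s_cl["H1"]),
               unname(cfg$delta0["H1"]) + cfg$a_hb * exp(-r / cfg$r0),
               tolerance = 1e-12)
  expect_equal(unname(s_cl["N7"]),
               unname(cfg$delta0["N7"]) + cfg$a_hb_n * exp(-r / cfg$r0),
               tolerance = 1e-12)
  expect_equal(unname(s_cl["C8"]),
               unname(cfg$delta0["C8"]) + cfg$b_tau * cos(-60 * pi / 180),
               tolerance = 1e-9)
  # non-coupled site: baseline only
  expect_equal(unname(s_cl["C3"]), unname(cfg$delta0["C3"]))

  # determinism of the noise stream under an explicit seed
  cfg2 <- synthetic_config(noise_sigma = 0.2)
  a <- surrogate_shifts(fr_cl, 1, cfg2, seed = 77)
  b <- surrogate_shifts(fr_cl, 1, cfg2, seed = 77)
  expect_identical(a, b)
  expect_error(surrogate_shifts(two_molecule_frame(), 1, cfg),
               "toy template")
})

test_that("ground truth is recomputable from emitted geometry alone", {
  case <- small_case(seed = 13)
  gt2 <- recompute_ground_truth(case$frames)
  gt <- case$ground_truth
  i <- match(gt$env_id, gt2$env_id)
  expect_equal(gt2$basin[i], gt$basin)
  expect_equal(gt2$r_ha[i], gt$r_ha, tolerance = 1e-9)
  expect_equal(gt2$tau1[i], gt$tau1, tolerance = 1e-6)
})

test_that("planted distributions summarize the designated subensemble", {
  case <- small_case(seed = 9)
  cfg <- case$config
  d <- case$distributions
  expect_setequal(d$atom_label, cfg$scored_sites)
  closed <- case$ground_truth$env_id[case$ground_truth$basin == "closed"]
  sub <- case$predictions[case$predictions$env_id %in% closed &
                            case$predictions$atom_label == "H1", ]
  expect_equal(d$mu[d$atom_label == "H1"], mean(sub$shift))
  expect_equal(d$sigma[d$atom_label == "H1"], sd(sub$shift))
  # closed-form check of the planted mean: delta0 + A exp(-r/r0) over the
  # basin's geometric spread (plus zero-mean noise)
  r_bar <- mean(case$ground_truth$r_ha[case$ground_truth$basin == "closed"])
  expect_equal(d$mu[d$atom_label == "H1"],
               unname(cfg$delta0["H1"]) + cfg$a_hb * exp(-r_bar / cfg$r0),
               tolerance = 0.05)
  # sigma floor engages for a coupling-free noiseless site
  case0 <- make_benchmark_case("planted_hbond", seed = 3, n_runs = 1,
                               n_frames = 2, molecules_per_frame = 6,
                               noise_sigma = 0, b_tau = 0)
  expect_true(any(case0$distributions$sigma == 0.01))
})

test_that("benchmark presets carry their planted expectations", {
  case <- small_case("null", seed = 2)
  expect_equal(case$expected$bias_fraction, 0.5)
  expect_equal(case$config$a_hb, 0)
  expect_error(make_benchmark_case("bogus"), "arg")
  # null preset: distributions come from the whole ensemble
  expect_match(case$distributions$source[1], "all")
})

test_that("benchmark fixtures write a self-contained directory", {
  dir <- withr::local_tempdir()
  case <- make_benchmark_case("planted_hbond", seed = 3, n_runs = 1,
                              n_frames = 2, molecules_per_frame = 6,
                              out_dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("ensemble.extxyz", "predictions.csv", "distributions.csv",
      "ground_truth.json", "config.yaml")))))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$preset, "planted_hbond")
  expect_equal(length(gt$ground_truth$env_id), 12)
})
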