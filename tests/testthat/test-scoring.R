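test_that("per-shift probability is the two-sided gaussian tail", {
  d <- shift_distribution("H1", mu = 4, sigma = 0.5)
  expect_equal(shift_probability(4.0, d), 1.0)
  # reference values of the two-sided normal tail
  expect_equal(shift_probability(4.5, d), 0.3173105, tolerance = 1e-6)
  expect_equal(shift_probability(5.5, d), 0.002699796, tolerance = 1e-6)
  # symmetry
  expect_equal(shift_probability(3.5, d), shift_probability(4.5, d))
  expect_error(shift_probability(NaN, d), "non-finite")
})

test_that("probability decreases with deviation and increases with width", {
  d <- shift_distribution("H1", mu = 0, sigma = 1)
  devs <- seq(0, 5, by = 0.25)
  p <- shift_probability(devs, d)
  expect_true(all(diff(p) < 0))
  widths <- c(0.5, 1, 2, 4)
  pw <- vapply(widths, function(s)
    shift_probability(1, shift_distribution("H1", 0, s)), 0)
  expect_true(all(diff(pw) > 0))
})

test_that("environment p-value is the geometric mean of site probabilities", {
  mk <- function(p) {
    # invert the tail probability to a deviation so score_environment
    # reproduces exactly the wanted per-site p
    dev <- -qnorm(p / 2)
    dists <- shift_distribution(paste0("C", seq_along(p)),
                                mu = rep(0, length(p)),
                                sigma = rep(1, length(p)))
    shifts <- setNames(dev, dists$atom_label)
    score_environment(shifts, dists)
  }
  expect_equal(mk(c(1, 1, 1))$pvalue, 1)
  expect_equal(mk(c(0.04, 0.25))$pvalue, 0.1, tolerance = 1e-12)
  for (x in c(0.001, 0.5)) {
    expect_equal(mk(c(1, 1, x))$pvalue, x^(1 / 3), tolerance = 1e-12)
  }
})

test_that("geometric mean is invariant to atom ordering", {
  dists <- shift_distribution(c("A1", "B1", "C1"), c(1, 2, 3) * 0,
                              c(1, 2, 0.5),
                              nucleus = c("1H", "1H", "1H"))
  shifts <- c(A1 = 0.7, B1 = -1.1, C1 = 0.2)
  p1 <- score_environment(shifts, dists)$pvalue
  p2 <- score_environment(shifts[c(3, 1, 2)], dists)$pvalue
  expect_equal(p1, p2)
})

test_that("lumped peaks score every member against the shared gaussian", {
  dists <- shift_distribution("C13", 100, 2, lumped_with = "C14;C15")
  shifts <- c(C13 = 100, C14 = 102, C15 = 98)
  res <- score_environment(shifts, dists,
                           atom_subset = c("C13", "C14", "C15"))
  expect_equal(unname(res$per_atom_p["C14"]),
               unname(shift_probability(102, dists)))
  expect_equal(unname(res$per_atom_p["C14"]),
               unname(res$per_atom_p["C15"]))
  expect_error(score_environment(shifts, dists, atom_subset = "C99"),
               "C99")
})

test_that("equivalent protons are averaged before scoring", {
  dists <- shift_distribution("H5", 2.0, 0.2)
  shifts <- c(H5 = 1.8, H5b = 2.2)
  res <- score_environment(shifts, dists, atom_subset = "H5",
                           equivalent_groups = list(c("H5", "H5b")))
  expect_equal(unname(res$pvalue), 1)  # mean(1.8, 2.2) == mu
})

test_that("ranking selects the top-N with deterministic tie-breaks", {
  scores <- data.frame(env_id = c("e1", "e2", "e3", "e4"),
                       pvalue = c(0.9, 0.5, 0.7, 0.2))
  sel <- rank_and_select(scores, 3)
  expect_equal(sel$nmr_set, c("e1", "e3", "e2"))
  expect_equal(sel$min_selected_pvalue, 0.5)
  # saturation
  expect_equal(rank_and_select(scores, 10)$nmr_set, sel$md_set)
  # ties broken lexicographically by env_id
  tie <- data.frame(env_id = c("b", "a", "c"), pvalue = c(0.5, 0.5, 0.5))
  expect_equal(rank_and_select(tie, 2)$nmr_set, c("a", "b"))
  expect_error(rank_and_select(data.frame(env_id = c("a", "a"),
                                          pvalue = c(1, 1)), 1),
               "duplicate")
})

test_that("selection satisfies the threshold property on random scores", {
  set.seed(31)
  scores <- data.frame(env_id = sprintf("env%05d", 1:1000),
                       pvalue = round(runif(1000), 2))  # forces ties
  sel <- rank_and_select(scores, 400)
  inside <- scores$pvalue[match(sel$nmr_set, scores$env_id)]
  outside <- scores$pvalue[!scores$env_id %in% sel$nmr_set]
  expect_gte(min(inside), max(outside))
})

test_that("dataset scoring equals the per-environment oracle", {
  case <- small_case(seed = 5)
  sel <- score_dataset(case$predictions, case$distributions,
                       n = case$config$nmr_set_size)
  # oracle: score each environment independently, then sort in memory
  ids <- unique(case$predictions$env_id)
  pv <- vapply(ids, function(id) {
    d <- case$predictions[case$predictions$env_id == id, ]
    score_environment(setNames(d$shift, d$atom_label),
                      case$distributions,
                      atom_subset = case$config$scored_sites)$pvalue
  }, 0)
  oracle <- rank_and_select(data.frame(env_id = ids, pvalue = unname(pv)),
                            case$config$nmr_set_size)
  expect_equal(sel$nmr_set, oracle$nmr_set)
  expect_equal(sel$ranked$pvalue, oracle$ranked$pvalue, tolerance = 1e-12)
})

test_that("dataset scoring handles degenerate and invalid streams", {
  dists <- shift_distribution("H1", 4, 0.5)
  one <- data.frame(env_id = "r_0_1", atom_label = "H1", shift = 4.3)
  sel <- score_dataset(one, dists, n = 5)
  expect_equal(sel$nmr_set, "r_0_1")
  expect_equal(sel$min_selected_pvalue,
               unname(shift_probability(4.3, dists)))
  dup <- rbind(one, data.frame(env_id = "r_0_2", atom_label = "H1",
                               shift = 4),
               one)
  expect_error(score_dataset(dup, dists, n = 1), "duplicate env_id")
})

test_that("infinitely wide distributions reduce selection to tie-breaks", {
  dists <- shift_distribution(c("H1", "N7"), c(4, 115), c(1e9, 1e9))
  preds <- data.frame(
    env_id = rep(c("b_env", "a_env", "c_env"), each = 2),
    atom_label = rep(c("H1", "N7"), 3),
    shift = c(4.5, 110, 3.2, 119, 8, 140))
  sel <- score_dataset(preds, dists, n = 2)
  expect_true(all(abs(sel$ranked$pvalue - 1) < 1e-6))
  expect_equal(sel$nmr_set, c("a_env", "b_env"))
})

test_that("prediction tables read shifts or referenced shieldings", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("run_id,frame,molecule,atom_label,shielding_ppm",
               "run1,0,1,H1,27.78",
               "run1,0,1,C2,150.04"), f)
  p <- read_predictions(f)
  expect_equal(p$shift, c(3.00, 20.00))
  expect_equal(p$env_id, c("run1_0_1", "run1_0_1"))
})
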