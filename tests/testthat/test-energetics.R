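test_that("cluster membership respects the cutoff boundary", {
  fr <- two_molecule_frame(gap = 6)
  cl <- extract_cluster(fr, 1, cutoff = 7)
  expect_equal(cl$members, 2L)
  expect_equal(extract_cluster(two_molecule_frame(gap = 8), 1, 7)$members,
               integer(0))
  # boundary inclusive
  expect_equal(extract_cluster(two_molecule_frame(gap = 7), 1, 7)$members,
               2L)
  expect_error(extract_cluster(two_molecule_frame(gap = 3, box = 12), 1,
                               cutoff = 7), "half the shortest cell")
})

test_that("cluster membership matches the brute-force image search", {
  set.seed(41)
  for (i in 1:10) {
    fr <- random_frame(n_mol = 8)
    cl <- extract_cluster(fr, 3, cutoff = 6)
    expect_equal(cl$members, brute_members(fr, 3, 6))
    # every member's returned coordinates lie within the cutoff directly
    # (minimum-image copies nearest the central molecule)
    C <- as.matrix(cl$atoms[cl$atoms$molecule == 3,
                            c("x", "y", "z")])
    for (m in cl$members) {
      P <- as.matrix(cl$atoms[cl$atoms$molecule == m, c("x", "y", "z")])
      expect_lte(min(shiftsel:::proxy_dist(P, C)), 6)
    }
  }
})

test_that("toy backend is pairwise, local and invariant", {
  be <- toy_backend()
  # isolated molecule: no intermolecular pairs, zero energy
  fr <- two_molecule_frame(gap = 6)
  solo <- fr$atoms[fr$atoms$molecule == 1, ]
  expect_equal(be(solo), 0)
  cl <- extract_cluster(fr, 1, 7)
  fe <- formation_energy(cl, be)
  expect_equal(fe$e_without, 0)
  expect_equal(fe$e_central, 0)
  expect_equal(fe$delta, fe$e_with)

  # permutation invariance
  perm <- cl$atoms[sample(nrow(cl$atoms)), ]
  expect_equal(be(perm), be(cl$atoms), tolerance = 1e-12)

  # rigid-motion invariance
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  P <- as.matrix(cl$atoms[, c("x", "y", "z")]) %*% R
  moved <- cl$atoms
  moved[, c("x", "y", "z")] <- sweep(P, 2, c(5, -3, 11), "+")
  expect_equal(be(moved), be(cl$atoms), tolerance = 1e-9)

  # locality: molecules beyond the truncation radius contribute nothing
  far <- fr$atoms[fr$atoms$molecule == 2, ]
  far$molecule <- 3L
  far$x <- far$x + 40
  expect_equal(be(rbind(cl$atoms, far)), be(cl$atoms), tolerance = 1e-12)
})

test_that("pair energies match independent arithmetic", {
  be <- toy_backend()
  # two single-atom molecules at the donor-acceptor well position
  mk <- function(r, el1, el2) {
    data.frame(molecule = c(1L, 2L), atom_label = c("X1", "X2"),
               element = c(el1, el2), x = c(0, r), y = 0, z = 0,
               stringsAsFactors = FALSE)
  }
  for (r in c(1.9, 2.5, 3.0, 3.3674, 5.5, 9.9)) {
    expect_equal(be(mk(r, "H", "N")), analytic_pair_energy(r, "H", "N"),
                 tolerance = 1e-12)
    expect_equal(be(mk(r, "C", "C")), analytic_pair_energy(r, "C", "C"),
                 tolerance = 1e-12)
    # hydrogens carry no LJ term
    expect_equal(be(mk(r, "H", "C")), 0)
  }
  # H...N at the well: delta for the dimer equals the well depth (minus
  # the vanishing tail correction)
  cl <- structure(list(env_id = "t_0_1", central = 1L, members = 2L,
                       atoms = mk(1.9, "H", "N")),
                  class = "mol_cluster")
  expect_equal(formation_energy(cl, be)$delta,
               analytic_pair_energy(1.9, "H", "N"), tolerance = 1e-12)
  expect_equal(analytic_pair_energy(1.9, "H", "N"), -10)
})

test_that("delta decomposes exactly into central-member pair sums", {
  be <- toy_backend()
  set.seed(51)
  for (i in 1:5) {
    fr <- random_frame(n_mol = 6)
    cl <- extract_cluster(fr, 2, cutoff = 6)
    if (!length(cl$members)) next
    fe <- formation_energy(cl, be)
    A <- cl$atoms
    C <- A[A$molecule == 2, ]
    pair_sum <- sum(vapply(cl$members, function(m) {
      M <- A[A$molecule == m, ]
      s <- 0
      for (a in seq_len(nrow(C))) for (b in seq_len(nrow(M))) {
        r <- sqrt(sum((as.numeric(C[a, c("x", "y", "z")]) -
                         as.numeric(M[b, c("x", "y", "z")]))^2))
        s <- s + analytic_pair_energy(r, C$element[a], M$element[b])
      }
      s
    }, 0))
    expect_equal(fe$delta, pair_sum, tolerance = 1e-9)
  }
})

test_that("file-based backend returns stored cluster energies", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("env_id,e_with,e_without,e_central",
               "runA_0_1,-120.5,-80.25,-30.5"), f)
  fb <- file_backend(f)
  cl <- structure(list(env_id = "runA_0_1", central = 1L,
                       members = integer(0),
                       atoms = data.frame()), class = "mol_cluster")
  fe <- formation_energy(cl, fb)
  expect_equal(fe$delta, -120.5 - (-80.25) - (-30.5))
  cl$env_id <- "missing_env"
  expect_error(formation_energy(cl, fb), "no stored energies")
})

test_that("MD reference sampling is per-run, seeded and validated", {
  env_table <- data.frame(
    env_id = paste0("e", 1:40),
    run_id = rep(c("run1", "run2"), each = 20))
  s1 <- sample_md_environments(env_table, per_run = 10, seed = 5)
  s2 <- sample_md_environments(env_table, per_run = 10, seed = 5)
  s3 <- sample_md_environments(env_table, per_run = 10, seed = 6)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_length(s1, 20)
  expect_equal(sum(s1 %in% env_table$env_id[1:20]), 10)
  # exhaustive sampling returns the whole run
  s4 <- sample_md_environments(env_table, per_run = 20, seed = 1)
  expect_setequal(s4, env_table$env_id)
  expect_error(sample_md_environments(env_table, per_run = 21, seed = 1),
               "run1")
})

test_that("energy profiles are referenced to the MD minimum bin", {
  feats <- setNames(c(1, 1.2, 2.6, 2.8, 1.4, 2.5), paste0("e", 1:6))
  ens <- setNames(c(-20, -20, -10, -10, -20, -10), paste0("e", 1:6))
  prof <- binned_energy_profile(feats, ens, c(1, 2, 3),
                                md_ids = paste0("e", 1:6))
  expect_equal(prof$mean_rel, c(0, 10))
  expect_equal(prof$spread, c(0, 0))
  expect_equal(attr(prof, "reference"), -20)
  expect_equal(sum(prof$count), 6)

  # both sets share the MD zero
  prof2 <- binned_energy_profile(feats, ens, c(1, 2, 3),
                                 md_ids = paste0("e", 1:4),
                                 nmr_ids = paste0("e", 5:6))
  expect_equal(prof2$mean_rel[prof2$set == "nmr"], c(0, 10))
  expect_error(binned_energy_profile(feats, ens, c(1, 2, 3),
                                     md_ids = "zz"), "no overlap")
})

test_that("planted well geometries produce lower energy bins", {
  # dimers: H...N contact at the well distance vs far apart
  be <- toy_backend()
  mk_fr <- function(r, i) {
    atoms <- data.frame(
      molecule = c(1L, 1L, 2L),
      atom_label = c("O1", "H1", "N1"),
      element = c("O", "H", "N"),
      x = c(-0.97, 0, r), y = 0, z = 0, stringsAsFactors = FALSE)
    new_frame(atoms, run_id = "w", frame_index = i)
  }
  frames <- c(lapply(1:6, function(i) mk_fr(1.9, i)),
              lapply(7:12, function(i) mk_fr(6.0, i)))
  envs <- environments(frames)
  ids <- envs$env_id[envs$molecule == 1]
  # the H...N contact is intermolecular here, so take the planted
  # distances directly as the binning feature
  feats <- setNames(rep(c(1.9, 6.0), each = 6), ids)
  deltas <- vapply(ids, function(id) {
    e <- envs[envs$env_id == id, ]
    fr <- frames[[which(vapply(frames, function(f)
      f$frame_index == e$frame, TRUE))[1]]]
    formation_energy(extract_cluster(fr, 1, 7), be)$delta
  }, 0)
  prof <- binned_energy_profile(feats, deltas, c(0, 4, 8), md_ids = ids)
  gap <- prof$mean_rel[2] - prof$mean_rel[1]
  expected_gap <- analytic_pair_energy(6.0, "H", "N") +
    analytic_pair_energy(6.0 + 0.97, "O", "N") -
    (analytic_pair_energy(1.9, "H", "N") +
       analytic_pair_energy(2.87, "O", "N"))
  expect_equal(gap, expected_gap, tolerance = 1e-9)
  # the H-bonded bin sits below the unbonded bin by roughly the well depth
  expect_lt(prof$mean_rel[1], prof$mean_rel[2])
  expect_equal(gap, 10, tolerance = 0.1)
})
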