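test_that("anchor_variance finds the least-variant window", {
  toy <- make_toy_complex(toy_complex_spec(loop_flex_sigma = 0))
  pep <- select_atoms(toy$receptor, selection(chain = "P"))

  # identical peptides: variance 0 at every defined offset
  pv <- anchor_variance(list(pep, pep), list(list("P", 268), list("P", 268)),
                        window_radius = 2, window_size = 4)
  defined <- !is.na(pv$variance)
  expect_true(all(pv$variance[defined] == 0))
  expect_true(0 %in% pv$window)

  # synthetic trio: 0.2 A jitter inside offsets -1..+2, 3 A jitter outside
  set.seed(21)
  jitter_at <- function(s, offs, sd) {
    xyz <- coords(s)
    res <- s$atoms$resseq - 268L
    hit <- res %in% offs
    xyz[hit, ] <- xyz[hit, ] + matrix(rnorm(3 * sum(hit), sd = sd),
                                      sum(hit), 3)
    set_coords(s, xyz)
  }
  # peptide spans offsets -2..+3 around residue 268
  make_var <- function() jitter_at(jitter_at(pep, -1:2, 0.2),
                                   c(-2, 3), 3)
  trio <- list(make_var(), make_var(), make_var())
  pv2 <- anchor_variance(trio, rep(list(list("P", 268)), 3),
                         window_radius = 2, window_size = 4)
  expect_equal(sort(pv2$window), -1:2)
  expect_true(all(pv2$variance[pv2$offsets %in% (-1:2)] <
                    pv2$variance[pv2$offsets == -2], na.rm = TRUE))

  # offsets outside the peptide are reported undefined, not dropped
  pv3 <- anchor_variance(list(pep, pep), rep(list(list("P", 268)), 2),
                         window_radius = 4)
  expect_true(any(is.na(pv3$variance)))
  expect_equal(length(pv3$variance), 9L)
})

test_that("dock_by_anchor reproduces the constructed-feasible solution", {
  toy <- make_toy_complex(toy_complex_spec(loop_flex_sigma = 0))
  d <- dock_by_anchor(toy$receptor, toy$substrate, toy$modified_residue,
                      toy$ref_residue)
  expect_equal(d$anchor_rmsd, 0, tolerance = 1e-8)
  expect_equal(d$clash_count, 0L)
  expect_true(d$accepted)

  # anchor RMSD is invariant to rigid pre-transformation of the conformer
  set.seed(3)
  moved <- apply_transform(toy$substrate,
                           list(rotation = oracle_rotation(),
                                translation = runif(3, -30, 30)))
  d2 <- dock_by_anchor(toy$receptor, moved, toy$modified_residue,
                       toy$ref_residue)
  expect_equal(d2$anchor_rmsd, d$anchor_rmsd, tolerance = 1e-8)
  expect_equal(coords(d2$pose), coords(d$pose), tolerance = 1e-6)

  # missing window atoms are reported by name
  clipped <- select_atoms(toy$substrate,
                          selection(resseq = c(266:269, 200:219)))
  expect_error(dock_by_anchor(toy$receptor, clipped, toy$modified_residue,
                              toy$ref_residue), "missing anchor-window")
})

test_that("clash counts equal the O(n^2) oracle and are monotone in cutoff", {
  far_a <- random_struct(10, seed = 1)
  far_b <- random_struct(10, chain = "B", seed = 2)
  far_b <- set_coords(far_b, coords(far_b) + 100)
  expect_equal(count_clashes(far_a, far_b), 0L)

  two_a <- set_coords(random_struct(1, seed = 3), matrix(c(0, 0, 0), 1))
  two_b <- set_coords(random_struct(1, chain = "B", seed = 4),
                      matrix(c(2.4, 0, 0), 1))
  expect_equal(count_clashes(two_a, two_b, 2.5), 1L)
  expect_equal(count_clashes(two_a, two_b, 2.3), 0L)

  set.seed(31)
  for (k in 1:5) {
    a <- random_struct(50, seed = k)
    b <- random_struct(50, chain = "B", seed = k + 100)
    for (cut in c(2.5, 5)) {
      expect_equal(count_clashes(a, b, cut),
                   oracle_pair_count(coords(a), coords(b), cut))
    }
    # monotone: count non-decreasing in clash_distance
    expect_lte(count_clashes(a, b, 2.5), count_clashes(a, b, 4))
  }
})

test_that("dock_ensemble yields one record per conformer", {
  toy <- make_toy_complex(toy_complex_spec(loop_flex_sigma = 0))
  cs <- sample_generations(toy$substrate,
                           generation_schedule(n_generations = 1, seed = 17))
  ens <- dock_ensemble(toy$receptor, cs, toy$modified_residue,
                       toy$ref_residue)
  expect_equal(length(ens$members), nframes(cs$frames))
  expect_true(all(vapply(ens$members, `[[`, 0L, "clash_count") >= 0))
})

test_that("reduce_ensemble separates basins and honors the requested count", {
  toy <- make_toy_complex(toy_complex_spec(loop_flex_sigma = 0))

  # 100 poses in two separated basins -> n = 2 recovers the partition
  set.seed(12)
  mk <- function(shift, n) lapply(seq_len(n), function(i) {
    s <- toy$substrate
    s <- set_coords(s, coords(s) + shift +
                      matrix(rnorm(3 * natoms(s), sd = 0.05), natoms(s), 3))
    list(receptor = toy$receptor, pose = s, anchor_rmsd = runif(1),
         clash_count = 0L, accepted = TRUE)
  })
  members <- c(mk(0, 50), mk(12, 50))
  ens <- structure(list(members = members, labels = NULL,
                        representatives = NULL),
                   class = "complex_ensemble")
  red <- reduce_ensemble(ens, 2)
  expect_equal(length(red$representatives), 2L)
  expect_equal(length(unique(red$labels[1:50])), 1L)
  expect_equal(length(unique(red$labels[51:100])), 1L)
  # representative = lowest anchor_rmsd member of its cluster
  for (r in red$representatives) {
    cl <- which(red$labels == red$labels[r])
    expect_equal(members[[r]]$anchor_rmsd,
                 min(vapply(members[cl], `[[`, 0, "anchor_rmsd")))
  }

  # n >= ensemble size -> everyone is a representative
  red_all <- reduce_ensemble(ens, 150)
  expect_equal(sort(red_all$representatives), 1:100)

  expect_error(reduce_ensemble(ens, 0), "n_representatives")

  # deterministic under fixed input ordering
  red2 <- reduce_ensemble(ens, 2)
  expect_identical(red$labels, red2$labels)
  expect_identical(red$representatives, red2$representatives)
})
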