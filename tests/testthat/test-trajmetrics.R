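# Two-chain Ca-only topology with controllable geometry.
two_domain_struct <- function(n_a = 5, n_b = 5, seed = 1, spread = 8) {
  set.seed(seed)
  n <- n_a + n_b
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n), name = "CA", altloc = "",
    resname = "ALA", chain = rep(c("A", "B"), c(n_a, n_b)),
    resseq = c(seq_len(n_a), seq_len(n_b)), icode = "", occupancy = 1,
    element = "C")
  new_struct(atoms, matrix(round(rnorm(3 * n, sd = spread), 3), nrow = 1))
}

test_that("native contacts match the double-loop oracle", {
  # two atoms 4 A apart -> one pair with r0 = 4; 6 A apart -> none
  s <- two_domain_struct(1, 1)
  s <- set_coords(s, rbind(c(0, 0, 0), c(4, 0, 0)))
  traj <- bind_frames(list(s))
  nc <- build_native_contacts(traj, selection(chain = "A"),
                              selection(chain = "B"), reference_frame = 1)
  expect_equal(length(nc$i), 1L)
  expect_equal(nc$r0, 4)

  s6 <- set_coords(s, rbind(c(0, 0, 0), c(6, 0, 0)))
  expect_warning(nc6 <- build_native_contacts(bind_frames(list(s6)),
                                              selection(chain = "A"),
                                              selection(chain = "B")),
                 "no native contacts")
  expect_equal(length(nc6$i), 0L)

  # random interface vs oracle
  for (k in 1:5) {
    sr <- two_domain_struct(8, 8, seed = k, spread = 4)
    trajr <- bind_frames(list(sr))
    ncr <- build_native_contacts(trajr, selection(chain = "A"),
                                 selection(chain = "B"), cutoff = 5)
    ia <- which(sr$atoms$chain == "A"); ib <- which(sr$atoms$chain == "B")
    expect_equal(length(ncr$i),
                 oracle_pair_count(coords(sr)[ia, , drop = FALSE],
                                   coords(sr)[ib, , drop = FALSE], 5))
  }
})

test_that("Q has the right limits, midpoint, and matches direct summation", {
  # reference frame with r0 >= 3 gives Q ~ 1
  s <- two_domain_struct(4, 4, seed = 2, spread = 3)
  # force all inter-chain distances into [4, 5): two parallel 4-atom rows
  xyz <- rbind(cbind(seq(0, 3, 1), 0, 0), cbind(seq(0, 3, 1), 4, 0))
  s <- set_coords(s, xyz)
  traj <- bind_frames(list(s))
  nc <- build_native_contacts(traj, selection(chain = "A"),
                              selection(chain = "B"))
  expect_true(all(nc$r0 >= 3))
  expect_gte(q_fraction(traj, nc)[1], 1 - 1e-5)

  # single pair at r = lambda * r0 exactly -> Q = 0.5
  p <- two_domain_struct(1, 1)
  p <- set_coords(p, rbind(c(0, 0, 0), c(4, 0, 0)))
  ncp <- build_native_contacts(bind_frames(list(p)), selection(chain = "A"),
                               selection(chain = "B"))
  stretched <- set_coords(p, rbind(c(0, 0, 0), c(1.8 * 4, 0, 0)))
  expect_equal(q_fraction(bind_frames(list(stretched)), ncp), 0.5,
               tolerance = 1e-12)

  # 10x expansion breaks every contact
  blown <- set_coords(p, rbind(c(0, 0, 0), c(40, 0, 0)))
  expect_lt(q_fraction(bind_frames(list(blown)), ncp), 1e-6)

  # 20-frame random trajectory vs direct per-pair summation oracle
  base <- two_domain_struct(6, 6, seed = 3, spread = 4)
  traj20 <- make_trajectory(base, 20, noise_sigma = 1, seed = 5)
  nc20 <- build_native_contacts(traj20, selection(chain = "A"),
                                selection(chain = "B"),
                                reference_frame = 20)
  got <- q_fraction(traj20, nc20, beta = 5, lambda = 1.8)
  for (fr in c(1, 7, 20)) {
    xyz <- coords(traj20, fr)
    acc <- 0
    for (m in seq_along(nc20$i)) {
      r <- sqrt(sum((xyz[nc20$i[m], ] - xyz[nc20$j[m], ])^2))
      acc <- acc + 1 / (1 + exp(5 * (r - 1.8 * nc20$r0[m])))
    }
    expect_equal(got[fr], acc / length(nc20$i), tolerance = 1e-12)
  }
  expect_true(all(got >= 0 & got <= 1))

  # invariance to global rigid motion of a frame
  R <- oracle_rotation()
  moved <- traj20
  moved <- set_coords(moved, coords(traj20, 1) %*% R + 7, 1)
  expect_equal(q_fraction(moved, nc20)[1], got[1], tolerance = 1e-10)

  expect_error(q_fraction(traj20, list(i = integer(0), j = integer(0),
                                       r0 = numeric(0))), "empty")
})

test_that("Q decreases when distances scale up from the reference", {
  base <- two_domain_struct(5, 5, seed = 4, spread = 4)
  traj <- bind_frames(list(base))
  nc <- build_native_contacts(traj, selection(chain = "A"),
                              selection(chain = "B"))
  qs <- vapply(c(1, 1.5, 2, 3, 5), function(f) {
    q_fraction(bind_frames(list(set_coords(base, coords(base) * f))), nc)
  }, 0)
  expect_true(all(diff(qs) <= 1e-12))
})

test_that("contact frequency matches brute force; static maps are 0/1", {
  # static pair at 4 A -> 1.0; alternating 4/6 -> 0.5
  p <- two_domain_struct(1, 1)
  near <- set_coords(p, rbind(c(0, 0, 0), c(4, 0, 0)))
  far <- set_coords(p, rbind(c(0, 0, 0), c(6, 0, 0)))
  traj <- bind_frames(list(near, far, near, far))
  cm <- contact_frequency(traj, selection(chain = "A"),
                          selection(chain = "B"))
  expect_equal(as.numeric(cm$freq), 0.5)
  cm_static <- contact_frequency(bind_frames(rep(list(near), 4)),
                                 selection(chain = "A"),
                                 selection(chain = "B"))
  expect_equal(as.numeric(cm_static$freq), 1.0)

  # static trajectories only ever produce frequencies 0 or 1
  st <- two_domain_struct(6, 6, seed = 8, spread = 5)
  cmap <- contact_frequency(bind_frames(rep(list(st), 3)),
                            selection(chain = "A"), selection(chain = "B"))
  expect_true(all(cmap$freq %in% c(0, 1)))

  # random trajectory vs per-frame min-distance brute force
  base <- two_domain_struct(4, 4, seed = 9, spread = 4)
  trj <- make_trajectory(base, 6, noise_sigma = 1.2, seed = 10)
  got <- contact_frequency(trj, selection(chain = "A"),
                           selection(chain = "B"), cutoff = 5)
  ia <- which(base$atoms$chain == "A"); ib <- which(base$atoms$chain == "B")
  for (ra in 1:4) for (rb in 1:4) {
    hits <- 0
    for (fr in 1:6) {
      xyz <- coords(trj, fr)
      dmin <- sqrt(sum((xyz[ia[ra], ] - xyz[ib[rb], ])^2))
      if (dmin < 5) hits <- hits + 1
    }
    expect_equal(got$freq[ra, rb], hits / 6)
  }

  expect_error(contact_frequency(trj, selection(chain = "A"),
                                 selection(chain = "B"),
                                 frame_window = integer(0)), "empty")
})

test_that("interface_pairs thresholds and sorts", {
  M <- matrix(c(0.9, 0.1, 0.3, 0.7), 2, 2,
              dimnames = list(c("A 1 ", "A 2 "), c("B 1 ", "B 2 ")))
  got <- interface_pairs(M, 0.5)
  expect_equal(nrow(got), 2L)
  expect_equal(got$frequency, c(0.9, 0.7))
  expect_equal(got$residue_a[1], "A 1 ")
  expect_equal(nrow(interface_pairs(M, 1.1)), 0L)

  # planted persistent pairs recovered exactly at an intermediate threshold
  base <- two_domain_struct(5, 5, seed = 12, spread = 30)  # far apart
  ia <- which(base$atoms$chain == "A"); ib <- which(base$atoms$chain == "B")
  planted <- list(list(i = ia[2], j = ib[3], freq = 0.9),
                  list(i = ia[4], j = ib[1], freq = 0.85))
  trj <- make_trajectory(base, 400, planted_pairs = planted,
                         noise_sigma = 0.05, seed = 13)
  cmap <- contact_frequency(trj, selection(chain = "A"),
                            selection(chain = "B"))
  hits <- interface_pairs(cmap, 0.5)
  expect_equal(nrow(hits), 2L)
  expect_setequal(paste(hits$residue_a, hits$residue_b),
                  c("A 2  B 3 ", "A 4  B 1 "))
})

test_that("domain geometry series composes center and angle oracles", {
  base <- two_domain_struct(4, 4, seed = 14, spread = 6)
  # add a third chain
  extra <- two_domain_struct(3, 1, seed = 15, spread = 6)
  extra$atoms$chain <- "C"
  full <- cat_structs(list(base, extra))
  doms <- list(a = selection(chain = "A"), b = selection(chain = "B"),
               c = selection(chain = "C"))

  static <- bind_frames(rep(list(full), 3))
  ser <- domain_geometry_series(static, doms)
  expect_equal(nrow(ser), 3L)
  expect_equal(length(unique(ser$d12)), 1L)
  expect_equal(length(unique(ser$angle)), 1L)

  # translating one domain apart by 10 A at frame 2 jumps d12 by 10
  shifted <- full
  xyz <- coords(full)
  iA <- select_idx(full, doms$a)
  dir <- geometric_center(full, doms$a) - geometric_center(full, doms$b)
  dir <- dir / sqrt(sum(dir^2))
  xyz[iA, ] <- xyz[iA, ] + matrix(10 * dir, length(iA), 3, byrow = TRUE)
  shifted <- set_coords(shifted, xyz)
  traj <- bind_frames(list(full, shifted))
  s2 <- domain_geometry_series(traj, doms)
  expect_equal(s2$d12[2] - s2$d12[1], 10, tolerance = 1e-8)

  # random frames match composition of the exported primitives
  trj <- make_trajectory(full, 4, noise_sigma = 1, seed = 16)
  ser3 <- domain_geometry_series(trj, doms)
  for (fr in 1:4) {
    ca <- geometric_center(trj, doms$a, fr)
    cb <- geometric_center(trj, doms$b, fr)
    cc <- geometric_center(trj, doms$c, fr)
    expect_equal(ser3$d12[fr], sqrt(sum((ca - cb)^2)), tolerance = 1e-12)
    expect_equal(ser3$angle[fr], interdomain_angle(ca, cb, cc),
                 tolerance = 1e-12)
  }
})

test_that("analysis-window convention: last 40% of 1000 frames is 400", {
  w <- last_fraction_window(1000, 0.4)
  expect_equal(length(w), 400L)
  expect_equal(w[1], 601L)
  expect_equal(w[400], 1000L)
})
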