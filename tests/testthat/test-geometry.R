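# Independent oracle for kabsch: numerical search over rotations
# parameterised by Euler angles (coarse grid + Nelder-Mead polish), never
# touching the SVD path.
grid_search_rmsd <- function(mobile, ref) {
  obj <- function(ang) {
    R <- axis_rot(c(1, 0, 0), ang[1]) %*% axis_rot(c(0, 1, 0), ang[2]) %*%
      axis_rot(c(0, 0, 1), ang[3])
    m <- sweep(mobile, 2, colMeans(mobile)) %*% R
    r <- sweep(ref, 2, colMeans(ref))
    sqrt(mean(rowSums((m - r)^2)))
  }
  axis_rot <- function(ax, th) {
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                3, 3, byrow = TRUE)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- Inf; best_ang <- c(0, 0, 0)
  for (a in grid) for (b in grid) for (c in grid) {
    v <- obj(c(a, b, c))
    if (v < best) { best <- v; best_ang <- c(a, b, c) }
  }
  stats::optim(best_ang, obj, control = list(reltol = 1e-14,
                                             maxit = 5000))$value
}

test_that("kabsch recovers exact and noisy rigid transforms", {
  set.seed(42)
  p <- matrix(rnorm(12, sd = 3), 4, 3)

  r0 <- kabsch(p, p)
  expect_equal(r0$rmsd, 0, tolerance = 1e-10)
  expect_equal(r0$rotation, diag(3), tolerance = 1e-8)

  # pure translation of the reference
  rt <- kabsch(p, sweep(p, 2, c(5, 0, 0), "+"))
  expect_equal(rt$rmsd, 0, tolerance = 1e-10)
  expect_equal(rt$translation, c(5, 0, 0), tolerance = 1e-8)
  # and the symmetric direction
  expect_equal(kabsch(sweep(p, 2, c(5, 0, 0), "+"), p)$translation,
               c(-5, 0, 0), tolerance = 1e-8)

  # rotated + noised copy vs independent rotation-search oracle
  R <- oracle_rotation()
  ref <- p %*% R + matrix(rnorm(12, sd = 0.3), 4, 3)
  got <- kabsch(p, ref)$rmsd
  expect_equal(got, grid_search_rmsd(p, ref), tolerance = 1e-3)
})

test_that("kabsch contracts: dimensions, degeneracy, properness", {
  p <- matrix(rnorm(12), 4, 3)
  expect_error(kabsch(p, p[1:3, ]), "dimension")
  col <- cbind(1:5, 0, 0)   # collinear points: no unique rotation
  res <- kabsch(col, col + 2)
  expect_true(res$degenerate)
  expect_equal(res$rmsd, 0, tolerance = 1e-10)

  # properties: det +1 and invariance to rigid pre-transformation
  set.seed(7)
  for (k in 1:10) {
    a <- matrix(rnorm(18, sd = 4), 6, 3)
    b <- matrix(rnorm(18, sd = 4), 6, 3)
    fit <- kabsch(a, b)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
    expect_lt(max(abs(crossprod(fit$rotation) - diag(3))), 1e-8)
    pre <- a %*% oracle_rotation() + matrix(runif(3, -9, 9), 6, 3,
                                            byrow = TRUE)
    expect_equal(kabsch(pre, b)$rmsd, fit$rmsd, tolerance = 1e-8)
    expect_equal(kabsch(b, a)$rmsd, fit$rmsd, tolerance = 1e-8)  # symmetry
  }
})

test_that("rmsd_series handles static, shifted, and random-walk trajectories", {
  base <- random_struct(20, seed = 1)
  static <- bind_frames(rep(list(base), 5))
  expect_equal(rmsd_series(static), rep(0, 5), tolerance = 1e-10)

  shifted <- base
  shifted <- set_coords(shifted, coords(base) + 3 / sqrt(3))
  traj <- bind_frames(list(base, shifted))
  expect_equal(rmsd_series(traj, fit = TRUE)[2], 0, tolerance = 1e-8)
  expect_equal(rmsd_series(traj, fit = FALSE)[2], 3, tolerance = 1e-8)

  # random-walk trajectory equals per-frame kabsch applied independently
  set.seed(9)
  walk <- Reduce(function(s, i) set_coords(s, coords(s) +
                                             matrix(rnorm(60, sd = .5), 20, 3)),
                 1:4, accumulate = TRUE, init = base)
  traj <- bind_frames(walk)
  got <- rmsd_series(traj, ref_frame = 1)
  exp <- vapply(walk, function(s) kabsch(coords(s), coords(base))$rmsd, 0)
  expect_equal(got, exp, tolerance = 1e-10)

  expect_error(rmsd_series(traj, sel = selection(chain = "Z")), "empty")
})

test_that("geometric centers and inter-domain angles match direct arithmetic", {
  one <- random_struct(1, seed = 2)
  one <- set_coords(one, matrix(c(1, 2, 3), 1))
  expect_equal(geometric_center(one), c(1, 2, 3))

  two <- random_struct(2, seed = 3)
  two <- set_coords(two, rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_equal(geometric_center(two), c(0, 0, 0))

  ten <- random_struct(10, seed = 4)
  expect_equal(geometric_center(ten), colMeans(coords(ten)), tolerance = 1e-12)
  expect_error(geometric_center(ten, selection(chain = "Q")), "empty")

  expect_equal(interdomain_angle(c(-1, 0, 0), c(0, 0, 0), c(2, 0, 0)), 180)
  expect_equal(interdomain_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0)), 90)
  expect_error(interdomain_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")

  # oracle + rigid-motion invariance on random triples
  set.seed(11)
  for (k in 1:10) {
    abc <- matrix(rnorm(9, sd = 5), 3, 3)
    u <- abc[1, ] - abc[2, ]; v <- abc[3, ] - abc[2, ]
    oracle <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    expect_equal(interdomain_angle(abc[1, ], abc[2, ], abc[3, ]), oracle,
                 tolerance = 1e-9)
    R <- oracle_rotation(); t <- runif(3, -20, 20)
    moved <- abc %*% R + matrix(t, 3, 3, byrow = TRUE)
    expect_equal(interdomain_angle(moved[1, ], moved[2, ], moved[3, ]),
                 oracle, tolerance = 1e-9)
  }
})
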