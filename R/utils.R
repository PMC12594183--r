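# Internal numerical helpers shared across modules.

# All-pairs Euclidean distance between the rows of a (n x 3) and b (m x 3).
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Uniform random rotation matrices via unit quaternions (Shoemake).
rand_rotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Rotation about axis `ax` (unit) by `theta` radians (Rodrigues).
axis_rotation <- function(ax, theta) {
  ax <- ax / sqrt(sum(ax^2))
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Index window for "last `fraction` of the frames" analysis convention.
last_fraction_window <- function(n_frames, fraction) {
  stopifnot(n_frames >= 1, fraction > 0, fraction <= 1)
  k <- max(1L, round(n_frames * fraction))
  seq.int(n_frames - k + 1L, n_frames)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
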