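# Synthetic fixtures with known ground truth: toy structures exercising the
# docking geometry, trajectories with planted contact dynamics, and noisy
# assay tables. Everything is seed-deterministic and built in code — no
# binary fixtures anywhere.

# Ideal alpha-helix backbone: rise 1.5 A per residue, 100 degrees per turn,
# Ca radius 2.3 A; N, C, O placed at fixed offsets in the rotating frame
# (coarse but stereochemically sensible for distance logic).
.helix_backbone <- function(n_res, origin = c(0, 0, 0), axis = c(0, 0, 1),
                            phase = 0) {
  rot_to_axis <- function(v) {
    v <- v / sqrt(sum(v^2))
    z <- c(0, 0, 1)
    if (sum((v - z)^2) < 1e-12) return(diag(3))
    if (sum((v + z)^2) < 1e-12) return(diag(c(1, -1, -1)))
    ax <- c(z[2] * v[3] - z[3] * v[2], z[3] * v[1] - z[1] * v[3],
            z[1] * v[2] - z[2] * v[1])
    axis_rotation(ax, acos(max(-1, min(1, sum(z * v)))))
  }
  R <- rot_to_axis(axis)
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    th <- phase + (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    frame <- function(r, dth, dz)
      c(r * cos(th + dth), r * sin(th + dth), z + dz)
    ca <- frame(2.3, 0, 0)
    nn <- frame(1.8, -35 * pi / 180, -0.8)
    cc <- frame(2.0, 30 * pi / 180, 0.7)
    oo <- frame(3.1, 40 * pi / 180, 0.8)
    out[[i]] <- rbind(nn, ca, cc, oo)
  }
  xyz <- do.call(rbind, out) %*% t(R)
  sweep(xyz, 2, origin, "+")
}

# Extended-strand backbone along +x: Ca every 3.5 A with a small zig-zag.
.strand_backbone <- function(n_res, origin = c(0, 0, 0)) {
  out <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    x <- (i - 1) * 3.5
    zig <- 0.5 * (-1)^i
    ca <- c(x, zig, 0)
    nn <- c(x - 1.2, -zig * 0.5, 0.3)
    cc <- c(x + 1.2, -zig * 0.5, -0.3)
    oo <- c(x + 1.4, -zig * 0.5, -1.5)
    out[[i]] <- rbind(nn, ca, cc, oo)
  }
  sweep(do.call(rbind, out), 2, origin, "+")
}

.backbone_struct <- function(xyz, chain, resseq_start, resname = "ALA",
                             serial_start = 1L, modified_resseq = NULL) {
  n_res <- nrow(xyz) / 4L
  resseq <- rep(resseq_start + seq_len(n_res) - 1L, each = 4L)
  name <- rep(c("N", "CA", "C", "O"), n_res)
  resname <- rep(resname, length.out = 4L * n_res)
  if (!is.null(modified_resseq))
    resname[resseq == modified_resseq] <- "ALY"   # acetyl-lysine flag
  atoms <- data.frame(record = "ATOM",
                      serial = serial_start + seq_len(4L * n_res) - 1L,
                      name = name, altloc = "", resname = resname,
                      chain = chain, resseq = resseq, icode = "",
                      occupancy = 1,
                      element = substr(name, 1, 1))
  new_struct(atoms, matrix(as.numeric(t(xyz)), nrow = 1))
}

#' Specification of the toy deacetylase-substrate system
#'
#' Describes the synthetic stand-in for a sirtuin receptor with a reference
#' acetyl-peptide bound in its active-site groove, a substrate domain whose
#' flexible loop carries the modified (acetyl-lysine analog) residue, and an
#' accessory three-helix bundle.
#'
#' @param receptor_size receptor residue count, split over two groove
#'   helices (default 40).
#' @param groove_peptide_length reference peptide length (default 6; the
#'   modified residue sits at index 2, 0-based).
#' @param modified_resseq residue number assigned to the modified residue
#'   (default 268, so the peptide spans 266-271).
#' @param accessory_helices helix count of the accessory bundle (default 3).
#' @param accessory_helix_len residues per accessory helix (default 8).
#' @param loop_flex_sigma Gaussian jitter (Å) applied to the substrate loop
#'   backbone (default 0.3); 0 makes the loop identical to the reference
#'   peptide backbone.
#' @param body_helix_len residues of the substrate body helix (default 20).
#' @param seed RNG seed (default 2024).
#' @return list of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(receptor_size = 40L, groove_peptide_length = 6L,
                             modified_resseq = 268L, accessory_helices = 3L,
                             accessory_helix_len = 8L, loop_flex_sigma = 0.3,
                             body_helix_len = 20L, seed = 2024L) {
  stopifnot(groove_peptide_length >= 4L)
  structure(as.list(environment()), class = "toy_complex_spec")
}

#' Generate the toy receptor/substrate/accessory structures
#'
#' Constructs, deterministically for a given seed:
#' \itemize{
#'  \item `receptor`: chain R, two parallel helices flanking a surface groove,
#'    plus chain P, the reference peptide (extended strand) lying in the
#'    groove with its modified residue flagged by resname `ALY`;
#'  \item `substrate`: chain S, a copy of the reference-peptide backbone
#'    (the flexible loop, jittered by `loop_flex_sigma`) fused to a body
#'    helix extending away from the receptor, so the native loop
#'    conformation docks with zero clashes by construction;
#'  \item `accessory`: chain B, a three-helix bundle placed in free space.
#' }
#'
#' @param spec a [toy_complex_spec()].
#' @return list with `receptor` (chains R+P), `substrate` (chain S),
#'   `accessory` (chain B), and bookkeeping: `modified_residue`
#'   (chain/resseq of the substrate's modified residue), `ref_residue`
#'   (same for the reference peptide), `spec`.
#' @export
make_toy_complex <- function(spec = toy_complex_spec()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  set.seed(spec$seed)
  np <- spec$groove_peptide_length
  res0 <- spec$modified_resseq - 2L             # modified residue at index 2
  pep_xyz <- .strand_backbone(np)
  peptide <- .backbone_struct(pep_xyz, "P", res0,
                              modified_resseq = spec$modified_resseq)

  n_per <- spec$receptor_size %/% 2L
  helA <- .helix_backbone(n_per, origin = c(0, -5.5, -5), axis = c(1, 0, 0))
  helB <- .helix_backbone(spec$receptor_size - n_per,
                          origin = c(0, 5.5, -5), axis = c(1, 0, 0),
                          phase = pi)
  recA <- .backbone_struct(helA, "R", 1L)
  recB <- .backbone_struct(helB, "R", n_per + 1L,
                           serial_start = 4L * n_per + 1L)
  receptor <- cat_structs(list(recA, recB, peptide))

  # substrate: loop copies the reference peptide backbone, body helix rises
  # away from the receptor (+z), fused at the loop's far end
  loop_xyz <- pep_xyz
  if (spec$loop_flex_sigma > 0)
    loop_xyz <- loop_xyz + matrix(stats::rnorm(length(loop_xyz),
                                               sd = spec$loop_flex_sigma),
                                  nrow(loop_xyz), 3)
  body_xyz <- .helix_backbone(spec$body_helix_len,
                              origin = c((np - 1) * 3.5 / 2, 0, 6),
                              axis = c(0, 0, 1))
  loop <- .backbone_struct(loop_xyz, "S", res0,
                           modified_resseq = spec$modified_resseq)
  body <- .backbone_struct(body_xyz, "S", 200L,
                           serial_start = 4L * np + 1L)
  substrate <- cat_structs(list(loop, body))

  # accessory three-helix bundle, off in free space
  acc <- lapply(seq_len(spec$accessory_helices), function(h) {
    .helix_backbone(spec$accessory_helix_len,
                    origin = c(60 + 6 * cos(2 * pi * h / 3),
                               6 * sin(2 * pi * h / 3), 0),
                    axis = c(0, 0, if (h %% 2) 1 else -1))
  })
  acc_structs <- lapply(seq_along(acc), function(h)
    .backbone_struct(acc[[h]], "B",
                     100L + (h - 1L) * spec$accessory_helix_len,
                     serial_start = 1L + (h - 1L) * 4L * spec$accessory_helix_len))
  accessory <- cat_structs(acc_structs)

  list(receptor = receptor, substrate = substrate, accessory = accessory,
       modified_residue = list("S", spec$modified_resseq),
       ref_residue = list("P", spec$modified_resseq),
       spec = spec)
}

#' Synthetic trajectory with planted contact dynamics
#'
#' Produces a multi-frame structure over a given topology in which each
#' planted atom pair is in contact (3.9 Å) in a stated fraction of frames
#' (independent Bernoulli draws) and separated (6.5 Å) otherwise, while all
#' other atoms receive isotropic Gaussian jitter. Ground truth is therefore
#' known exactly for contact-frequency and Q analyses.
#'
#' @param topology single-frame `struct`.
#' @param n_frames frame count.
#' @param planted_pairs list of `list(i =, j =, freq =)` atom-index pairs
#'   with target contact frequencies in [0, 1]; atom `j` is repositioned
#'   relative to atom `i`.
#' @param noise_sigma Å jitter for all atoms (default 0.1).
#' @param seed RNG seed.
#' @return multi-frame `struct`.
#' @export
make_trajectory <- function(topology, n_frames, planted_pairs = list(),
                            noise_sigma = 0.1, seed = 2024L) {
  stopifnot(inherits(topology, "struct"), n_frames >= 1)
  for (p in planted_pairs)
    stopifnot(p$i <= natoms(topology), p$j <= natoms(topology),
              p$freq >= 0, p$freq <= 1)
  set.seed(seed)
  base <- coords(topology)
  n <- natoms(topology)
  frames <- matrix(NA_real_, n_frames, 3L * n)
  for (fr in seq_len(n_frames)) {
    xyz <- base
    if (noise_sigma > 0)
      xyz <- xyz + matrix(stats::rnorm(3 * n, sd = noise_sigma), n, 3)
    for (p in planted_pairs) {
      dir <- base[p$j, ] - base[p$i, ]
      if (sum(dir^2) < 1e-12) dir <- c(1, 0, 0)
      dir <- dir / sqrt(sum(dir^2))
      d <- if (stats::runif(1) < p$freq) 3.9 else 6.5
      xyz[p$j, ] <- xyz[p$i, ] + dir * d
    }
    frames[fr, ] <- as.numeric(t(xyz))
  }
  new_struct(topology$atoms, frames)
}

#' Serial-dilution concentration ladder
#'
#' Two-fold dilutions from `top` (default 12.5 µM, 10 points reaching
#' ~0.024 µM, emulating a 12.5-0.02 µM titration design).
#'
#' @param top highest concentration, µM.
#' @param n_points number of dilutions.
#' @return numeric vector, ascending.
#' @export
titration_concentrations <- function(top = 12.5, n_points = 10L)
  sort(top / 2^(seq_len(n_points) - 1))

#' Synthetic assay datasets with known ground truth
#'
#' Draws titration, CD-melt, and nanoDSF tables from the stated generative
#' models: a Hill binding isotherm over a serial dilution, a sigmoid melt
#' over 20-80 °C, and a logistic 350/330 nm ratio over 25-90 °C, each with
#' homoscedastic Gaussian noise of standard deviation `noise_frac` times the
#' dynamic range, in `replicates` replicates.
#'
#' @param true_kd µM (default 0.24).
#' @param true_tm °C (default 45.11).
#' @param true_ti °C (default 52.19).
#' @param hill_n Hill coefficient of the titration truth (default 1).
#' @param noise_frac noise SD as a fraction of the dynamic range
#'   (default 0.03).
#' @param replicates replicate count (default 3).
#' @param seed RNG seed.
#' @param concentrations titration ladder (default
#'   [titration_concentrations()]).
#' @return list of class `assay_data`: `titration`, `melt`, `nanodsf`
#'   data.frames (long format with `replicate`), plus `truth`.
#' @export
make_assay_data <- function(true_kd = 0.24, true_tm = 45.11, true_ti = 52.19,
                            hill_n = 1, noise_frac = 0.03, replicates = 3L,
                            seed = 2024L,
                            concentrations = titration_concentrations()) {
  stopifnot(noise_frac >= 0, replicates >= 1)
  set.seed(seed)
  base_fp <- 60; amp_fp <- 260          # polarization plateaus (mP-like)
  tit <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- hill_curve(concentrations, base_fp, amp_fp, true_kd, hill_n)
    data.frame(concentration = concentrations,
               signal = mu + stats::rnorm(length(mu),
                                          sd = noise_frac * (amp_fp - base_fp)),
               replicate = r)
  }))
  temps_cd <- seq(20, 80, by = 0.5)
  melt <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- hill_curve(temps_cd, -20, -2, true_tm, 60)   # 222 nm signal decay
    data.frame(temperature = temps_cd,
               signal = mu + stats::rnorm(length(mu), sd = noise_frac * 18),
               replicate = r)
  }))
  temps_dsf <- seq(25, 90, by = 0.25)
  dsf <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    mu <- 0.8 + 0.4 / (1 + exp(-(temps_dsf - true_ti) / 1.5))
    data.frame(temperature = temps_dsf,
               signal = mu + stats::rnorm(length(mu), sd = noise_frac * 0.4),
               replicate = r)
  }))
  structure(list(titration = tit, melt = melt, nanodsf = dsf,
                 truth = list(kd = true_kd, tm = true_tm, ti = true_ti,
                              hill_n = hill_n, noise_frac = noise_frac)),
            class = "assay_data")
}
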