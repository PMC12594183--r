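#' Native inter-domain contacts from a reference frame
#'
#' Collects all inter-domain heavy-atom pairs whose distance in the
#' reference frame is below `cutoff` (5 Å by default), storing the reference
#' distance r0 of each pair. The protocol takes the *last* frame of a
#' simulation as the reference; any frame index may be given.
#'
#' @param traj multi-frame `struct`.
#' @param domain_a,domain_b [selection()]s defining the two domains
#'   (hydrogens and HETATM records are excluded regardless).
#' @param reference_frame frame index; defaults to the last frame.
#' @param cutoff Å (default 5).
#' @return list of class `native_contacts`: `i`, `j` (atom indices into
#'   `traj`), `r0` (Å), `reference_frame`, `cutoff`. Empty sets are returned
#'   with a warning.
#' @export
build_native_contacts <- function(traj, domain_a, domain_b,
                                  reference_frame = nframes(traj),
                                  cutoff = 5) {
  stopifnot(reference_frame >= 1, reference_frame <= nframes(traj))
  ia <- intersect(select_idx(traj, domain_a), heavy_idx(traj))
  ib <- intersect(select_idx(traj, domain_b), heavy_idx(traj))
  xyz <- coords(traj, reference_frame)
  D <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  hit <- which(D < cutoff, arr.ind = TRUE)
  if (nrow(hit) == 0)
    warning("no native contacts under cutoff ", cutoff, " A")
  structure(list(i = ia[hit[, 1]], j = ib[hit[, 2]],
                 r0 = D[hit], reference_frame = reference_frame,
                 cutoff = cutoff), class = "native_contacts")
}

#' Fraction of native contacts Q per frame (Best-Hummer-Eaton)
#'
#' For each frame X, `Q(X) = (1/N) sum_ij 1 / (1 + exp(beta * (r_ij(X) -
#' lambda * r0_ij)))` over the native pair list: a soft count of preserved
#' reference contacts, in [0, 1] per frame. `beta` is a sharpness in 1/Å
#' (default 5) and `lambda` a dimensionless tolerance factor (default 1.8).
#'
#' @param traj multi-frame `struct`.
#' @param contacts a [build_native_contacts()] result (must be non-empty).
#' @param beta 1/Å (default 5).
#' @param lambda dimensionless (default 1.8).
#' @return numeric vector, Q per frame.
#' @export
q_fraction <- function(traj, contacts, beta = 5, lambda = 1.8) {
  if (length(contacts$i) == 0) stop("empty native contact set")
  thr <- lambda * contacts$r0
  vapply(seq_len(nframes(traj)), function(fr) {
    xyz <- coords(traj, fr)
    r <- sqrt(rowSums((xyz[contacts$i, , drop = FALSE] -
                       xyz[contacts$j, , drop = FALSE])^2))
    mean(1 / (1 + exp(beta * (r - thr))))
  }, 0)
}

# residue grouping key for a set of atom indices
.res_key <- function(s, idx)
  paste(s$atoms$chain[idx], s$atoms$resseq[idx], s$atoms$icode[idx])

#' Residue contact-frequency map between two domains
#'
#' For every residue pair (one residue from each domain), the fraction of
#' analysed frames in which the minimum inter-residue heavy-atom distance is
#' below `cutoff`. This is the "persistence of interaction" map used to read
#' off which residue pairs hold an interface together over a trajectory.
#'
#' @inheritParams build_native_contacts
#' @param frame_window integer frame indices to analyse (e.g.
#'   `last_fraction_window(nframes(traj), 0.4)` for the last 40% of a run);
#'   default all frames.
#' @return object of class `contact_map`: `freq` matrix (rows = domain-a
#'   residues, cols = domain-b residues, dimnames "chain resseq"), `cutoff`,
#'   `n_frames`.
#' @export
contact_frequency <- function(traj, domain_a, domain_b, cutoff = 5,
                              frame_window = NULL) {
  frame_window <- frame_window %||% seq_len(nframes(traj))
  if (length(frame_window) == 0) stop("empty frame window")
  stopifnot(all(frame_window >= 1), all(frame_window <= nframes(traj)))
  ia <- intersect(select_idx(traj, domain_a), heavy_idx(traj))
  ib <- intersect(select_idx(traj, domain_b), heavy_idx(traj))
  if (!length(ia) || !length(ib)) stop("empty domain selection")
  ra <- .res_key(traj, ia); rb <- .res_key(traj, ib)
  ures_a <- unique(ra); ures_b <- unique(rb)
  ga <- match(ra, ures_a); gb <- match(rb, ures_b)
  counts <- matrix(0, length(ures_a), length(ures_b),
                   dimnames = list(ures_a, ures_b))
  for (fr in frame_window) {
    xyz <- coords(traj, fr)
    D <- cross_dist(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
    hit <- D < cutoff
    # residue-pair contact = any atom pair under cutoff
    touched <- unique(cbind(ga[row(D)[hit]], gb[col(D)[hit]]))
    if (nrow(touched)) counts[touched] <- counts[touched] + 1
  }
  structure(list(freq = counts / length(frame_window), cutoff = cutoff,
                 n_frames = length(frame_window)), class = "contact_map")
}

#' Persistent interface pairs from a contact-frequency map
#'
#' @param map a [contact_frequency()] result (or a bare frequency matrix).
#' @param min_frequency report pairs with frequency >= this value.
#' @return data.frame (residue_a, residue_b, frequency), sorted by
#'   descending frequency; empty when nothing passes.
#' @export
interface_pairs <- function(map, min_frequency = 0.5) {
  M <- if (inherits(map, "contact_map")) map$freq else as.matrix(map)
  hit <- which(M >= min_frequency, arr.ind = TRUE)
  out <- data.frame(residue_a = rownames(M)[hit[, 1]] %||% hit[, 1],
                    residue_b = colnames(M)[hit[, 2]] %||% hit[, 2],
                    frequency = M[hit])
  out[order(-out$frequency), , drop = FALSE]
}

#' Per-frame inter-domain geometry series
#'
#' For three domain definitions (conventionally accessory NTD, catalytic
#' domain, substrate), computes per frame the three pairwise distances
#' between domain geometric centers and the angle at the second domain's
#' center (the NTD–CD–substrate angle describing the relative orientation of
#' the domains).
#'
#' @param traj multi-frame `struct`.
#' @param domains named list of exactly three [selection()]s.
#' @return data.frame: frame, d12, d13, d23 (Å), angle (degrees, vertex at
#'   domain 2).
#' @export
domain_geometry_series <- function(traj, domains) {
  stopifnot(length(domains) == 3)
  out <- lapply(seq_len(nframes(traj)), function(fr) {
    ctr <- lapply(domains, function(sel) geometric_center(traj, sel, fr))
    data.frame(frame = fr,
               d12 = sqrt(sum((ctr[[1]] - ctr[[2]])^2)),
               d13 = sqrt(sum((ctr[[1]] - ctr[[3]])^2)),
               d23 = sqrt(sum((ctr[[2]] - ctr[[3]])^2)),
               angle = interdomain_angle(ctr[[1]], ctr[[2]], ctr[[3]]))
  })
  do.call(rbind, out)
}

#' Descriptive equilibration frame from an RMSD series
#'
#' Reports the first frame after which the RMSD stays within `band` Å of the
#' mean over the trailing stable stretch — a descriptive diagnostic, never
#' auto-applied to analyses.
#'
#' @param r numeric RMSD series.
#' @param band Å half-width (default 0.5).
#' @return frame index, or NA if the series never settles.
#' @export
detect_equilibration <- function(r, band = 0.5) {
  n <- length(r)
  for (k in seq_len(n)) {
    tail_mean <- mean(r[k:n])
    if (all(abs(r[k:n] - tail_mean) <= band)) return(k)
  }
  NA_integer_
}
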