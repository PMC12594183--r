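#' Distance restraint between two named atoms
#'
#' Encodes the linker-length restraint used when re-attaching an accessory
#' domain: the distance between an atom on the accessory C-terminus
#' (`atom_a`) and one on the catalytic-domain N-terminus (`atom_b`) must not
#' exceed `max_distance` (the protocol tests 25 and 30 Å). By default each
#' terminus is represented by its Cα.
#'
#' @param atom_a,atom_b lists/vectors `c(chain, resseq, name)`; `name`
#'   defaults to "CA" when omitted.
#' @param max_distance Å, must be positive.
#' @return object of class `restraint`.
#' @export
restraint_spec <- function(atom_a, atom_b, max_distance) {
  stopifnot(max_distance > 0)
  pad <- function(a) {
    a <- as.list(a)
    if (length(a) == 2) a <- c(a, "CA")
    stats::setNames(a, c("chain", "resseq", "name"))
  }
  structure(list(atom_a = pad(atom_a), atom_b = pad(atom_b),
                 max_distance = max_distance), class = "restraint")
}

.resolve_atom <- function(s, at) {
  i <- select_idx(s, selection(chain = at$chain,
                               resseq = as.integer(at$resseq),
                               atoms = at$name))
  if (length(i) != 1)
    stop(sprintf("cannot resolve restraint atom %s:%s %s (matched %d)",
                 at$chain, at$resseq, at$name, length(i)))
  i
}

#' Evaluate a distance restraint for a placed accessory domain
#'
#' @param accessory `struct` of the (placed) accessory domain holding
#'   `atom_a`.
#' @param complex `struct` holding `atom_b`.
#' @param restraint a [restraint_spec()].
#' @return list with `distance` (Å) and `satisfied`
#'   (`distance <= max_distance`).
#' @export
check_restraint <- function(accessory, complex, restraint) {
  pa <- coords(accessory)[.resolve_atom(accessory, restraint$atom_a), ]
  pb <- coords(complex)[.resolve_atom(complex, restraint$atom_b), ]
  d <- sqrt(sum((pa - pb)^2))
  list(distance = d, satisfied = d <= restraint$max_distance)
}

#' Restraint-filtered rigid placement of an accessory domain
#'
#' A transparent stand-in for FFT docking engines: `n_samples` rigid poses of
#' the accessory domain are drawn with uniformly random orientation and the
#' restraint atom placed uniformly in a sampling ball of fixed radius around
#' its partner atom. Poses are then filtered: restraint satisfied, zero
#' heavy-atom clashes, and at least `min_contacts` inter-domain heavy-atom
#' pairs under `contact_cutoff`; survivors are ranked by contact count
#' (descending). The sampling ball radius is independent of `max_distance`,
#' so at a fixed seed the poses retained under a tighter restraint are a
#' subset of those retained under a looser one.
#'
#' @param complex `struct` of the docked receptor-substrate complex.
#' @param accessory single-frame `struct` of the accessory domain.
#' @param restraint a [restraint_spec()].
#' @param n_samples number of random poses (default 10000).
#' @param seed RNG seed (default 2024).
#' @param clash_distance heavy-atom clash threshold, Å (default 2.5).
#' @param min_contacts minimum inter-domain heavy-atom pairs < `contact_cutoff`
#'   for a pose to count as docked rather than grazing (default 10).
#' @param contact_cutoff Å (default 5).
#' @param sampling_radius radius of the positional sampling ball, Å
#'   (default 40; keep it >= `max_distance` and fixed when comparing
#'   restraints).
#' @return list of class `pose_set`: `report` (data.frame: pose, distance,
#'   satisfied, clash_count, contact_count, retained), `poses` (list of
#'   placed accessory `struct`s for retained poses, ranked by contact count),
#'   `ranked` (retained pose ids in rank order), and the call parameters.
#'   Zero retained poses yields an empty set with a warning, not an error.
#' @export
sample_placements <- function(complex, accessory, restraint,
                              n_samples = 10000L, seed = 2024L,
                              clash_distance = 2.5, min_contacts = 10L,
                              contact_cutoff = 5, sampling_radius = 40) {
  stopifnot(inherits(restraint, "restraint"),
            !any(accessory$atoms$chain %in% complex$atoms$chain))
  ia <- .resolve_atom(accessory, restraint$atom_a)
  pb <- coords(complex)[.resolve_atom(complex, restraint$atom_b), ]
  acc_xyz <- coords(accessory)
  anchor <- acc_xyz[ia, ]
  heavy_c <- which(complex$atoms$element != "H")
  cxyz <- coords(complex)[heavy_c, , drop = FALSE]
  heavy_a <- which(accessory$atoms$element != "H")

  set.seed(seed)
  # draw all randomness up-front so pose k is identical across restraint radii
  rots <- replicate(n_samples, rand_rotation(), simplify = FALSE)
  dirs <- matrix(stats::rnorm(3 * n_samples), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  radii <- sampling_radius * stats::runif(n_samples)^(1 / 3)

  distance <- radii
  satisfied <- distance <= restraint$max_distance
  clash_count <- rep(NA_integer_, n_samples)
  contact_count <- rep(NA_integer_, n_samples)
  placed <- vector("list", n_samples)
  for (k in which(satisfied)) {
    target <- pb + radii[k] * dirs[k, ]
    rot <- rots[[k]]
    xyz <- sweep(acc_xyz, 2, anchor) %*% rot
    xyz <- sweep(xyz, 2, target, "+")
    D <- cross_dist(xyz[heavy_a, , drop = FALSE], cxyz)
    clash_count[k] <- sum(D < clash_distance)
    contact_count[k] <- sum(D < contact_cutoff)
    placed[[k]] <- xyz
  }
  retained <- satisfied & !is.na(clash_count) & clash_count == 0 &
    contact_count >= min_contacts
  retained[is.na(retained)] <- FALSE
  if (!any(retained))
    warning("no placement satisfied the restraint/clash/contact criteria")
  ranked <- which(retained)[order(-contact_count[retained],
                                  which(retained))]
  poses <- lapply(ranked, function(k) set_coords(accessory, placed[[k]]))
  structure(list(
    report = data.frame(pose = seq_len(n_samples), distance = distance,
                        satisfied = satisfied, clash_count = clash_count,
                        contact_count = contact_count, retained = retained),
    poses = poses, ranked = ranked, restraint = restraint, seed = seed,
    sampling_radius = sampling_radius), class = "pose_set")
}
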