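#' Anchor-window positional variance across aligned reference complexes
#'
#' Across two or more deacetylase-peptide structures pre-superposed on their
#' catalytic domains, measures how invariant each peptide position is:
#' for each offset relative to the modified residue (offset 0 = the
#' acetyl-lysine), the mean pairwise distance between corresponding backbone
#' atoms is computed, and the contiguous window of `window_size` offsets
#' (containing 0) with the lowest mean deviation is reported. In sirtuin
#' crystal structures this window is -1, 0, +1, +2.
#'
#' @param structs list of `struct` objects (pre-aligned).
#' @param modified_residues list of `c(chain, resseq)` per structure flagging
#'   the acetylated residue.
#' @param window_radius offsets examined are `-window_radius .. +window_radius`.
#' @param window_size length of the contiguous window sought (default 4).
#' @param atoms backbone atom set used for the comparison.
#' @return list of class `positional_variance`: `offsets`, `variance`
#'   (Å, NA where a backbone atom is missing in any structure — reported as
#'   undefined, never silently dropped), `window` (offsets of the
#'   minimal-variance window).
#' @export
anchor_variance <- function(structs, modified_residues, window_radius = 4L,
                            window_size = 4L,
                            atoms = c("N", "CA", "C", "O")) {
  stopifnot(length(structs) >= 2,
            length(modified_residues) == length(structs))
  offsets <- seq.int(-window_radius, window_radius)
  # per structure, per offset: coordinate block of the backbone atoms
  blocks <- lapply(seq_along(structs), function(si) {
    s <- structs[[si]]
    mr <- modified_residues[[si]]
    lapply(offsets, function(off) {
      i <- select_idx(s, selection(chain = mr[[1]],
                                   resseq = as.integer(mr[[2]]) + off,
                                   atoms = atoms))
      if (length(i) != length(atoms)) return(NULL)
      a <- select_atoms(s, selection(chain = mr[[1]],
                                     resseq = as.integer(mr[[2]]) + off,
                                     atoms = atoms))
      coords(a)[match(atoms, a$atoms$name), , drop = FALSE]
    })
  })
  pairs <- utils::combn(length(structs), 2)
  variance <- vapply(seq_along(offsets), function(oi) {
    bl <- lapply(blocks, `[[`, oi)
    if (any(vapply(bl, is.null, TRUE))) return(NA_real_)
    mean(apply(pairs, 2, function(p) {
      mean(sqrt(rowSums((bl[[p[1]]] - bl[[p[2]]])^2)))
    }))
  }, 0)
  # best contiguous window containing offset 0 with all offsets defined
  best <- NULL; best_val <- Inf
  for (st in seq_len(length(offsets) - window_size + 1L)) {
    w <- offsets[st:(st + window_size - 1L)]
    if (!0L %in% w) next
    v <- variance[st:(st + window_size - 1L)]
    if (any(is.na(v))) next
    if (mean(v) < best_val) { best_val <- mean(v); best <- w }
  }
  structure(list(offsets = offsets, variance = variance, window = best),
            class = "positional_variance")
}

#' Count steric clashes between two molecules
#'
#' Number of inter-molecular heavy-atom pairs closer than `clash_distance`.
#' "No significant clashes" in the docking protocol is taken as a count of
#' zero at the default 2.5 Å heavy-atom threshold (both configurable).
#'
#' @param pose,receptor `struct` objects (single frame used).
#' @param clash_distance Å (default 2.5).
#' @return integer clash count.
#' @export
count_clashes <- function(pose, receptor, clash_distance = 2.5) {
  stopifnot(natoms(pose) > 0, natoms(receptor) > 0)
  ia <- which(pose$atoms$element != "H")
  ib <- which(receptor$atoms$element != "H")
  if (!length(ia) || !length(ib)) return(0L)
  D <- cross_dist(coords(pose)[ia, , drop = FALSE],
                  coords(receptor)[ib, , drop = FALSE])
  sum(D < clash_distance)
}

# Backbone window atoms (ordered by offset then atom name) of the residue
# window around `resseq` on `chain`; errors listing anything missing.
.window_coords <- function(s, chain, resseq, window,
                           atoms = c("N", "CA", "C", "O"), frame = 1L) {
  out <- matrix(NA_real_, 0, 3)
  missing <- character(0)
  for (off in window) {
    sel <- selection(chain = chain, resseq = resseq + off, atoms = atoms)
    i <- select_idx(s, sel)
    sub <- s$atoms[i, , drop = FALSE]
    for (nm in atoms) {
      j <- i[sub$name == nm]
      if (length(j) != 1) {
        missing <- c(missing, sprintf("%s:%d %s", chain, resseq + off, nm))
      } else {
        out <- rbind(out, coords(s, frame)[j, ])
      }
    }
  }
  if (length(missing))
    stop("missing anchor-window atoms: ", paste(missing, collapse = ", "))
  out
}

#' Dock a substrate conformer by anchor-window superposition
#'
#' The conformer's backbone window around its modified residue is superposed
#' (Kabsch) onto the matching window of the reference peptide bound in the
#' receptor; the whole conformer is transformed accordingly. The anchor RMSD
#' (post-fit, window atoms) and the clash count against the receptor
#' excluding the reference peptide are recorded; the pose is accepted when
#' the clash count does not exceed `clash_tolerance`.
#'
#' @param receptor `struct` holding the receptor with its bound reference
#'   peptide.
#' @param conformer single-frame `struct` of the substrate.
#' @param modified_residue `c(chain, resseq)` of the acetylated residue in the
#'   conformer.
#' @param ref_residue `c(chain, resseq)` of the acetylated residue of the
#'   reference peptide inside `receptor`.
#' @param window integer offsets of the anchor window (default `-1:2`).
#' @param clash_distance,clash_tolerance steric criterion (defaults 2.5 Å, 0).
#' @param exclude_receptor_sel optional [selection()] removed from the
#'   receptor before clash counting *and* from the docking frame (e.g. an
#'   accessory three-helix bundle detached to free the docking space and
#'   re-attached at the placement stage).
#' @return list of class `docked_complex`: `receptor`, `pose` (transformed
#'   conformer), `anchor_rmsd`, `clash_count`, `accepted`, `transform`.
#' @export
dock_by_anchor <- function(receptor, conformer, modified_residue,
                           ref_residue, window = -1:2,
                           clash_distance = 2.5, clash_tolerance = 0L,
                           exclude_receptor_sel = NULL) {
  stopifnot(0L %in% window)
  if (!is.null(exclude_receptor_sel)) {
    drop <- select_idx(receptor, exclude_receptor_sel)
    if (length(drop)) {
      keep <- setdiff(seq_len(natoms(receptor)), drop)
      cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
      receptor <- new_struct(receptor$atoms[keep, , drop = FALSE],
                             receptor$xyz[, cols, drop = FALSE])
    }
  }
  ref_w <- .window_coords(receptor, ref_residue[[1]],
                          as.integer(ref_residue[[2]]), window)
  mob_w <- .window_coords(conformer, modified_residue[[1]],
                          as.integer(modified_residue[[2]]), window)
  fit <- kabsch(mob_w, ref_w)
  pose <- apply_transform(conformer, fit)
  # receptor minus the reference peptide chain for clash counting
  pep_chain <- ref_residue[[1]]
  rec_noPep <- select_atoms(receptor,
                            selection(chain = setdiff(unique(receptor$atoms$chain),
                                                      pep_chain)))
  cc <- if (natoms(rec_noPep) > 0)
    count_clashes(pose, rec_noPep, clash_distance) else 0L
  structure(list(receptor = receptor, pose = pose, anchor_rmsd = fit$rmsd,
                 clash_count = cc,
                 accepted = cc <= clash_tolerance, transform = fit),
            class = "docked_complex")
}

#' Dock every conformer of a set
#'
#' @param receptor,modified_residue,ref_residue,window,clash_distance,clash_tolerance,exclude_receptor_sel
#'   see [dock_by_anchor()].
#' @param conformers a `conformer_set` (from [sample_generations()]) or a
#'   multi-frame `struct`.
#' @return list of class `complex_ensemble` with `members` (one
#'   `docked_complex` per conformer), `labels`, `representatives` (NULL until
#'   [reduce_ensemble()]).
#' @export
dock_ensemble <- function(receptor, conformers, modified_residue, ref_residue,
                          window = -1:2, clash_distance = 2.5,
                          clash_tolerance = 0L, exclude_receptor_sel = NULL) {
  frames <- if (inherits(conformers, "conformer_set")) conformers$frames
            else conformers
  members <- lapply(seq_len(nframes(frames)), function(fr) {
    conf <- new_struct(frames$atoms, frames$xyz[fr, , drop = FALSE])
    dock_by_anchor(receptor, conf, modified_residue, ref_residue, window,
                   clash_distance, clash_tolerance, exclude_receptor_sel)
  })
  structure(list(members = members, labels = NULL, representatives = NULL),
            class = "complex_ensemble")
}

#' Reduce a docked ensemble to representative structures
#'
#' Hierarchical (average-linkage) clustering of the substrate poses on
#' pairwise Cα-RMSD measured in the common receptor frame (no re-fitting:
#' the receptor provides the frame, avoiding double superposition), cut at
#' `n_representatives` clusters. The representative of each cluster is the
#' member with the lowest anchor RMSD relative to the reference peptide;
#' ties break by lowest clash count, then input order. Deterministic for a
#' fixed input ordering.
#'
#' @param ensemble a `complex_ensemble` from [dock_ensemble()].
#' @param n_representatives requested cluster count (e.g. 60).
#' @return the ensemble with `labels` and `representatives` (member indices)
#'   filled in.
#' @export
reduce_ensemble <- function(ensemble, n_representatives = 60L) {
  stopifnot(inherits(ensemble, "complex_ensemble"),
            length(ensemble$members) >= 1)
  if (n_representatives < 1) stop("n_representatives must be >= 1")
  mem <- ensemble$members
  ca <- select_idx(mem[[1]]$pose, sel_calpha())
  M <- t(vapply(mem, function(m) as.numeric(t(coords(m$pose)[ca, , drop = FALSE])),
                numeric(3L * length(ca))))
  n <- length(mem)
  k <- min(n_representatives, n)
  if (n == 1) { labels <- 1L } else {
    d <- stats::dist(M) / sqrt(length(ca))
    if (max(d) < 1e-12) {
      labels <- seq_len(n)                     # identical poses: arbitrary split
      labels[labels > k] <- k
    } else {
      labels <- stats::cutree(stats::hclust(d, method = "average"), k = k)
    }
  }
  anchor <- vapply(mem, `[[`, 0, "anchor_rmsd")
  clash <- vapply(mem, `[[`, 0L, "clash_count")
  reps <- vapply(sort(unique(labels)), function(cl) {
    m <- which(labels == cl)
    m[order(anchor[m], clash[m], m)][1]
  }, 0L)
  ensemble$labels <- labels
  ensemble$representatives <- reps
  ensemble
}
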