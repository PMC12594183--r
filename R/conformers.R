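#' Anisotropic network model on C-alpha nodes
#'
#' Builds the standard ANM Hessian: for every Cα pair within `cutoff`, the
#' 3x3 super-element is `-gamma * d d' / |d|^2` (d the inter-node vector),
#' diagonal blocks the negative sum of the off-diagonal blocks in their row.
#' A connected network has exactly six zero modes (rigid-body null space);
#' disconnected networks are rejected with the component sizes named.
#'
#' @param x a `struct` (its Cα atoms are the nodes) or an n x 3 matrix of
#'   node coordinates.
#' @param cutoff interaction cutoff in Å (default 15).
#' @param gamma uniform spring constant, arbitrary units (default 1).
#' @return list of class `enm` with `coords`, `hessian`, `evalues` (ascending),
#'   `modes` (columns, matching order), `n_rigid = 6`, `cutoff`, `gamma`.
#' @export
build_anm <- function(x, cutoff = 15, gamma = 1) {
  xyz <- if (inherits(x, "struct")) {
    i <- select_idx(x, sel_calpha())
    coords(x)[i, , drop = FALSE]
  } else as.matrix(x)
  n <- nrow(xyz)
  if (n < 3) stop("need at least 3 C-alpha nodes")
  D <- cross_dist(xyz, xyz)
  adj <- D <= cutoff & D > 0
  comp <- .components(adj)
  if (max(comp) > 1)
    stop(sprintf("disconnected elastic network at cutoff %g: component sizes %s",
                 cutoff, paste(tabulate(comp), collapse = ", ")))
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in which(adj[i, ] & seq_len(n) > i)) {
      d <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(d) / sum(d^2)
      ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
      H[ri, rj] <- blk; H[rj, ri] <- blk
      H[ri, ri] <- H[ri, ri] - blk
      H[rj, rj] <- H[rj, rj] - blk
    }
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(e$values))
  structure(list(coords = xyz, hessian = H, evalues = e$values[ord],
                 modes = e$vectors[, ord, drop = FALSE], n_rigid = 6L,
                 cutoff = cutoff, gamma = gamma), class = "enm")
}

# Connected components of an adjacency matrix by BFS; returns component id.
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0))
    }
  }
  comp
}

#' Generational schedule for conformer sampling
#'
#' Encodes the cluster-expansion schedule used for loop sampling: the cluster
#' cap starts at 20 in generation 1 and grows by 20 per generation (200 by
#' generation 10); each generation deforms every parent along random
#' combinations of the first `modes_used` non-rigid ANM modes, scaled so the
#' child-parent Cα-RMSD equals `step_amplitude`.
#'
#' @param n_generations number of generations (default 10).
#' @param modes_used number of non-rigid global modes combined (default 5).
#' @param step_amplitude Cα-RMSD of each deformation step, Å (default 1.5,
#'   loop-scale perturbation).
#' @param children_per_parent conformers spawned per parent per generation
#'   (default 5).
#' @param cluster_base cap increment per generation (default 20, so the cap
#'   is `20 * g`, reaching 200 at generation 10).
#' @param cluster_cap_max absolute cap (default 200).
#' @param seed RNG seed (default 2024).
#' @return list of class `generation_schedule`.
#' @export
generation_schedule <- function(n_generations = 10L, modes_used = 5L,
                                step_amplitude = 1.5,
                                children_per_parent = 5L,
                                cluster_base = 20L, cluster_cap_max = 200L,
                                seed = 2024L) {
  sched <- structure(list(n_generations = as.integer(n_generations),
                          modes_used = as.integer(modes_used),
                          step_amplitude = step_amplitude,
                          children_per_parent = as.integer(children_per_parent),
                          cluster_base = as.integer(cluster_base),
                          cluster_cap_max = as.integer(cluster_cap_max),
                          seed = as.integer(seed)),
                     class = "generation_schedule")
  sched
}

#' @rdname generation_schedule
#' @param sched a `generation_schedule`.
#' @param g generation index (1-based).
#' @return cluster cap for generation `g`.
#' @export
clusters_per_generation <- function(sched, g)
  pmin(sched$cluster_base * as.integer(g), sched$cluster_cap_max)

#' Hierarchical clustering of conformer frames by C-alpha RMSD
#'
#' Average-linkage agglomerative clustering on pairwise Cα-RMSD, cut to at
#' most `k_max` clusters. Because conformers produced by mode-following share
#' one coordinate frame (rigid modes are excluded from the deformations), the
#' RMSD is computed without re-superposition and reduces to a Euclidean
#' distance on flattened coordinates, which keeps large pools fast.
#' The representative of a cluster is the member with the lowest mean RMSD
#' to its co-members.
#'
#' @param frames multi-frame `struct` or an `n_frames x 3n` coordinate matrix
#'   (Cα only).
#' @param k_max maximum number of clusters.
#' @param linkage linkage method for [stats::hclust()] (default "average").
#' @return list with `labels` (per frame), `representatives` (frame indices,
#'   one per cluster), `k` (clusters actually formed).
#' @export
cluster_conformers <- function(frames, k_max, linkage = "average") {
  M <- if (inherits(frames, "struct")) {
    i <- select_idx(frames, sel_calpha())
    cols <- as.vector(rbind(3L * i - 2L, 3L * i - 1L, 3L * i))
    frames$xyz[, cols, drop = FALSE]
  } else as.matrix(frames)
  n <- nrow(M)
  stopifnot(n >= 1, k_max >= 1)
  n_ca <- ncol(M) / 3
  if (n == 1) return(list(labels = 1L, representatives = 1L, k = 1L))
  d <- stats::dist(M) / sqrt(n_ca)          # pairwise Ca-RMSD
  if (max(d) < 1e-12) {
    return(list(labels = rep(1L, n), representatives = 1L, k = 1L))
  }
  hc <- stats::hclust(d, method = linkage)
  labels <- stats::cutree(hc, k = min(k_max, n))
  dm <- as.matrix(d)
  reps <- vapply(sort(unique(labels)), function(cl) {
    m <- which(labels == cl)
    if (length(m) == 1) return(m)
    m[which.min(rowMeans(dm[m, m, drop = FALSE]))]
  }, 0L)
  list(labels = labels, representatives = reps, k = length(reps))
}

# Displace every atom of each residue by its residue's Ca displacement:
# coarse-grained reconstruction of an all-atom conformer from a Ca-level
# deformation field.
.apply_ca_field <- function(struct, ca_idx, disp) {
  xyz <- coords(struct)
  res_key <- paste(struct$atoms$chain, struct$atoms$resseq,
                   struct$atoms$icode)
  ca_key <- res_key[ca_idx]
  map <- match(res_key, ca_key)
  moved <- !is.na(map)
  xyz[moved, ] <- xyz[moved, ] + disp[map[moved], , drop = FALSE]
  set_coords(struct, xyz)
}

#' Generational elastic-network conformer sampling
#'
#' A desk-scale stand-in for cluster-expansion ENM samplers: per generation,
#' each parent conformer gets an ANM rebuilt on its Cα trace; children are
#' spawned by uniform random combinations of the first `modes_used` non-rigid
#' modes scaled to `step_amplitude` Cα-RMSD; the pooled children are clustered
#' ([cluster_conformers()]) under that generation's cap and the cluster
#' representatives seed the next generation. The force-field relaxation of
#' the original method is replaced by amplitude control (see the methods
#' vignette). All representatives across generations are returned.
#'
#' @param x single-frame `struct` with Cα atoms (all-atom structures are
#'   carried along: every atom of a residue moves with its Cα).
#' @param sched a [generation_schedule()].
#' @param cutoff,gamma ANM parameters (see [build_anm()]).
#' @return list of class `conformer_set`: `frames` (multi-frame `struct` of
#'   all representatives), `provenance` (data.frame: frame, generation,
#'   parent), `n_generated` (total children drawn).
#' @export
sample_generations <- function(x, sched = generation_schedule(),
                               cutoff = 15, gamma = 1) {
  stopifnot(inherits(x, "struct"), inherits(sched, "generation_schedule"))
  ca_idx <- select_idx(x, sel_calpha())
  if (sched$n_generations < 1L)
    return(structure(list(frames = NULL, provenance = data.frame(),
                          n_generated = 0L), class = "conformer_set"))
  set.seed(sched$seed)
  parents <- list(x)
  parent_ids <- 0L
  reps_all <- list(); prov <- list(); total <- 0L
  for (g in seq_len(sched$n_generations)) {
    children <- list(); child_parent <- integer(0)
    for (p in seq_along(parents)) {
      par <- parents[[p]]
      anm <- build_anm(coords(par)[ca_idx, , drop = FALSE], cutoff, gamma)
      n_ca <- length(ca_idx)
      usable <- seq.int(anm$n_rigid + 1L,
                        min(anm$n_rigid + sched$modes_used, 3L * n_ca))
      V <- anm$modes[, usable, drop = FALSE]
      for (k in seq_len(sched$children_per_parent)) {
        w <- stats::rnorm(length(usable))
        w <- w / sqrt(sum(w^2)) * sched$step_amplitude * sqrt(n_ca)
        disp <- matrix(V %*% w, ncol = 3, byrow = TRUE)
        children[[length(children) + 1L]] <- .apply_ca_field(par, ca_idx, disp)
        child_parent <- c(child_parent, parent_ids[p])
      }
    }
    total <- total + length(children)
    pool <- bind_frames(children)
    cl <- cluster_conformers(pool, clusters_per_generation(sched, g))
    reps <- cl$representatives
    base_id <- sum(vapply(reps_all, nframes, 0L))
    parents <- children[reps]
    parent_ids <- base_id + seq_along(reps)
    reps_all[[g]] <- bind_frames(children[reps])
    prov[[g]] <- data.frame(generation = g, parent = child_parent[reps])
  }
  frames <- bind_frames(reps_all)
  provenance <- do.call(rbind, prov)
  provenance$frame <- seq_len(nrow(provenance))
  structure(list(frames = frames,
                 provenance = provenance[c("frame", "generation", "parent")],
                 n_generated = total),
            class = "conformer_set")
}
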