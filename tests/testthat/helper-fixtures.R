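# Fixture builders shared across the suite. Everything is generated in code;
# PDB texts are written to tempfiles on demand.

# A random single- or multi-frame structure with simple topology.
random_struct <- function(n_atoms = 10, n_frames = 1, chain = "A",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  atoms <- data.frame(
    record = "ATOM", serial = seq_len(n_atoms),
    name = rep(c("N", "CA", "C", "O"), length.out = n_atoms),
    altloc = "", resname = "ALA", chain = chain,
    resseq = rep(seq_len(ceiling(n_atoms / 4)), each = 4)[seq_len(n_atoms)],
    icode = "", occupancy = 1,
    element = rep(c("N", "C", "C", "O"), length.out = n_atoms))
  xyz <- matrix(round(stats::rnorm(3 * n_atoms * n_frames, sd = 5), 3),
                nrow = n_frames)
  new_struct(atoms, xyz)
}

# Write PDB lines (character vector) to a tempfile, return the path.
pdb_tempfile <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

# A correctly-columned ATOM record.
atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                      occ = 1, altloc = " ", record = "ATOM  ",
                      element = substr(trimws(name), 1, 1)) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name4, altloc, resname, chain, resseq,
          x, y, z, occ, 0, element)
}

# Brute-force O(n^2) inter-molecular pair count below a cutoff (oracle).
oracle_pair_count <- function(a_xyz, b_xyz, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(a_xyz)))
    for (j in seq_len(nrow(b_xyz)))
      if (sqrt(sum((a_xyz[i, ] - b_xyz[j, ])^2)) < cutoff) n <- n + 1L
  n
}

# Random proper rotation matrix (QR-based, independent of package internals).
oracle_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
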