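## shared fixtures and independent oracles

## straight CA chain along +x, spacing in Angstrom
straight_chain <- function(n, chain = "D", resno_start = 1L, spacing = 3.8,
                           y = 0, z = 0) {
  atoms <- data.frame(
    chain = chain, resno = resno_start + seq_len(n) - 1L, insert = "",
    resid = "GLY", elety = "CA",
    x = (seq_len(n) - 1) * spacing, y = y, z = z,
    occ = 1, alt = "", stringsAsFactors = FALSE
  )
  bam_structure("straight_chain", atoms)
}

## random rigid transform applied to a structure, seeded
random_pose <- function(s, seed) {
  R <- random_rotation(seed)
  set.seed(seed + 1000L)
  apply_transform(s, R, runif(3, -40, 40))
}

## independent superposition oracle: exhaustive Euler-angle grid followed
## by Nelder-Mead refinement; never touches the SVD path
euler_rotation <- function(a, b, g) {
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  Rz(a) %*% Ry(b) %*% Rz(g)
}

bf_rmsd <- function(angles, mobile, reference) {
  R <- euler_rotation(angles[1], angles[2], angles[3])
  rotated <- mobile %*% t(R)
  ## for any fixed rotation the optimal translation matches centroids
  fitted <- sweep(rotated, 2, colMeans(reference) - colMeans(rotated), "+")
  sqrt(mean(rowSums((fitted - reference)^2)))
}

brute_force_min_rmsd <- function(mobile, reference, n_grid = 14) {
  a <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  b <- seq(0, pi, length.out = n_grid)
  best <- c(0, 0, 0); best_val <- Inf
  for (ai in a) for (bi in b) for (gi in a) {
    v <- bf_rmsd(c(ai, bi, gi), mobile, reference)
    if (v < best_val) { best_val <- v; best <- c(ai, bi, gi) }
  }
  opt <- stats::optim(best, bf_rmsd, mobile = mobile, reference = reference,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  opt$value
}

## minimal mmCIF writer for CA-only fixtures (auth numbering)
write_mini_cif <- function(structure, path) {
  a <- structure$atoms
  hdr <- c("data_fixture", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
                    "auth_comp_id", "auth_asym_id", "auth_atom_id",
                    "pdbx_PDB_model_num")))
  rows <- sprintf("ATOM %d C %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
                  seq_len(nrow(a)), a$elety, a$resid, a$chain, a$resno,
                  a$x, a$y, a$z, a$resno, a$resid, a$chain, a$elety)
  writeLines(c(hdr, rows), path)
  path
}

## raw PDB ATOM line (for altloc / insertion-code fixtures)
pdb_line <- function(serial, name, alt, resid, chain, resno, icode,
                     x, y, z, occ) {
  sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial, name, alt, resid, chain, resno, icode, x, y, z, occ, 0)
}
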