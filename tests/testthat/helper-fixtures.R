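# shared fixtures, all generated in code

# minimal fixed-width PDB ATOM line
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1.00, alt = "", icode = "", record = "ATOM",
                     element = substr(name, 1, 1)) {
  sprintf("%-6s%5d  %-3s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, icode,
          x, y, z, occ, 0, element)
}

# write a CA-only PDB text for one or more chains given xyz matrices
write_ca_pdb <- function(path, chains_xyz, resno = NULL) {
  lines <- character(0)
  serial <- 0L
  for (ch in names(chains_xyz)) {
    xyz <- chains_xyz[[ch]]
    rn <- if (is.null(resno)) seq_len(nrow(xyz)) else resno[[ch]]
    for (i in seq_len(nrow(xyz))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_line(serial, "CA", "ALA", ch, rn[i],
                                 xyz[i, 1], xyz[i, 2], xyz[i, 3]))
    }
    lines <- c(lines, "TER")
  }
  writeLines(c(lines, "END"), path)
  path
}

# brute-force maximum-probability path for small HMMs (oracle for Viterbi)
brute_force_path <- function(desc, model) {
  k <- length(model$letters)
  m <- nrow(desc)
  ld <- matrix(NA_real_, m, k)
  for (j in seq_len(k)) {
    v <- model$cov[j, ]
    dev <- sweep(desc, 2, model$mean[j, ])
    ld[, j] <- -0.5 * (sum(log(2 * pi * v)) + rowSums(sweep(dev^2, 2, v, "/")))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  score <- log(model$initial)[paths[, 1]] + ld[cbind(1L, paths[, 1])]
  if (m > 1) for (t in 2:m) {
    score <- score + log(model$transition)[cbind(paths[, t - 1], paths[, t])] +
      ld[cbind(t, paths[, t])]
  }
  model$letters[paths[which.max(score), ]]
}

# random proper rotation matrix
random_rotation <- function(seed) {
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# descriptor matrix of a chain (rows = fragments)
chain_descriptors <- function(chain) {
  starts <- fragmentize(chain)
  t(vapply(starts, function(s)
    as.numeric(compute_descriptors(chain$xyz[s:(s + 3), , drop = FALSE])),
    numeric(4)))
}
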