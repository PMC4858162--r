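# independent oracles and fixture builders used across the suite

.cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# brute-force dihedral: angle between the two plane normals via acos, sign
# from the triple product -- a different arithmetic path from the package's
# atan2 formulation
dihedral_oracle <- function(p1, p2, p3, p4) {
  n1 <- .cross(p2 - p1, p3 - p2)
  n2 <- .cross(p3 - p2, p4 - p3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(max(-1, min(1, ct))) * 180 / pi
  s <- sum(.cross(n1, n2) * (p3 - p2))
  if (s < 0) -ang else ang
}

# quaternion (Horn) superposition: best-fit RMSD from the largest eigenvalue
# of the 4x4 key matrix -- independent of the package's SVD route
horn_rmsd <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  S <- t(Xc) %*% Yc
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, sum(Xc^2) + sum(Yc^2) - 2 * lam) / n)
}

random_rotation <- function() {
  axis <- rnorm(3)
  clampring:::rotation_matrix(axis, runif(1, -180, 180))
}

# tiny fixed-column PDB fixtures written from code
write_minimal_pdb <- function(path, coords, n_models = 1L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_models)) {
    if (n_models > 1L) writeLines(sprintf("MODEL %8d", m), con)
    for (i in seq_len(nrow(coords))) {
      writeLines(sprintf(
        "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        i, i, coords[i, 1], coords[i, 2], coords[i, 3]), con)
    }
    if (n_models > 1L) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# reference constants (AKMA-like units)
KB_TEST <- 0.0019872041
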