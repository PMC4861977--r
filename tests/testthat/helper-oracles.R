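# Independent oracles used to cross-check the package's geometry code.

# Horn's closed-form absolute orientation: the optimal rotation is recovered
# from the dominant eigenvector of a 4x4 quaternion matrix - an algorithm
# independent of the SVD-based Kabsch implementation under test.
quaternion_superpose <- function(moving, fixed) {
  cm <- colMeans(moving); cf <- colMeans(fixed)
  A <- sweep(moving, 2, cm); B <- sweep(fixed, 2, cf)
  S <- t(A) %*% B
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  R <- quat_to_rotmat(q)
  moved <- sweep(sweep(moving, 2, cm) %*% t(R), 2, cf, "+")
  list(R = R, rmsd = sqrt(mean(rowSums((moved - fixed)^2))))
}

quat_to_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w*w+x*x-y*y-z*z, 2*(x*y-w*z),     2*(x*z+w*y),
    2*(x*y+w*z),     w*w-x*x+y*y-z*z, 2*(y*z-w*x),
    2*(x*z-w*y),     2*(y*z+w*x),     w*w-x*x-y*y+z*z),
    3, 3, byrow = TRUE)
}

quat_mult <- function(p, q) {
  c(p[1]*q[1] - sum(p[2:4]*q[2:4]),
    p[1]*q[2:4] + q[1]*p[2:4] + c(p[3]*q[4]-p[4]*q[3],
                                  p[4]*q[2]-p[2]*q[4],
                                  p[2]*q[3]-p[3]*q[2]))
}

# rotate vector v by angle theta about unit axis u, via quaternion arithmetic
quat_rotate <- function(v, u, theta) {
  q <- c(cos(theta/2), sin(theta/2) * u)
  qi <- c(q[1], -q[2:4])
  quat_mult(quat_mult(q, c(0, v)), qi)[2:4]
}

# brute-force restraint checker: plain double loop over all residues
brute_validate <- function(candidate, residue_index, model,
                           clash_dist = 3.5, chain_dist = 4.5) {
  r <- match(residue_index, model$index)
  for (k in seq_along(model$index)) {
    if (k == r || !all(is.finite(model$xyz[k, ]))) next
    d <- sqrt(sum((candidate - model$xyz[k, ])^2))
    if (abs(k - r) == 1L) {
      if (d < clash_dist || d > chain_dist) return(FALSE)
    } else if (d < clash_dist) return(FALSE)
  }
  TRUE
}

# brute-force clash count: plain double loop
brute_clashes <- function(xyz, clash_dist = 3.5) {
  n <- nrow(xyz); cnt <- 0L
  for (i in seq_len(n - 2L)) for (j in seq(i + 2L, n)) {
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < clash_dist) cnt <- cnt + 1L
  }
  cnt
}

# minimal hand-rolled PDB writer for parser tests (independent of bio3d)
write_min_pdb <- function(path, resno, xyz, resid = "ALA", chain = "A",
                          elety = " CA ", altloc = " ", ins = rep(" ", length(resno))) {
  resid <- rep_len(resid, length(resno))
  lines <- sprintf(
    "ATOM  %5d %s%s%s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_along(resno), elety, altloc, resid, chain, resno, ins,
    xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(lines, "END"), path)
  path
}

helix40 <- function() make_chain(40, "helix")
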