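# Independent oracles used across the test suite. These are deliberately
# written with different algorithms than the package (Horn's quaternion
# superposition instead of SVD, exhaustive enumeration instead of search) so
# the two routes can disagree when either is wrong.

# Horn (1987) closed-form optimal superposition via the largest eigenvalue of
# the 4x4 quaternion cross-covariance matrix. Maps a onto b.
oracle_superpose <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  A <- sweep(a, 2, ca); B <- sweep(b, 2, cb)
  M <- t(A) %*% B
  S <- function(i, j) M[i, j]
  N <- matrix(c(
    S(1,1)+S(2,2)+S(3,3), S(2,3)-S(3,2),        S(3,1)-S(1,3),        S(1,2)-S(2,1),
    S(2,3)-S(3,2),        S(1,1)-S(2,2)-S(3,3), S(1,2)+S(2,1),        S(3,1)+S(1,3),
    S(3,1)-S(1,3),        S(1,2)+S(2,1),        -S(1,1)+S(2,2)-S(3,3), S(2,3)+S(3,2),
    S(1,2)-S(2,1),        S(3,1)+S(1,3),        S(2,3)+S(3,2),        -S(1,1)-S(2,2)+S(3,3)),
    4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  tvec <- cb - as.numeric(R %*% ca)
  fit <- a %*% t(R)
  fit <- sweep(fit, 2, -tvec)
  list(rotation = R, translation = tvec,
       rmsd = sqrt(mean(rowSums((fit - b)^2))), fit = fit)
}

oracle_fitted_dists <- function(a, b, sel) {
  sp <- oracle_superpose(a[sel, , drop = FALSE], b[sel, , drop = FALSE])
  fit <- sweep(a %*% t(sp$rotation), 2, -sp$translation)
  sqrt(rowSums((fit - b)^2))
}

# exhaustive subset-superposition GDT oracle: fit every residue subset of
# size >= 3 and take the per-cutoff maximum fraction within the cutoff
oracle_gdt <- function(model, reference, cutoffs = c(1, 2, 4, 8)) {
  shared <- intersect(model$residue_index, reference$residue_index)
  a <- model$ca_coords[match(shared, model$residue_index), , drop = FALSE]
  b <- reference$ca_coords[match(shared, reference$residue_index), , drop = FALSE]
  n <- nrow(a)
  best <- rep(0L, length(cutoffs))
  for (mask in seq_len(2^n) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(sel) < 3L) next
    d <- oracle_fitted_dists(a, b, sel)
    for (k in seq_along(cutoffs))
      best[k] <- max(best[k], sum(d <= cutoffs[k]))
  }
  mean(best / n)
}

# brute-force contact enumeration with explicit loops
oracle_contacts <- function(m, threshold, lo, hi) {
  L <- nrow(m)
  out <- NULL
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j <= i) next
    if (j - i >= lo && j - i <= hi && m[i, j] <= threshold)
      out <- rbind(out, c(i, j))
  }
  out
}

# all-pairs greedy clustering oracle for Neff (same definition, explicit)
oracle_neff <- function(rows, cut = 0.62) {
  mm <- do.call(rbind, strsplit(rows, ""))
  qpos <- which(mm[1, ] != "-")
  ident <- function(r1, r2)
    sum(mm[r1, qpos] == mm[r2, qpos] & mm[r1, qpos] != "-" &
          mm[r2, qpos] != "-") / length(qpos)
  reps <- c()
  for (r in seq_len(nrow(mm))) {
    hit <- FALSE
    for (p in reps) if (ident(p, r) > cut) { hit <- TRUE; break }
    if (!hit) reps <- c(reps, r)
  }
  length(reps)
}

# random rigid motion
random_rigid <- function(xyz) {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)), 3, 3, byrow = TRUE)
  sweep(xyz %*% t(R), 2, -stats::rnorm(3, 0, 20))
}

moved_copy <- function(s) {
  ca_structure(random_rigid(s$ca_coords), sequence = s$sequence,
               residue_index = s$residue_index, target_id = s$target_id)
}

# minimal hand-written PDB text for read_model tests
pdb_lines <- function(xyz, resno = seq_len(nrow(xyz)), elety = "CA",
                      altloc = "", chain = "A", resid = "ALA") {
  sprintf("ATOM  %5d  %-3s%1s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          seq_len(nrow(xyz)), elety, altloc, resid, chain, resno,
          xyz[, 1], xyz[, 2], xyz[, 3])
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(lines, "END"), f)
  f
}
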