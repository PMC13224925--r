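# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force rather than calling the implementation paths
# they check.

# brute-force per-residue helical assignment: residue i is helical iff the
# three forward C-alpha distances fall in the stated windows
oracle_helical_flags <- function(xyz, d13 = c(4.9, 6.1), d14 = c(4.7, 5.9),
                                 d15 = c(5.7, 7.1)) {
  n <- nrow(xyz)
  flags <- logical(n)
  for (i in seq_len(n)) {
    if (i + 4 > n) next
    ds <- sapply(2:4, function(k) {
      sqrt(sum((xyz[i, ] - xyz[i + k, ])^2))
    })
    win <- rbind(d13, d14, d15)
    flags[i] <- all(!is.na(ds)) &&
      all(ds >= win[, 1] & ds <= win[, 2])
  }
  flags
}

oracle_segments <- function(flags, min_run = 5) {
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  data.frame(start = starts[keep], end = ends[keep])
}

# direct minimization of RMSD over rigid motions (rotation as Euler angles
# + translation), as a numeric oracle for the closed-form superposition
oracle_rmsd <- function(P, Q) {
  rotmat <- function(a) {
    cx <- cos(a[1]); sx <- sin(a[1])
    cy <- cos(a[2]); sy <- sin(a[2])
    cz <- cos(a[3]); sz <- sin(a[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  f <- function(par) {
    R <- rotmat(par[1:3])
    Pf <- t(R %*% t(P)) + matrix(par[4:6], nrow(P), 3, byrow = TRUE)
    sqrt(mean(rowSums((Pf - Q)^2)))
  }
  best <- Inf
  for (start in list(rep(0, 6), c(pi / 2, 0, 0, 0, 0, 0),
                     c(0, pi, 0, 0, 0, 0), c(pi, pi / 2, pi / 4, 1, 1, 1))) {
    fit <- optim(start, f, method = "BFGS",
                 control = list(maxit = 2000, reltol = 1e-14))
    best <- min(best, fit$value)
  }
  best
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rotate_model <- function(s, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(s[, c("x", "y", "z")])
  new_xyz <- t(R %*% t(xyz)) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  s$x <- new_xyz[, 1]; s$y <- new_xyz[, 2]; s$z <- new_xyz[, 3]
  s
}

# small receptor/tag pair used by fusion and assessment tests
demo_receptor <- function() {
  set.seed(42)
  numbered_sequence("RCPT",
                    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 315, replace = TRUE), collapse = ""),
                    first_auth = 2L)
}

demo_tag <- function(len = 72L, first_auth = 1L) {
  set.seed(7)
  numbered_sequence("TAG",
                    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                 len, replace = TRUE), collapse = ""),
                    first_auth = first_auth)
}
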