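# Independent oracles, deliberately written as direct (slow) restatements of
# the definitions, sharing no code with the implementation.

# exhaustive all-pairs all-frames candidate scan
brute_force_candidates <- function(traj, topo, cutoff = 4.0, stride = 1L) {
  a <- topo$atoms
  lig <- a$atom_index[a$is_ligand & a$is_heavy]
  prot <- a$atom_index[!a$is_ligand & a$is_heavy]
  frames <- seq(1L, traj$n_frames, by = stride)
  out <- NULL
  for (j in prot) for (i in lig) {
    hit <- FALSE
    for (k in frames) {
      d <- sqrt(sum((traj$coords[k, i, ] - traj$coords[k, j, ])^2))
      if (d <= cutoff) { hit <- TRUE; break }
    }
    if (hit) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) return(data.frame(ligand_atom = integer(0),
                                      residue_atom = integer(0)))
  data.frame(ligand_atom = out[, 1], residue_atom = out[, 2])
}

# SIMPLS (de Jong 1993) for a single response, from the algorithm definition
simpls_oracle <- function(X, y, A, scale = TRUE) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_scale <- if (scale) ifelse(x_sd > 0, x_sd, 1) else rep(1, p)
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  s <- crossprod(Xs, y - y_mean)          # p x 1
  R <- matrix(0, p, A); V <- matrix(0, p, A)
  Tm <- matrix(0, n, A); q <- numeric(A)
  for (a in seq_len(A)) {
    r <- s                                 # single response: dominant direction
    t_ <- Xs %*% r
    t_ <- t_ - mean(t_)
    normt <- sqrt(sum(t_^2))
    r <- r / normt; t_ <- t_ / normt
    pload <- crossprod(Xs, t_)
    q[a] <- sum((y - y_mean) * t_)
    v <- pload
    if (a > 1) {
      Va <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Va %*% crossprod(Va, pload)
    }
    v <- v / sqrt(sum(v^2))
    s <- s - v %*% crossprod(v, s)
    R[, a] <- r; Tm[, a] <- t_; V[, a] <- v
  }
  beta_std <- R %*% q
  list(beta_standardized = as.numeric(beta_std),
       predict = function(Xnew) {
         Xn <- sweep(sweep(as.matrix(Xnew), 2, x_mean), 2, x_scale, "/")
         as.numeric(y_mean + Xn %*% beta_std)
       })
}

# direct windowed mean/sd with truncated edges
rolling_oracle <- function(x, window) {
  n <- length(x)
  half <- (window - 1) %/% 2
  up <- window %/% 2
  trend <- band <- numeric(n)
  for (i in seq_len(n)) {
    w <- x[max(1, i - half):min(n, i + up)]
    trend[i] <- mean(w)
    band[i] <- if (length(w) > 1) stats::sd(w) else 0
  }
  list(trend = trend, band = band)
}

random_orthogonal <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(traj, Q, shift) {
  for (k in seq_len(traj$n_frames)) {
    fr <- traj$coords[k, , , drop = TRUE]
    traj$coords[k, , ] <- fr %*% t(Q) + matrix(shift, nrow(fr), 3, byrow = TRUE)
  }
  traj
}
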