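# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: matrix algebra instead of quaternion algebra,
# grid/random search instead of closed-form solutions.

# Hamilton product via the 4x4 left-multiplication matrix representation
quat_mult_matrix_oracle <- function(q1, q2) {
  q1 <- as.numeric(q1); q2 <- as.numeric(q2)
  w <- q1[1]; x <- q1[2]; y <- q1[3]; z <- q1[4]
  L <- matrix(c(w, -x, -y, -z,
                x, w, -z, y,
                y, z, w, -x,
                z, -y, x, w), 4, 4, byrow = TRUE)
  as.numeric(L %*% q2)
}

# Rodrigues rotation matrix for axis-angle
rodrigues_oracle <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# swing-twist by brute-force minimization of the swing angle over a fine grid
# of candidate twist angles about `axis`
swing_twist_grid_oracle <- function(qr, axis, step = 1e-4) {
  axis <- axis / sqrt(sum(axis^2))
  tgrid <- seq(-pi, pi, by = step)
  ct <- cos(tgrid / 2); st <- sin(tgrid / 2)
  # swing = conj(twist) x qr ; swing angle = 2 acos(|w_swing|)
  w <- qr[1]; v <- qr[2:4]
  # conj(twist) = (ct, -st*axis); product scalar part:
  ws <- ct * w + st * (axis[1] * v[1] + axis[2] * v[2] + axis[3] * v[3])
  # swing angle minimal where |ws| maximal
  best <- tgrid[which.max(abs(ws))]
  best
}

# independent least-squares rotation search: coarse random sampling of unit
# quaternions followed by two rounds of local axis-angle perturbation
brute_rotation_search <- function(A, B, n_coarse = 20000, seed = 99) {
  set.seed(seed)
  rmsd_of <- function(R) sqrt(mean(rowSums((A %*% t(R) - B)^2)))
  q_to_R <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  Q <- matrix(rnorm(4 * n_coarse), ncol = 4)
  Q <- Q / sqrt(rowSums(Q^2))
  best_q <- Q[1, ]; best <- Inf
  # center once, like any least-squares rotation fit
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  for (i in seq_len(n_coarse)) {
    r <- rmsd_of(q_to_R(Q[i, ]))
    if (r < best) { best <- r; best_q <- Q[i, ] }
  }
  for (scale in c(0.05, 0.012)) {
    grid <- as.matrix(expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)) * scale
    for (g in seq_len(nrow(grid))) {
      ang <- sqrt(sum(grid[g, ]^2))
      dq <- if (ang > 0) c(cos(ang / 2), sin(ang / 2) * grid[g, ] / ang)
            else c(1, 0, 0, 0)
      cand <- quat_mult_matrix_oracle(dq, best_q)
      r <- rmsd_of(q_to_R(cand))
      if (r < best) { best <- r; best_q <- cand }
    }
  }
  if (best_q[1] < 0) best_q <- -best_q
  list(q = best_q, rmsd = best)
}

# random unit quaternion(s)
random_unit_quat <- function(n = 1) {
  q <- matrix(rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}

# band-limited test signal from random sinusoids (<= fmax Hz), evaluable at
# arbitrary times, i.e. an exact fractional-delay reference
bandlimited_signal <- function(fmax = 10, n_comp = 40, fmin = 0.2) {
  fr <- runif(n_comp, fmin, fmax)
  ph <- runif(n_comp, 0, 2 * pi)
  am <- runif(n_comp) / (0.2 + fr)
  function(tt) {
    s <- numeric(length(tt))
    for (j in seq_len(n_comp)) s <- s + am[j] * sin(2 * pi * fr[j] * tt + ph[j])
    s
  }
}

# largest distance from each event in a to its nearest event in b (seconds)
max_event_error <- function(a, b) {
  max(vapply(a, function(x) min(abs(b - x)), numeric(1)))
}

quiet_trial <- function(...) suppressWarnings(process_trial(...))
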