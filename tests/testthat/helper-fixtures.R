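# shared fixtures and small numerical tools for the test suite

# central-difference gradient of a scalar function of an N x 3 matrix
num_grad <- function(f, x, h = 1e-6) {
  g <- x * 0
  for (i in seq_len(nrow(x)))
    for (d in 1:3) {
      xp <- x; xp[i, d] <- xp[i, d] + h
      xm <- x; xm[i, d] <- xm[i, d] - h
      g[i, d] <- (f(xp) - f(xm)) / (2 * h)
    }
  g
}

# a small bulk water box (fully periodic unless walled)
water_box <- function(box = c(6, 6, 6), density = 3, seed = 1,
                      walled = FALSE) {
  ff <- default_forcefield()
  st <- build_confined(box, "water", density, ff, seed = seed)
  if (!walled) st$walled <- FALSE
  st
}

# brute-force O(N^2) conservative pair forces + virial, independent of the
# engine's neighbor-list path
brute_pair_forces <- function(state, ff) {
  p <- state$positions
  n <- nrow(p)
  L <- state$box
  f <- matrix(0, n, 3)
  vir <- matrix(0, 3, 3)
  energy <- 0
  for (i in seq_len(n - 1)) {
    d <- matrix(p[i, ], n - i, 3, byrow = TRUE) -
      p[(i + 1):n, , drop = FALSE]
    for (k in 1:2) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
    if (!state$walled) d[, 3] <- d[, 3] - L[3] * round(d[, 3] / L[3])
    r <- sqrt(rowSums(d^2))
    for (jj in seq_len(n - i)) {
      j <- i + jj
      Rij <- ff$R[state$species[i], state$species[j]]
      if (r[jj] < Rij) {
        Aij <- ff$A[state$species[i], state$species[j]]
        omr <- 1 - r[jj] / Rij
        fv <- Aij * omr * d[jj, ] / r[jj]
        f[i, ] <- f[i, ] + fv
        f[j, ] <- f[j, ] - fv
        vir <- vir + outer(fv, d[jj, ])
        energy <- energy + 0.5 * Aij * Rij * omr^2
      }
    }
  }
  list(forces = f, virial = vir, energy = energy)
}
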