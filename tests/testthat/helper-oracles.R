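# Independent oracles kept out of the package code on purpose: a naive
# recursive Cox-de Boor evaluation, and a brute-force voxel adjacency scan.

# textbook recursive B-spline basis N_{i,p}(u) (1-based i)
naive_bspline <- function(i, p, u, U) {
  if (p == 0) {
    # half-open spans, closed at the right end of the domain
    if ((u >= U[i] && u < U[i + 1]) ||
        (u == U[length(U)] && U[i + 1] == u && U[i] < u)) {
      return(1)
    }
    return(0)
  }
  d1 <- U[i + p] - U[i]
  d2 <- U[i + p + 1] - U[i + 1]
  t1 <- if (d1 > 0) (u - U[i]) / d1 * naive_bspline(i, p - 1, u, U) else 0
  t2 <- if (d2 > 0) (U[i + p + 1] - u) / d2 * naive_bspline(i + 1, p - 1, u, U) else 0
  t1 + t2
}

naive_surface_point <- function(surface, xi, eta) {
  d <- dim(surface$control)
  out <- c(0, 0, 0)
  for (i in seq_len(d[1])) {
    Ni <- naive_bspline(i, surface$p, xi, surface$U)
    if (Ni == 0) next
    for (j in seq_len(d[2])) {
      Nj <- naive_bspline(j, surface$q, eta, surface$V)
      if (Nj == 0) next
      out <- out + Ni * Nj * surface$control[i, j, ]
    }
  }
  out
}

# brute-force: all voxels of label `a` with a 26-neighbor of label `b`
brute_adjacency <- function(grid, a, b) {
  d <- dim(grid)
  hits <- integer(0)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    if (as.integer(grid[i, j, k]) != a) next
    found <- FALSE
    for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      ii <- i + di; jj <- j + dj; kk <- k + dk
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3]) next
      if (as.integer(grid[ii, jj, kk]) == b) { found <- TRUE; break }
    }
    if (found) hits <- c(hits, i + d[1] * ((j - 1) + d[2] * (k - 1)))
  }
  sort(as.integer(hits))
}
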