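# Independent brute-force oracles used to validate the nonlinear fit.
# These never call the package's optimizer: they evaluate the residual
# sum of squares on a dense (A, b) grid and return the grid minimum.

# Dense single grid over A in [1, 40] (step dA) x b in [0.001, 1]
# (step db). rss(A, b) = sum_i (y_i - A e^{-b t_i})^2 is expanded as
# Syy - 2 A Sye(b) + A^2 See(b), an exact evaluation at every grid
# point, vectorized for speed.
grid_search_oracle <- function(t, y, dA = 0.05, db = 0.001,
                               A_range = c(1, 40), b_range = c(0.001, 1)) {
  A_grid <- seq(A_range[1], A_range[2], by = dA)
  b_grid <- seq(b_range[1], b_range[2], by = db)
  E <- exp(-outer(t, b_grid))            # n_t x n_b
  Sye <- drop(crossprod(y, E))           # n_b
  See <- colSums(E * E)                  # n_b
  Syy <- sum(y * y)
  rss <- outer(A_grid^2, See) - 2 * outer(A_grid, Sye) + Syy
  k <- arrayInd(which.min(rss), dim(rss))
  list(A = A_grid[k[1]], b = b_grid[k[2]], rss = min(rss),
       dA = dA, db = db)
}

# Successively refined grid search: repeats a 201 x 201 grid, zooming
# on the minimum, to locate the least-squares optimum to ~1e-4 in both
# parameters without any gradient information.
grid_search_refined <- function(t, y, A_range = c(1, 40),
                                b_range = c(0.001, 1), n = 201L,
                                rounds = 4L) {
  for (r in seq_len(rounds)) {
    A_grid <- seq(A_range[1], A_range[2], length.out = n)
    b_grid <- seq(b_range[1], b_range[2], length.out = n)
    E <- exp(-outer(t, b_grid))
    Sye <- drop(crossprod(y, E))
    See <- colSums(E * E)
    Syy <- sum(y * y)
    rss <- outer(A_grid^2, See) - 2 * outer(A_grid, Sye) + Syy
    k <- arrayInd(which.min(rss), dim(rss))
    dA <- A_grid[2] - A_grid[1]
    db <- b_grid[2] - b_grid[1]
    A_range <- c(max(A_grid[k[1]] - 2 * dA, 1e-8), A_grid[k[1]] + 2 * dA)
    b_range <- c(max(b_grid[k[2]] - 2 * db, 0), b_grid[k[2]] + 2 * db)
    best <- list(A = A_grid[k[1]], b = b_grid[k[2]], rss = min(rss))
  }
  best
}

# Welch two-sample t-test from first principles (hand formula), the
# oracle for compare_genotypes.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p)
}
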