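# Independent brute-force oracles used to cross-check the solver. These
# deliberately share no code with the package's optimization paths.

# vertex-enumeration oracle for min w'x s.t. Ax = b, x >= 0 (upper bounds
# assumed inactive): the optimum of a bounded LP is attained at a basic
# feasible solution, so enumerate all column bases.
oracle_lp_vertex <- function(A, b, w) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  best <- Inf
  for (cols in utils::combn(n, m, simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    xb <- solve(B, b)
    if (any(xb < -1e-9)) next
    x <- rep(0, n)
    x[cols] <- xb
    best <- min(best, sum(w * x))
  }
  best
}

# Lagrangian-dual oracle for min sum((w_i x_i)^p) (p = 2 or 3, w > 0) s.t.
# Ax = b, 0 <= x <= ub. The coordinatewise primal minimizer given dual
# multipliers is closed-form; the concave dual is maximized with BFGS from
# several starts. Strong duality holds (convex problem, feasible by
# construction).
oracle_dual_power <- function(A, b, weights, p, ub) {
  w <- weights^p  # objective as sum(w_i x_i^p)
  A <- as.matrix(A)
  m <- nrow(A)
  x_of <- function(lam) {
    s <- as.numeric(crossprod(A, lam))
    if (p == 2) pmin(pmax(s / (2 * w), 0), ub)
    else pmin(sqrt(pmax(s, 0) / (3 * w)), ub)
  }
  negdual <- function(lam) {
    x <- x_of(lam)
    -(sum(w * x^p) - sum(lam * (as.numeric(A %*% x) - b)))
  }
  best <- -Inf
  for (start in list(rep(0, m), rep(1, m), rep(-1, m))) {
    o <- stats::optim(start, negdual, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    best <- max(best, -o$value)
  }
  best
}

# dense-grid oracle for min max(w_i x_i) s.t. Ax = b (single row), x >= 0,
# x <= ub: grid the first n-1 coordinates, solve the last from the equality,
# refine around the best coarse point.
oracle_grid_minimax <- function(a, b, w, ub, n_coarse = 201L) {
  n <- length(a)
  stopifnot(n %in% c(2L, 3L), abs(a[n]) > 1e-6)
  evalpt <- function(head) {
    xn <- (b - sum(a[-n] * head)) / a[n]
    if (xn < -1e-9 || xn > ub[n] || any(head > ub[-n])) return(Inf)
    max(w * c(head, max(xn, 0)))
  }
  search <- function(lo, hi, steps) {
    grids <- lapply(seq_len(n - 1L), function(k) seq(lo[k], hi[k],
                                                     length.out = steps))
    pts <- as.matrix(expand.grid(grids))
    vals <- apply(pts, 1L, evalpt)
    k <- which.min(vals)
    list(x = pts[k, ], val = vals[k],
         h = vapply(grids, function(g) g[2] - g[1], numeric(1)))
  }
  hi0 <- pmin(ub[-n], abs(b) / pmax(abs(a[-n]), 1e-3) + 10)
  s1 <- search(rep(0, n - 1L), hi0, n_coarse)
  lo <- pmax(s1$x - 2 * s1$h, 0)
  hi <- pmin(s1$x + 2 * s1$h, hi0)
  s2 <- search(lo, hi, n_coarse)
  lo <- pmax(s2$x - 2 * s2$h, 0)
  hi <- s2$x + 2 * s2$h
  search(lo, hi, n_coarse)$val
}

# random small instance: k structures with random unit lines of action and
# lever arms, m equipollence-style rows, b made feasible by construction.
random_instance <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:5, 1)
  if (is.null(m)) m <- sample(seq_len(min(3L, n - 1L)), 1)
  repeat {
    rows6 <- matrix(0, 6, n)
    for (j in seq_len(n)) {
      l <- stats::rnorm(3)
      l <- l / sqrt(sum(l^2))
      d <- stats::runif(3, -0.08, 0.08)
      rows6[1:3, j] <- l
      rows6[4:6, j] <- c(d[2] * l[3] - d[3] * l[2],
                         d[3] * l[1] - d[1] * l[3],
                         d[1] * l[2] - d[2] * l[1])
    }
    A <- rows6[sample(1:3, m), , drop = FALSE]  # force-style rows: O(1) scale
    if (all(apply(A, 1, function(r) max(abs(r)) > 0.2))) break
  }
  x0 <- stats::runif(n, 0, 50)
  list(A = A, b = as.numeric(A %*% x0), n = n, m = m)
}
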