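# Independent brute-force oracles used across tests. These deliberately
# re-derive every quantity from first principles (loops over probability
# tables, exhaustive path enumeration) rather than sharing code with the
# implementations they check.

# entropy (bits) of a probability vector
oracle_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# mutual information of a joint probability matrix
oracle_mi <- function(pxy) {
  px <- rowSums(pxy)
  py <- colSums(pxy)
  oracle_entropy(px) + oracle_entropy(py) - oracle_entropy(as.vector(pxy))
}

# conditional MI I(X;Y|Z) by direct summation over a 3-d probability array
oracle_cmi <- function(pxyz) {
  val <- 0
  pz <- apply(pxyz, 3, sum)
  for (k in seq_len(dim(pxyz)[3])) {
    if (pz[k] == 0) next
    val <- val + pz[k] * oracle_mi(pxyz[, , k] / pz[k])
  }
  val
}

# empirical joint probability array from three discrete series
empirical_joint3 <- function(x, y, z) {
  nx <- max(x); ny <- max(y); nz <- max(z)
  tab <- array(0, c(nx, ny, nz))
  for (i in seq_along(x)) {
    tab[x[i], y[i], z[i]] <- tab[x[i], y[i], z[i]] + 1
  }
  tab / length(x)
}

# direct-definition conditional MI from discrete series (not chain rule)
oracle_cmi_series <- function(x, y, z) {
  oracle_cmi(empirical_joint3(x, y, z))
}

# --- weighted-digraph oracles (exhaustive, n <= 7) ---

# all simple paths between every ordered pair with their lengths
# (length = 1/weight per edge); returns shortest length + count matrices
oracle_shortest_paths <- function(W, tol = 1e-9) {
  n <- nrow(W)
  L <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  through <- array(0, c(n, n, n))  # counts of shortest paths via node m
  walk <- function(path, len, target) {
    last <- path[length(path)]
    if (last == target && length(path) > 1) {
      i <- path[1]
      if (len < L[i, target] - tol) {
        L[i, target] <<- len
        cnt[i, target] <<- 1
        through[i, target, ] <<- 0
        mids <- setdiff(path, c(i, target))
        through[i, target, mids] <<- 1
      } else if (abs(len - L[i, target]) <= tol) {
        cnt[i, target] <<- cnt[i, target] + 1
        mids <- setdiff(path, c(i, target))
        through[i, target, mids] <<- through[i, target, mids] + 1
      }
      return()
    }
    for (j in seq_len(n)) {
      if (j %in% path || W[last, j] <= 0) next
      walk(c(path, j), len + 1 / W[last, j], target)
    }
  }
  for (i in seq_len(n)) {
    for (t in seq_len(n)) {
      if (t != i) walk(i, 0, t)
    }
  }
  list(lengths = L, counts = cnt, through = through)
}

oracle_efficiency <- function(W) {
  n <- nrow(W)
  sp <- oracle_shortest_paths(W)
  vapply(seq_len(n), function(m) {
    inv <- 1 / sp$lengths[m, -m]
    sum(inv[is.finite(inv)]) / (n - 1)
  }, numeric(1))
}

oracle_betweenness <- function(W) {
  n <- nrow(W)
  sp <- oracle_shortest_paths(W)
  vapply(seq_len(n), function(m) {
    acc <- 0
    for (h in seq_len(n)) {
      for (j in seq_len(n)) {
        if (h == j || h == m || j == m || sp$counts[h, j] == 0) next
        acc <- acc + sp$through[h, j, m] / sp$counts[h, j]
      }
    }
    acc / ((n - 1) * (n - 2))
  }, numeric(1))
}

# literal triangle-sum clustering coefficient
oracle_clustering <- function(W) {
  n <- nrow(W)
  Wh <- W^(1/3)
  S <- Wh + t(Wh)
  A <- (W > 0) * 1
  vapply(seq_len(n), function(m) {
    num <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        num <- num + S[m, j] * S[j, h] * S[h, m]
      }
    }
    dtot <- sum(A[m, ]) + sum(A[, m])
    drec <- sum(A[m, ] * A[, m])
    den <- 2 * (dtot * (dtot - 1) - 2 * drec)
    if (den <= 0) 0 else num / den
  }, numeric(1))
}

# random weighted digraph without self-loops
random_digraph <- function(n, p_edge = 0.5) {
  W <- matrix(runif(n * n, 0.2, 2) * (runif(n * n) < p_edge), n, n)
  diag(W) <- 0
  W
}

# small planted-coupling fixture shared by estimator tests
planted_pac_decomposition <- function(m_depth = 0.8, seed = 1, fs = 1000,
                                      duration = 10, lag_s = 0.04) {
  fx <- generate_fixture("am_coupled",
                         params = list(m = m_depth, duration = duration,
                                       fs = fs, lag_s = lag_s),
                         seed = seed)
  bands <- list(theta = band_definition("theta", 4, 8),
                gamma = band_definition("gamma", 30, 120))
  decompose_bands(fx$data, bands, fs = fx$fs)
}
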