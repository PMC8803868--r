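# Independent brute-force oracles for the weighted graph metrics, an
# exhaustive partition enumerator for small graphs, and small fixture
# builders. Oracles are written as literal double loops over the defining
# sums, independent of the package's vectorised implementations.

oracle_modularity <- function(W, m) {
  n <- ncol(W)
  l <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (m[i] == m[j]) q <- q + W[i, j] - k[i] * k[j] / l
  }
  q / l
}

oracle_module_degree_zscore <- function(W, m) {
  n <- ncol(W)
  z <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(m == m[i])
    kin <- vapply(members, function(v) sum(W[v, members]), numeric(1))
    mu <- mean(kin)
    sg <- sqrt(mean((kin - mu)^2))
    ki <- sum(W[i, members])
    z[i] <- if (length(members) < 2 || sg == 0) 0 else (ki - mu) / sg
  }
  z
}

oracle_participation <- function(W, m) {
  n <- ncol(W)
  y <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(W[i, ])
    if (k == 0) next
    acc <- 0
    for (mod in unique(m)) {
      acc <- acc + (sum(W[i, m == mod]) / k)^2
    }
    y[i] <- 1 - acc
  }
  y
}

oracle_assortativity <- function(W) {
  n <- ncol(W)
  k <- rowSums(W)
  wij <- c(); ki <- c(); kj <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && W[i, j] > 0) {
      wij <- c(wij, W[i, j]); ki <- c(ki, k[i]); kj <- c(kj, k[j])
    }
  }
  if (length(wij) < 2) return(NA_real_)
  l <- sum(wij)
  m1 <- sum(wij * (ki + kj) / 2) / l
  num <- sum(wij * ki * kj) / l - m1^2
  den <- sum(wij * (ki^2 + kj^2) / 2) / l - m1^2
  if (abs(den) < 1e-12) return(NA_real_)
  num / den
}

# all set partitions of n labelled items (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    i <- length(prefix) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(W) {
  parts <- all_partitions(ncol(W))
  max(vapply(parts, function(m) oracle_modularity(W, m), numeric(1)))
}

# random sparse symmetric weighted graph with no self-loops
random_weighted_graph <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[stats::runif(length(ut)) < density]
  W[on] <- stats::runif(length(on), 0.1, 1)
  W + t(W)
}

# fixed printed-mean geometry (zero sampling variance)
mean_geometry <- function() {
  generate_zebrin_geometry(seed = 1, sd_widths = rep(0, 7), pc_sd = 0)
}

# small deterministic connectivity map with given amplitude matrix
toy_map <- function(amp, site_size = 20, geometry = mean_geometry()) {
  nc <- ncol(amp)
  pos <- (seq_len(nc) - (nc + 1) / 2) * site_size
  connectivity_map(amp, site_size, pos, geometry, condition = "control",
                   map_id = "toy")
}

# distinct arrangements of a label multiset (for exhaustive permutation
# oracles); uniform over arrangements == uniform over permutations when
# multiplicities are equal across relabellings of positions
distinct_arrangements <- function(labels) {
  labels <- sort(labels)
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(remaining) == 0L) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in unique(remaining)) {
      idx <- match(v, remaining)
      rec(c(prefix, v), remaining[-idx])
    }
  }
  rec(character(0), labels)
  out
}
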