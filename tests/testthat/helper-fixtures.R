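# Shared fixtures and independent oracles, all built in code.

# Two disjoint unit-weight triangles on 6 nodes.
two_triangles <- function() {
  w <- matrix(0, 6, 6)
  for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    w[e[1], e[2]] <- 1
    w[e[2], e[1]] <- 1
  }
  w
}

# Random weighted graph: edge prob `p_edge`, weights U(0.1, 1).
random_graph <- function(n, p_edge = 0.6) {
  w <- matrix(0, n, n)
  up <- upper.tri(w)
  on <- runif(sum(up)) < p_edge
  vals <- ifelse(on, runif(sum(up), 0.1, 1), 0)
  w[up] <- vals
  w <- w + t(w)
  if (sum(w) == 0) w[1, 2] <- w[2, 1] <- 1
  w
}

# Exhaustive set-partition enumeration (restricted growth strings).
set_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1L]] <<- a + 1L
      return(invisible(NULL))
    }
    for (v in 0:mx) {
      a[i] <<- v
      rec(i + 1L, max(mx, v + 1L))
    }
  }
  rec(1L, 0L)
  out
}

# Brute-force maximum modularity over all partitions: the independent
# oracle for the Louvain optimizer (feasible up to n = 8, Bell(8) = 4140).
brute_force_modularity <- function(w, gamma = 1) {
  n <- nrow(w)
  k <- rowSums(w)
  m2 <- sum(k)
  B <- (w - gamma * outer(k, k) / m2) / m2
  best <- -Inf
  for (labels in set_partitions(n)) {
    same <- outer(labels, labels, `==`)
    q <- sum(B[same])
    if (q > best) best <- q
  }
  best
}

# Atrophy-pattern container built directly from a z matrix (rows subjects).
patterns_from_z <- function(z, mask = NULL, ids = NULL) {
  if (is.null(ids)) {
    ids <- rownames(z)
    if (is.null(ids)) ids <- paste0("p", seq_len(nrow(z)))
  }
  if (is.null(mask)) mask <- rep(TRUE, ncol(z))
  rownames(z) <- ids
  if (is.null(colnames(z))) colnames(z) <- paste0("loc", seq_len(ncol(z)))
  structure(list(z = z, mask = mask, reference = NULL, subject_ids = ids),
            class = "atrophy_patterns")
}

# Small planted-block z matrix: `k` blocks of `per` patients sharing a
# random template of depth `depth` on disjoint location sets.
planted_block_z <- function(k = 3, per = 10, loc_per_block = 20,
                            depth = -1, noise = 0.05) {
  p <- k * loc_per_block
  z <- matrix(rnorm(k * per * p, 0, noise), k * per, p)
  for (b in seq_len(k)) {
    rows <- (b - 1) * per + seq_len(per)
    cols <- (b - 1) * loc_per_block + seq_len(loc_per_block)
    z[rows, cols] <- z[rows, cols] + depth
  }
  z
}

# Small cohort for IO / atrophy tests.
tiny_cohort <- function(n_cn = 6, n_ad = 4, p = 8, seed = 42) {
  withr::with_seed(seed, {
    th <- matrix(runif((n_cn + n_ad) * p, 2, 3), n_cn + n_ad, p)
    cohort(th, group = rep(c("CN", "AD"), c(n_cn, n_ad)),
           age = runif(n_cn + n_ad, 55, 85),
           sex = sample(c("F", "M"), n_cn + n_ad, TRUE),
           education = runif(n_cn + n_ad, 6, 18),
           roi_map = rep(paste0("roi", seq_len(p / 2)), each = 2))
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
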