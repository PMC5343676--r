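# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive `n` child seeds (< 2^31) from one parent seed, reproducibly.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Relabel an integer label vector to contiguous 0-based ids, in order of
# first appearance.
relabel0 <- function(labels) {
  u <- unique(labels)
  match(labels, u) - 1L
}

# Maximum-overlap matching of `labels` onto `ref` (both integer vectors over
# the same subjects). Returns `labels` rewritten in the reference label
# space; communities with no matched reference label get fresh ids beyond
# max(ref). Exact assignment by permutation enumeration for small label
# counts, greedy otherwise.
match_labels <- function(ref, labels) {
  ru <- sort(unique(ref)); lu <- sort(unique(labels))
  tab <- table(factor(labels, levels = lu), factor(ref, levels = ru))
  k <- max(length(ru), length(lu))
  m <- matrix(0, k, k)
  m[seq_along(lu), seq_along(ru)] <- as.matrix(tab)

  if (k <= 7L) {
    perms <- all_permutations(k)
    scores <- apply(perms, 1L, function(p) sum(m[cbind(seq_len(k), p)]))
    best <- perms[which.max(scores), ]
  } else {
    best <- rep(NA_integer_, k)
    mm <- m
    for (step in seq_len(k)) {
      idx <- arrayInd(which.max(mm), dim(mm))
      best[idx[1L]] <- idx[2L]
      mm[idx[1L], ] <- -1
      mm[, idx[2L]] <- -1
    }
  }

  # map each observed label to its matched reference label (or a fresh id)
  fresh <- if (length(ru)) max(ru) + 1L else 0L
  out <- integer(length(lu))
  for (i in seq_along(lu)) {
    j <- best[i]
    if (j <= length(ru) && m[i, j] > 0) {
      out[i] <- ru[j]
    } else {
      out[i] <- fresh
      fresh <- fresh + 1L
    }
  }
  out[match(labels, lu)]
}

# All permutations of 1..k as a matrix (k! rows); k <= 7 keeps this small.
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow = k * nrow(sub), ncol = k)
  r <- 1L
  for (pos in seq_len(k)) {
    for (i in seq_len(nrow(sub))) {
      row <- append(sub[i, ], k, after = pos - 1L)
      out[r, ] <- row
      r <- r + 1L
    }
  }
  out
}
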