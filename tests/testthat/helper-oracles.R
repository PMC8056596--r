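# Independent oracles used across the suite. These reimplement the checked
# quantities by enumeration / direct summation and never call the package's
# own code paths.

# --- 1-D k-medoids clustering score -----------------------------------------
# Exhaustive enumeration over contiguous partitions of the sorted positions
# (optimal 1-D k-medoids clusters are contiguous runs); each segment's cost
# is minimized over every candidate medoid in the segment. Ties broken by
# the lexicographically first boundary vector; silhouette from memberships,
# singletons scoring 0; k = 1 is the silhouette-0 baseline, smallest k wins
# ties; k forced to 1 when m < 3.
oracle_clump <- function(positions, L, k_max = 3, tol = 1e-9) {
  x <- sort(positions / L)
  m <- length(x)
  u <- length(unique(x))
  k_hi <- min(k_max, m, u)
  if (m < 3) k_hi <- 1

  seg_cost <- function(l, r) {
    min(vapply(l:r, function(p) sum(abs(x[l:r] - x[p])), numeric(1)))
  }
  partition_cost <- function(bounds) { # bounds: last index of each segment
    starts <- c(1, head(bounds, -1) + 1)
    sum(mapply(seg_cost, starts, bounds))
  }
  sil_of <- function(bounds) {
    starts <- c(1, head(bounds, -1) + 1)
    member <- rep(seq_along(bounds), times = bounds - starts + 1)
    K <- length(bounds)
    if (K < 2) return(0)
    s <- numeric(m)
    for (i in seq_len(m)) {
      own <- which(member == member[i])
      if (length(own) == 1) { s[i] <- 0; next }
      a <- mean(abs(x[i] - x[setdiff(own, i)]))
      b <- min(vapply(setdiff(seq_len(K), member[i]), function(cc)
        mean(abs(x[i] - x[member == cc])), numeric(1)))
      mx <- max(a, b)
      s[i] <- if (mx > tol) (b - a) / mx else 0
    }
    mean(s)
  }

  sils <- numeric(k_hi); costs <- numeric(k_hi)
  for (k in seq_len(k_hi)) {
    if (k == 1) {
      costs[1] <- seg_cost(1, m); sils[1] <- 0
    } else {
      combos <- combn(m - 1, k - 1)
      cs <- apply(combos, 2, function(b) partition_cost(c(b, m)))
      mn <- min(cs)
      costs[k] <- mn
      sils[k] <- sil_of(c(combos[, which(cs <= mn + tol)[1]], m))
    }
  }
  k_sel <- 1; sbest <- 0
  for (k in seq_len(k_hi)) {
    if (sils[k] > sbest + tol) { sbest <- sils[k]; k_sel <- k }
  }
  list(S = costs[k_sel] / m, k = k_sel, costs = costs, silhouettes = sils)
}

# --- global alignment score by exhaustive path enumeration ------------------
# Affine gaps: a gap of length l scores gap_open + l * gap_extend. All
# alignment paths enumerated recursively (strings must be short).
oracle_align_score <- function(a, b, match = 1, mismatch = 0,
                               gap_open = -5, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j, last) {
    if (i > length(A) && j > length(B)) return(0)
    best <- -Inf
    if (i <= length(A) && j <= length(B)) {
      sc <- if (A[i] == B[j]) match else mismatch
      best <- max(best, sc + rec(i + 1, j + 1, "M"))
    }
    if (i <= length(A)) { # gap in b
      open <- if (last != "X") gap_open else 0
      best <- max(best, open + gap_extend + rec(i + 1, j, "X"))
    }
    if (j <= length(B)) { # gap in a
      open <- if (last != "Y") gap_open else 0
      best <- max(best, open + gap_extend + rec(i, j + 1, "Y"))
    }
    best
  }
  rec(1, 1, "M")
}

# --- Poisson upper tail by direct series summation --------------------------
oracle_poisson_tail <- function(o, lambda) {
  if (o == 0) return(1)
  # direct summation of the upper tail (avoids 1 - lower cancellation)
  i <- o:(o + 300)
  sum(exp(-lambda + i * log(lambda) - lfactorial(i)))
}

# --- hypergeometric enrichment tail by direct summation ---------------------
# P(overlap >= a) drawing |set| from universe with K marked
oracle_hyper_tail <- function(a, K, n_other, set_size) {
  sum(vapply(a:min(K, set_size), function(i)
    choose(K, i) * choose(n_other, set_size - i) /
      choose(K + n_other, set_size), numeric(1)))
}

# --- two-sided Fisher p by enumeration of the hypergeometric support --------
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(x)
    choose(c1, x) * choose(n - c1, r1 - x) / choose(n, r1), numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- brute-force interval overlap scan --------------------------------------
oracle_overlaps <- function(genes, regions) {
  hits <- list()
  for (i in seq_len(nrow(genes))) {
    for (j in seq_len(nrow(regions))) {
      if (genes$chrom[i] != regions$chrom[j]) next
      ov <- min(genes$end[i], regions$end[j]) -
        max(genes$start[i], regions$start[j])
      if (ov > 0) {
        hits[[length(hits) + 1]] <- data.frame(
          gene = genes$name[i], region = regions$name[j], overlap_bp = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) return(data.frame(gene = character(0),
                                           region = character(0),
                                           overlap_bp = integer(0)))
  do.call(rbind, hits)
}

# --- adjusted Rand index (exact recovery check uses == 1) -------------------
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}

random_positions <- function(m, L) sample.int(L, m, replace = TRUE)
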