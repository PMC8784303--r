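# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# two-pass covariance Pearson correlation of two vectors
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# elementwise loop over all time-point combinations
oracle_ttcor <- function(a, b) {
  out <- matrix(NA_real_, ncol(a), ncol(b))
  for (i in seq_len(ncol(a))) {
    for (j in seq_len(ncol(b))) {
      out[i, j] <- oracle_pearson(a[, i], b[, j])
    }
  }
  out
}

# one-sample t of a vector against zero, by the textbook formula
oracle_one_sample_t <- function(d) {
  n <- length(d)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) return(if (m == 0) 0 else sign(m) * Inf)
  m / (s / sqrt(n))
}

# BFS connected-component labeling over a channel x t1 x t2 mask with
# +/-1 moves along t1 or t2 (same channel) and channel-neighbour moves at
# the same (t1, t2); returns a list of integer index sets (linear indices)
oracle_bfs_clusters <- function(mask, adj) {
  dm <- dim(mask)
  visited <- array(FALSE, dm)
  comps <- list()
  idx_all <- which(mask)
  coord <- arrayInd(idx_all, dm)
  key <- function(c) (c[3] - 1) * dm[1] * dm[2] + (c[2] - 1) * dm[1] + c[1]
  for (start_row in seq_len(nrow(coord))) {
    s <- coord[start_row, ]
    if (visited[s[1], s[2], s[3]]) next
    queue <- list(s)
    visited[s[1], s[2], s[3]] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, key(cur))
      cand <- list(
        cur + c(0, 1, 0), cur - c(0, 1, 0),
        cur + c(0, 0, 1), cur - c(0, 0, 1)
      )
      for (ch2 in which(adj[cur[1], ])) {
        cand <- c(cand, list(c(ch2, cur[2], cur[3])))
      }
      for (nb in cand) {
        if (any(nb < 1) || nb[2] > dm[2] || nb[3] > dm[3] || nb[1] > dm[1]) next
        if (mask[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
          visited[nb[1], nb[2], nb[3]] <- TRUE
          queue <- c(queue, list(nb))
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# exact reference distribution of the max positive / min negative cluster
# mass under all 2^n sign flips of subject maps (n small), using the BFS
# oracle and textbook t; returns exact p for a given observed mass
oracle_exact_perm <- function(x_maps, thr, adj, dm) {
  n <- nrow(x_maps)
  n_draw <- 2^n
  max_pos <- numeric(n_draw)
  min_neg <- numeric(n_draw)
  for (d in seq_len(n_draw)) {
    bits <- as.integer(intToBits(d - 1))[1:n]
    signs <- ifelse(bits == 1, -1, 1)
    tvec <- apply(signs * x_maps, 2, oracle_one_sample_t)
    tmap <- array(tvec, dm)
    cp <- oracle_bfs_clusters(tmap > thr, adj)
    mp <- if (length(cp)) max(vapply(cp, function(i) sum(tmap[i]), numeric(1))) else 0
    cn <- oracle_bfs_clusters(tmap < -thr, adj)
    mn <- if (length(cn)) min(vapply(cn, function(i) sum(tmap[i]), numeric(1))) else 0
    max_pos[d] <- mp
    min_neg[d] <- mn
  }
  list(max_pos = max_pos, min_neg = min_neg)
}
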