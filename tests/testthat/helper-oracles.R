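# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain double loops over an explicit character matrix.

ALPHA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

aln_chars <- function(alignment) {
  do.call(rbind, strsplit(alignment$seq, "", fixed = TRUE))
}

# MI between two columns of a character matrix, weighted + pseudocounted;
# like the package, weights are normalized to mean 1 so the pseudocount
# balance is scale-free
oracle_pair_mi <- function(chars, w, i, j, lambda) {
  w <- w * length(w) / sum(w)
  joint <- matrix(lambda, 20, 20, dimnames = list(ALPHA, ALPHA))
  contrib <- 0
  for (s in seq_len(nrow(chars))) {
    a <- chars[s, i]; b <- chars[s, j]
    if (a %in% ALPHA && b %in% ALPHA) {
      joint[a, b] <- joint[a, b] + w[s]
      contrib <- contrib + 1
    }
  }
  if (contrib < 2) return(NA_real_)
  joint <- joint / sum(joint)
  pi <- rowSums(joint); pj <- colSums(joint)
  mi <- 0
  for (a in seq_len(20)) for (b in seq_len(20)) {
    p <- joint[a, b]
    if (p > 0) mi <- mi + p * log(p / (pi[a] * pj[b]))
  }
  unname(mi)
}

oracle_mi_matrix <- function(alignment, keep_cols, w, lambda) {
  chars <- aln_chars(alignment)
  m <- length(keep_cols)
  out <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) {
      out[i, j] <- oracle_pair_mi(chars, w, keep_cols[i], keep_cols[j],
                                  lambda)
    }
  }
  out
}

oracle_apc <- function(mi) {
  m <- nrow(mi)
  out <- matrix(NA_real_, m, m)
  row_mean <- numeric(m)
  for (i in seq_len(m)) {
    v <- mi[i, -i]
    row_mean[i] <- mean(v[!is.na(v)])
  }
  allv <- c()
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (j > i && !is.na(mi[i, j])) allv <- c(allv, mi[i, j])
  }
  mean_all <- mean(allv)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j && !is.na(mi[i, j])) {
      out[i, j] <- mi[i, j] - row_mean[i] * row_mean[j] / mean_all
    }
  }
  out
}

oracle_kl <- function(alignment, keep_cols, w, q, lambda) {
  w <- w * length(w) / sum(w)
  chars <- aln_chars(alignment)
  sapply(keep_cols, function(c0) {
    counts <- rep(lambda, 20); names(counts) <- ALPHA
    any_aa <- FALSE
    for (s in seq_len(nrow(chars))) {
      a <- chars[s, c0]
      if (a %in% ALPHA) { counts[a] <- counts[a] + w[s]; any_aa <- TRUE }
    }
    if (!any_aa) return(NA_real_)
    p <- counts / sum(counts)
    kl <- 0
    for (a in seq_len(20)) if (p[a] > 0) kl <- kl + p[a] * log(p[a] / q[a])
    kl
  })
}

# minimum heavy-atom distances from a parsed structure, pure loops
oracle_min_distances <- function(structure) {
  res <- structure$residues
  at <- structure$atoms[!structure$atoms$hydrogen, ]
  n <- nrow(res)
  out <- matrix(NA_real_, n, n)
  for (r in seq_len(n)) for (s in seq_len(n)) {
    ar <- at[at$res == r, ]; as_ <- at[at$res == s, ]
    if (!nrow(ar) || !nrow(as_)) next
    best <- Inf
    for (k in seq_len(nrow(ar))) for (l in seq_len(nrow(as_))) {
      d <- sqrt((ar$x[k] - as_$x[l])^2 + (ar$y[k] - as_$y[l])^2 +
                  (ar$z[k] - as_$z[l])^2)
      if (d < best) best <- d
    }
    out[r, s] <- best
  }
  out
}

# transitive closure of the identity >= threshold relation
oracle_clusters <- function(seqs, threshold) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    adj[i, j] <- pairwise_identity(seqs[i], seqs[j]) >= threshold
  }
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  cl <- integer(n); next_id <- 0L
  for (i in seq_len(n)) {
    if (cl[i] == 0L) {
      next_id <- next_id + 1L
      cl[adj[i, ]] <- next_id
    }
  }
  cl
}

# plain BFS connected component over an edge table of positions
oracle_component <- function(edges, start) {
  seen <- start
  frontier <- start
  while (length(frontier)) {
    nb <- c(edges$position_j[edges$position_i %in% frontier],
            edges$position_i[edges$position_j %in% frontier])
    frontier <- setdiff(nb, seen)
    seen <- union(seen, frontier)
  }
  sort(seen)
}
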