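# Independent oracles used to verify the package implementations.

# single-component PLS1 via the textbook NIPALS step (X scaled, y centered)
pls1_oracle <- function(X, y) {
  w <- crossprod(X, y) / c(crossprod(y))
  w <- w / sqrt(sum(w^2))
  tt <- X %*% w
  q <- c(crossprod(y, tt)) / c(crossprod(tt))
  list(w = drop(w), t = drop(tt), q = q, yhat = drop(tt * q))
}

# ROC area as the Mann-Whitney U statistic over pooled scores
auc_rank_oracle <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# balanced two-way ANOVA sums of squares from cell means
anova2_oracle <- function(v, A, B) {
  A <- factor(A); B <- factor(B)
  r <- nlevels(A); s <- nlevels(B)
  nc <- table(A, B)
  stopifnot(length(unique(c(nc))) == 1L) # balanced only
  n_cell <- nc[1L, 1L]
  gm <- mean(v)
  mA <- tapply(v, A, mean); mB <- tapply(v, B, mean)
  mAB <- tapply(v, interaction(A, B), mean)
  ssa <- n_cell * s * sum((mA - gm)^2)
  ssb <- n_cell * r * sum((mB - gm)^2)
  sscells <- n_cell * sum((mAB - gm)^2)
  ssab <- sscells - ssa - ssb
  sse <- sum((v - ave(v, A, B))^2)
  dfe <- length(v) - r * s
  list(F_A = (ssa / (r - 1)) / (sse / dfe),
       F_B = (ssb / (s - 1)) / (sse / dfe),
       F_AB = (ssab / ((r - 1) * (s - 1))) / (sse / dfe))
}

# upper-tail hypergeometric p by exhaustive enumeration of query draws
hyper_enum_oracle <- function(N, K, n, k) {
  if (k == 0L) return(1)
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the pathway
  mean(hits >= k)
}

# betweenness by explicit shortest-path enumeration (small graphs only)
betweenness_oracle <- function(adj) {
  n <- nrow(adj)
  dist_from <- function(s) {
    d <- rep(Inf, n); d[s] <- 0; frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (u in frontier) {
        for (v in which(adj[u, ] > 0)) {
          if (d[v] > d[u] + 1) { d[v] <- d[u] + 1; nxt <- c(nxt, v) }
        }
      }
      frontier <- unique(nxt)
    }
    d
  }
  all_shortest <- function(s, t, d) {
    # enumerate all shortest s->t paths walking distances backwards
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1L]] <<- c(s, rev(acc)); return() }
      for (u in which(adj[v, ] > 0)) {
        if (d[u] == d[v] - 1) walk(u, c(acc, v))
      }
    }
    walk(t, integer())
    paths
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1L)) {
    d <- dist_from(s)
    for (t in seq.int(s + 1L, n)) {
      if (!is.finite(d[t])) next
      paths <- all_shortest(s, t, d)
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        btw[v] <- btw[v] +
          mean(vapply(paths, function(p) v %in% p, logical(1)))
      }
    }
  }
  btw
}
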