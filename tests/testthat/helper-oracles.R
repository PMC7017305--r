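# Independent brute-force oracles, kept free of the package's code paths.

# Step-up FDR adjustment written from the definition: sort ascending,
# q_(k) = min_{j >= k} m * p_(j) / j, clipped at 1, mapped back.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (k in seq_len(m)) {
    cand <- vapply(k:m, function(j) m * p[ord[j]] / j, numeric(1))
    q_sorted[k] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Hypergeometric upper tail P(X >= k) by direct summation of the pmf.
hyper_tail_bruteforce <- function(k, K, n, N) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- max(k, max(0, n - (N - K))):hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Betweenness by exhaustive simple-path enumeration. `adj` is a logical
# adjacency matrix; returns the unnormalized undirected betweenness.
betweenness_bruteforce <- function(adj) {
  n <- nrow(adj)
  b <- numeric(n)
  all_simple_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) {
        paths[[length(paths) + 1]] <<- seen
        return()
      }
      for (w in which(adj[v, ])) {
        if (!(w %in% seen)) walk(w, c(seen, w))
      }
    }
    walk(s, s)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      inner <- unlist(lapply(shortest, function(p) p[-c(1, length(p))]))
      if (length(inner) > 0) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        b[idx] <- b[idx] + as.numeric(tab) / sigma
      }
    }
  }
  b
}

# Type-III sums of squares by projection matrices under sum-to-zero
# contrasts: SS(term) = y' (P_full - P_without_term) y on the same
# column space.
anova_projection_oracle <- function(y, tissue, state) {
  tissue <- factor(tissue); state <- factor(state)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  X <- model.matrix(~ tissue * state)
  asg <- attr(X, "assign")  # 0 intercept, 1 tissue, 2 state, 3 interaction
  proj <- function(cols) {
    Xs <- X[, cols, drop = FALSE]
    Xs %*% solve(crossprod(Xs), t(Xs))
  }
  P_full <- proj(seq_len(ncol(X)))
  ss <- function(term) {
    P_red <- proj(which(asg != term))
    drop(t(y) %*% (P_full - P_red) %*% y)
  }
  rss <- drop(t(y) %*% (diag(length(y)) - P_full) %*% y)
  df_e <- length(y) - ncol(X)
  list(
    ss = c(tissue = ss(1), state = ss(2), interaction = ss(3)),
    df = c(tissue = nlevels(tissue) - 1, state = nlevels(state) - 1,
           interaction = (nlevels(tissue) - 1) * (nlevels(state) - 1)),
    rss = rss, df_e = df_e
  )
}

# Small fixture builders -------------------------------------------------

make_gene_matrix <- function(values, samples = NULL, genes = NULL) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  if (is.null(genes)) genes <- paste0("G", seq_len(nrow(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, level = "gene", stage = "normalized")
}

balanced_2x2_meta <- function() {
  data.frame(
    sample_id = paste0("s", 1:8),
    tissue = rep(c("A", "B"), each = 4),
    state = rep(rep(c("x", "y"), each = 2), 2),
    stringsAsFactors = FALSE
  )
}

# h1 and h2 each carry five leaves and are bridged by x.
bridged_double_star <- function() {
  edges <- c(rbind("h1", paste0("a", 1:5)), rbind("h2", paste0("b", 1:5)),
             "x", "h1", "x", "h2")
  igraph::make_graph(edges, directed = FALSE)
}
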