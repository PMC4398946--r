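# Shared fixtures, built once per test run.

# small sheet: 16 x 12 mm at 2 mm spacing, compact grid
small_surface <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_surface(sheet_spec(c(16, 12), 2, grid_margin_mm = 2,
                                        n_slices = 5))
    cache
  }
})

small_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      surf <- small_surface()
      cache <<- make_ground_truth(surf$mesh, surf$parcellation)
    }
    cache
  }
})

# default-size sheet used by the recovery tests
default_surface <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_surface(sheet_spec())
    cache
  }
})

# independent OLS oracle: normal equations + classical t / F / R^2
ols_oracle <- function(X, y, test_cols) {
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(XtXi))
  X0 <- X[, -test_cols, drop = FALSE]
  b0 <- solve(t(X0) %*% X0) %*% t(X0) %*% y
  rss0 <- sum((y - X0 %*% b0)^2)
  q <- length(test_cols)
  Fs <- ((rss0 - sum(res^2)) / q) / s2
  list(beta = as.numeric(b), se = as.numeric(se),
       t = as.numeric(b / se), F = Fs,
       p = pf(Fs, q, df, lower.tail = FALSE), df = df)
}

# vertex adjacency from the triangle list (for connectivity checks)
mesh_adjacency <- function(mesh) {
  tr <- mesh$triangles
  edges <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(1, 3)])
  adj <- vector("list", nrow(mesh$vertices))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

is_connected <- function(vertices, adj) {
  if (length(vertices) <= 1) return(TRUE)
  seen <- vertices[1]
  frontier <- vertices[1]
  vs <- as.integer(vertices)
  while (length(frontier) > 0) {
    nxt <- setdiff(intersect(unlist(adj[frontier]), vs), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(vs)
}
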