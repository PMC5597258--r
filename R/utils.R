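# Internal helpers shared across modules.

# 1-based linear index from 0-based voxel coordinates
lin_index <- function(i, j, k, dims) {
  1L + as.integer(i) + dims[1] * (as.integer(j) + dims[2] * as.integer(k))
}

# 0-based voxel coordinates (n x 3) from 1-based linear indices
vox_coords <- function(idx, dims) {
  idx0 <- as.integer(idx) - 1L
  i <- idx0 %% dims[1]
  j <- (idx0 %/% dims[1]) %% dims[2]
  k <- idx0 %/% (dims[1] * dims[2])
  cbind(i = i, j = j, k = k)
}

# Run `expr` under a private RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Connected components of an undirected graph given as an adjacency list
# (list of integer vectors, 1-based). Returns integer component labels.
adj_components <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
      for (w in nbr[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          stack <- c(stack, w)
        }
      }
    }
  }
  comp
}

# Symmetric de-duplicated link matrix (m x 2) -> adjacency list
links_to_adj <- function(links, n) {
  if (!length(links) || !nrow(links)) return(rep(list(integer(0)), n))
  a <- pmin(links[, 1], links[, 2])
  b <- pmax(links[, 1], links[, 2])
  key <- as.numeric(a) * (n + 1) + b   # unique id per undirected pair
  keep <- !duplicated(key) & a != b
  a <- a[keep]; b <- b[keep]
  f <- split(c(b, a), factor(c(a, b), levels = seq_len(n)))
  lapply(f, function(v) sort(as.integer(v)))
}

# adjacency list -> link matrix (m x 2, a < b)
adj_to_links <- function(nbr) {
  out <- list()
  for (q in seq_along(nbr)) {
    w <- nbr[[q]]
    w <- w[w > q]
    if (length(w)) out[[length(out) + 1L]] <- cbind(q, w)
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}

n_links <- function(nbr) sum(lengths(nbr)) / 2
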