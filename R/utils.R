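# Internal helpers shared across the package.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

CELL_TYPES <- c("infected", "uninfected", "meristematic")

check_cell_type <- function(x) {
  bad <- setdiff(unique(x), CELL_TYPES)
  if (length(bad) > 0) {
    stopf("unknown cell_type(s): %s (must be one of %s)",
          paste(bad, collapse = ", "), paste(CELL_TYPES, collapse = ", "))
  }
  invisible(x)
}

# Connected components of an undirected graph given by integer edge endpoints
# (indices into 1..n). Returns a component id per node.
graph_components <- function(n, from, to) {
  comp <- integer(n)
  adj <- vector("list", n)
  for (k in seq_along(from)) {
    adj[[from[k]]] <- c(adj[[from[k]]], to[k])
    adj[[to[k]]] <- c(adj[[to[k]]], from[k])
  }
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# Connected components of the nonzero pixels of a single label in a label
# matrix, under 4-connectivity. Used for contiguity warnings.
n_pixel_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0L)
  key <- function(r, c) paste(r, c)
  remaining <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(idx))) assign(key(idx[k, 1], idx[k, 2]), c(idx[k, 1], idx[k, 2]), envir = remaining)
  ncomp <- 0L
  while (length(ls(remaining)) > 0) {
    ncomp <- ncomp + 1L
    start <- get(ls(remaining)[[1]], envir = remaining)
    queue <- list(start)
    rm(list = key(start[1], start[2]), envir = remaining)
    while (length(queue) > 0) {
      p <- queue[[1]]
      queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        k <- key(p[1] + d[1], p[2] + d[2])
        if (exists(k, envir = remaining, inherits = FALSE)) {
          queue <- c(queue, list(get(k, envir = remaining)))
          rm(list = k, envir = remaining)
        }
      }
    }
  }
  ncomp
}
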