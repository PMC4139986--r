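# Independent oracles and fixture builders used across the test suite.

# Brute-force rate evaluation: literal term-by-term expansion of the flux
# law, one cell at a time, independent of the package's vectorized /
# operator implementations.
brute_rate <- function(state, tissue, layout, params) {
  ids <- tissue$cells$cell_id
  n <- length(ids)
  out <- numeric(n)
  for (i in seq_len(n)) {
    id_i <- ids[i]
    acc <- params$sigma +
      params$s_frankia * as.numeric(tissue$cells$has_frankia[i]) -
      params$delta * state[i]
    for (k in seq_len(nrow(tissue$interfaces))) {
      a_id <- tissue$interfaces$cell_a[k]
      b_id <- tissue$interfaces$cell_b[k]
      if (a_id != id_i && b_id != id_i) next
      w <- tissue$interfaces$wall_length[k]
      ia <- match(a_id, ids); ib <- match(b_id, ids)
      # J from a-side cell toward b-side cell, per unit wall
      J_ab <- (params$d_wall + params$p_pin * layout$pin_a[k]) * state[ia] -
        (params$d_wall + params$p_pin * layout$pin_b[k]) * state[ib] +
        params$p_aux * layout$aux_b[k] * state[ia] -
        params$p_aux * layout$aux_a[k] * state[ib]
      signed <- if (a_id == id_i) -J_ab else J_ab
      acc <- acc + w * signed / tissue$cells$area[i]
    }
    out[i] <- acc
  }
  out
}

# Closed-form steady state of the two-cell system with a PIN efflux carrier
# on the cell-1 side only (density 1), solved symbolically by hand:
#   alpha = w*(d_wall + p_pin), beta = w*d_wall
#   (alpha + delta*A1) a1 - beta a2             = A1*s1
#    alpha a1           - (beta + delta*A2) a2  = -A2*s2
two_cell_pin_analytic <- function(A1, A2, w, d_wall, p_pin, delta, s1, s2) {
  alpha <- w * (d_wall + p_pin)
  beta <- w * d_wall
  D <- delta * (alpha * A2 + beta * A1 + delta * A1 * A2)
  c(a1 = (A1 * s1 * (beta + delta * A2) + beta * A2 * s2) / D,
    a2 = (A2 * s2 * (alpha + delta * A1) + alpha * A1 * s1) / D)
}

# Brute-force adjacency of a label image: O(P^2) loop over all pixel pairs.
brute_adjacency <- function(lm) {
  px <- which(lm > 0, arr.ind = TRUE)
  pairs <- character(0)
  counts <- integer(0)
  if (nrow(px) > 1) {
    for (i in seq_len(nrow(px) - 1)) {
      for (j in (i + 1):nrow(px)) {
        if (abs(px[i, 1] - px[j, 1]) + abs(px[i, 2] - px[j, 2]) != 1) next
        li <- lm[px[i, 1], px[i, 2]]
        lj <- lm[px[j, 1], px[j, 2]]
        if (li == lj) next
        key <- paste(min(li, lj), max(li, lj))
        at <- match(key, pairs)
        if (is.na(at)) { pairs <- c(pairs, key); counts <- c(counts, 1L) }
        else counts[at] <- counts[at] + 1L
      }
    }
  }
  if (length(pairs) == 0) {
    return(data.frame(a = integer(0), b = integer(0), wall = integer(0)))
  }
  ends <- do.call(rbind, strsplit(pairs, " "))
  out <- data.frame(a = as.integer(ends[, 1]), b = as.integer(ends[, 2]),
                    wall = counts)
  out[order(out$a, out$b), ]
}

rand_types <- function(n) sample(c("infected", "uninfected", "meristematic"),
                                 n, replace = TRUE)

rand_grid_tissue <- function(nx = NULL, ny = NULL) {
  if (is.null(nx)) nx <- sample(2:6, 1)
  if (is.null(ny)) ny <- sample(2:6, 1)
  types <- matrix(rand_types(nx * ny), ny, nx)
  generate_grid_tissue(nx, ny, function(r, c) types[r, c])
}

rand_layout <- function(tissue) {
  lay <- place_carriers(tissue, "none")
  n <- nrow(lay)
  lay$aux_a <- round(stats::runif(n, 0, 2), 3)
  lay$aux_b <- round(stats::runif(n, 0, 2), 3)
  lay$pin_a <- round(stats::runif(n, 0, 2), 3)
  lay$pin_b <- round(stats::runif(n, 0, 2), 3)
  lay
}

rand_params <- function(...) {
  args <- list(d_wall = stats::runif(1, 0.2, 2),
               p_pin = stats::runif(1, 0, 10),
               p_aux = stats::runif(1, 0, 10),
               sigma = stats::runif(1, 0.05, 0.5),
               delta = stats::runif(1, 0.05, 0.5),
               s_frankia = stats::runif(1, 0, 2),
               a0 = stats::runif(1, 0, 2))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(model_params, args)
}

total_amount <- function(state, tissue) {
  sum(tissue$cells$area * as.numeric(state[as.character(tissue$cells$cell_id)]))
}

expect_tissue_equal <- function(t1, t2) {
  expect_equal(t1$cells[, c("cell_id", "cell_type", "area", "has_frankia",
                            "centroid_x", "centroid_y")],
               t2$cells[, c("cell_id", "cell_type", "area", "has_frankia",
                            "centroid_x", "centroid_y")])
  expect_equal(t1$interfaces, t2$interfaces)
}
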