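# Synthetic nodule tissues.
#
# The generator emulates a digitized longitudinal section of one actinorhizal
# nodule lobe on an integer pixel grid: an elongated elliptical lobe with a
# contiguous meristematic cap at the apex, an infection zone of hypertrophied
# Frankia-infected cells directly beneath the cap, and the remaining cortex
# tiled with infected cells interspersed among small uninfected cells.
# Building on a pixel grid keeps the digitization round trip
# (render_label_map -> import_label_map) exact and free of floating-point
# geometry.

#' Specification for the synthetic nodule-tissue generator
#'
#' @param n_cells_target desired number of cells (default 200).
#' @param meristem_fraction fraction of cells in the apical meristematic cap,
#'   in (0,1) (default 0.10).
#' @param infected_fraction_of_cortex fraction of cortical (non-meristem)
#'   cells that are infected, in (0,1) (default 0.35).
#' @param infected_size_ratio area of an infected cell relative to an
#'   uninfected cell, > 1 (default 4; infected cells are hypertrophied).
#'   The pixel-grid generator realizes this as square blocks of
#'   `round(sqrt(ratio))^2` pixels.
#' @param aspect_ratio lobe elongation (height/width of the ellipse, default
#'   2.2).
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the spec.
#' @return a `nodule_gen_spec` list.
#' @export
nodule_spec <- function(n_cells_target = 200, meristem_fraction = 0.10,
                        infected_fraction_of_cortex = 0.35,
                        infected_size_ratio = 4.0, aspect_ratio = 2.2,
                        seed = 1L) {
  if (n_cells_target < 10) stopf("infeasible spec: n_cells_target must be >= 10")
  if (meristem_fraction <= 0 || meristem_fraction >= 1) {
    stopf("meristem_fraction must be in (0,1)")
  }
  if (infected_fraction_of_cortex <= 0 || infected_fraction_of_cortex >= 1) {
    stopf("infected_fraction_of_cortex must be in (0,1)")
  }
  if (infected_size_ratio <= 1) stopf("infected_size_ratio must be > 1")
  structure(list(n_cells_target = as.integer(n_cells_target),
                 meristem_fraction = meristem_fraction,
                 infected_fraction_of_cortex = infected_fraction_of_cortex,
                 infected_size_ratio = infected_size_ratio,
                 aspect_ratio = aspect_ratio,
                 seed = as.integer(seed)),
            class = "nodule_gen_spec")
}

# distinct adjacent (4-connectivity) nonzero label pairs of a label matrix,
# with shared-wall pixel-pair counts
adjacent_label_pairs <- function(lm) {
  pair_a <- integer(0); pair_b <- integer(0)
  if (nrow(lm) > 1) {
    u <- lm[-nrow(lm), , drop = FALSE]; v <- lm[-1, , drop = FALSE]
    keep <- u > 0 & v > 0 & u != v
    pair_a <- c(pair_a, u[keep]); pair_b <- c(pair_b, v[keep])
  }
  if (ncol(lm) > 1) {
    u <- lm[, -ncol(lm), drop = FALSE]; v <- lm[, -1, drop = FALSE]
    keep <- u > 0 & v > 0 & u != v
    pair_a <- c(pair_a, u[keep]); pair_b <- c(pair_b, v[keep])
  }
  if (length(pair_a) == 0) {
    return(data.frame(a = integer(0), b = integer(0), wall = numeric(0)))
  }
  key <- paste(pmin(pair_a, pair_b), pmax(pair_a, pair_b))
  wall <- table(key)
  ends <- do.call(rbind, strsplit(names(wall), " ", fixed = TRUE))
  data.frame(a = as.integer(ends[, 1]), b = as.integer(ends[, 2]),
             wall = as.numeric(wall))
}

#' Generate a synthetic nodule-lobe tissue
#'
#' Lays out one nodule lobe on an integer pixel grid (see the package
#' vignette for the geometric conventions): an elliptical lobe mask, a
#' meristematic cap of unit cells at the apex covering about
#' `meristem_fraction` of the cells, square hypertrophied infected cells
#' placed first in the infection zone directly beneath the cap and then
#' interspersed through the cortex by seeded rejection sampling, and unit
#' uninfected cells filling the rest. Placement guarantees every infected
#' cell at least one uninfected neighbor (with a logged post-hoc repair as a
#' fallback). Infected cells carry a Frankia compartment.
#'
#' The result is produced through [import_label_map()], so it carries a pixel
#' backing and [render_label_map()] inverts it exactly.
#'
#' @param spec a [nodule_spec()].
#' @return a valid, connected `nodule_tissue`.
#' @export
generate_nodule_tissue <- function(spec = nodule_spec()) {
  stopifnot(inherits(spec, "nodule_gen_spec"))
  n <- spec$n_cells_target
  n_mer <- max(1L, round(spec$meristem_fraction * n))
  n_cortex <- n - n_mer
  side <- max(2L, round(sqrt(spec$infected_size_ratio)))
  px_inf <- side^2
  f <- spec$infected_fraction_of_cortex
  n_inf_target <- max(1L, round(f * n_cortex))
  n_uninf_target <- n_cortex - n_inf_target
  P <- n_mer + n_uninf_target + px_inf * n_inf_target

  a <- sqrt(P / (pi * spec$aspect_ratio))   # semi-minor (x)
  b <- spec$aspect_ratio * a                # semi-major (y)
  W <- max(4L, ceiling(2 * a) + 1L)
  H <- max(6L, ceiling(2 * b) + 1L)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  mask <- outer(seq_len(H), seq_len(W), function(y, x) {
    ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
  })

  # meristematic cap: whole rows from the apex until ~n_mer pixels
  mer <- matrix(FALSE, H, W)
  cum <- 0L
  mer_last_row <- 0L
  for (y in seq_len(H)) {
    row_px <- sum(mask[y, ])
    if (row_px == 0) next
    if (cum >= n_mer || abs(cum + row_px - n_mer) >= abs(cum - n_mer)) break
    mer[y, mask[y, ]] <- TRUE
    cum <- cum + row_px
    mer_last_row <- y
  }
  cortex <- mask & !mer

  with_seed(spec$seed, {
    # candidate anchors for side x side infected blocks fully inside cortex
    fits <- function(y, x) {
      y + side - 1L <= H && x + side - 1L <= W &&
        all(cortex[y:(y + side - 1L), x:(x + side - 1L)])
    }
    anchors <- which(cortex, arr.ind = TRUE)
    ok <- vapply(seq_len(nrow(anchors)), function(k) fits(anchors[k, 1], anchors[k, 2]),
                 logical(1))
    anchors <- anchors[ok, , drop = FALSE]
    band_top <- mer_last_row + 1L
    in_band <- anchors[, 1] == band_top
    # infection zone first (random x order), then the rest in random order
    ord <- c(sample(which(in_band)), sample(which(!in_band)))

    used <- matrix(FALSE, H, W)
    blocks <- list()
    block_px <- function(y, x) cbind(rep(y:(y + side - 1L), side),
                                     rep(x:(x + side - 1L), each = side))
    outer_nb <- function(px) {
      nb <- rbind(cbind(px[, 1] - 1L, px[, 2]), cbind(px[, 1] + 1L, px[, 2]),
                  cbind(px[, 1], px[, 2] - 1L), cbind(px[, 1], px[, 2] + 1L))
      nb <- nb[nb[, 1] >= 1 & nb[, 1] <= H & nb[, 2] >= 1 & nb[, 2] <= W, , drop = FALSE]
      nb[!(paste(nb[, 1], nb[, 2]) %in% paste(px[, 1], px[, 2])), , drop = FALSE]
    }
    free_uninf_nb <- function(px, used_now) {
      nb <- outer_nb(px)
      any(cortex[nb] & !used_now[nb])
    }
    for (k in ord) {
      if (length(blocks) >= n_inf_target) break
      y <- anchors[k, 1]; x <- anchors[k, 2]
      px <- block_px(y, x)
      if (any(used[px])) next
      used_next <- used
      used_next[px] <- TRUE
      if (!free_uninf_nb(px, used_next)) next   # block itself needs an uninfected contact
      # do not strand a previously placed neighboring block
      strands <- FALSE
      for (blk in blocks) {
        if (!free_uninf_nb(blk, used_next)) { strands <- TRUE; break }
      }
      if (strands) next
      used <- used_next
      blocks[[length(blocks) + 1L]] <- px
    }

    # assemble the label map: meristem, then infected blocks, then uninfected
    lm <- matrix(0L, H, W)
    nl <- 0L
    for (y in seq_len(H)) for (x in seq_len(W)) if (mer[y, x]) {
      nl <- nl + 1L; lm[y, x] <- nl
    }
    types <- rep("meristematic", nl)
    for (blk in blocks) {
      nl <- nl + 1L
      lm[blk] <- nl
      types <- c(types, "infected")
    }
    for (y in seq_len(H)) for (x in seq_len(W)) if (cortex[y, x] && !used[y, x]) {
      nl <- nl + 1L; lm[y, x] <- nl
      types <- c(types, "uninfected")
    }

    # post-hoc repair: every infected cell must keep >= 1 uninfected neighbor
    repeat {
      pairs <- adjacent_label_pairs(lm)
      nb_of <- function(id) c(pairs$b[pairs$a == id], pairs$a[pairs$b == id])
      has_uninf_nb <- vapply(seq_len(nl), function(id) any(types[nb_of(id)] == "uninfected"),
                             logical(1))
      bad <- which(types == "infected" & !has_uninf_nb)
      if (length(bad) == 0) break
      id <- bad[1]
      inf_nb <- nb_of(id)
      inf_nb <- inf_nb[types[inf_nb] == "infected"]
      flip <- if (length(inf_nb) > 0) inf_nb[1] else id
      message(sprintf("generate_nodule_tissue: repair, infected cell %d flipped to uninfected", flip))
      types[flip] <- "uninfected"
    }

    tt <- stats::setNames(types, seq_len(nl))
    tissue <- import_label_map(lm, tt, pixel_size = 1,
                               metadata = list(generator = "nodule_lobe",
                                               seed = spec$seed,
                                               gen_spec = unclass(spec)))
    tissue
  })
}

#' Generate a rectangular grid tissue of unit cells
#'
#' `nx` columns by `ny` rows of unit-area cells under 4-connectivity; all
#' wall lengths 1. Mostly a test fixture.
#'
#' @param nx,ny grid dimensions (`nx * ny >= 1`).
#' @param type_of either a single cell type for all cells or a
#'   `function(row, col)` returning the cell type.
#' @return a `nodule_tissue` with pixel backing.
#' @export
generate_grid_tissue <- function(nx, ny, type_of = "uninfected") {
  stopifnot(nx >= 1, ny >= 1)
  lm <- matrix(seq_len(nx * ny), nrow = ny, ncol = nx, byrow = TRUE)
  types <- character(nx * ny)
  for (r in seq_len(ny)) for (c in seq_len(nx)) {
    types[lm[r, c]] <- if (is.function(type_of)) type_of(r, c) else type_of
  }
  check_cell_type(types)
  import_label_map(lm, stats::setNames(types, seq_len(nx * ny)), pixel_size = 1,
                   metadata = list(generator = "grid", nx = nx, ny = ny))
}

#' Generate a two-cell tissue
#'
#' The minimal fixture: two cells joined by a single interface. Analytic
#' steady states of the transport model on this tissue are available in
#' closed form, which makes it the reference case for solver checks.
#'
#' @param area_a,area_b cell areas (> 0).
#' @param wall_length shared wall length (> 0).
#' @param type_a,type_b cell types.
#' @return a `nodule_tissue` (no pixel backing).
#' @export
generate_two_cell_tissue <- function(area_a = 1, area_b = 1, wall_length = 1,
                                     type_a = "infected", type_b = "uninfected") {
  check_cell_type(c(type_a, type_b))
  new_tissue(
    cells = data.frame(cell_id = 1:2, cell_type = c(type_a, type_b),
                       area = c(area_a, area_b)),
    interfaces = data.frame(cell_a = 1L, cell_b = 2L, wall_length = wall_length),
    metadata = list(generator = "two_cell"))
}

#' Render a pixel-backed tissue as a label map plus type table
#'
#' The inverse of [import_label_map()] for tissues that carry a pixel backing
#' (everything produced by the generators in this package and by
#' [import_label_map()] itself): re-importing the rendered label map
#' reproduces the same cells, types, areas, centroids and interfaces.
#'
#' @param tissue a pixel-backed `nodule_tissue`.
#' @return list with `label_map` (integer matrix), `type_table` (data.frame
#'   `label`, `cell_type`) and `pixel_size`.
#' @export
render_label_map <- function(tissue) {
  lm <- tissue$metadata$label_map
  if (is.null(lm)) stopf("tissue has no pixel backing (label_map metadata)")
  ps <- tissue$metadata$pixel_size
  if (is.null(ps)) ps <- 1
  list(label_map = lm,
       type_table = data.frame(label = tissue$cells$cell_id,
                               cell_type = tissue$cells$cell_type),
       pixel_size = ps)
}
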