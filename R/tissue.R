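#' Construct a virtual nodule tissue
#'
#' A tissue is a cell-adjacency graph: one record per cell (type, area,
#' optional centroid, optional Frankia compartment) and one record per
#' interface between two adjacent cells (shared wall length). It is the
#' geometric substrate on which carrier-mediated auxin transport is simulated.
#'
#' @param cells data.frame with columns `cell_id` (unique positive integers),
#'   `cell_type` (one of `"infected"`, `"uninfected"`, `"meristematic"`),
#'   `area` (positive; pixel count times squared pixel size when digitized),
#'   and optionally `has_frankia` (logical; defaults to
#'   `cell_type == "infected"`), `centroid_x`, `centroid_y`.
#' @param interfaces data.frame with columns `cell_a`, `cell_b` (cell ids of
#'   the two adjacent cells) and `wall_length` (positive shared boundary
#'   measure). Pairs are unordered and must be unique.
#' @param metadata named list of free-form provenance (source image, pixel
#'   size, generator seed, pixel backing).
#' @param validate if `TRUE` (default) stop on any invariant violation.
#'
#' @return An object of class `nodule_tissue`.
#' @seealso [validate_tissue()], [import_label_map()], [generate_nodule_tissue()]
#' @export
new_tissue <- function(cells, interfaces, metadata = list(), validate = TRUE) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (is.null(cells$has_frankia)) cells$has_frankia <- cells$cell_type == "infected"
  if (is.null(cells$centroid_x)) cells$centroid_x <- NA_real_
  if (is.null(cells$centroid_y)) cells$centroid_y <- NA_real_
  cells <- cells[, c("cell_id", "cell_type", "area", "has_frankia",
                     "centroid_x", "centroid_y")]
  cells$cell_id <- as.integer(cells$cell_id)
  cells$area <- as.numeric(cells$area)
  cells$has_frankia <- as.logical(cells$has_frankia)
  rownames(cells) <- NULL
  if (nrow(interfaces) > 0) {
    interfaces <- as.data.frame(interfaces, stringsAsFactors = FALSE)
    interfaces <- interfaces[, c("cell_a", "cell_b", "wall_length")]
    # store unordered pairs canonically (a < b)
    a <- pmin(interfaces$cell_a, interfaces$cell_b)
    b <- pmax(interfaces$cell_a, interfaces$cell_b)
    interfaces$cell_a <- as.integer(a)
    interfaces$cell_b <- as.integer(b)
    interfaces$wall_length <- as.numeric(interfaces$wall_length)
    interfaces <- interfaces[order(interfaces$cell_a, interfaces$cell_b), ]
  } else {
    interfaces <- data.frame(cell_a = integer(0), cell_b = integer(0),
                             wall_length = numeric(0))
  }
  rownames(interfaces) <- NULL
  tissue <- structure(list(cells = cells, interfaces = interfaces,
                           metadata = metadata),
                      class = "nodule_tissue")
  if (validate) {
    report <- validate_tissue(tissue)
    if (length(report) > 0) {
      stopf("invalid tissue:\n%s", paste("-", report, collapse = "\n"))
    }
  }
  tissue
}

#' @export
print.nodule_tissue <- function(x, ...) {
  tab <- table(factor(x$cells$cell_type, levels = CELL_TYPES))
  cat(sprintf("<nodule_tissue> %d cells (%s), %d interfaces, total area %g\n",
              nrow(x$cells),
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", "),
              nrow(x$interfaces), sum(x$cells$area)))
  invisible(x)
}

#' Validate a tissue against its structural invariants
#'
#' Checks cell-level invariants (unique positive ids, known type, positive
#' area, Frankia compartment restricted to infected cells), interface-level
#' invariants (distinct existing endpoints, unique unordered pairs, positive
#' wall length) and tissue-level invariants (interface graph connected; every
#' cell on at least one interface when there are two or more cells).
#' Violations are data, not exceptions: the return value is a character vector
#' of human-readable violation messages, empty for a valid tissue.
#'
#' A non-infected cell flagged `has_frankia` is reported unless the tissue's
#' metadata carries `allow_noninfected_frankia = TRUE` (an explicit override
#' for hand-edited files).
#'
#' @param tissue a `nodule_tissue` (or a structurally similar list).
#' @return character vector of violations; `character(0)` if valid.
#' @export
validate_tissue <- function(tissue) {
  out <- character(0)
  cells <- tissue$cells
  ifs <- tissue$interfaces

  dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup) > 0) {
    out <- c(out, sprintf("duplicate cell_id %d", dup))
  }
  bad <- cells$cell_id[!is.finite(cells$cell_id) | cells$cell_id <= 0]
  if (length(bad) > 0) out <- c(out, sprintf("non-positive cell_id %s", bad))
  bad <- cells$cell_id[!(cells$cell_type %in% CELL_TYPES)]
  if (length(bad) > 0) out <- c(out, sprintf("cell %d has unknown cell_type", bad))
  bad <- cells$cell_id[!is.finite(cells$area) | cells$area <= 0]
  if (length(bad) > 0) out <- c(out, sprintf("cell %d has non-positive area", bad))
  override <- isTRUE(tissue$metadata$allow_noninfected_frankia)
  if (!override) {
    bad <- cells$cell_id[cells$has_frankia & cells$cell_type != "infected"]
    if (length(bad) > 0) {
      out <- c(out, sprintf("cell %d has a Frankia compartment but is not infected", bad))
    }
  }

  if (nrow(ifs) > 0) {
    bad <- which(ifs$cell_a == ifs$cell_b)
    if (length(bad) > 0) {
      out <- c(out, sprintf("interface %d links cell %d to itself", bad, ifs$cell_a[bad]))
    }
    key <- paste(pmin(ifs$cell_a, ifs$cell_b), pmax(ifs$cell_a, ifs$cell_b))
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      out <- c(out, sprintf("duplicate interface (%d,%d)", ifs$cell_a[dup], ifs$cell_b[dup]))
    }
    unknown <- setdiff(c(ifs$cell_a, ifs$cell_b), cells$cell_id)
    if (length(unknown) > 0) {
      out <- c(out, sprintf("interface references unknown cell %d", unknown))
    }
    bad <- which(!is.finite(ifs$wall_length) | ifs$wall_length <= 0)
    if (length(bad) > 0) {
      out <- c(out, sprintf("interface (%d,%d) has non-positive wall_length",
                            ifs$cell_a[bad], ifs$cell_b[bad]))
    }
  }

  # connectivity (only meaningful if endpoints resolve)
  if (nrow(cells) >= 2 && length(setdiff(c(ifs$cell_a, ifs$cell_b), cells$cell_id)) == 0) {
    from <- match(ifs$cell_a, cells$cell_id)
    to <- match(ifs$cell_b, cells$cell_id)
    comp <- graph_components(nrow(cells), from, to)
    if (max(comp) > 1) {
      orphan <- cells$cell_id[comp != comp[1]]
      out <- c(out, sprintf("tissue is disconnected (e.g. cell %d not reachable from cell %d)",
                            orphan[1], cells$cell_id[1]))
    }
    lonely <- setdiff(cells$cell_id, c(ifs$cell_a, ifs$cell_b))
    if (length(lonely) > 0) {
      out <- c(out, sprintf("cell %d has no interface", lonely))
    }
  }
  out
}

#' Digitize an integer label map into a tissue
#'
#' Converts a segmented tissue-section image (an integer label matrix, 0 =
#' background) into a cell-adjacency graph: one cell per nonzero label with
#' area = pixel count x `pixel_size`^2 and centroid = mean pixel coordinate
#' (column = x, row = y), and one interface per pair of labels adjacent under
#' 4-connectivity with wall length = number of adjacent pixel pairs x
#' `pixel_size`. Diagonal contact carries no shared wall and produces no
#' interface.
#'
#' @param label_map integer matrix of nonnegative labels.
#' @param type_table named character vector or data.frame (`label`,
#'   `cell_type`) assigning every nonzero label a cell type.
#' @param pixel_size positive real; side length of one pixel (default 1).
#' @param metadata extra provenance merged into the tissue metadata.
#' @return a `nodule_tissue` whose metadata records the pixel backing
#'   (`label_map`, `pixel_size`), so that [render_label_map()] can invert the
#'   digitization.
#' @export
import_label_map <- function(label_map, type_table, pixel_size = 1, metadata = list()) {
  if (!is.matrix(label_map)) stopf("label_map must be a matrix")
  lm <- matrix(as.integer(round(label_map)), nrow(label_map), ncol(label_map))
  if (any(lm < 0)) stopf("labels must be nonnegative integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stopf("pixel_size must be a positive scalar")
  }
  labels <- sort(unique(lm[lm > 0]))
  if (length(labels) == 0) stopf("all-background image: no nonzero labels")

  if (is.data.frame(type_table)) {
    tt <- stats::setNames(as.character(type_table$cell_type), type_table$label)
  } else {
    tt <- type_table
  }
  missing <- setdiff(as.character(labels), names(tt))
  if (length(missing) > 0) {
    stopf("label(s) missing from type_table: %s", paste(missing, collapse = ", "))
  }
  types <- unname(tt[as.character(labels)])
  check_cell_type(types)

  counts <- table(factor(lm[lm > 0], levels = labels))
  idx <- which(lm > 0, arr.ind = TRUE)
  f <- factor(lm[lm > 0], levels = labels)
  cx <- tapply(idx[, "col"], f, mean)
  cy <- tapply(idx[, "row"], f, mean)

  # contiguity check per label (warning, not error)
  split_labels <- labels[vapply(labels, function(l) n_pixel_components(lm == l) > 1, logical(1))]
  if (length(split_labels) > 0) {
    warning(sprintf("label region(s) not contiguous (accepted): %s",
                    paste(split_labels, collapse = ", ")), call. = FALSE)
  }

  # 4-connectivity adjacency: vertical and horizontal neighbor pixel pairs
  pair_a <- c()
  pair_b <- c()
  if (nrow(lm) > 1) {
    u <- lm[-nrow(lm), , drop = FALSE]
    v <- lm[-1, , drop = FALSE]
    keep <- u > 0 & v > 0 & u != v
    pair_a <- c(pair_a, u[keep]); pair_b <- c(pair_b, v[keep])
  }
  if (ncol(lm) > 1) {
    u <- lm[, -ncol(lm), drop = FALSE]
    v <- lm[, -1, drop = FALSE]
    keep <- u > 0 & v > 0 & u != v
    pair_a <- c(pair_a, u[keep]); pair_b <- c(pair_b, v[keep])
  }
  if (length(pair_a) > 0) {
    key <- paste(pmin(pair_a, pair_b), pmax(pair_a, pair_b))
    wall <- table(key)
    ends <- do.call(rbind, strsplit(names(wall), " ", fixed = TRUE))
    interfaces <- data.frame(cell_a = as.integer(ends[, 1]),
                             cell_b = as.integer(ends[, 2]),
                             wall_length = as.numeric(wall) * pixel_size)
  } else {
    interfaces <- data.frame(cell_a = integer(0), cell_b = integer(0),
                             wall_length = numeric(0))
  }

  cells <- data.frame(cell_id = labels,
                      cell_type = types,
                      area = as.numeric(counts) * pixel_size^2,
                      has_frankia = types == "infected",
                      centroid_x = as.numeric(cx),
                      centroid_y = as.numeric(cy))
  md <- c(metadata, list(pixel_size = pixel_size, label_map = lm))
  new_tissue(cells, interfaces, metadata = md)
}

#' Replace the tissue geometry by uniform unit geometry
#'
#' Sets every cell area and every wall length to 1, keeping types, adjacency
#' and Frankia compartments. Useful for testing the sensitivity of a simulated
#' pattern to the digitized geometry.
#'
#' @param tissue a `nodule_tissue`.
#' @return a `nodule_tissue` with unit geometry (pixel backing dropped).
#' @export
uniform_geometry <- function(tissue) {
  tissue$cells$area <- 1
  if (nrow(tissue$interfaces) > 0) tissue$interfaces$wall_length <- 1
  tissue$metadata$label_map <- NULL
  tissue$metadata$uniform_geometry <- TRUE
  tissue
}
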