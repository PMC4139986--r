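# Tissue serialization (versioned JSON schema "tissue/1") and label-map I/O.

SCHEMA_VERSION <- "tissue/1"

tissue_to_list <- function(tissue) {
  cells <- lapply(seq_len(nrow(tissue$cells)), function(i) {
    row <- tissue$cells[i, ]
    rec <- list(id = row$cell_id, type = row$cell_type, area = row$area,
                has_frankia = row$has_frankia)
    if (is.finite(row$centroid_x) && is.finite(row$centroid_y)) {
      rec$centroid <- c(row$centroid_x, row$centroid_y)
    }
    rec
  })
  interfaces <- lapply(seq_len(nrow(tissue$interfaces)), function(i) {
    row <- tissue$interfaces[i, ]
    list(a = row$cell_a, b = row$cell_b, wall_length = row$wall_length)
  })
  md <- tissue$metadata
  if (!is.null(md$label_map)) {
    lm <- md$label_map
    md$label_map <- list(nrow = nrow(lm), ncol = ncol(lm),
                         values = as.integer(t(lm)))  # row-major
  }
  list(schema = SCHEMA_VERSION, metadata = md, cells = cells,
       interfaces = interfaces)
}

list_to_tissue <- function(x, path = "<input>") {
  if (is.null(x$schema) || !identical(as.character(x$schema), SCHEMA_VERSION)) {
    stopf("%s: unsupported or missing schema (expected \"%s\")", path, SCHEMA_VERSION)
  }
  if (length(x$cells) == 0) stopf("%s: no cells", path)
  cells <- do.call(rbind, lapply(x$cells, function(cl) {
    if (is.null(cl$id) || is.null(cl$type) || is.null(cl$area)) {
      stopf("%s: cell record missing id/type/area", path)
    }
    data.frame(cell_id = as.integer(cl$id), cell_type = as.character(cl$type),
               area = as.numeric(cl$area),
               has_frankia = if (is.null(cl$has_frankia))
                 as.character(cl$type) == "infected" else isTRUE(cl$has_frankia),
               centroid_x = if (is.null(cl$centroid)) NA_real_ else as.numeric(cl$centroid[1]),
               centroid_y = if (is.null(cl$centroid)) NA_real_ else as.numeric(cl$centroid[2]))
  }))
  interfaces <- if (length(x$interfaces) == 0) {
    data.frame(cell_a = integer(0), cell_b = integer(0), wall_length = numeric(0))
  } else {
    do.call(rbind, lapply(x$interfaces, function(fc) {
      data.frame(cell_a = as.integer(fc$a), cell_b = as.integer(fc$b),
                 wall_length = as.numeric(fc$wall_length))
    }))
  }
  md <- x$metadata
  if (length(md) == 0) md <- list()
  if (!is.null(md$label_map)) {
    lmrec <- md$label_map
    md$label_map <- matrix(as.integer(unlist(lmrec$values)),
                           nrow = as.integer(lmrec$nrow),
                           ncol = as.integer(lmrec$ncol), byrow = TRUE)
  }
  tissue <- structure(list(cells = cells, interfaces = interfaces, metadata = md),
                      class = "nodule_tissue")
  report <- validate_tissue(tissue)
  if (length(report) > 0) {
    stopf("%s: invalid tissue:\n%s", path, paste("-", report, collapse = "\n"))
  }
  # normalize ordering / canonical pair orientation
  new_tissue(cells, interfaces, metadata = md, validate = FALSE)
}

#' Write a tissue to a versioned JSON file
#'
#' The file layout is deterministic (fixed key order, full numeric precision),
#' so saving the same tissue twice yields byte-identical files. A tissue that
#' fails [validate_tissue()] is refused.
#'
#' @param tissue a valid `nodule_tissue`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_tissue <- function(tissue, path) {
  report <- validate_tissue(tissue)
  if (length(report) > 0) {
    stopf("refusing to save invalid tissue:\n%s", paste("-", report, collapse = "\n"))
  }
  json <- jsonlite::toJSON(tissue_to_list(tissue), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a tissue from a JSON file
#'
#' Parses and validates a file written by [save_tissue()] (schema
#' `"tissue/1"`). Any invariant violation aborts with a message naming the
#' offending record.
#'
#' @param path file path.
#' @return a `nodule_tissue`.
#' @export
load_tissue <- function(path) {
  if (!file.exists(path)) stopf("cannot read %s", path)
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  list_to_tissue(x, path = path)
}

#' Read an integer label map from a PNG or TIFF image
#'
#' Grayscale images are interpreted as integer labels at the image's native
#' bit depth; RGB PNGs use the 16-bit two-channel encoding of
#' [write_label_map()] (label = R * 256 + G). 0 is background.
#'
#' @param path image path; format chosen by extension (`.png`, `.tif(f)`).
#' @return integer label matrix.
#' @export
read_label_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    if (length(dim(img)) == 3 && dim(img)[3] >= 2) {
      lm <- round(img[, , 1] * 255) * 256L + round(img[, , 2] * 255)
    } else {
      depth <- attr(img, "info")$bit.depth
      if (is.null(depth)) depth <- 8
      if (length(dim(img)) == 3) img <- img[, , 1]
      lm <- round(img * (2^depth - 1))
    }
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) stopf("package 'tiff' required for TIFF input")
    img <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(img)) == 3) img <- img[, , 1]
    lm <- img
  } else {
    stopf("unsupported label-map format: .%s", ext)
  }
  matrix(as.integer(lm), nrow(lm), ncol(lm))
}

#' Write an integer label map as a PNG
#'
#' Labels are stored losslessly across the red and green channels
#' (label = R * 256 + G), which supports up to 65535 cells; [read_label_map()]
#' decodes this layout.
#'
#' @param label_map integer matrix (labels must fit in 0..65535).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(label_map, path) {
  if (max(label_map) > 65535) stopf("labels exceed 16-bit range")
  img <- array(0, dim = c(nrow(label_map), ncol(label_map), 3))
  img[, , 1] <- (label_map %/% 256) / 255
  img[, , 2] <- (label_map %% 256) / 255
  png::writePNG(img, target = path)
  invisible(path)
}

#' Read a label-to-cell-type table from CSV
#'
#' Expects columns `label` and `cell_type`.
#'
#' @param path CSV path.
#' @return named character vector mapping label to cell type.
#' @export
read_type_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "cell_type") %in% names(df))) {
    stopf("%s: type table needs columns label, cell_type", path)
  }
  check_cell_type(df$cell_type)
  stats::setNames(as.character(df$cell_type), df$label)
}
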