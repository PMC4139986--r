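# Tissue data model, validation, serialization, label-map digitization.

test_that("label-map import counts cells, areas and walls by 4-adjacency", {
  # two 2x2 blocks side by side share a wall of 2 pixel edges
  lm <- matrix(c(1, 1, 2, 2,
                 1, 1, 2, 2), nrow = 2, byrow = TRUE)
  t <- import_label_map(lm, c("1" = "infected", "2" = "uninfected"))
  expect_equal(nrow(t$cells), 2)
  expect_equal(t$cells$area, c(4, 4))
  expect_equal(nrow(t$interfaces), 1)
  expect_equal(t$interfaces$wall_length, 2)
  expect_equal(t$cells$has_frankia, c(TRUE, FALSE))

  # pixel_size scales area quadratically and walls linearly
  t2 <- import_label_map(lm, c("1" = "infected", "2" = "uninfected"), pixel_size = 2)
  expect_equal(t2$cells$area, c(16, 16))
  expect_equal(t2$interfaces$wall_length, 4)

  # single nonzero label: one cell, no interfaces
  t3 <- import_label_map(matrix(c(0, 5, 5, 5), 2), c("5" = "meristematic"))
  expect_equal(nrow(t3$cells), 1)
  expect_equal(nrow(t3$interfaces), 0)

  # 1|2|3 strip: only consecutive labels touch
  t4 <- import_label_map(matrix(c(1, 2, 3), nrow = 1),
                         c("1" = "uninfected", "2" = "uninfected", "3" = "uninfected"))
  expect_equal(t4$interfaces[, c("cell_a", "cell_b")],
               data.frame(cell_a = c(1L, 2L), cell_b = c(2L, 3L)))
})

test_that("label-map import rejects bad input and warns on split regions", {
  lm <- matrix(c(1, 2), nrow = 1)
  expect_error(import_label_map(lm, c("1" = "uninfected")), "missing from type_table.*2")
  expect_error(import_label_map(matrix(0, 2, 2), c("1" = "uninfected")), "all-background")
  expect_error(import_label_map(lm, c("1" = "uninfected", "2" = "cortex")), "unknown cell_type")
  # label 1 in two disconnected pieces: accepted with a warning
  lm2 <- matrix(c(1, 2, 1), nrow = 1)
  expect_warning(t <- import_label_map(lm2, c("1" = "uninfected", "2" = "infected")),
                 "not contiguous.*1")
  expect_equal(t$cells$area[t$cells$cell_id == 1], 2)
})

test_that("imported adjacency matches a brute-force pixel-pair scan", {
  withr_seed <- 42
  set.seed(withr_seed)
  for (rep in 1:8) {
    h <- sample(3:12, 1); w <- sample(3:12, 1)
    lm <- matrix(sample(0:5, h * w, replace = TRUE), h, w)
    if (all(lm == 0)) lm[1, 1] <- 1
    labs <- sort(unique(lm[lm > 0]))
    tt <- stats::setNames(rep("uninfected", length(labs)), labs)
    t <- suppressWarnings(
      tryCatch(import_label_map(lm, tt), error = function(e) NULL))
    # random scatters are usually disconnected tissues; compare adjacency on
    # the raw pair table instead of requiring a valid tissue
    got <- nodusim:::adjacent_label_pairs(lm)
    want <- brute_adjacency(lm)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[order(got$a, got$b), ], want, ignore_attr = TRUE)
    # total area is the nonzero pixel count
    if (!is.null(t)) expect_equal(sum(t$cells$area), sum(lm > 0))
  }
})

test_that("validation reports each violation and accepts valid tissues", {
  g <- generate_grid_tissue(3, 3)
  expect_length(validate_tissue(g), 0)

  # disconnected cell
  t <- g
  t$interfaces <- t$interfaces[!(t$interfaces$cell_a == 9 | t$interfaces$cell_b == 9), ]
  expect_match(paste(validate_tissue(t), collapse = "; "), "disconnected|no interface")

  # nonpositive wall length named
  t2 <- g
  t2$interfaces$wall_length[3] <- 0
  v <- validate_tissue(t2)
  expect_match(paste(v, collapse = "; "), sprintf("\\(%d,%d\\)", t2$interfaces$cell_a[3],
                                                  t2$interfaces$cell_b[3]))

  # frankia outside infected cells is rejected unless overridden
  t3 <- g
  t3$cells$has_frankia[1] <- TRUE   # cell 1 is uninfected
  expect_match(paste(validate_tissue(t3), collapse = "; "), "Frankia")
  t3$metadata$allow_noninfected_frankia <- TRUE
  expect_length(validate_tissue(t3), 0)

  # duplicate ids
  t4 <- g
  t4$cells$cell_id[2] <- 1L
  expect_match(paste(validate_tissue(t4), collapse = "; "), "duplicate cell_id 1")
})

test_that("save/load is a lossless round trip with deterministic bytes", {
  tissues <- list(generate_grid_tissue(3, 3),
                  generate_two_cell_tissue(2.5, 1, 0.75),
                  generate_nodule_tissue(nodule_spec(n_cells_target = 40, seed = 7)))
  for (t in tissues) {
    p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
    save_tissue(t, p1)
    save_tissue(t, p2)
    expect_identical(readBin(p1, "raw", file.size(p1)), readBin(p2, "raw", file.size(p2)))
    back <- load_tissue(p1)
    expect_tissue_equal(t, back)
    expect_equal(back$metadata[setdiff(names(back$metadata), "label_map")],
                 t$metadata[setdiff(names(t$metadata), "label_map")])
    expect_equal(back$metadata$label_map, t$metadata$label_map)
    unlink(c(p1, p2))
  }
})

test_that("saving refuses invalid tissues; loading names offending records", {
  g <- generate_grid_tissue(2, 2)
  g$cells$area[1] <- -1
  expect_error(save_tissue(g, tempfile()), "non-positive area")

  p <- tempfile(fileext = ".json")
  writeLines('{"schema":"tissue/1","metadata":{},
    "cells":[{"id":1,"type":"uninfected","area":1},{"id":1,"type":"infected","area":1}],
    "interfaces":[{"a":1,"b":1,"wall_length":1}]}', p)
  expect_error(load_tissue(p), "duplicate cell_id 1")

  writeLines('{"schema":"tissue/1","metadata":{},
    "cells":[{"id":1,"type":"uninfected","area":1},{"id":2,"type":"uninfected","area":1}],
    "interfaces":[{"a":1,"b":3,"wall_length":1}]}', p)
  expect_error(load_tissue(p), "unknown cell 3")

  writeLines('{"schema":"tissue/2","cells":[],"interfaces":[]}', p)
  expect_error(load_tissue(p), "schema")
  unlink(p)
})

test_that("a 3x3 grid fixture file digitizes to 9 cells and 12 interfaces", {
  lm <- matrix(1:9, 3, 3, byrow = TRUE)
  tt <- stats::setNames(rep("uninfected", 9), 1:9)
  t <- import_label_map(lm, tt)
  expect_equal(nrow(t$cells), 9)
  expect_equal(nrow(t$interfaces), 12)  # 2*3*2 interior edges
  expect_true(all(t$interfaces$wall_length == 1))
  expect_equal(t$cells$centroid_x[1], 1)
  expect_equal(t$cells$centroid_y[1], 1)
})

test_that("PNG label maps round-trip through 16-bit grayscale", {
  lm <- matrix(c(0, 1, 1, 2, 300, 300), 2, 3)
  p <- tempfile(fileext = ".png")
  write_label_map(lm, p)
  expect_equal(read_label_map(p), lm)
  unlink(p)
})

test_that("uniform_geometry flattens areas and walls but keeps structure", {
  t <- generate_nodule_tissue(nodule_spec(n_cells_target = 40, seed = 3))
  u <- uniform_geometry(t)
  expect_true(all(u$cells$area == 1))
  expect_true(all(u$interfaces$wall_length == 1))
  expect_equal(u$cells$cell_type, t$cells$cell_type)
  expect_equal(u$interfaces[, c("cell_a", "cell_b")], t$interfaces[, c("cell_a", "cell_b")])
  expect_length(validate_tissue(u), 0)
})
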