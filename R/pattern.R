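# Accumulation-pattern classification and tissue rendering.

PATTERN_LABELS <- c("infected", "uninfected", "meristem",
                    "infected_and_meristem", "uniform_ambiguous")

# relative excess of x over y, scale-invariant
rel_excess <- function(x, y) {
  if (y > 0) (x - y) / y
  else if (x > 0) Inf
  else 0
}

#' Classify the cell-type accumulation pattern of a simulation result
#'
#' Computes the area-weighted mean steady-state concentration per cell type
#' and assigns a categorical label. A type whose mean exceeds the runner-up
#' mean by at least `epsilon` (relative) is the single winner and gives the
#' label (`"infected"`, `"uninfected"` or `"meristem"`). When no single type
#' wins, the biological reference pattern `"infected_and_meristem"` is called
#' if infected and meristematic cells are the top two and both exceed the
#' uninfected mean by at least `epsilon`; anything else is
#' `"uniform_ambiguous"`. All comparisons are ratios, so the label is
#' invariant to uniform rescaling of the concentrations. The margin rule is
#' this package's operationalization of "accumulation"; the underlying
#' observation is qualitative.
#'
#' @param result a `simulation_result` (or bare `auxin_state`).
#' @param tissue the `nodule_tissue` the result was computed on.
#' @param epsilon relative margin for calling a winner (default 0.01).
#' @param area_weighted if `FALSE`, use unweighted per-cell means.
#' @return a `pattern_call`: list with `mean_by_type` (named by cell type),
#'   `ranking` (types sorted by mean, descending), `label`, `margin`, and
#'   `converged`.
#' @export
classify_pattern <- function(result, tissue, epsilon = 0.01, area_weighted = TRUE) {
  state <- if (inherits(result, "simulation_result")) result$final_state else result
  converged <- if (inherits(result, "simulation_result")) result$converged else TRUE
  ids <- tissue$cells$cell_id
  if (is.null(names(state)) || !setequal(names(state), as.character(ids))) {
    stopf("result cell ids do not match tissue cell ids")
  }
  a <- as.numeric(state[as.character(ids)])
  w <- if (area_weighted) tissue$cells$area else rep(1, nrow(tissue$cells))
  types_present <- intersect(CELL_TYPES, unique(tissue$cells$cell_type))
  means <- vapply(types_present, function(ty) {
    sel <- tissue$cells$cell_type == ty
    sum(w[sel] * a[sel]) / sum(w[sel])
  }, numeric(1))

  type_label <- c(infected = "infected", uninfected = "uninfected",
                  meristematic = "meristem")
  ranking <- names(sort(means, decreasing = TRUE))
  top <- ranking[1]
  if (length(means) == 1) {
    margin <- Inf
    label <- type_label[[top]]
  } else {
    margin <- rel_excess(means[[ranking[1]]], means[[ranking[2]]])
    if (margin >= epsilon) {
      # one type clearly dominates the runner-up
      label <- type_label[[top]]
    } else {
      # no single winner: joint infected+meristem accumulation, or ambiguous
      both_over_uninf <- all(c("infected", "meristematic", "uninfected") %in% types_present) &&
        setequal(ranking[1:2], c("infected", "meristematic")) &&
        rel_excess(means[["infected"]], means[["uninfected"]]) >= epsilon &&
        rel_excess(means[["meristematic"]], means[["uninfected"]]) >= epsilon
      if (both_over_uninf) {
        label <- "infected_and_meristem"
        margin <- min(rel_excess(means[["infected"]], means[["uninfected"]]),
                      rel_excess(means[["meristematic"]], means[["uninfected"]]))
      } else {
        label <- "uniform_ambiguous"
      }
    }
  }
  structure(list(mean_by_type = means, ranking = ranking, label = label,
                 margin = unname(margin), epsilon = epsilon,
                 area_weighted = area_weighted, converged = converged),
            class = "pattern_call")
}

#' @export
print.pattern_call <- function(x, ...) {
  cat(sprintf("<pattern_call> label: %s (margin %.3g%s)\n", x$label, x$margin,
              if (!x$converged) ", UNCONVERGED" else ""))
  print(round(x$mean_by_type, 4))
  invisible(x)
}

#' Tabulate a collection of pattern calls
#'
#' @param calls nonempty list of `pattern_call` objects (optionally carrying
#'   `$layout` / `$scenario` fields, used for grouping when present).
#' @return data.frame of counts per label (and per layout/scenario when
#'   available); counts sum to `length(calls)`.
#' @export
summarize_patterns <- function(calls) {
  if (length(calls) == 0) stopf("empty collection of pattern calls")
  stopifnot(all(vapply(calls, inherits, logical(1), "pattern_call")))
  df <- data.frame(
    label = vapply(calls, function(x) x$label, character(1)),
    layout = vapply(calls, function(x) if (is.null(x$layout)) NA_character_ else x$layout, character(1)),
    scenario = vapply(calls, function(x) if (is.null(x$scenario)) NA_character_ else x$scenario, character(1)))
  by <- c("label", if (!all(is.na(df$layout))) "layout", if (!all(is.na(df$scenario))) "scenario")
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))), by = df[, by, drop = FALSE], FUN = sum)
  agg[do.call(order, agg[by]), , drop = FALSE]
}

TYPE_COLORS <- c(infected = "#CC0000", uninfected = "#E6C800", meristematic = "#2255CC")

#' Render a tissue as a raster image
#'
#' Pixel-backed tissues are rendered exactly, one image pixel per tissue
#' pixel (scaled up by `scale`). In `"types"` mode cells are colored by the
#' conventional scheme (infected red, uninfected yellow, meristematic blue);
#' in `"concentration"` mode cells are colored by an auxin state on a
#' white-to-darkred ramp normalized to the state's range. Output is
#' deterministic for fixed input.
#'
#' @param tissue a pixel-backed `nodule_tissue`.
#' @param path output PNG path.
#' @param state an `auxin_state` (required for `mode = "concentration"`).
#' @param mode `"types"` or `"concentration"`.
#' @param scale integer pixel upscaling factor (default 4).
#' @return `path`, invisibly.
#' @export
render_tissue <- function(tissue, path, state = NULL,
                          mode = c("types", "concentration"), scale = 4L) {
  mode <- match.arg(mode)
  lm <- tissue$metadata$label_map
  if (is.null(lm)) stopf("render_tissue needs a pixel-backed tissue (missing geometry)")
  ids <- tissue$cells$cell_id
  if (mode == "types") {
    cols <- TYPE_COLORS[tissue$cells$cell_type]
  } else {
    if (is.null(state)) stopf("mode 'concentration' needs a state")
    a <- as.numeric(state[as.character(ids)])
    rng <- range(a)
    z <- if (diff(rng) > 0) (a - rng[1]) / diff(rng) else rep(0.5, length(a))
    ramp <- grDevices::colorRamp(c("#FFFFFF", "#FFD24D", "#E07000", "#8B0000"))
    cols <- grDevices::rgb(ramp(z), maxColorValue = 255)
  }
  rgbval <- grDevices::col2rgb(cols) / 255
  img <- array(1, dim = c(nrow(lm), ncol(lm), 3))  # white background
  for (k in seq_along(ids)) {
    sel <- lm == ids[k]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[sel] <- rgbval[ch, k]
      img[, , ch] <- plane
    }
  }
  if (scale > 1L) {
    img <- img[rep(seq_len(nrow(lm)), each = scale),
               rep(seq_len(ncol(lm)), each = scale), , drop = FALSE]
  }
  png::writePNG(img, target = path)
  invisible(path)
}
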