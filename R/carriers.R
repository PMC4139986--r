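# Membrane carrier layouts.
#
# A layout assigns, for every interface of a tissue and each of its two
# membrane sides, a dimensionless AUX1-like influx-carrier density and a
# PIN1-like efflux-carrier density. Densities multiply the global
# permeability coefficients p_aux / p_pin of the transport model; the
# immunolocalization data behind the presets report membrane presence per
# cell type, not absolute amounts, so presence is encoded as density 1.

new_carrier_layout <- function(tissue, aux_a = 0, pin_a = 0, aux_b = 0, pin_b = 0) {
  ifs <- tissue$interfaces
  n <- nrow(ifs)
  layout <- data.frame(cell_a = ifs$cell_a, cell_b = ifs$cell_b,
                       aux_a = rep_len(aux_a, n), pin_a = rep_len(pin_a, n),
                       aux_b = rep_len(aux_b, n), pin_b = rep_len(pin_b, n))
  structure(layout, class = c("carrier_layout", "data.frame"))
}

#' Validate a carrier layout against a tissue
#'
#' Checks that the layout covers exactly the tissue's interfaces (both sides
#' of each) and that all densities are nonnegative and finite.
#'
#' @param layout a `carrier_layout`.
#' @param tissue the `nodule_tissue` the layout belongs to.
#' @return character vector of violations; empty if valid.
#' @export
validate_layout <- function(layout, tissue) {
  out <- character(0)
  ifs <- tissue$interfaces
  if (nrow(layout) != nrow(ifs) ||
      !all(layout$cell_a == ifs$cell_a) || !all(layout$cell_b == ifs$cell_b)) {
    out <- c(out, "layout interfaces do not match tissue interfaces")
    return(out)
  }
  dens <- as.matrix(layout[, c("aux_a", "pin_a", "aux_b", "pin_b")])
  if (any(!is.finite(dens))) out <- c(out, "non-finite carrier density")
  else if (any(dens < 0)) out <- c(out, "negative carrier density")
  out
}

type_of_cells <- function(tissue, ids) {
  tissue$cells$cell_type[match(ids, tissue$cells$cell_id)]
}

#' Carrier layout observed in *Discaria trinervis* nodules
#'
#' PIN1-like efflux carriers on every membrane of infected cells and
#' AUX1-like influx carriers on every membrane of meristematic cells
#' (membrane presence per cell type; no subcellular polarity). All other
#' densities are zero.
#'
#' @param tissue a `nodule_tissue`.
#' @return a `carrier_layout`.
#' @export
place_carriers_discaria <- function(tissue) {
  ta <- type_of_cells(tissue, tissue$interfaces$cell_a)
  tb <- type_of_cells(tissue, tissue$interfaces$cell_b)
  new_carrier_layout(tissue,
                     pin_a = as.numeric(ta == "infected"),
                     pin_b = as.numeric(tb == "infected"),
                     aux_a = as.numeric(ta == "meristematic"),
                     aux_b = as.numeric(tb == "meristematic"))
}

#' Carrier layout observed in *Casuarina glauca* nodules
#'
#' AUX1-like influx carriers on every membrane of infected cells, and
#' PIN1-like efflux carriers on the membranes of uninfected cells that face
#' an infected cell (the uninfected cells surrounding infection sites). All
#' other densities are zero. This is the positive-control layout: it drives
#' auxin into infected cells.
#'
#' @param tissue a `nodule_tissue`.
#' @return a `carrier_layout`.
#' @export
place_carriers_casuarina <- function(tissue) {
  ta <- type_of_cells(tissue, tissue$interfaces$cell_a)
  tb <- type_of_cells(tissue, tissue$interfaces$cell_b)
  new_carrier_layout(tissue,
                     aux_a = as.numeric(ta == "infected"),
                     aux_b = as.numeric(tb == "infected"),
                     pin_a = as.numeric(ta == "uninfected" & tb == "infected"),
                     pin_b = as.numeric(tb == "uninfected" & ta == "infected"))
}

#' Carrier layout from an ordered rule list
#'
#' Each rule assigns a density to one carrier on every membrane side whose
#' cell type matches `side_type` and whose facing cell matches `facing_type`.
#' Rules are applied in order; a later rule overrides earlier ones for the
#' same side and carrier. An empty rule set yields the all-zero layout.
#'
#' @param tissue a `nodule_tissue`.
#' @param rules data.frame with columns `side_type` (cell type or `"any"`),
#'   `facing_type` (cell type or `"any"`), `carrier` (`"aux"` or `"pin"`),
#'   `density` (nonnegative).
#' @return a `carrier_layout`.
#' @export
place_carriers_custom <- function(tissue, rules) {
  layout <- new_carrier_layout(tissue)
  if (is.null(rules) || nrow(rules) == 0) return(layout)
  stopifnot(all(c("side_type", "facing_type", "carrier", "density") %in% names(rules)))
  if (any(rules$density < 0)) stopf("carrier densities must be nonnegative")
  if (!all(rules$carrier %in% c("aux", "pin"))) stopf("carrier must be 'aux' or 'pin'")
  ok_type <- c(CELL_TYPES, "any")
  if (!all(rules$side_type %in% ok_type) || !all(rules$facing_type %in% ok_type)) {
    stopf("rule cell types must be one of %s", paste(ok_type, collapse = ", "))
  }
  ta <- type_of_cells(tissue, layout$cell_a)
  tb <- type_of_cells(tissue, layout$cell_b)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    side_a <- (r$side_type == "any" | ta == r$side_type) &
      (r$facing_type == "any" | tb == r$facing_type)
    side_b <- (r$side_type == "any" | tb == r$side_type) &
      (r$facing_type == "any" | ta == r$facing_type)
    col_a <- paste0(r$carrier, "_a")
    col_b <- paste0(r$carrier, "_b")
    layout[[col_a]][side_a] <- r$density
    layout[[col_b]][side_b] <- r$density
  }
  layout
}

#' Resolve a named carrier-layout preset
#'
#' @param tissue a `nodule_tissue`.
#' @param layout `"discaria"`, `"casuarina"`, `"none"` (all-zero), or an
#'   already-built `carrier_layout`.
#' @param rules custom rules for `layout = "custom"`.
#' @return a `carrier_layout`.
#' @export
place_carriers <- function(tissue, layout = c("discaria", "casuarina", "none", "custom"),
                           rules = NULL) {
  if (inherits(layout, "carrier_layout")) return(layout)
  layout <- match.arg(layout)
  switch(layout,
         discaria = place_carriers_discaria(tissue),
         casuarina = place_carriers_casuarina(tissue),
         none = new_carrier_layout(tissue),
         custom = place_carriers_custom(tissue, rules))
}
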