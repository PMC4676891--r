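#' Zone geometry for FDT defect maps
#'
#' The FDT C-20 pattern tests the central 20 degrees at 17 zones: four
#' square zones per quadrant (a 4 x 4 grid split by the horizontal and
#' vertical meridians) plus one central zone. The instrument's printout does
#' not define hemifield membership, edge zones or adjacency, so the grading
#' rules here operate on an explicit, configurable geometry table:
#'
#' * hemifield: `superior` (grid rows 1-2), `inferior` (rows 3-4) or
#'   `central`; the central zone is excluded from hemifield-restricted
#'   counts;
#' * edge: zones touching the outer boundary of the pattern (for the 4 x 4
#'   grid, every zone except the inner 2 x 2 ring);
#' * adjacency: side-sharing between zones of the same hemifield.
#'
#' @param n_rows,n_cols grid dimensions (rows split evenly into superior and
#'   inferior hemifields; `n_rows` must be even).
#' @param central add a central zone (hemifield `central`, never edge)?
#' @param edge_rule `"boundary"` marks zones touching any outer grid border
#'   as edge; `"lateral"` marks only the outermost columns (useful for
#'   reduced grids with a single row per hemifield, where every zone touches
#'   the boundary).
#' @return data.frame with columns `zone`, `row`, `col`, `quadrant`,
#'   `hemifield`, `edge`.
#' @examples
#' fdt_c20_zones()
#' @export
zone_grid <- function(n_rows = 4, n_cols = 4, central = TRUE,
                      edge_rule = c("boundary", "lateral")) {
  edge_rule <- match.arg(edge_rule)
  stopifnot(n_rows %% 2 == 0, n_rows >= 2, n_cols >= 2)
  g <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  g <- g[order(g$row, g$col), c("row", "col")]
  g$hemifield <- ifelse(g$row <= n_rows / 2, "superior", "inferior")
  g$quadrant <- paste0(substr(g$hemifield, 1, 1),
                       ifelse(g$col <= n_cols / 2, "L", "R"))
  g$edge <- switch(edge_rule,
    boundary = g$row %in% c(1L, n_rows) | g$col %in% c(1L, n_cols),
    lateral  = g$col %in% c(1L, n_cols))
  if (central) {
    g <- rbind(g, data.frame(row = NA_integer_, col = NA_integer_,
                             hemifield = "central", quadrant = "C",
                             edge = FALSE))
  }
  g$zone <- sprintf("Z%02d", seq_len(nrow(g)))
  rownames(g) <- NULL
  g[, c("zone", "row", "col", "quadrant", "hemifield", "edge")]
}

#' @rdname zone_grid
#' @export
fdt_c20_zones <- function() zone_grid(4, 4, central = TRUE)

# index pairs of side-sharing zones within one hemifield
zone_adjacent_pairs <- function(zones, hemifield = NULL) {
  idx <- seq_len(nrow(zones))
  if (!is.null(hemifield)) idx <- idx[zones$hemifield %in% hemifield]
  pairs <- list()
  for (a in idx) for (b in idx) {
    if (b <= a) next
    if (zones$hemifield[a] != zones$hemifield[b]) next
    if (is.na(zones$row[a]) || is.na(zones$row[b])) next
    dr <- abs(zones$row[a] - zones$row[b])
    dc <- abs(zones$col[a] - zones$col[b])
    if ((dr == 1L && dc == 0L) || (dr == 0L && dc == 1L)) {
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  if (!length(pairs)) {
    return(data.frame(i = integer(0), j = integer(0)))
  }
  m <- do.call(rbind, pairs)
  data.frame(i = m[, 1], j = m[, 2])
}
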