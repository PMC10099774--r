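#' Spatial heatmap of a variant's per-piece frequencies
#'
#' Draws the dissection layout (slices as large rectangles, pieces as a
#' checkerboard within each) coloured by per-piece variant frequency on a
#' log scale: gray below 1e-5 through orange to red above 1e-3, with
#' missing pieces in near-white — the convention of the study's spatial
#' figures, where a significant cluster appears as adjacent warm pieces.
#'
#' @param table Piece-call table for one testis.
#' @param local_index,alt Variant identity.
#' @param donor Optional donor filter.
#' @param main Plot title.
#' @param pieces_per_row Pieces drawn per row within a slice (default 8).
#' @return Invisibly, the matrix of per-piece frequencies.
#' @export
plot_piece_heatmap <- function(table, local_index, alt, donor = NULL,
                               main = NULL, pieces_per_row = 8L) {
  tab <- as.data.table(table)
  li <- local_index; a <- alt
  v <- tab[tab$local_index == li & tab$alt == a]
  if (!is.null(donor)) v <- v[v$donor == donor]
  if (!nrow(v)) stop("no rows for that variant")
  setorderv(v, c("slice", "piece"))
  freq <- v$mutant_families / v$total_families
  freq[v$missing] <- NA                      # missing pieces: near-white
  n_slices <- length(unique(v$slice))
  ppr <- pieces_per_row
  npc <- nrow(v) / n_slices                  # pieces per slice
  rows_per_slice <- ceiling(npc / ppr)

  # log colour ramp over [1e-5, 1e-3]
  ramp <- grDevices::colorRampPalette(
    c("gray85", "gray60", "goldenrod2", "darkorange2", "red3"))(64)
  col_of <- function(f) {
    out <- rep("#FDFDFD", length(f))        # missing
    ok <- !is.na(f)
    z <- pmin(pmax(log10(pmax(f[ok], 1e-10)), -5), -3)
    out[ok] <- ramp[1 + floor((z + 5) / 2 * 63)]
    out[ok][f[ok] < 1e-5] <- "gray85"
    out
  }
  cols <- col_of(freq)

  op <- graphics::par(mar = c(1, 1, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, ppr), ylim = c(0, n_slices * (rows_per_slice + 0.5)))
  for (s in seq_len(n_slices)) {
    y0 <- (n_slices - s) * (rows_per_slice + 0.5)
    idx <- which(v$slice == sort(unique(v$slice))[s])
    for (k in seq_along(idx)) {
      r <- (k - 1L) %/% ppr
      cc <- (k - 1L) %% ppr
      graphics::rect(cc, y0 + rows_per_slice - r - 1, cc + 1,
                     y0 + rows_per_slice - r,
                     col = cols[idx[k]], border = "white")
    }
    graphics::rect(0, y0, ppr, y0 + rows_per_slice, border = "gray30", lwd = 2)
  }
  graphics::title(main = main %||%
                    sprintf("%s  (gray < 1e-5, red > 1e-3)", v$ref[1]))
  invisible(matrix(freq, nrow = n_slices, byrow = TRUE))
}
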