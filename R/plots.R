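#' Plot congruent color-choice frequencies
#'
#' One panel per group x odor: the congruent choices are drawn as a stack
#' of color boxes ordered by frequency (most frequent lowest), each box's
#' height proportional to its count, rendered in the palette's RGB colors.
#' Box heights within a panel sum to `3 x n_participants`.
#'
#' @param dataset An `odor_dataset`.
#' @param path Output figure path (`.png` or `.svg`).
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
plot_congruency <- function(dataset, path, width = NULL, height = NULL) {
  if (nrow(dataset$records) == 0) stop("empty dataset")
  hex <- .palette_hex(dataset$palette)
  groups <- dataset$groups
  odors <- dataset$odors
  .open_device(path, width, height,
               default_px = c(160 * length(odors) %/% 2 + 400, 220 * length(groups)))
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(length(groups), 1),
                mar = c(4.5, 4, 2, 1), xpd = NA)
  for (g in groups) {
    n_part <- length(.group_participants(dataset, g))
    graphics::plot(NULL, xlim = c(0.5, length(odors) + 0.5),
                   ylim = c(0, 3 * n_part),
                   xlab = "", ylab = "congruent choices",
                   main = g, xaxt = "n")
    graphics::axis(1, at = seq_along(odors), labels = odors, las = 2,
                   cex.axis = 0.8)
    for (oi in seq_along(odors)) {
      counts <- compile_pattern(dataset, g, odors[oi])$counts[1:36]
      ord <- order(counts, decreasing = TRUE)
      ord <- ord[counts[ord] > 0]
      y0 <- 0
      for (cid in ord) {  # most frequent lowest on the stack
        graphics::rect(oi - 0.4, y0, oi + 0.4, y0 + counts[cid],
                       col = hex[cid], border = NA)
        y0 <- y0 + counts[cid]
      }
    }
  }
  invisible(path)
}

#' Plot an RDM heatmap
#'
#' Heatmap of the dissimilarity matrix with labeled axes; warmer colors
#' mean higher dissimilarity and the zero diagonal renders at the colormap
#' minimum (dark blue). When the RDM carries a null distribution, a
#' density line graph is drawn along the color legend.
#'
#' @param rdm An `rdm`.
#' @param path Output figure path (`.png` or `.svg`).
#' @param width,height Device size in pixels (png) or inches (svg).
#' @return `path`, invisibly.
#' @export
plot_rdm <- function(rdm, path, width = NULL, height = NULL) {
  validate_rdm(rdm)
  m <- rdm$matrix
  n <- nrow(m)
  cmap <- grDevices::colorRampPalette(
    c("#08306B", "#2171B5", "#6BAED6", "#FEE08B", "#F46D43", "#A50026"))(256)
  zmax <- max(m, 1e-9)
  .open_device(path, width, height, default_px = c(760, 600))
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2), widths = c(4, 1.2))
  graphics::par(mar = c(7, 7, 2, 1))
  # flip rows so the first label appears at the top-left
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(0, zmax), col = cmap, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(n), labels = rdm$labels, las = 2,
                 cex.axis = 0.8)
  graphics::axis(2, at = seq_len(n), labels = rev(rdm$labels), las = 1,
                 cex.axis = 0.8)
  graphics::box()
  graphics::par(mar = c(7, 1, 2, 4))
  leg_z <- seq(0, zmax, length.out = 256)
  graphics::image(1, leg_z, matrix(leg_z, 1), col = cmap, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(4, las = 1, cex.axis = 0.8)
  if (!is.null(rdm$null_distribution) &&
      length(rdm$null_distribution) > 1) {
    dens <- stats::density(rdm$null_distribution, from = 0, to = zmax)
    graphics::lines(0.6 + 0.8 * dens$y / max(dens$y), dens$x,
                    col = "black", lwd = 2)
  }
  graphics::mtext("dissimilarity (1 - r)", side = 4, line = 2.5,
                  cex = 0.8)
  invisible(path)
}

.open_device <- function(path, width, height, default_px) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    grDevices::png(path,
                   width = if (is.null(width)) default_px[1] else width,
                   height = if (is.null(height)) default_px[2] else height)
  } else if (ext == "svg") {
    grDevices::svg(path,
                   width = if (is.null(width)) default_px[1] / 100 else width,
                   height = if (is.null(height)) default_px[2] / 100 else height)
  } else {
    stop("unsupported figure format: .", ext, " (use .png or .svg)")
  }
}
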