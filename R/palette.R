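#' The default 36-color palette
#'
#' Builds the palette used in the color-odor matching task: the 32 colors of
#' the Berkeley Color Project (8 hues -- red, orange, yellow, chartreuse,
#' green, cyan, blue, purple -- at 4 cuts -- saturated, light, muted, dark)
#' plus white, light gray, dark gray and black, for 36 colors in total.
#'
#' The RGB coordinates are renderings for figures only; every statistic in
#' the package depends solely on `color_id`.
#'
#' @param source Optional path to a palette table (CSV with columns
#'   `color_id,name,r,g,b`). When `NULL` the built-in default is returned.
#' @return A `data.frame` with columns `color_id` (integer 1..36), `name`,
#'   and `r`, `g`, `b` (integers 0--255), of class `c("color_palette",
#'   "data.frame")`.
#' @examples
#' pal <- load_palette()
#' nrow(pal)     # 36
#' pal$color_id  # 1..36
#' @export
load_palette <- function(source = NULL) {
  if (is.null(source)) {
    return(.default_palette())
  }
  tab <- utils::read.csv(source, stringsAsFactors = FALSE)
  names(tab) <- tolower(trimws(names(tab)))
  needed <- c("color_id", "name", "r", "g", "b")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0) {
    stop("palette table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[needed]
  tab$color_id <- as.integer(tab$color_id)
  .validate_palette(tab)
}

.validate_palette <- function(tab) {
  if (nrow(tab) != 36L) {
    stop("expected 36 colors, got ", nrow(tab))
  }
  if (anyNA(tab$color_id)) {
    stop("non-integer color_id in palette row(s) ",
         paste(which(is.na(tab$color_id)), collapse = ", "))
  }
  dup <- which(duplicated(tab$color_id))
  if (length(dup) > 0) {
    stop("duplicate color_id in palette row(s) ",
         paste(dup, collapse = ", "))
  }
  bad <- which(!(tab$color_id %in% 1:36))
  if (length(bad) > 0) {
    stop("color_id out of 1..36 in palette row(s) ",
         paste(bad, collapse = ", "))
  }
  for (ch in c("r", "g", "b")) {
    badc <- which(is.na(tab[[ch]]) | tab[[ch]] < 0 | tab[[ch]] > 255)
    if (length(badc) > 0) {
      stop("channel ", ch, " out of 0..255 in palette row(s) ",
           paste(badc, collapse = ", "))
    }
  }
  tab <- tab[order(tab$color_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("color_palette", "data.frame")
  tab
}

.default_palette <- function() {
  hues <- c("red", "orange", "yellow", "chartreuse",
            "green", "cyan", "blue", "purple")
  rgb <- rbind(
    # saturated
    c(227, 2, 24), c(241, 134, 12), c(249, 221, 0), c(140, 212, 0),
    c(0, 162, 79), c(0, 174, 219), c(0, 90, 181), c(131, 44, 146),
    # light
    c(245, 152, 157), c(248, 192, 130), c(250, 240, 146), c(198, 233, 131),
    c(142, 212, 164), c(138, 219, 240), c(139, 176, 226), c(195, 152, 202),
    # muted
    c(204, 83, 91), c(213, 152, 88), c(218, 200, 91), c(152, 186, 91),
    c(89, 168, 116), c(85, 170, 191), c(87, 126, 175), c(149, 101, 157),
    # dark
    c(132, 27, 45), c(132, 82, 27), c(135, 118, 22), c(83, 107, 29),
    c(14, 98, 56), c(24, 96, 115), c(27, 62, 116), c(83, 42, 94),
    # achromatic
    c(255, 255, 255), c(190, 190, 190), c(85, 85, 85), c(0, 0, 0)
  )
  nm <- c(paste0("saturated_", hues), paste0("light_", hues),
          paste0("muted_", hues), paste0("dark_", hues),
          "white", "light_gray", "dark_gray", "black")
  tab <- data.frame(color_id = 1:36, name = nm,
                    r = rgb[, 1], g = rgb[, 2], b = rgb[, 3],
                    stringsAsFactors = FALSE)
  class(tab) <- c("color_palette", "data.frame")
  tab
}

# Hex rendering colors in color_id order, for figures.
.palette_hex <- function(palette) {
  grDevices::rgb(palette$r, palette$g, palette$b, maxColorValue = 255)
}
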