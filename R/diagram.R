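# Radar (polar polygon) rendering of radius profiles.  The 12 axes are laid
# out clockwise from 12 o'clock in canonical parameter order; the radial
# scale is 0-10 with the acceptability circle drawn at r = 5.  SVG output
# is written directly so vertex coordinates are exact and machine-checkable;
# PNG goes through the standard graphics device.

diagram_geometry <- function(profile, cx, cy, scale) {
  r <- as_sedem_profile(profile)
  k <- length(r)
  ang <- pi / 2 - 2 * pi * (seq_len(k) - 1) / k   # clockwise from top
  list(x = cx + scale * as.numeric(r) * cos(ang),
       y = cy - scale * as.numeric(r) * sin(ang),
       ang = ang)
}

svg_num <- function(x) formatC(x, format = "f", digits = 3)

#' Render one or more radius profiles as a SeDeM radar diagram
#'
#' @param profiles A single profile or a named list of up to four profiles
#'   to overlay (superimposed, semi-transparent fills).
#' @param path Output file; extension selects the format (`.svg` or
#'   `.png`).
#' @param title Optional title.
#' @param colors Line/fill colors, recycled over profiles.
#' @param size Canvas size in pixels.
#' @return `path`, invisibly.  In the SVG output each profile is a
#'   `<polygon class="sedem-profile">` whose vertices are at the exact
#'   radius positions.
#' @examples
#' p <- reference_batch_profiles("Glenmarck", "pilot")[["GL-1"]]
#' f <- tempfile(fileext = ".svg")
#' sedem_diagram(p, f)
#' @export
sedem_diagram <- function(profiles, path, title = NULL,
                          colors = c("#1f77b4", "#d62728", "#2ca02c",
                                     "#9467bd"),
                          size = 560) {
  if (inherits(profiles, "sedem_profile") || (is.numeric(profiles) &&
                                              length(profiles) == 12)) {
    profiles <- list(profile = profiles)
  }
  stopifnot(is.list(profiles), length(profiles) >= 1, length(profiles) <= 4)
  profiles <- lapply(profiles, as_sedem_profile)
  labels <- if (is.null(names(profiles)))
    paste("profile", seq_along(profiles)) else names(profiles)
  fmt <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  cx <- size / 2; cy <- size / 2; scale <- size * 0.40 / 10
  if (fmt == "svg") {
    ln <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      size, size, size, size),
      sprintf('<rect width="%d" height="%d" fill="white"/>', size, size))
    # grid circles at r = 2,4,6,8,10 and the acceptability circle at 5
    for (g in c(2, 4, 6, 8, 10)) {
      ln <- c(ln, sprintf(
        '<circle cx="%s" cy="%s" r="%s" fill="none" stroke="#cccccc" stroke-width="1"/>',
        svg_num(cx), svg_num(cy), svg_num(g * scale)))
    }
    ln <- c(ln, sprintf(
      '<circle class="acceptability" cx="%s" cy="%s" r="%s" fill="none" stroke="#444444" stroke-width="1.5" stroke-dasharray="6,4"/>',
      svg_num(cx), svg_num(cy), svg_num(5 * scale)))
    axes <- diagram_geometry(rep(10, 12), cx, cy, scale)
    for (i in 1:12) {
      ln <- c(ln, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#dddddd" stroke-width="1"/>',
        svg_num(cx), svg_num(cy), svg_num(axes$x[i]), svg_num(axes$y[i])))
      lx <- cx + (10.8 * scale) * cos(axes$ang[i])
      ly <- cy - (10.8 * scale) * sin(axes$ang[i])
      ln <- c(ln, sprintf(
        '<text x="%s" y="%s" font-size="13" text-anchor="middle" dominant-baseline="middle">%s</text>',
        svg_num(lx), svg_num(ly), SEDEM_PARAMS[i]))
    }
    for (k_i in seq_along(profiles)) {
      geo <- diagram_geometry(profiles[[k_i]], cx, cy, scale)
      pts <- paste(svg_num(geo$x), svg_num(geo$y), sep = ",",
                   collapse = " ")
      col <- colors[(k_i - 1) %% length(colors) + 1]
      ln <- c(ln, sprintf(
        '<polygon class="sedem-profile" data-label="%s" points="%s" fill="%s" fill-opacity="0.25" stroke="%s" stroke-width="2"/>',
        labels[k_i], pts, col, col))
    }
    if (!is.null(title)) {
      ln <- c(ln, sprintf(
        '<text x="%s" y="20" font-size="16" text-anchor="middle">%s</text>',
        svg_num(cx), title))
    }
    ln <- c(ln, "</svg>")
    ok <- tryCatch({ writeLines(ln, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write diagram to ", path)
  } else {
    png(path, width = size, height = size)
    on.exit(dev.off())
    graphics::par(mar = c(1, 1, if (is.null(title)) 1 else 3, 1))
    graphics::plot(NA, xlim = c(-12, 12), ylim = c(-12, 12), asp = 1,
                   axes = FALSE, xlab = "", ylab = "",
                   main = if (is.null(title)) "" else title)
    th <- seq(0, 2 * pi, length.out = 200)
    for (g in c(2, 4, 6, 8, 10)) {
      graphics::lines(g * cos(th), g * sin(th), col = "grey80")
    }
    graphics::lines(5 * cos(th), 5 * sin(th), col = "grey30", lty = 2)
    ang <- pi / 2 - 2 * pi * (0:11) / 12
    graphics::segments(0, 0, 10 * cos(ang), 10 * sin(ang), col = "grey90")
    graphics::text(10.9 * cos(ang), 10.9 * sin(ang), SEDEM_PARAMS)
    for (k_i in seq_along(profiles)) {
      r <- as.numeric(profiles[[k_i]])
      col <- colors[(k_i - 1) %% length(colors) + 1]
      graphics::polygon(r * cos(ang), r * sin(ang), border = col, lwd = 2,
                        col = grDevices::adjustcolor(col, alpha.f = 0.25))
    }
    if (length(profiles) > 1) {
      graphics::legend("bottomright", legend = labels, lwd = 2,
                       col = colors[seq_along(profiles)], bty = "n")
    }
  }
  invisible(path)
}
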