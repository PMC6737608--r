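# Device-independent layouts for the two graphical devices, plus base
# graphics renderers.  All layout arithmetic is done in natural logs;
# base 10 enters only in the nomogram display transforms.

#' Fan-plot layout
#'
#' Each risk factor is placed at `(1 / P, beta_ave)`, where `P` is its
#' control-side exposure prevalence.  The line from the origin through
#' that point has slope `P * beta_ave` -- the approximate PAF -- and
#' intercepts the vertical axis drawn at `1/P = 1` at that same value,
#' so the approximate PAF is visible both as a slope and as an
#' intercept.  Factors are ranked by descending approximate PAF.
#'
#' @param results A list of [paf()] fits, a single fit, or a summary
#'   data frame with columns `factor`, `prevalence`, `beta_ave`.
#' @return An object of class `"fan_layout"` with a `points` data
#'   frame (`factor`, `prevalence`, `beta_ave`, `x`, `y`, `slope`,
#'   `intercept`, `rank`).
#' @seealso [nomogram_layout()], [render()]
#' @export
fan_layout <- function(results) {
  tab <- as_paf_table(results)
  if (any(tab$prevalence <= 0 | tab$prevalence > 1))
    stop("control prevalences must lie in (0, 1]")
  bad <- tab$factor[tab$beta_ave <= 0]
  if (length(bad))
    stop("non-positive average log-odds ratio for: ",
         paste(bad, collapse = ", "),
         "; the fan plot requires beta_ave > 0")
  pts <- data.frame(
    factor = tab$factor,
    prevalence = tab$prevalence,
    beta_ave = tab$beta_ave,
    x = 1 / tab$prevalence,
    y = tab$beta_ave,
    slope = tab$approx_paf,
    intercept = tab$approx_paf,
    rank = rank(-tab$approx_paf, ties.method = "first")
  )
  structure(list(points = pts), class = "fan_layout")
}

#' @export
print.fan_layout <- function(x, ...) {
  cat("Fan-plot layout,", nrow(x$points), "risk factor(s)\n")
  print(x$points[order(x$points$rank),
                 c("factor", "prevalence", "beta_ave", "slope", "rank")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

# Display transforms for the nomogram axes (base 10 only here).
nomogram_ordinates <- function(prevalence, beta_ave, ordering) {
  paf_a <- prevalence * beta_ave
  if (ordering == "prevalence-left") {
    list(y_left = -log10(prevalence),
         y_mid = 0.5 * log10(beta_ave),
         y_right = log10(paf_a))
  } else {
    list(y_left = -log10(beta_ave),
         y_mid = 0.5 * log10(prevalence),
         y_right = log10(paf_a))
  }
}

#' Attributable-fraction nomogram layout
#'
#' Three parallel vertical log-scale axes at horizontal positions 0,
#' 1/2 and 1.  Taking logs of `PAF_a = P * beta_ave` turns the product
#' into a sum, so with the middle axis drawn at half scale the three
#' values of any factor fall on a straight line (the Fagan
#' construction).  Two orderings are supported: prevalence on the left
#' axis, or average OR on the left axis.  In the `"or-left"` ordering a
#' line can be tilted about its left-axis (OR) point to show the
#' approximate PAF at a different prevalence -- a partial intervention
#' (new prevalence below the observed one) or an alternative population
#' (above it).
#'
#' @param results As for [fan_layout()].
#' @param ordering `"prevalence-left"` or `"or-left"`.
#' @param tilts Optional named numeric vector `c(factor = new_prev)`
#'   of alternative prevalences (only with `ordering = "or-left"`).
#' @return An object of class `"nomogram_layout"`: `ordering`, an
#'   `axes` list (label, x position, tick values and ordinates for each
#'   axis), a `factors` data frame with the three axis values and
#'   plotted ordinates, and a `tilts` data frame (or `NULL`).
#' @export
#' @examples
#' tab <- data.frame(factor = "hypertension", prevalence = 0.474,
#'                   beta_ave = 1.093)
#' nomogram_layout(tab, ordering = "or-left",
#'                 tilts = c(hypertension = 0.237))
nomogram_layout <- function(results,
                            ordering = c("prevalence-left", "or-left"),
                            tilts = NULL) {
  ordering <- match.arg(ordering)
  tab <- as_paf_table(results)
  if (any(tab$prevalence <= 0 | tab$prevalence > 1))
    stop("control prevalences must lie in (0, 1]")
  bad <- tab$factor[tab$beta_ave <= 0]
  if (length(bad))
    stop("non-positive average log-odds ratio for: ",
         paste(bad, collapse = ", "))
  if (any(tab$approx_paf >= 1))
    warning("approximate PAF >= 1 for some factor(s); the right axis ",
            "cannot display them faithfully")

  ords <- nomogram_ordinates(tab$prevalence, tab$beta_ave, ordering)
  factors <- data.frame(
    factor = tab$factor,
    prevalence = tab$prevalence,
    beta_ave = tab$beta_ave,
    or_ave = tab$or_ave,
    approx_paf = tab$approx_paf,
    y_left = ords$y_left, y_mid = ords$y_mid, y_right = ords$y_right,
    rank = rank(-tab$approx_paf, ties.method = "first")
  )

  prev_ticks <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.3, 0.4, 0.5,
                  0.6, 0.7, 0.8, 0.9)
  or_ticks <- c(1.1, 1.2, 1.5, 2, 3, 5)
  paf_ticks <- c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5, 1)
  axis_def <- function(label, x, values, ordinates)
    list(label = label, x = x, tick_values = values,
         tick_ordinates = ordinates)
  if (ordering == "prevalence-left") {
    axes <- list(
      left = axis_def("prevalence in controls", 0, prev_ticks,
                      -log10(prev_ticks)),
      middle = axis_def("average odds ratio", 0.5, or_ticks,
                        0.5 * log10(log(or_ticks))),
      right = axis_def("approximate PAF", 1, paf_ticks, log10(paf_ticks))
    )
  } else {
    axes <- list(
      left = axis_def("average odds ratio", 0, or_ticks,
                      -log10(log(or_ticks))),
      middle = axis_def("prevalence in controls", 0.5, prev_ticks,
                        0.5 * log10(prev_ticks)),
      right = axis_def("approximate PAF", 1, paf_ticks, log10(paf_ticks))
    )
  }

  tilt_df <- NULL
  if (!is.null(tilts) && length(tilts)) {
    if (ordering != "or-left")
      stop("tilted lines pivot about the left-axis odds-ratio point and ",
           "are only available with ordering = \"or-left\"")
    if (is.null(names(tilts)) || any(!nzchar(names(tilts))))
      stop("tilts must be a named vector: c(factor = new_prevalence)")
    miss <- setdiff(names(tilts), factors$factor)
    if (length(miss))
      stop("tilt names not among the plotted factors: ",
           paste(miss, collapse = ", "))
    if (any(tilts <= 0 | tilts > 1))
      stop("tilt prevalences must lie in (0, 1]")
    i <- match(names(tilts), factors$factor)
    b <- factors$beta_ave[i]
    ords_t <- nomogram_ordinates(as.numeric(tilts), b, ordering)
    tilt_df <- data.frame(
      factor = names(tilts),
      new_prevalence = as.numeric(tilts),
      beta_ave = b,
      approx_paf = as.numeric(tilts) * b,
      y_left = ords_t$y_left, y_mid = ords_t$y_mid,
      y_right = ords_t$y_right,
      type = ifelse(as.numeric(tilts) < factors$prevalence[i],
                    "intervention", "alternative-population")
    )
  }

  structure(list(ordering = ordering, axes = axes, factors = factors,
                 tilts = tilt_df),
            class = "nomogram_layout")
}

#' @export
print.nomogram_layout <- function(x, ...) {
  cat("Attributable-fraction nomogram layout (", x$ordering, "), ",
      nrow(x$factors), " factor(s)", sep = "")
  if (!is.null(x$tilts)) cat(",", nrow(x$tilts), "tilted line(s)")
  cat("\n")
  print(x$factors[order(x$factors$rank),
                  c("factor", "prevalence", "or_ave", "approx_paf", "rank")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
plot.fan_layout <- function(x, xlab_mode = c("prevalence", "inverse"),
                            main = "Approximate attributable fractions",
                            ...) {
  xlab_mode <- match.arg(xlab_mode)
  pts <- x$points
  xmax <- max(pts$x) * 1.05
  ymax <- max(pts$y) * 1.15
  op <- graphics::par(mar = c(5, 5, 4, 5))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(1, xmax), ylim = c(0, ymax), xaxt = "n",
                 xlab = if (xlab_mode == "prevalence")
                   "prevalence in controls (decreasing)" else "1 / prevalence",
                 ylab = "average log odds ratio", main = main, ...)
  if (xlab_mode == "prevalence") {
    pticks <- c(1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25, 0.2, 0.15, 0.1, 0.05)
    pticks <- pticks[1 / pticks <= xmax]
    graphics::axis(1, at = 1 / pticks, labels = paste0(100 * pticks, "%"))
  } else {
    graphics::axis(1)
  }
  for (i in seq_len(nrow(pts))) {
    graphics::segments(0, 0, pts$x[i], pts$y[i], lty = 2, col = "grey40")
    graphics::points(pts$x[i], pts$y[i], pch = 19)
    graphics::text(pts$x[i], pts$y[i], labels = pts$rank[i], pos = 3,
                   cex = 0.8)
  }
  or_ticks <- c(1.2, 1.5, 2, 3, 5)
  or_ticks <- or_ticks[log(or_ticks) <= ymax]
  graphics::axis(4, at = log(or_ticks), labels = or_ticks)
  graphics::mtext("average odds ratio", side = 4, line = 3)
  graphics::mtext("left-axis intercept = approximate PAF", side = 2,
                  line = 3.7, cex = 0.8)
  invisible(x)
}

#' @export
plot.nomogram_layout <- function(x, main = "Attributable-fraction nomogram",
                                 ...) {
  axes <- x$axes
  yr <- range(unlist(lapply(axes, `[[`, "tick_ordinates")),
              x$factors$y_left, x$factors$y_mid, x$factors$y_right,
              if (!is.null(x$tilts))
                c(x$tilts$y_mid, x$tilts$y_right))
  op <- graphics::par(mar = c(2, 1, 4, 1))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-0.22, 1.3), ylim = yr + c(-0.1, 0.1) * diff(yr),
                 axes = FALSE, xlab = "", ylab = "", main = main, ...)
  fmt_tick <- function(label, v) {
    if (grepl("prevalence|PAF", label)) paste0(100 * v, "%") else format(v)
  }
  for (ax in axes) {
    graphics::segments(ax$x, min(ax$tick_ordinates),
                       ax$x, max(ax$tick_ordinates), lwd = 1.5)
    graphics::segments(ax$x - 0.012, ax$tick_ordinates,
                       ax$x + 0.012, ax$tick_ordinates)
    graphics::text(ax$x - 0.02, ax$tick_ordinates,
                   fmt_tick(ax$label, ax$tick_values),
                   pos = 2, cex = 0.65, offset = 0.1)
    graphics::mtext(ax$label, side = 3, at = ax$x, line = 0.3, cex = 0.8)
  }
  f <- x$factors
  for (i in seq_len(nrow(f))) {
    graphics::segments(0, f$y_left[i], 1, f$y_right[i], col = "grey25")
    graphics::text(1.02, f$y_right[i],
                   paste0(f$rank[i], ". ", f$factor[i]),
                   pos = 4, cex = 0.6)
  }
  if (!is.null(x$tilts)) {
    cols <- c(intervention = "red", `alternative-population` = "blue")
    for (i in seq_len(nrow(x$tilts))) {
      graphics::segments(0, x$tilts$y_left[i], 1, x$tilts$y_right[i],
                         col = cols[[x$tilts$type[i]]], lty = 2)
    }
  }
  invisible(x)
}

# Internal: open an svg/png device with path diagnostics (the cairo
# devices only warn about unwritable paths at close time).
open_image_device <- function(path, format, width, height) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("cannot open '", path, "' for writing: directory '", dir,
         "' does not exist")
  ok <- tryCatch({
    if (format == "svg")
      grDevices::svg(path, width = width, height = height)
    else
      grDevices::png(path, width = width, height = height, units = "in",
                     res = 150)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot open '", path, "' for writing: ", conditionMessage(ok))
  invisible(path)
}

#' Render a layout to an image file
#'
#' Writes a fan plot or nomogram layout to SVG or PNG.  Output is
#' deterministic for fixed layout and style, so rendered files can be
#' compared byte-for-byte.
#'
#' @param layout A `"fan_layout"` or `"nomogram_layout"`.
#' @param path Output file path.
#' @param format `"svg"` or `"png"` (default inferred from `path`).
#' @param width,height Device size in inches.
#' @param ... Passed to the layout's `plot` method.
#' @return `path`, invisibly.
#' @export
render <- function(layout, path, format = c("svg", "png"), width = 8,
                   height = 6, ...) {
  if (!inherits(layout, c("fan_layout", "nomogram_layout")))
    stop("layout must be a fan_layout or nomogram_layout")
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("svg", "png")) ext else "svg"
  } else format <- match.arg(format)
  open_image_device(path, format, width, height)
  on.exit(grDevices::dev.off())
  plot(layout, ...)
  invisible(path)
}

#' Render a bias surface as a heatmap
#'
#' @param surface A [bias_surface()].
#' @param which `"b_abs"` (absolute bias) or `"b_r"` (relative bias).
#' @param path Optional output file; `NULL` draws on the current
#'   device.
#' @param format `"svg"` or `"png"`.
#' @param ... Passed to [graphics::image()].
#' @return `path` (or `NULL`), invisibly.
#' @export
bias_heatmap <- function(surface, which = c("b_abs", "b_r"), path = NULL,
                         format = c("svg", "png"), ...) {
  stopifnot(inherits(surface, "bias_surface"))
  which <- match.arg(which)
  format <- match.arg(format)
  z <- surface[[which]]
  ttl <- if (which == "b_abs")
    "Absolute bias of the approximate PAF" else
    "Relative bias of the approximate PAF"
  draw <- function() {
    graphics::image(surface$prevalence_grid, surface$or_grid, z,
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    xlab = "prevalence in controls", ylab = "odds ratio",
                    main = ttl, ...)
    graphics::contour(surface$prevalence_grid, surface$or_grid, z,
                      add = TRUE)
  }
  if (is.null(path)) {
    draw()
  } else {
    open_image_device(path, format, 7, 6)
    on.exit(grDevices::dev.off())
    draw()
  }
  invisible(path)
}

#' Export a layout as JSON
#'
#' Serialises the axes and per-factor coordinates of a layout for
#' downstream re-rendering or testing.
#'
#' @param layout A `"fan_layout"` or `"nomogram_layout"`.
#' @param path Optional file; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
layout_json <- function(layout, path = NULL) {
  if (!inherits(layout, c("fan_layout", "nomogram_layout")))
    stop("layout must be a fan_layout or nomogram_layout")
  obj <- unclass(layout)
  obj$layout_class <- class(layout)
  js <- jsonlite::toJSON(obj, dataframe = "rows", pretty = TRUE,
                         digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
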