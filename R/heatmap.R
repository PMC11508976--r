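# Aggregation of fracture records into frequency matrices and smoothed
# along-rib densities, and painting them onto the thorax template.

scope_records <- function(cohort, side_scope) {
  stopifnot(inherits(cohort, "rib_cohort"))
  side_scope <- match.arg(side_scope, c("pooled", "left", "right",
                                        "mirrored"))
  fr <- cohort$fractures
  fr <- switch(side_scope,
               left = fr[fr$side == "left", , drop = FALSE],
               right = fr[fr$side == "right", , drop = FALSE],
               # pooling and mirroring act on positions, which are side
               # symmetric by construction, so both keep every record
               pooled = fr,
               mirrored = fr)
  list(records = fr, side_scope = side_scope)
}

#' Rib-by-position-bin fracture frequency matrix
#'
#' Counts fracture lines per rib (rows 1-12) and percentage-position bin
#' (columns, [bin_index()] convention). This matrix is the numeric
#' substrate of the fracture-frequency heat map and of the position
#' histogram.
#'
#' @param cohort A [validate_cohort()] / [generate_cohort()] cohort.
#' @param bin_width Bin width in percentage points; must divide 100.
#' @param side_scope `"pooled"` (both sides), `"left"`, `"right"`, or
#'   `"mirrored"` (left records reflected onto the right hemithorax;
#'   identical counts to `"pooled"` since position is measured from the
#'   spine on either side).
#' @return Integer matrix of class `frequency_matrix` with attributes
#'   `bin_width` and `side_scope`; `rownames` are ribs, `colnames` bin
#'   intervals.
#' @export
frequency_matrix <- function(cohort, bin_width = 10,
                             side_scope = "pooled") {
  k <- check_bin_width(bin_width)
  sc <- scope_records(cohort, side_scope)
  fr <- sc$records
  bins <- if (nrow(fr)) bin_index(fr$percent, bin_width) else integer()
  m <- table(factor(fr$rib, levels = 1:12),
             factor(bins, levels = 0:(k - 1L)))
  m <- matrix(as.integer(m), nrow = 12L,
              dimnames = list(rib = paste0("rib", 1:12),
                              bin = sprintf("[%g,%g%s", (0:(k - 1L)) *
                                              bin_width,
                                            (1:k) * bin_width,
                                            c(rep(")", k - 1L), "]"))))
  structure(m, class = c("frequency_matrix", "matrix"),
            bin_width = bin_width, side_scope = sc$side_scope)
}

#' @export
print.frequency_matrix <- function(x, ...) {
  cat(sprintf("<frequency_matrix> %s, bin width %g%%, %d fracture lines\n",
              attr(x, "side_scope"), attr(x, "bin_width"), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Frequency matrix as a tidy data frame
#'
#' @param m A [frequency_matrix()].
#' @return Data frame with columns `rib`, `bin_start`, `bin_end`, `count`.
#' @export
frequency_matrix_df <- function(m) {
  stopifnot(inherits(m, "frequency_matrix"))
  w <- attr(m, "bin_width")
  k <- ncol(m)
  data.frame(rib = rep(1:12, times = k),
             bin_start = rep((0:(k - 1)) * w, each = 12L),
             bin_end = rep((1:k) * w, each = 12L),
             count = as.integer(m))
}

#' Smoothed along-rib fracture-line density
#'
#' Gaussian kernel density of fracture-line positions in percent
#' coordinates, with boundary reflection at 0 and 100 so no mass leaks
#' outside the rib, scaled so that the integral over \[0, 100\] equals the
#' number of contributing records (a frequency density, not a
#' probability).
#'
#' @param cohort A `rib_cohort`.
#' @param rib_index Rib to profile (1-12), or `NULL` to pool all ribs.
#' @param side_scope See [frequency_matrix()].
#' @param bandwidth Kernel standard deviation in percentage points.
#' @param grid_step Spacing of the evaluation grid in percentage points.
#' @return Object of class `density_profile`: list with `rib_index`,
#'   `side_scope`, `positions`, `density`, `bandwidth`, `n`. A rib with no
#'   records yields an all-zero profile.
#' @export
density_profile <- function(cohort, rib_index = NULL,
                            side_scope = "pooled", bandwidth = 5,
                            grid_step = 0.5) {
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  sc <- scope_records(cohort, side_scope)
  fr <- sc$records
  if (!is.null(rib_index)) {
    fr <- fr[fr$rib == check_rib_index(rib_index), , drop = FALSE]
  }
  grid <- seq(0, 100, by = grid_step)
  dens <- reflected_kernel_sum(fr$percent, grid, bandwidth)
  structure(list(rib_index = rib_index, side_scope = sc$side_scope,
                 positions = grid, density = dens, bandwidth = bandwidth,
                 n = nrow(fr)),
            class = "density_profile")
}

# Sum of Gaussian kernels centred at `at`, evaluated on `grid`, with the
# kernel mass falling outside [0, 100] reflected back across the
# boundary. Each kernel then integrates to ~1 on [0, 100].
reflected_kernel_sum <- function(at, grid, bw) {
  if (length(at) == 0L) return(numeric(length(grid)))
  dens <- numeric(length(grid))
  for (p in at) {
    dens <- dens +
      stats::dnorm(grid, p, bw) +
      stats::dnorm(grid, -p, bw) +          # reflection at 0
      stats::dnorm(grid, 200 - p, bw)       # reflection at 100
  }
  dens
}

#' @export
print.density_profile <- function(x, ...) {
  scope <- if (is.null(x$rib_index)) "all ribs" else
    paste("rib", x$rib_index)
  cat(sprintf(
    "<density_profile> %s (%s), n = %d, bandwidth %g%%, peak %.3f at %g%%\n",
    scope, x$side_scope, x$n, x$bandwidth, max(x$density),
    x$positions[which.max(x$density)]))
  invisible(x)
}

#' Trapezoidal integral of a density profile
#'
#' @param profile A [density_profile()].
#' @return The integral over \[0, 100\]; equals the record count to within
#'   the boundary-reflection error (< 1%).
#' @export
profile_integral <- function(profile) {
  stopifnot(inherits(profile, "density_profile"))
  x <- profile$positions
  y <- profile$density
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# ---- painting ---------------------------------------------------------------

#' Heat-map colormap
#'
#' Monotone blue-to-red ramp (through green and yellow): low fracture
#' frequency maps to blue, high to red.
#'
#' @param values Non-negative scalars.
#' @param range Length-2 fixed color range; defaults to `c(0, max(values))`
#'   so the scale is global across ribs within one figure.
#' @param colors Ramp anchor colors.
#' @return Matrix with columns `r`, `g`, `b` in 0-255.
#' @export
heatmap_colors <- function(values, range = NULL,
                           colors = c("blue", "green", "yellow", "red")) {
  if (is.null(range)) range <- c(0, max(values, 0))
  if (diff(range) <= 0) range <- c(range[1], range[1] + 1)
  t <- pmin(pmax((values - range[1]) / diff(range), 0), 1)
  m <- grDevices::colorRamp(colors)(t)
  colnames(m) <- c("r", "g", "b")
  round(m)
}

#' Paint a fracture-frequency heat map onto the thorax template
#'
#' Transfers the 1D positional aggregation (a [frequency_matrix()] or a
#' set of per-rib [density_profile()]s) onto the 3D template: every vertex
#' of every in-scope rib curve receives the scalar value at its arc-length
#' percentage, and scalars are mapped to colors by a fixed, monotone
#' colormap whose range is global across all ribs, so between-rib
#' frequency differences stay visible.
#'
#' @param template A [default_template()] or user template.
#' @param values A `frequency_matrix`, or a list of 12 `density_profile`s
#'   indexed by rib.
#' @param range Optional fixed color-range endpoints.
#' @param colors Colormap anchors, see [heatmap_colors()].
#' @return Object of class `painted_template`: list with `curves` (each a
#'   `rib_curve` plus per-vertex `scalar` and `color`), `side_scope`,
#'   `range`.
#' @export
paint_heatmap <- function(template, values, range = NULL,
                          colors = c("blue", "green", "yellow", "red")) {
  stopifnot(inherits(template, "thorax_template"))
  if (inherits(values, "frequency_matrix")) {
    side_scope <- attr(values, "side_scope")
    w <- attr(values, "bin_width")
    value_at <- function(rib, pct) {
      values[rib, bin_index(pct, w) + 1L]
    }
    vmax <- max(values)
  } else if (is.list(values) &&
             all(vapply(values, inherits, logical(1), "density_profile"))) {
    if (length(values) != 12L) {
      stop("need one density profile per rib (a list of 12)", call. = FALSE)
    }
    scopes <- unique(vapply(values, `[[`, character(1), "side_scope"))
    if (length(scopes) != 1L) {
      stop("density profiles mix side scopes", call. = FALSE)
    }
    side_scope <- scopes
    value_at <- function(rib, pct) {
      pr <- values[[rib]]
      stats::approx(pr$positions, pr$density, xout = pct, rule = 2)$y
    }
    vmax <- max(vapply(values, function(pr) max(pr$density), numeric(1)))
  } else {
    stop("values must be a frequency_matrix or a list of density_profile",
         call. = FALSE)
  }

  sides <- switch(side_scope,
                  pooled = c("left", "right"),
                  mirrored = "right",
                  left = "left",
                  right = "right")
  if (is.null(range)) range <- c(0, vmax)

  painted <- list()
  for (side in sides) {
    for (r in 1:12) {
      cu <- template_curve(template, r, side)
      sc <- value_at(r, vertex_percents(cu))
      cu$scalar <- sc
      cu$color <- heatmap_colors(sc, range = range, colors = colors)
      painted[[template_curve_id(r, side)]] <- cu
    }
  }
  structure(list(curves = painted, side_scope = side_scope, range = range),
            class = "painted_template")
}

#' @export
print.painted_template <- function(x, ...) {
  cat(sprintf(
    "<painted_template> %d curves (%s), scalar range [%.3g, %.3g]\n",
    length(x$curves), x$side_scope, x$range[1], x$range[2]))
  invisible(x)
}

#' Position histogram of fracture lines
#'
#' Pooled 10%-bin histogram of fracture-line positions (the 2D companion
#' of the 3D heat map). Requires ggplot2.
#'
#' @param cohort A `rib_cohort`.
#' @param bin_width Bin width in percentage points.
#' @return A ggplot object.
#' @export
plot_position_histogram <- function(cohort, bin_width = 10) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  m <- frequency_matrix(cohort, bin_width = bin_width)
  agg <- data.frame(mid = (seq_len(ncol(m)) - 0.5) * bin_width,
                    count = colSums(m))
  ggplot2::ggplot(agg, ggplot2::aes(x = mid, y = count)) +
    ggplot2::geom_col(width = bin_width * 0.92, fill = "steelblue") +
    ggplot2::labs(x = "position along rib (%)",
                  y = "fracture lines") +
    ggplot2::theme_minimal()
}
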