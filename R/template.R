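# Parametric thorax template: 24 rib centerline curves.

#' Shape parameters for the parametric thorax template
#'
#' The built-in template is synthetic: each rib centerline is an elliptical
#' arc lying in a tilted plane, with semi-axes, sweep angle, tilt and
#' vertical position varying smoothly with rib index so that the rib cage
#' widens down to about rib 8 and narrows again, and the floating ribs
#' (11-12) are short. It stands in for a patient-derived healthy-adult
#' template; real centerlines can be supplied via [read_template_csv()].
#'
#' @param scale Overall isotropic scale factor applied to the in-plane
#'   radii (dimensionless; 1 gives an adult-sized cage, half-widths of
#'   roughly 70-115 mm).
#' @param n_vertices Number of vertices per rib curve (>= 50).
#' @param depth_ratio Anteroposterior semi-axis as a fraction of the
#'   lateral semi-axis.
#' @param z_spacing Vertical distance between consecutive ribs (mm).
#' @param tilt_deg Length-12 vector of per-rib plane tilts (degrees about
#'   the lateral axis; anterior ends drop by the tilt), or a single value
#'   recycled.
#' @param span_fraction Length-12 vector of sweep fractions; 1 means the
#'   rib reaches the parasternal line, smaller values give shorter ribs.
#' @return A list of class `template_config`.
#' @export
template_config <- function(scale = 1,
                            n_vertices = 120,
                            depth_ratio = 0.75,
                            z_spacing = 18,
                            tilt_deg = seq(8, 24, length.out = 12),
                            span_fraction = c(rep(1, 7), 0.93, 0.85,
                                              0.74, 0.50, 0.34)) {
  tilt_deg <- rep_len(as.numeric(tilt_deg), 12L)
  span_fraction <- rep_len(as.numeric(span_fraction), 12L)
  cfg <- list(scale = as.numeric(scale), n_vertices = as.integer(n_vertices),
              depth_ratio = as.numeric(depth_ratio),
              z_spacing = as.numeric(z_spacing),
              tilt_deg = tilt_deg, span_fraction = span_fraction)
  nums <- unlist(cfg)
  if (any(!is.finite(nums))) {
    stop("template_config parameters must be finite", call. = FALSE)
  }
  if (cfg$scale <= 0 || cfg$depth_ratio <= 0 || cfg$z_spacing <= 0 ||
      any(span_fraction <= 0) || any(span_fraction > 1)) {
    stop("template_config parameters out of range", call. = FALSE)
  }
  if (cfg$n_vertices < 50L) {
    stop("n_vertices must be at least 50", call. = FALSE)
  }
  structure(cfg, class = "template_config")
}

#' Build the default 24-curve thorax template
#'
#' Generates one [rib_curve()] per (rib, side) pair, 24 in total, from the
#' parametric shape model described in [template_config()]. The
#' construction is deterministic: the same configuration always yields
#' byte-identical vertex arrays. Coordinates: +x right, +y anterior,
#' +z superior; each curve starts at its costovertebral (posterior) end.
#'
#' @param config A [template_config()].
#' @return An object of class `thorax_template`: list with `curves` (a
#'   list of 24 `rib_curve`s, names like `"r5_left"`) and `metadata`.
#' @export
#' @examples
#' tpl <- default_template()
#' length(tpl$curves)  # 24
default_template <- function(config = template_config()) {
  stopifnot(inherits(config, "template_config"))
  curves <- list()
  for (r in 1:12) {
    for (side in c("left", "right")) {
      curves[[template_curve_id(r, side)]] <- template_rib_curve(r, side,
                                                                 config)
    }
  }
  structure(
    list(curves = curves,
         metadata = list(source = "ribmap parametric template",
                         config = config)),
    class = "thorax_template"
  )
}

template_curve_id <- function(rib_index, side) {
  sprintf("r%d_%s", rib_index, side)
}

# Elliptical-arc centerline for one rib. The arc lives in the z = 0 plane
# of a local frame, is tilted rigidly about the x axis, then translated to
# the rib's vertical station; tilting and translation preserve arc length,
# so scaling the radii scales every curve length by exactly the same
# factor.
template_rib_curve <- function(rib_index, side, config) {
  r <- rib_index
  # lateral half-width: widens to rib 8, narrows to rib 12
  a <- config$scale * (60 + 55 * sin(pi * r / 13))
  b <- a * config$depth_ratio
  eps_post <- 0.10   # angular gap at the spine
  eps_ant <- 0.12    # angular gap at the sternum
  span <- config$span_fraction[r] * (pi - eps_post - eps_ant)
  phi <- seq(eps_post, eps_post + span, length.out = config$n_vertices)
  sgn <- if (side == "right") 1 else -1
  x <- sgn * a * sin(phi)
  y <- -b * cos(phi)            # phi = 0 is the posterior midline
  tilt <- config$tilt_deg[r] * pi / 180
  z0 <- -config$z_spacing * (r - 1)
  v <- cbind(x, y * cos(tilt), z0 - y * sin(tilt))
  rib_curve(rib_index, side, v)
}

#' @export
print.thorax_template <- function(x, ...) {
  lens <- vapply(x$curves, function(cu) cu$length, numeric(1))
  cat(sprintf("<thorax_template> %d curves (%s)\n", length(x$curves),
              x$metadata$source))
  cat(sprintf("  arc lengths %.0f-%.0f mm, %d vertices/curve\n",
              min(lens), max(lens), nrow(x$curves[[1]]$vertices)))
  invisible(x)
}

#' Extract one curve from a template
#'
#' @param template A `thorax_template`.
#' @param rib_index Rib number 1-12.
#' @param side `"left"` or `"right"`.
#' @return A [rib_curve()].
#' @export
template_curve <- function(template, rib_index, side) {
  stopifnot(inherits(template, "thorax_template"))
  id <- template_curve_id(check_rib_index(rib_index), normalize_side(side))
  cu <- template$curves[[id]]
  if (is.null(cu)) stop("template has no curve ", id, call. = FALSE)
  cu
}

#' Assemble a template from user-supplied curves
#'
#' @param curves List of 24 [rib_curve()]s covering every (rib, side) pair
#'   exactly once.
#' @param source Provenance string stored in the metadata.
#' @return A `thorax_template`.
#' @export
thorax_template <- function(curves, source = "user-supplied") {
  if (!all(vapply(curves, inherits, logical(1), "rib_curve"))) {
    stop("all elements must be rib_curve objects", call. = FALSE)
  }
  ids <- vapply(curves, function(cu) template_curve_id(cu$rib_index, cu$side),
                character(1))
  expected <- as.vector(outer(1:12, c("left", "right"), template_curve_id))
  if (length(ids) != 24L || anyDuplicated(ids) ||
      !setequal(ids, expected)) {
    stop("a template needs exactly one curve per (rib, side) pair, 24 total",
         call. = FALSE)
  }
  names(curves) <- ids
  structure(list(curves = curves[expected],
                 metadata = list(source = source)),
            class = "thorax_template")
}

# ---- CSV interchange --------------------------------------------------------

#' Read / write a template as an ordered-vertex CSV
#'
#' The schema is one row per vertex with columns `rib`, `side`, `x`, `y`,
#' `z`; row order within each (rib, side) group is curve order, starting
#' at the costovertebral end.
#'
#' @param path CSV file path.
#' @return `read_template_csv()` returns a `thorax_template`;
#'   `write_template_csv()` returns `path` invisibly.
#' @export
read_template_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rib", "side", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("template CSV must have columns rib, side, x, y, z", call. = FALSE)
  }
  df$side <- normalize_side(df$side)
  key <- paste(df$rib, df$side)
  curves <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    rib_curve(g$rib[1], g$side[1], cbind(g$x, g$y, g$z))
  })
  thorax_template(unname(curves), source = paste0("csv:", basename(path)))
}

#' @rdname read_template_csv
#' @param template A `thorax_template`.
#' @export
write_template_csv <- function(template, path) {
  stopifnot(inherits(template, "thorax_template"))
  rows <- lapply(template$curves, function(cu) {
    data.frame(rib = cu$rib_index, side = cu$side,
               x = cu$vertices[, 1], y = cu$vertices[, 2],
               z = cu$vertices[, 3])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
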