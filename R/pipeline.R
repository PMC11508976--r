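# End-to-end pipeline: read (or simulate) a cohort, aggregate, paint the
# 3D heat map, run the statistics, and write every artifact to an output
# directory.

#' Pipeline run configuration
#'
#' @param patients,fractures Input CSV paths (ignored when `cohort` is
#'   passed directly to [run_pipeline()]).
#' @param template_csv Optional path to a centerline CSV replacing the
#'   parametric template (see [read_template_csv()]).
#' @param bin_width Position-bin width in percentage points.
#' @param sector_boundaries CWIS-style sector boundaries `(b1, b2)`.
#' @param bandwidth Density bandwidth in percentage points.
#' @param side_scope Aggregation scope, see [frequency_matrix()].
#' @param alpha Significance level used when flagging test results.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the report (the analysis itself is
#'   deterministic; the seed matters when the input cohort is simulated).
#' @param make_figures Write a position-histogram PNG (requires ggplot2).
#' @param verbose Log per-stage record counts with `message()`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(patients = NULL, fractures = NULL,
                       template_csv = NULL,
                       bin_width = 10,
                       sector_boundaries = c(33.33, 66.67),
                       bandwidth = 5,
                       side_scope = "pooled",
                       alpha = 0.05,
                       out_dir = "ribmap-out",
                       seed = 1L,
                       make_figures = FALSE,
                       verbose = TRUE) {
  check_bin_width(bin_width)
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be positive", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(list(patients = patients, fractures = fractures,
                 template_csv = template_csv, bin_width = bin_width,
                 sector_boundaries = as.numeric(sector_boundaries),
                 bandwidth = bandwidth,
                 side_scope = match.arg(side_scope,
                                        c("pooled", "left", "right",
                                          "mirrored")),
                 alpha = alpha, out_dir = out_dir, seed = as.integer(seed),
                 make_figures = isTRUE(make_figures),
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' The round trip is lossless: `read_run_config(write_run_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Full statistical report for a cohort
#'
#' Computes every tabular output of the analysis: the descriptive cohort
#' summary, the per-rib count table, the rib-by-bin frequency matrix, the
#' positional group comparison for each associated-fracture flag, and the
#' clavicle/upper-rib association. Flags whose groups contribute no
#' records are reported as skipped rather than failing the report.
#'
#' @param cohort A `rib_cohort`.
#' @param bin_width Bin width for the frequency matrix.
#' @param side_scope Aggregation scope.
#' @param alpha Significance level used for the `significant` field.
#' @return A list of class `cohort_report`.
#' @export
cohort_report <- function(cohort, bin_width = 10, side_scope = "pooled",
                          alpha = 0.05) {
  stopifnot(inherits(cohort, "rib_cohort"))
  comparisons <- lapply(cohort_flags(), function(fl) {
    tryCatch(position_comparison(cohort, fl),
             error = function(e) list(flag = fl, skipped = TRUE,
                                      reason = conditionMessage(e)))
  })
  names(comparisons) <- cohort_flags()
  upper <- tryCatch(upper_rib_association(cohort, "clavicle"),
                    error = function(e) list(skipped = TRUE,
                                             reason = conditionMessage(e)))
  structure(list(summary = cohort_summary(cohort),
                 rib_counts = rib_count_table(cohort),
                 frequency = frequency_matrix(cohort, bin_width, side_scope),
                 comparisons = comparisons,
                 upper_rib = upper,
                 alpha = alpha),
            class = "cohort_report")
}

report_to_list <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  s <- report$summary
  rc <- report$rib_counts
  cmp <- lapply(report$comparisons, function(x) {
    if (!is.null(x$skipped)) return(list(flag = x$flag, skipped = TRUE))
    list(flag = x$flag, n_yes = x$n_yes, n_no = x$n_no,
         mean_yes = round(x$mean_yes, 2), sd_yes = round(x$sd_yes, 2),
         mean_no = round(x$mean_no, 2), sd_no = round(x$sd_no, 2),
         U = x$U, p_value = x$p.value,
         significant = x$p.value < report$alpha)
  })
  upper <- if (!is.null(report$upper_rib$skipped)) {
    list(skipped = TRUE)
  } else {
    u <- report$upper_rib
    list(flag = u$flag, ribs = u$ribs, counts = as.vector(t(u$counts)),
         rate_yes = round(100 * u$rate_yes, 2),
         rate_no = round(100 * u$rate_no, 2),
         method = u$method, statistic = u$statistic, p_value = u$p.value,
         significant = u$p.value < report$alpha)
  }
  list(
    summary = list(n_patients = s$n_patients,
                   n_fracture_lines = s$n_fracture_lines,
                   lines_per_patient = round(unname(s$lines_per_patient), 2),
                   side_share = if (!is.null(s$side_share))
                     as.list(round(s$side_share, 2)) else NULL,
                   position = if (!is.null(s$position))
                     round(unname(s$position), 2) else NULL,
                   flag_prevalence = apply(s$flag_prevalence, 2, as.list)),
    rib_counts = list(rib = rc$rib, left = rc$left, right = rc$right,
                      total = rc$total, percent = rc$percent,
                      grand_total = attr(rc, "grand_total"),
                      left_share = attr(rc, "left_share"),
                      right_share = attr(rc, "right_share")),
    frequency = list(bin_width = attr(report$frequency, "bin_width"),
                     side_scope = attr(report$frequency, "side_scope"),
                     counts = unclass(unname(report$frequency))),
    position_comparisons = cmp,
    upper_rib_association = upper
  )
}

format_report_text <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  s <- report$summary
  rc <- report$rib_counts
  out <- c(
    "ribmap cohort report",
    strrep("=", 60),
    sprintf("patients: %d   fracture lines: %d", s$n_patients,
            s$n_fracture_lines),
    sprintf("lines per patient: %.2f (SD %.2f)",
            s$lines_per_patient["mean"], s$lines_per_patient["sd"]),
    if (!is.null(s$position))
      sprintf("position: mean %.2f%%  SD %.2f  median %.2f  range %.2f-%.2f",
              s$position["mean"], s$position["sd"], s$position["median"],
              s$position["min"], s$position["max"]),
    "",
    "fracture lines per rib",
    strrep("-", 60),
    sprintf("%4s %6s %6s %6s %9s", "rib", "left", "right", "total",
            "percent"),
    sprintf("%4d %6d %6d %6d %9.2f", rc$rib, rc$left, rc$right, rc$total,
            rc$percent),
    sprintf("%4s %6d %6d %6d %9s", "all", sum(rc$left), sum(rc$right),
            attr(rc, "grand_total"), "100"),
    sprintf("side share: left %.2f%%  right %.2f%%",
            attr(rc, "left_share"), attr(rc, "right_share")),
    "",
    "positional group comparisons (fracture-record level)",
    strrep("-", 60)
  )
  for (x in report$comparisons) {
    if (!is.null(x$skipped)) {
      out <- c(out, sprintf("%-18s skipped (%s)", x$flag, x$reason))
    } else {
      out <- c(out, sprintf(
        "%-18s yes %.2f%% (SD %.2f, n=%d)  no %.2f%% (SD %.2f, n=%d)",
        x$flag, x$mean_yes, x$sd_yes, x$n_yes, x$mean_no, x$sd_no, x$n_no),
        sprintf("%-18s U = %.1f  p = %.4g%s", "", x$U, x$p.value,
                if (x$p.value < report$alpha) " *" else ""))
    }
  }
  u <- report$upper_rib
  out <- c(out, "", "upper-rib (1-3) involvement by clavicle fracture",
           strrep("-", 60))
  if (!is.null(u$skipped)) {
    out <- c(out, sprintf("skipped (%s)", u$reason))
  } else {
    out <- c(out, sprintf("flagged %.2f%%  unflagged %.2f%%",
                          100 * u$rate_yes, 100 * u$rate_no),
             sprintf("%s: %sp = %.4g%s", u$method,
                     if (!is.na(u$statistic))
                       sprintf("chi-square = %.3f, ", u$statistic) else "",
                     u$p.value,
                     if (u$p.value < report$alpha) " *" else ""))
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

#' Run the full mapping-and-statistics pipeline
#'
#' Validates the input cohort, aggregates it into a frequency matrix and
#' per-rib density profiles, paints the 3D fracture-frequency heat map on
#' the thorax template, computes the statistical report, and writes all
#' artifacts to `config$out_dir`: `matrix.csv`, `density.csv`,
#' `heatmap.ply`, `report.json`, `report.txt` and optionally
#' `positions.png`. All outputs are re-parseable by the package's own
#' readers, and the run is deterministic for a fixed configuration.
#'
#' @param config A [run_config()].
#' @param cohort Optionally a ready-made `rib_cohort`; otherwise the
#'   cohort is read from `config$patients` / `config$fractures`.
#' @return Invisibly, a list with the `cohort`, `report`, `matrix`,
#'   `profiles`, `painted` template and the output `paths`.
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_msg <- function(...) if (config$verbose) message(sprintf(...))

  if (is.null(cohort)) {
    if (is.null(config$patients) || is.null(config$fractures)) {
      stop("config must give patients/fractures paths (or pass a cohort)",
           call. = FALSE)
    }
    cohort <- read_cohort_csv(config$patients, config$fractures,
                              sector_boundaries = config$sector_boundaries,
                              bin_width = config$bin_width)
  }
  stopifnot(inherits(cohort, "rib_cohort"))
  log_msg("[map] %d patients, %d fracture lines validated",
          nrow(cohort$patients), nrow(cohort$fractures))

  template <- if (is.null(config$template_csv)) {
    default_template()
  } else {
    read_template_csv(config$template_csv)
  }
  log_msg("[template] %d curves (%s)", length(template$curves),
          template$metadata$source)

  m <- frequency_matrix(cohort, config$bin_width, config$side_scope)
  profiles <- lapply(1:12, function(r) {
    density_profile(cohort, r, config$side_scope, config$bandwidth)
  })
  painted <- paint_heatmap(template, profiles)
  log_msg("[heatmap] %d lines binned (%s scope), density bandwidth %g%%",
          sum(m), config$side_scope, config$bandwidth)

  report <- cohort_report(cohort, config$bin_width, config$side_scope,
                          config$alpha)
  log_msg("[stats] %d comparisons, grand total %d lines",
          length(report$comparisons), attr(report$rib_counts, "grand_total"))

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    matrix = file.path(config$out_dir, "matrix.csv"),
    density = file.path(config$out_dir, "density.csv"),
    heatmap = file.path(config$out_dir, "heatmap.ply"),
    report_json = file.path(config$out_dir, "report.json"),
    report_txt = file.path(config$out_dir, "report.txt"))

  utils::write.csv(frequency_matrix_df(m), paths$matrix, row.names = FALSE)
  dens <- do.call(rbind, lapply(profiles, function(pr) {
    data.frame(rib = pr$rib_index, position = pr$positions,
               density = pr$density)
  }))
  utils::write.csv(dens, paths$density, row.names = FALSE)
  write_heatmap_ply(painted, paths$heatmap)
  jsonlite::write_json(report_to_list(report), paths$report_json,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report_text(report), paths$report_txt)
  if (config$make_figures) {
    fig <- file.path(config$out_dir, "positions.png")
    grDevices::png(fig, width = 1200, height = 700, res = 150)
    print(plot_position_histogram(cohort, config$bin_width))
    grDevices::dev.off()
    paths$figure <- fig
  }
  log_msg("[write] artifacts in %s", config$out_dir)

  invisible(list(cohort = cohort, report = report, matrix = m,
                 profiles = profiles, painted = painted, paths = paths))
}
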