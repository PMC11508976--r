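# Cohort-level statistics: per-rib count tables, nonparametric positional
# group comparisons, and 2x2 association tests.

#' Per-rib fracture-line count table
#'
#' Left/right/total fracture-line counts per rib with each rib's share of
#' the grand total. Shares are reported rounded to 2 decimals (the
#' conventional table precision); side shares likewise.
#'
#' @param cohort A `rib_cohort`.
#' @return Data frame of class `rib_count_table` with columns `rib`,
#'   `left`, `right`, `total`, `percent`, and attributes `grand_total`,
#'   `left_share`, `right_share` (percent, 2 d.p.). An empty cohort yields
#'   zero counts with `NA` percents.
#' @export
rib_count_table <- function(cohort) {
  stopifnot(inherits(cohort, "rib_cohort"))
  fr <- cohort$fractures
  left <- as.integer(table(factor(fr$rib[fr$side == "left"], levels = 1:12)))
  right <- as.integer(table(factor(fr$rib[fr$side == "right"],
                                   levels = 1:12)))
  total <- left + right
  g <- sum(total)
  pct <- if (g > 0) round(100 * total / g, 2) else rep(NA_real_, 12)
  out <- data.frame(rib = 1:12, left = left, right = right, total = total,
                    percent = pct)
  structure(out,
            grand_total = g,
            left_share = if (g > 0) round(100 * sum(left) / g, 2) else
              NA_real_,
            right_share = if (g > 0) round(100 * sum(right) / g, 2) else
              NA_real_,
            class = c("rib_count_table", "data.frame"))
}

#' @export
print.rib_count_table <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("total %d | left %s%% right %s%%\n", attr(x, "grand_total"),
              format(attr(x, "left_share")), format(attr(x, "right_share"))))
  invisible(x)
}

#' Mann-Whitney U (Wilcoxon rank-sum) test
#'
#' Two-sample location test on ranks. `U` is the number of pairwise wins
#' of `x` over `y` (ties count one half), computed from midrank sums. The
#' two-sided p-value comes from exhaustive enumeration of all group-label
#' assignments when the pooled size is at most `exact_limit` (correct
#' under arbitrary ties), and otherwise from the normal approximation with
#' tie-corrected variance.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_limit Pooled-size threshold below which the permutation
#'   null is enumerated exhaustively.
#' @return An object of class `htest` with `statistic` (U for `x`),
#'   `p.value` and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
mann_whitney <- function(x, y, exact_limit = 12) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) {
    stop("samples must be finite", call. = FALSE)
  }
  nx <- length(x)
  ny <- length(y)
  n <- nx + ny
  r <- rank(c(x, y))                       # midranks
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2

  if (n <= exact_limit) {
    # exhaustive permutation null of U over all choose(n, nx) label
    # assignments of the pooled midranks
    sets <- utils::combn(n, nx)
    u_perm <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(u_perm - mu) >= abs(u - mu) - 1e-9)
    method <- "Mann-Whitney U test (exact permutation enumeration)"
  } else {
    t_tab <- table(r)
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_term)
    if (v <= 0) {
      p <- 1
    } else {
      p <- 2 * stats::pnorm(-abs(u - mu) / sqrt(v))
      p <- min(1, p)
    }
    method <- "Mann-Whitney U test (normal approximation, tie-corrected)"
  }
  structure(list(statistic = c(U = u), p.value = p, method = method,
                 alternative = "two.sided",
                 data.name = "x and y",
                 n = c(n_x = nx, n_y = ny)),
            class = "htest")
}

#' 2x2 contingency-table test
#'
#' Association test for a 2x2 table of counts. With `method = "auto"` the
#' uncorrected chi-square test is used unless any expected cell count is
#' below 5, in which case Fisher's exact test is chosen; Yates continuity
#' correction is available explicitly.
#'
#' @param counts 2x2 matrix (or something coercible) of non-negative
#'   integer counts; rows are groups, columns outcomes. Both margins must
#'   be positive.
#' @param method `"auto"`, `"chi_square"`, `"chi_square_yates"` or
#'   `"fisher"`.
#' @return Object of class `contingency_result`: list with `counts`,
#'   `expected`, `method` (the method actually used), `statistic`
#'   (chi-square; `NA` for Fisher), `p.value`, and `rates` (first-column
#'   rate per row group).
#' @export
contingency_2x2 <- function(counts, method = c("auto", "chi_square",
                                               "chi_square_yates",
                                               "fisher")) {
  method <- match.arg(method)
  m <- as.matrix(counts)
  if (!all(dim(m) == c(2L, 2L)) || any(!is.finite(m)) || any(m < 0) ||
      any(m != round(m))) {
    stop("counts must be a 2x2 matrix of non-negative integers",
         call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("both margins of the 2x2 table must be positive", call. = FALSE)
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (method == "auto") {
    method <- if (any(expected < 5)) "fisher" else "chi_square"
  }
  if (method == "fisher") {
    ht <- stats::fisher.test(m)
    statistic <- NA_real_
  } else {
    ht <- stats::chisq.test(m, correct = method == "chi_square_yates")
    statistic <- unname(ht$statistic)
  }
  structure(list(counts = m, expected = expected, method = method,
                 statistic = statistic, p.value = ht$p.value,
                 rates = m[, 1] / rowSums(m)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> method = %s\n", x$method))
  print(x$counts)
  if (!is.na(x$statistic)) {
    cat(sprintf("chi-square = %.3f, ", x$statistic))
  }
  cat(sprintf("p = %.4g; rates = %s\n", x$p.value,
              paste(sprintf("%.2f%%", 100 * x$rates), collapse = " vs ")))
  invisible(x)
}

#' Positional group comparison under an associated-fracture flag
#'
#' Splits all fracture-line records by a patient-level flag (e.g. whether
#' the patient also has a scapular fracture) and compares the percentage
#' positions of the two groups with [mann_whitney()]. The statistical unit
#' is the fracture record; set `unit = "patient"` to compare per-patient
#' mean positions instead.
#'
#' @param cohort A `rib_cohort`.
#' @param flag One of [cohort_flags()].
#' @param unit `"record"` (default) or `"patient"`.
#' @return Object of class `group_comparison`: list with per-group `n`,
#'   `mean`, `sd`, the `U` statistic (flagged group), `p.value`,
#'   `shift_estimate` (`mean_yes - mean_no`) and `method`.
#' @export
position_comparison <- function(cohort, flag = cohort_flags(),
                                unit = c("record", "patient")) {
  stopifnot(inherits(cohort, "rib_cohort"))
  flag <- match.arg(flag)
  unit <- match.arg(unit)
  fr <- cohort$fractures
  flagged_ids <- cohort$patients$patient_id[cohort$patients[[flag]]]
  if (unit == "record") {
    yes <- fr$percent[fr$patient_id %in% flagged_ids]
    no <- fr$percent[!fr$patient_id %in% flagged_ids]
  } else {
    means <- tapply(fr$percent, fr$patient_id, mean)
    yes <- as.numeric(means[names(means) %in% flagged_ids])
    no <- as.numeric(means[!names(means) %in% flagged_ids])
  }
  if (length(yes) == 0L || length(no) == 0L) {
    stop(sprintf("flag '%s': a group contributes no fracture records", flag),
         call. = FALSE)
  }
  ht <- mann_whitney(yes, no)
  structure(list(flag = flag, unit = unit,
                 n_yes = length(yes), n_no = length(no),
                 mean_yes = mean(yes), sd_yes = stats::sd(yes),
                 mean_no = mean(no), sd_no = stats::sd(no),
                 U = unname(ht$statistic), p.value = ht$p.value,
                 shift_estimate = mean(yes) - mean(no),
                 method = ht$method),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s level)\n", x$flag, x$unit))
  cat(sprintf("  yes: n = %d, %.2f%% (SD %.2f)\n", x$n_yes, x$mean_yes,
              x$sd_yes))
  cat(sprintf("  no:  n = %d, %.2f%% (SD %.2f)\n", x$n_no, x$mean_no,
              x$sd_no))
  cat(sprintf("  shift %.2f points, U = %.1f, p = %.4g\n",
              x$shift_estimate, x$U, x$p.value))
  invisible(x)
}

#' Association between a flag and upper-rib involvement
#'
#' For each patient, computes the indicator "has at least one fracture on
#' a rib in `ribs`" (default ribs 1-3, the upper ribs), cross-tabulates it
#' against the associated-fracture flag, and tests the 2x2 table with
#' [contingency_2x2()].
#'
#' @param cohort A `rib_cohort`.
#' @param flag One of [cohort_flags()]; default `"clavicle"`.
#' @param ribs Rib indices defining involvement.
#' @param method Passed to [contingency_2x2()].
#' @return A `contingency_result` with extra fields `flag`, `ribs`,
#'   `rate_yes`, `rate_no` (involvement rate in the flagged / unflagged
#'   group).
#' @export
upper_rib_association <- function(cohort, flag = "clavicle", ribs = 1:3,
                                  method = "auto") {
  stopifnot(inherits(cohort, "rib_cohort"))
  flag <- match.arg(flag, cohort_flags())
  pats <- cohort$patients
  fr <- cohort$fractures
  involved_ids <- unique(fr$patient_id[fr$rib %in% ribs])
  involved <- pats$patient_id %in% involved_ids
  flagged <- pats[[flag]]
  m <- matrix(c(sum(flagged & involved), sum(flagged & !involved),
                sum(!flagged & involved), sum(!flagged & !involved)),
              nrow = 2, byrow = TRUE,
              dimnames = list(flag = c("yes", "no"),
                              involved = c("yes", "no")))
  if (any(colSums(m) == 0) && all(rowSums(m) > 0)) {
    # no variation in involvement: rates are still well defined, but no
    # association test applies
    res <- structure(list(counts = m,
                          expected = outer(rowSums(m), colSums(m)) / sum(m),
                          method = "none", statistic = NA_real_,
                          p.value = NA_real_,
                          rates = m[, 1] / rowSums(m)),
                     class = "contingency_result")
  } else {
    res <- contingency_2x2(m, method = method)
  }
  res$flag <- flag
  res$ribs <- ribs
  res$rate_yes <- unname(res$rates[1])
  res$rate_no <- unname(res$rates[2])
  res
}

#' Descriptive cohort summary
#'
#' Patient-level and fracture-level descriptives: demographics, injury
#' mechanisms, associated-fracture prevalences, fracture-line counts per
#' patient, side split and sector distribution. Only fracture-line counts
#' are reported (distinct fracture events are not modeled).
#'
#' @param cohort A `rib_cohort`.
#' @return A list of class `cohort_summary`.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "rib_cohort"))
  pats <- cohort$patients
  fr <- cohort$fractures
  per_patient <- table(factor(fr$patient_id, levels = pats$patient_id))
  flags <- vapply(cohort_flags(), function(fl) {
    c(n = sum(pats[[fl]]), pct = round(100 * mean(pats[[fl]]), 1))
  }, numeric(2))
  out <- list(
    n_patients = nrow(pats),
    n_fracture_lines = nrow(fr),
    age = if ("age" %in% names(pats)) {
      c(mean = mean(pats$age), sd = stats::sd(pats$age))
    } else NULL,
    sex = if ("sex" %in% names(pats)) table(pats$sex) else NULL,
    mechanism = if ("mechanism" %in% names(pats)) {
      table(pats$mechanism)
    } else NULL,
    flag_prevalence = flags,
    lines_per_patient = c(mean = mean(per_patient),
                          sd = stats::sd(per_patient)),
    side_share = if (nrow(fr)) {
      round(100 * prop.table(table(fr$side)), 2)
    } else NULL,
    sector_share = if (nrow(fr)) {
      round(100 * prop.table(table(factor(fr$sector,
                                          levels = c("posterior", "lateral",
                                                     "anterior")))), 2)
    } else NULL,
    position = if (nrow(fr)) {
      c(mean = mean(fr$percent), sd = stats::sd(fr$percent),
        median = stats::median(fr$percent), min = min(fr$percent),
        max = max(fr$percent))
    } else NULL
  )
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d patients, %d fracture lines\n",
              x$n_patients, x$n_fracture_lines))
  cat(sprintf("  lines/patient %.2f (SD %.2f)\n",
              x$lines_per_patient["mean"], x$lines_per_patient["sd"]))
  if (!is.null(x$position)) {
    cat(sprintf("  position %.2f%% (SD %.2f)\n", x$position["mean"],
                x$position["sd"]))
  }
  invisible(x)
}
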