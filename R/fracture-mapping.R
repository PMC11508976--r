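# Normalization of along-rib measurements and cohort validation.

#' Percentage position of a fracture line along a rib
#'
#' The core positional datum: a fracture site B on a rib measured by its
#' along-rib distances from the costovertebral joint A (`d1`, segment A-B)
#' and to the costochondral junction C (`d2`, segment B-C) is normalized to
#'
#' \deqn{100 \cdot d_1 / (d_1 + d_2)}
#'
#' so 0% is the posterior (spinal) end and 100% the anterior end of the
#' bony rib. The result is scale invariant: only the ratio of the two
#' distances matters, so the measurement template's absolute size cancels.
#'
#' @param d1 Distance (mm, >= 0) from the costovertebral joint to the
#'   fracture site. Vectorized.
#' @param d2 Distance (mm, >= 0) from the fracture site to the
#'   costochondral junction. Vectorized.
#' @return Percentage position(s) in \[0, 100\], full precision (rounding
#'   to 2 decimals is a display concern only).
#' @export
#' @examples
#' percent_position(266.10, 36.80)  # 87.8508...
percent_position <- function(d1, d2) {
  d1 <- as.numeric(d1)
  d2 <- as.numeric(d2)
  if (any(!is.finite(d1)) || any(!is.finite(d2))) {
    stop("distances must be finite", call. = FALSE)
  }
  if (any(d1 < 0) || any(d2 < 0)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  tot <- d1 + d2
  if (any(tot == 0)) {
    stop("d1 + d2 must be positive", call. = FALSE)
  }
  100 * d1 / tot
}

#' Anatomical chest-wall sector of a percentage position
#'
#' Classifies positions into the posterior / lateral / anterior sectors of
#' the chest wall. Because no consensus fixes the precise sector
#' boundaries, they are a configuration parameter; the default splits the
#' rib into equal thirds. Intervals are half-open: posterior is
#' \[0, b1), lateral \[b1, b2), anterior \[b2, 100\].
#'
#' @param percent Percentage position(s) in \[0, 100\].
#' @param boundaries Length-2 increasing vector `(b1, b2)` within
#'   \[0, 100\].
#' @return Character vector with levels `"posterior"`, `"lateral"`,
#'   `"anterior"`.
#' @export
#' @examples
#' classify_sector(c(10, 50, 87.85))
classify_sector <- function(percent, boundaries = c(33.33, 66.67)) {
  check_percent(percent)
  b <- as.numeric(boundaries)
  if (length(b) != 2L || any(!is.finite(b)) || b[1] < 0 || b[2] > 100 ||
      b[1] >= b[2]) {
    stop("boundaries must satisfy 0 <= b1 < b2 <= 100", call. = FALSE)
  }
  ifelse(percent < b[1], "posterior",
         ifelse(percent < b[2], "lateral", "anterior"))
}

#' Position-bin index of a percentage position
#'
#' Bins are left-closed, right-open (`[0,10), [10,20), ...`) with the last
#' bin closed at 100, and are numbered from 0, so with the default 10%
#' width bin 2 is the 20-30% segment and bin 8 the 80-90% segment.
#'
#' @param percent Percentage position(s) in \[0, 100\].
#' @param width Bin width in percentage points; must divide 100.
#' @return Integer bin indices, 0 to `100 / width - 1`.
#' @export
#' @examples
#' bin_index(c(20, 87.85, 100))  # 2, 8, 9
bin_index <- function(percent, width = 10) {
  check_percent(percent)
  k <- check_bin_width(width)
  pmin(as.integer(floor(percent / width)), k - 1L)
}

check_percent <- function(percent) {
  percent <- as.numeric(percent)
  if (any(!is.finite(percent)) || any(percent < 0) || any(percent > 100)) {
    stop("percent must lie in [0, 100]", call. = FALSE)
  }
  invisible(percent)
}

check_bin_width <- function(width) {
  width <- as.numeric(width)
  if (length(width) != 1L || !is.finite(width) || width <= 0 ||
      abs(100 / width - round(100 / width)) > 1e-9) {
    stop("bin width must be positive and divide 100", call. = FALSE)
  }
  as.integer(round(100 / width))
}

#' Validate raw cohort tables into a `rib_cohort`
#'
#' Takes patient-level and fracture-line-level tables, normalizes and
#' cross-checks them, and returns the cohort object every downstream
#' aggregation and test consumes.
#'
#' Patient table columns: `patient_id` (unique), optionally `age`, `sex`,
#' `mechanism`, and the associated-fracture flags `clavicle`, `scapula`,
#' `thoracic_vertebra`, `sternum` (logical or 0/1; absent flags default to
#' `FALSE`). Fracture table columns: `patient_id`, `rib` (1-12), `side`
#' (`left`/`right`, aliases `L`/`R`), and a position given as `percent`
#' and/or as raw along-rib distances `d1`, `d2`. Rows with only distances
#' are converted via [percent_position()]; rows carrying both must agree
#' within 0.01 percentage points. A patient with no fracture rows is
#' valid.
#'
#' @param patients Data frame of patient-level records.
#' @param fractures Data frame of fracture-line records.
#' @param sector_boundaries Passed to [classify_sector()].
#' @param bin_width Passed to [bin_index()].
#' @return An object of class `rib_cohort`: list with `patients`,
#'   `fractures` (with derived `sector` and `bin` columns),
#'   `sector_boundaries` and `bin_width`.
#' @export
validate_cohort <- function(patients, fractures,
                            sector_boundaries = c(33.33, 66.67),
                            bin_width = 10) {
  patients <- as.data.frame(patients, stringsAsFactors = FALSE)
  fractures <- as.data.frame(fractures, stringsAsFactors = FALSE)

  if (!"patient_id" %in% names(patients)) {
    stop("patients table needs a patient_id column", call. = FALSE)
  }
  patients$patient_id <- as.character(patients$patient_id)
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup)) {
    stop("duplicate patient ids: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  for (fl in cohort_flags()) {
    patients[[fl]] <- if (fl %in% names(patients)) {
      as.logical(as_flag(patients[[fl]], fl))
    } else {
      rep(FALSE, nrow(patients))
    }
  }

  if (nrow(fractures) == 0L) {
    fractures <- data.frame(patient_id = character(), rib = integer(),
                            side = character(), percent = numeric(),
                            stringsAsFactors = FALSE)
  }
  need <- c("patient_id", "rib", "side")
  if (!all(need %in% names(fractures))) {
    stop("fractures table needs columns patient_id, rib, side",
         call. = FALSE)
  }
  n <- nrow(fractures)
  fractures$patient_id <- as.character(fractures$patient_id)
  unknown <- setdiff(fractures$patient_id, patients$patient_id)
  if (length(unknown)) {
    stop("fracture rows reference unknown patient ids: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }

  rib <- suppressWarnings(as.integer(fractures$rib))
  bad <- which(is.na(rib) | rib < 1L | rib > 12L)
  if (length(bad)) {
    stop("rib index outside 1-12 in fracture row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  fractures$rib <- rib
  fractures$side <- normalize_side(fractures$side)

  has_pct <- "percent" %in% names(fractures) & n > 0
  pct <- if ("percent" %in% names(fractures)) {
    as.numeric(fractures$percent)
  } else {
    rep(NA_real_, n)
  }
  d1 <- if ("d1" %in% names(fractures)) as.numeric(fractures$d1) else
    rep(NA_real_, n)
  d2 <- if ("d2" %in% names(fractures)) as.numeric(fractures$d2) else
    rep(NA_real_, n)

  has_d <- !is.na(d1) & !is.na(d2)
  from_d <- rep(NA_real_, n)
  if (any(has_d)) {
    if (any(d1[has_d] < 0 | d2[has_d] < 0 | d1[has_d] + d2[has_d] <= 0)) {
      bad <- which(has_d & (d1 < 0 | d2 < 0 | d1 + d2 <= 0))
      stop("invalid d1/d2 in fracture row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    from_d[has_d] <- percent_position(d1[has_d], d2[has_d])
  }

  both <- !is.na(pct) & has_d
  if (any(both)) {
    off <- which(both & abs(pct - from_d) > 0.01)
    if (length(off)) {
      stop("percent disagrees with d1/d2 by more than 0.01 in row(s) ",
           paste(utils::head(off, 5), collapse = ", "), call. = FALSE)
    }
  }
  pct[is.na(pct)] <- from_d[is.na(pct)]
  miss <- which(is.na(pct))
  if (length(miss)) {
    stop("fracture row(s) with neither percent nor d1/d2: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  out <- which(pct < 0 | pct > 100)
  if (length(out)) {
    stop("percent outside [0, 100] in fracture row(s) ",
         paste(utils::head(out, 5), collapse = ", "), call. = FALSE)
  }

  fr <- data.frame(patient_id = fractures$patient_id,
                   rib = fractures$rib,
                   side = fractures$side,
                   percent = pct,
                   stringsAsFactors = FALSE)
  fr$sector <- if (n) classify_sector(fr$percent, sector_boundaries) else
    character()
  fr$bin <- if (n) bin_index(fr$percent, bin_width) else integer()
  rownames(fr) <- NULL
  rownames(patients) <- NULL

  structure(list(patients = patients, fractures = fr,
                 sector_boundaries = as.numeric(sector_boundaries),
                 bin_width = as.numeric(bin_width)),
            class = "rib_cohort")
}

#' Names of the associated-fracture flags
#' @return Character vector of the four patient-level flag columns.
#' @export
cohort_flags <- function() {
  c("clavicle", "scapula", "thoracic_vertebra", "sternum")
}

as_flag <- function(x, name) {
  if (is.logical(x)) return(x)
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) | !(v %in% c(0, 1)))) {
    stop("flag column ", name, " must be logical or 0/1", call. = FALSE)
  }
  v == 1
}

#' @export
print.rib_cohort <- function(x, ...) {
  cat(sprintf("<rib_cohort> %d patients, %d fracture lines\n",
              nrow(x$patients), nrow(x$fractures)))
  if (nrow(x$fractures)) {
    cat(sprintf("  mean position %.2f%% (SD %.2f), left share %.1f%%\n",
                mean(x$fractures$percent), stats::sd(x$fractures$percent),
                100 * mean(x$fractures$side == "left")))
  }
  invisible(x)
}
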