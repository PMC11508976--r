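# Fixtures and independent oracles, built in code at test time.

# A tiny hand-checkable cohort: 3 patients, 5 fracture lines.
toy_cohort <- function(...) {
  patients <- data.frame(
    patient_id = c("a", "b", "c"),
    age = c(40, 55, 63),
    sex = c("male", "male", "female"),
    clavicle = c(1, 0, 0),
    scapula = c(0, 1, 0),
    thoracic_vertebra = c(0, 0, 0),
    sternum = c(0, 0, 1))
  fractures <- data.frame(
    patient_id = c("a", "a", "b", "b", "c"),
    rib = c(2, 5, 5, 5, 7),
    side = c("left", "right", "left", "left", "right"),
    percent = c(15, 25, 25, 65, 90))
  validate_cohort(patients, fractures, ...)
}

# Cohort realizing exact per-rib, per-side fracture-line counts. Positions
# are spread deterministically over (0, 100); records are dealt round-robin
# over `n_patients` all-flags-false patients.
cohort_from_rib_counts <- function(left, right, n_patients = 102) {
  stopifnot(length(left) == 12, length(right) == 12)
  total <- sum(left) + sum(right)
  rib <- c(rep(1:12, times = left), rep(1:12, times = right))
  side <- c(rep("left", sum(left)), rep("right", sum(right)))
  patients <- data.frame(patient_id = sprintf("p%03d",
                                              seq_len(n_patients)))
  fractures <- data.frame(
    patient_id = patients$patient_id[(seq_len(total) - 1) %% n_patients + 1],
    rib = rib, side = side,
    percent = (seq_len(total) - 0.5) / total * 100)
  validate_cohort(patients, fractures)
}

# Independent Mann-Whitney oracle: U by direct pairwise counting, p by
# exhaustive enumeration of label subsets, again with pairwise-count U.
oracle_mann_whitney <- function(x, y) {
  u_pairwise <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u <- u_pairwise(x, y)
  pool <- c(x, y)
  n <- length(pool)
  mu <- length(x) * length(y) / 2
  sets <- utils::combn(n, length(x))
  u_all <- apply(sets, 2, function(ix) {
    u_pairwise(pool[ix], pool[-ix])
  })
  list(U = u, p = mean(abs(u_all - mu) >= abs(u - mu) - 1e-9))
}

# Closed-form uncorrected chi-square for a 2x2 table.
oracle_chisq_2x2 <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins.
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Random 3D rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_dec)
  q %*% diag(c(1, 1, det(q)))
}
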