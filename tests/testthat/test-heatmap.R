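test_that("frequency_matrix counts records per rib and bin", {
  patients <- data.frame(patient_id = "p1")
  fractures <- data.frame(patient_id = "p1", rib = c(5, 5, 5),
                          side = "left", percent = c(25, 25, 65))
  co <- validate_cohort(patients, fractures)
  m <- frequency_matrix(co)
  expect_equal(unname(m["rib5", 3]), 2)   # 20-30% bin
  expect_equal(unname(m["rib5", 7]), 1)   # 60-70% bin
  expect_equal(sum(m), 3)

  empty <- validate_cohort(data.frame(patient_id = "p1"),
                           data.frame(patient_id = character(),
                                      rib = integer(), side = character(),
                                      percent = numeric()))
  expect_equal(sum(frequency_matrix(empty)), 0)
  expect_error(frequency_matrix(co, bin_width = 7), "divide 100")
})

test_that("frequency_matrix conserves counts and is additive over sides", {
  for (seed in 1:5) {
    sim <- generate_cohort(sim_params(n_patients = 60, seed = seed))
    co <- sim$cohort
    pooled <- frequency_matrix(co, side_scope = "pooled")
    left <- frequency_matrix(co, side_scope = "left")
    right <- frequency_matrix(co, side_scope = "right")
    expect_equal(sum(pooled), nrow(co$fractures))
    expect_equal(unclass(pooled), unclass(left) + unclass(right),
                 ignore_attr = TRUE)
    mirrored <- frequency_matrix(co, side_scope = "mirrored")
    expect_equal(unclass(mirrored), unclass(pooled), ignore_attr = TRUE)
  }
})

test_that("density_profile is unimodal for one record and integrates to n", {
  patients <- data.frame(patient_id = "p1")
  co <- validate_cohort(patients,
                        data.frame(patient_id = "p1", rib = 5,
                                   side = "left", percent = 50))
  pr <- density_profile(co, 5, bandwidth = 5)
  expect_equal(pr$positions[which.max(pr$density)], 50, tolerance = 0.5)
  expect_equal(profile_integral(pr), 1, tolerance = 0.01)

  # a rib with no records gives an explicit all-zero profile
  pr0 <- density_profile(co, 9)
  expect_true(all(pr0$density == 0))
  expect_equal(pr0$n, 0)
})

test_that("density_profile integrals equal record counts within 1%", {
  for (seed in 1:3) {
    sim <- generate_cohort(sim_params(n_patients = 40, seed = seed))
    for (r in c(2, 5, 11)) {
      pr <- density_profile(sim$cohort, r, bandwidth = 5)
      if (pr$n > 0) {
        expect_equal(profile_integral(pr), pr$n, tolerance = 0.01)
      }
    }
    all_ribs <- density_profile(sim$cohort, NULL, bandwidth = 8)
    expect_equal(profile_integral(all_ribs), nrow(sim$cohort$fractures),
                 tolerance = 0.01)
  }
})

test_that("density_profile matches a brute-force kernel sum", {
  set.seed(31)
  pos <- runif(50, 0, 100)
  patients <- data.frame(patient_id = "p1")
  co <- validate_cohort(patients,
                        data.frame(patient_id = "p1", rib = 3,
                                   side = "right", percent = pos))
  bw <- 4
  pr <- density_profile(co, 3, bandwidth = bw)
  brute <- sapply(pr$positions, function(g) {
    s <- 0
    for (p in pos) {
      s <- s + dnorm(g, p, bw) + dnorm(g, -p, bw) + dnorm(g, 200 - p, bw)
    }
    s
  })
  expect_equal(pr$density, brute, tolerance = 1e-9)
})

test_that("well-separated records give two local maxima", {
  patients <- data.frame(patient_id = "p1")
  co <- validate_cohort(patients,
                        data.frame(patient_id = "p1", rib = 5,
                                   side = "left", percent = c(20, 80)))
  pr <- density_profile(co, 5, bandwidth = 3)
  d <- pr$density
  interior <- which(diff(sign(diff(d))) == -2) + 1
  expect_equal(length(interior), 2)
  expect_equal(sort(pr$positions[interior]), c(20, 80), tolerance = 1)
})

test_that("paint_heatmap maps scalars monotonically to the colormap", {
  tpl <- default_template(template_config(n_vertices = 60))
  sim <- generate_cohort(sim_params(n_patients = 80, seed = 4))
  m <- frequency_matrix(sim$cohort)
  painted <- paint_heatmap(tpl, m)
  expect_s3_class(painted, "painted_template")
  expect_length(painted$curves, 24)

  # ramp position (blue -> red) must order identically to the scalars
  ramp_pos <- function(col) {
    (as.numeric(col[, "r"]) - as.numeric(col[, "b"]) + 255) / 510
  }
  for (id in c("r5_left", "r3_right")) {
    cu <- painted$curves[[id]]
    o <- order(cu$scalar)
    expect_true(all(diff(ramp_pos(cu$color)[o]) >= -1e-9))
  }

  # deterministic repaint
  painted2 <- paint_heatmap(tpl, m)
  expect_identical(painted$curves, painted2$curves)
})

test_that("an all-zero matrix paints a uniform minimum-color model", {
  tpl <- default_template(template_config(n_vertices = 60))
  empty <- validate_cohort(data.frame(patient_id = "p1"),
                           data.frame(patient_id = character(),
                                      rib = integer(), side = character(),
                                      percent = numeric()))
  painted <- paint_heatmap(tpl, frequency_matrix(empty))
  cols <- unique(do.call(rbind, lapply(painted$curves, `[[`, "color")))
  expect_equal(nrow(cols), 1)
  expect_equal(unname(cols[1, ]), c(0, 0, 255))  # pure blue = minimum
})

test_that("rescaling densities with fixed range preserves color ordering", {
  tpl <- default_template(template_config(n_vertices = 60))
  sim <- generate_cohort(sim_params(n_patients = 40, seed = 5))
  profiles <- lapply(1:12, function(r) density_profile(sim$cohort, r))
  doubled <- lapply(profiles, function(pr) {
    pr$density <- 2 * pr$density
    pr
  })
  vmax <- max(vapply(doubled, function(pr) max(pr$density), numeric(1)))
  p1 <- paint_heatmap(tpl, profiles, range = c(0, vmax))
  p2 <- paint_heatmap(tpl, doubled, range = c(0, vmax))
  for (id in names(p1$curves)) {
    o1 <- order(p1$curves[[id]]$scalar)
    o2 <- order(p2$curves[[id]]$scalar)
    expect_identical(o1, o2)
  }
})

test_that("painting validates its aggregation input", {
  tpl <- default_template(template_config(n_vertices = 60))
  sim <- generate_cohort(sim_params(n_patients = 20, seed = 6))
  profiles <- lapply(1:6, function(r) density_profile(sim$cohort, r))
  expect_error(paint_heatmap(tpl, profiles), "12")
  mixed <- lapply(1:12, function(r) {
    density_profile(sim$cohort, r,
                    side_scope = if (r == 1) "left" else "pooled")
  })
  expect_error(paint_heatmap(tpl, mixed), "mix side scopes")
})
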