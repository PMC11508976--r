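test_that("arc_length sums segment lengths and matches analytic curves", {
  expect_equal(arc_length(rbind(c(0, 0, 0), c(10, 0, 0))), 10)
  expect_equal(arc_length(rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0))), 3)

  theta <- seq(0, pi, length.out = 1000)
  semicircle <- cbind(100 * cos(theta), 100 * sin(theta), 0)
  expect_equal(arc_length(semicircle), pi * 100, tolerance = 1e-3)

  expect_error(arc_length(rbind(c(0, 0, 0))), "at least 2")
})

test_that("arc_length is invariant under rigid motion", {
  set.seed(11)
  for (i in 1:10) {
    v <- matrix(runif(30, -50, 50), ncol = 3)
    len <- arc_length(v)
    moved <- v %*% random_rotation() +
      matrix(rnorm(3, sd = 100), nrow(v), 3, byrow = TRUE)
    expect_equal(arc_length(moved), len, tolerance = 1e-9)
  }
})

test_that("point_at_percent interpolates by arc-length fraction", {
  cu <- rib_curve(3, "left", rbind(c(0, 0, 0), c(1, 0, 0), c(3, 0, 0)))
  expect_equal(unname(point_at_percent(cu, 0)[1, ]), c(0, 0, 0))
  expect_equal(unname(point_at_percent(cu, 100)[1, ]), c(3, 0, 0))
  expect_equal(unname(point_at_percent(cu, 50)[1, ]), c(1.5, 0, 0))
  expect_error(point_at_percent(cu, 101), "\\[0, 100\\]")
  expect_error(point_at_percent(cu, -1), "\\[0, 100\\]")
})

test_that("point_at_percent is monotone along the curve", {
  tpl <- default_template()
  cu <- template_curve(tpl, 6, "right")
  ps <- sort(runif(25, 0, 100))
  pts <- point_at_percent(cu, ps)
  arc_pos <- vapply(seq_along(ps), function(i) {
    percent_at_point(cu, pts[i, ], tolerance = 1)
  }, numeric(1))
  expect_true(all(diff(arc_pos) > 0))
})

test_that("percent_at_point inverts point_at_percent and enforces tolerance", {
  tpl <- default_template()
  cu <- template_curve(tpl, 5, "left")
  for (p in c(0, 12.5, 50, 87.85, 100)) {
    pt <- point_at_percent(cu, p)[1, ]
    expect_equal(percent_at_point(cu, pt), p, tolerance = 1e-6)
  }
  expect_equal(percent_at_point(cu, cu$vertices[1, ]), 0)
  far <- cu$vertices[1, ] + c(500, 0, 0)
  expect_error(percent_at_point(cu, far, tolerance = 5), "tolerance")
})

test_that("rib_curve rejects degenerate input", {
  expect_error(rib_curve(5, "left", rbind(c(0, 0, 0))), "at least 2")
  expect_error(rib_curve(5, "left", rbind(c(0, 0, 0), c(0, 0, 0))),
               "duplicate")
  expect_error(rib_curve(13, "left", rbind(c(0, 0, 0), c(1, 0, 0))),
               "rib_index")
  expect_error(rib_curve(5, "dorsal", rbind(c(0, 0, 0), c(1, 0, 0))),
               "side")
})

test_that("default template has 24 deterministic curves", {
  tpl <- default_template()
  expect_s3_class(tpl, "thorax_template")
  expect_length(tpl$curves, 24)
  expect_true(all(vapply(tpl$curves, function(cu) nrow(cu$vertices),
                         integer(1)) >= 50))
  ids <- vapply(tpl$curves, function(cu) paste(cu$rib_index, cu$side),
                character(1))
  expect_length(unique(ids), 24)

  tpl2 <- default_template()
  expect_identical(tpl$curves, tpl2$curves)
})

test_that("scaling template radii scales every arc length proportionally", {
  tpl1 <- default_template(template_config(scale = 1))
  tpl2 <- default_template(template_config(scale = 2))
  for (id in names(tpl1$curves)) {
    expect_equal(tpl2$curves[[id]]$length, 2 * tpl1$curves[[id]]$length,
                 tolerance = 1e-9)
  }
})

test_that("template_config validates its parameters", {
  expect_error(template_config(scale = -1), "out of range")
  expect_error(template_config(scale = NaN), "finite")
  expect_error(template_config(n_vertices = 10), "at least 50")
  expect_error(template_config(span_fraction = rep(1.5, 12)),
               "out of range")
})

test_that("template CSV round trip preserves geometry", {
  tpl <- default_template(template_config(n_vertices = 60))
  path <- withr::local_tempfile(fileext = ".csv")
  write_template_csv(tpl, path)
  back <- read_template_csv(path)
  expect_length(back$curves, 24)
  for (id in names(tpl$curves)) {
    expect_equal(back$curves[[id]]$vertices, tpl$curves[[id]]$vertices,
                 tolerance = 1e-6)
  }
})

test_that("thorax_template rejects incomplete curve sets", {
  tpl <- default_template()
  expect_error(thorax_template(tpl$curves[1:23]), "24")
  dup <- c(tpl$curves[1:23], tpl$curves[1])
  expect_error(thorax_template(unname(dup)), "24")
})
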