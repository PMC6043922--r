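test_that("one reference and one target give the nearest-distance step function", {
  w <- obs_window(1000, 1000)
  cells <- tibble::tibble(x = c(500, 510), y = c(500, 500),
                          ref = c(TRUE, FALSE), tgt = c(FALSE, TRUE))
  g <- gcross(cells, "ref", "tgt", w, r_max = 20, grid_points = 41,
              correction = "none")
  expect_equal(g$g, as.numeric(g$r >= 10))
  expect_true(attr(g, "defined"))
})

test_that("coincident distinct cells register at r = 0; self-pairs are excluded", {
  w <- obs_window(1000, 1000)
  both <- tibble::tibble(x = c(500, 500, 700), y = c(500, 500, 700),
                         ref = c(TRUE, TRUE, FALSE),
                         tgt = c(TRUE, TRUE, TRUE))
  g <- gcross(both, "ref", "tgt", w, r_max = 10, correction = "none")
  expect_equal(g$g, rep(1, nrow(g)))  # each ref has a coincident *other* target

  solo <- tibble::tibble(x = c(500, 650), y = c(500, 500),
                         ref = c(TRUE, FALSE), tgt = c(TRUE, TRUE))
  g2 <- gcross(solo, "ref", "tgt", w, r_max = 200, grid_points = 101,
               correction = "none")
  # the ref cell is its own nearest target; must use the other one at 150
  expect_equal(g2$g, as.numeric(g2$r >= 150))
})

test_that("an absent phenotype yields an undefined curve, not an error", {
  w <- obs_window(100, 100)
  cells <- tibble::tibble(x = 50, y = 50, ref = TRUE, tgt = FALSE)
  g <- gcross(cells, "ref", "tgt", w, r_max = 10)
  expect_false(attr(g, "defined"))
  expect_true(all(is.na(g$g)))
  expect_true(is.na(simple_auc(g)))
  expect_equal(kbins_auc(g, K = 4), rep(NA_real_, 4))
})

test_that("uncorrected estimator equals the brute-force all-pairs oracle", {
  for (seed in 1:25) {
    set.seed(seed)
    cells <- random_pattern(sample(2:120, 1), sample(2:120, 1), seed = seed)
    g <- gcross(cells, "ref", "tgt", r_max = 150, grid_points = 61,
                correction = "none")
    expect_equal(g$g, brute_force_g(cells, g$r), tolerance = 1e-12)
  }
})

test_that("curves are probabilities, non-decreasing, and geometry-invariant", {
  for (seed in 1:10) {
    cells <- random_pattern(40, 60, seed = seed)
    w <- attr(cells, "window")
    for (corr in c("none", "border", "km")) {
      g <- gcross(cells, "ref", "tgt", w, r_max = 120, correction = corr)
      expect_true(all(g$g >= 0 & g$g <= 1))
      expect_true(all(diff(g$g) >= -1e-12))

      # translation-invariance within the window is implied by coordinates
      # only entering through differences; check reflection and rotation
      refl <- cells; refl$x <- w$width - refl$x
      g_refl <- gcross(refl, "ref", "tgt", w, r_max = 120, correction = corr)
      expect_equal(g_refl$g, g$g, tolerance = 1e-12)

      rot <- cells
      rot$x <- cells$y; rot$y <- w$width - cells$x  # 90 degrees, window swapped
      g_rot <- gcross(rot, "ref", "tgt", obs_window(w$height, w$width),
                      r_max = 120, correction = corr)
      expect_equal(g_rot$g, g$g, tolerance = 1e-12)
    }
  }
})

test_that("border and km corrections agree with none on interior patterns", {
  w <- obs_window(1000, 800)
  set.seed(7)
  n <- 60; r_max <- 60
  cells <- tibble::tibble(
    x = runif(n, r_max, w$width - r_max),
    y = runif(n, r_max, w$height - r_max),
    ref = rep(c(TRUE, FALSE), c(25, 35)),
    tgt = rep(c(FALSE, TRUE), c(25, 35)))
  g0 <- gcross(cells, "ref", "tgt", w, r_max = r_max, correction = "none")
  for (corr in c("border", "km")) {
    g <- gcross(cells, "ref", "tgt", w, r_max = r_max, correction = corr)
    expect_equal(g$g, g0$g, tolerance = 1e-12)
  }
})

test_that("km correction matches the survival-package product-limit oracle", {
  skip_if_not_installed("survival")
  set.seed(42)
  cells <- random_pattern(50, 50, window = obs_window(300, 300), seed = 42)
  w <- attr(cells, "window")
  g <- gcross(cells, "ref", "tgt", w, r_max = 100, grid_points = 51,
              correction = "km")
  # oracle: nearest distances + border censoring through survfit
  ref <- which(cells$ref); tgt <- which(cells$tgt)
  d <- vapply(ref, function(i) {
    js <- setdiff(tgt, i)
    min(sqrt((cells$x[i] - cells$x[js])^2 + (cells$y[i] - cells$y[js])^2))
  }, numeric(1))
  b <- pmin(cells$x[ref], w$width - cells$x[ref],
            cells$y[ref], w$height - cells$y[ref])
  fit <- survival::survfit(
    survival::Surv(pmin(d, b), d <= b) ~ 1, conf.type = "none")
  s <- summary(fit, times = g$r, extend = TRUE)$surv
  expect_equal(g$g, cummax(1 - s), tolerance = 1e-10)
})

test_that("estimates agree with an independent spatstat implementation", {
  skip_if_not_installed("spatstat.explore")
  set.seed(9)
  cells <- random_pattern(80, 120, window = obs_window(400, 300), seed = 9)
  w <- attr(cells, "window")
  pp <- spatstat.geom::ppp(
    x = c(cells$x[cells$ref], cells$x[cells$tgt]),
    y = c(cells$y[cells$ref], cells$y[cells$tgt]),
    window = spatstat.geom::owin(c(0, w$width), c(0, w$height)),
    marks = factor(rep(c("A", "B"), c(80, 120))))
  rr <- seq(0, 80, length.out = 81)
  gs <- spatstat.explore::Gcross(pp, "A", "B", r = rr,
                                 correction = c("none", "km"))
  g_none <- gcross(cells, "ref", "tgt", w, r_max = 80, grid_points = 81,
                   correction = "none")
  g_km <- gcross(cells, "ref", "tgt", w, r_max = 80, grid_points = 81,
                 correction = "km")
  expect_equal(g_none$g, gs$raw, tolerance = 1e-10)
  # spatstat bins censored times onto the r grid before its product-limit
  # step, so its KM curve agrees only up to the grid discretisation
  expect_lt(max(abs(g_km$g - cummax(gs$km))), 0.01)
})

test_that("tidy curve export carries curve metadata", {
  cells <- random_pattern(10, 10, seed = 3)
  g <- gcross(cells, "ref", "tgt", r_max = 50)
  tab <- gcurve_table(list(g, g), image_id = c("a", "b"))
  expect_equal(nrow(tab), 2 * nrow(g))
  expect_equal(unique(tab$correction), "km")
  expect_equal(unique(tab$image_id), c("a", "b"))
})
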