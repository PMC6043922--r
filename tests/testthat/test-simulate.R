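test_that("identical seeds reproduce identical patterns; seeds differ otherwise", {
  w <- obs_window(600, 500)
  p <- image_params(n_clusters = 3, cells_per_cluster = 15)
  a <- simulate_image(p, w, seed = 42)
  b <- simulate_image(p, w, seed = 42)
  c <- simulate_image(p, w, seed = 43)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(isTRUE(all.equal(as.data.frame(a), as.data.frame(c))))
  expect_true(all(a$x >= 0 & a$x <= w$width & a$y >= 0 & a$y <= w$height))
})

test_that("simulated marker hierarchy satisfies the phenotype containments", {
  w <- obs_window(600, 500)
  for (s in 1:5) {
    ci <- simulate_image(image_params(), w, seed = s)
    expect_true(all(ci$Epithelial[ci$EpithelialPDL1]))
    expect_true(all(ci$Tcell[ci$CytotoxicT]))
    expect_true(all(ci$Tcell[ci$AntigenExperiencedT]))
    expect_true(all(ci$Macrophage[ci$MacrophagePDL1]))
    # one kind per cell in this generator
    expect_false(any(ci$Epithelial & (ci$Tcell | ci$Macrophage)))
  }
})

test_that("immune counts follow their Poisson intensity", {
  w <- obs_window(500, 400)
  lam <- 4e-4
  p <- image_params(n_clusters = 2, cells_per_cluster = 10,
                    immune = default_immune(lambda_t = lam, lambda_mac = 0))
  n_imgs <- 200
  counts <- vapply(seq_len(n_imgs), function(s) {
    sum(simulate_image(p, w, seed = s)$Tcell)
  }, numeric(1))
  mu <- lam * w$area
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / n_imgs))
})

test_that("theta = 0 immune cells are spatially random with respect to epithelium", {
  # CSR oracle: mean uncorrected G over many images matches 1 - exp(-l*pi*r^2)
  w <- obs_window(600, 600)
  lam <- 3e-4
  p <- image_params(n_clusters = 3, cells_per_cluster = 25, cluster_sd = 30,
                    immune = default_immune(lambda_t = lam, lambda_mac = 0,
                                            theta_t = 0))
  r_half <- sqrt(log(2) / (lam * pi))  # theoretical G = 0.5
  n_imgs <- 60
  gbar <- mean(vapply(seq_len(n_imgs), function(s) {
    ci <- simulate_image(p, w, seed = 100 + s)
    # interior epithelial references avoid edge bias in the raw estimator
    inner <- ci$x > 2 * r_half & ci$x < w$width - 2 * r_half &
      ci$y > 2 * r_half & ci$y < w$height - 2 * r_half
    ci$RefInt <- ci$Epithelial & inner
    g <- gcross(ci, "RefInt", "Tcell", w, r_max = 2 * r_half,
                grid_points = 201, correction = "none")
    approx(g$r, g$g, xout = r_half)$y
  }, numeric(1)))
  expect_lt(abs(gbar - 0.5), 0.03)
})

test_that("theta = 1 with small tau puts immune cells next to epithelium", {
  w <- obs_window(600, 500)
  p <- image_params(immune = default_immune(lambda_t = 2e-4, lambda_mac = 0,
                                            theta_t = 1, tau = 5))
  ci <- simulate_image(p, w, seed = 77)
  ref <- which(ci$Tcell)
  epi <- which(ci$Epithelial)
  d <- vapply(ref, function(i) {
    min(sqrt((ci$x[i] - ci$x[epi])^2 + (ci$y[i] - ci$y[epi])^2))
  }, numeric(1))
  expect_lte(median(d), 10)
})

test_that("cohort structure follows the patient/region plan deterministically", {
  cfg <- cohort_config(n_patients = 29, n_mixed = 17, images_per_region = 5,
                       params_low = image_params(n_clusters = 1,
                                                 cells_per_cluster = 3),
                       params_high = image_params(n_clusters = 1,
                                                  cells_per_cluster = 3),
                       seed = 2)
  cells <- simulate_cohort(cfg)
  truth <- attr(cells, "truth")
  expect_equal(nrow(truth), 29 * 5 + 17 * 5)  # 230 images
  expect_equal(sum(truth$region_grade == "high"), 17 * 5)
  expect_equal(length(unique(truth$patient_id)), 29)
  expect_equal(sum(truth$patient_mixed & truth$region_grade == "low"), 17 * 5)
  # progression task keeps low-grade images only
  lab <- task_labels(truth, "progression")
  expect_true(all(lab$region_grade == "low"))
  expect_equal(sum(lab$label), 17 * 5)

  # same seed: identical cells; different seed: same plan, new coordinates
  cells2 <- simulate_cohort(cfg)
  expect_identical(as.data.frame(cells2), as.data.frame(cells))
  cfg3 <- cohort_config(n_patients = 29, n_mixed = 17, images_per_region = 5,
                        params_low = cfg$params_low,
                        params_high = cfg$params_high, seed = 3)
  cells3 <- simulate_cohort(cfg3)
  expect_identical(attr(cells3, "truth")$image_id, truth$image_id)
  expect_false(identical(cells3$x, cells$x))
  expect_error(cohort_config(n_patients = 3), "at least 4")
})

test_that("benchmark cohorts expose their design and emit the io dialect", {
  bm <- make_benchmark("null", n_patients = 5, n_mixed = 2,
                       images_per_region = 1, seed = 1)
  expect_equal(bm$expected$auc_range, c(0.35, 0.65))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cell_table(bm$cells, f)
  back <- read_cell_table(f)
  expect_equal(nrow(back), nrow(bm$cells))
  expect_equal(back$CytotoxicT, bm$cells$CytotoxicT)
})
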