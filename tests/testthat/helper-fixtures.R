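# shared fixture builders (all data generated in code)

random_marker_table <- function(n, seed = 1, p = 0.4) {
  set.seed(seed)
  out <- as.data.frame(matrix(runif(n * 6) < p, n, 6))
  names(out) <- markers()
  out
}

# bare point pattern with two logical mark columns, uniform in a window
random_pattern <- function(n_ref, n_tgt, window = obs_window(500, 400),
                           seed = 1) {
  set.seed(seed)
  n <- n_ref + n_tgt
  cells <- tibble::tibble(
    x = runif(n, 0, window$width),
    y = runif(n, 0, window$height),
    ref = rep(c(TRUE, FALSE), c(n_ref, n_tgt)),
    tgt = rep(c(FALSE, TRUE), c(n_ref, n_tgt))
  )
  attr(cells, "window") <- window
  cells
}

# all-pairs brute-force G-cross with no correction (independent oracle)
brute_force_g <- function(cells, r_grid) {
  ref <- which(cells$ref); tgt <- which(cells$tgt)
  d <- vapply(ref, function(i) {
    js <- setdiff(tgt, i)
    if (!length(js)) return(Inf)
    min(sqrt((cells$x[i] - cells$x[js])^2 + (cells$y[i] - cells$y[js])^2))
  }, numeric(1))
  vapply(r_grid, function(r) mean(d <= r), numeric(1))
}

# piecewise-linear curve wrapped as a g_curve for the AUC summaries
fake_curve <- function(r, g, defined = TRUE) {
  structure(tibble::tibble(r = r, g = g),
            class = c("g_curve", class(tibble::tibble())),
            defined = defined, correction = "none",
            n_reference = NA_integer_, n_target = NA_integer_)
}

# random monotone non-decreasing curve on [0, r_max] in [0, 1]
random_monotone_curve <- function(r_max = 32, n = 81) {
  inc <- c(0, cumsum(runif(n - 1)))
  g <- inc / max(inc[n], 1e-12) * runif(1)
  fake_curve(seq(0, r_max, length.out = n), pmin(g, 1))
}

# small cohort that runs the classifier quickly in unit tests
tiny_cohort <- function(seed = 1, sep = TRUE) {
  w <- obs_window(700, 500)
  im <- function(theta) image_params(
    n_clusters = 3, cells_per_cluster = 18, cluster_sd = 30,
    immune = default_immune(lambda_t = 2.5e-4, lambda_mac = 1.2e-4,
                            theta_t = theta, tau = 10))
  cfg <- cohort_config(n_patients = 8, n_mixed = 4, images_per_region = 2,
                       window = w, params_low = im(if (sep) 0.1 else 0.5),
                       params_high = im(if (sep) 0.9 else 0.5), seed = seed)
  simulate_cohort(cfg)
}

expect_no_mask <- function(features) {
  expect_false(any(attr(features, "mask")))
}
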