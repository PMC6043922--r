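#' Image-level simulation parameters
#'
#' Describes the cell populations of one simulated image. Epithelial cells
#' follow a Thomas-type cluster process (cluster centres uniform in the
#' window, Poisson-distributed offspring counts, isotropic Gaussian
#' spread, offspring outside the window discarded), emulating ductal
#' epithelium growing in compact papillary clusters. Each immune
#' population is an attraction mixture: a cell is, with probability
#' `theta`, placed at an Exponential(`tau`) distance and uniform angle
#' from a uniformly chosen epithelial cell (redrawn until inside the
#' window), and otherwise uniform in the window. `theta` therefore
#' directly controls the infiltration the G-cross function measures, and
#' `tau` its spatial scale.
#'
#' @param n_clusters Epithelial cluster centres per image.
#' @param cells_per_cluster Mean offspring per cluster (Poisson).
#' @param cluster_sd Isotropic Gaussian spread of a cluster (um).
#' @param p_pdl1_epi PD-L1 positivity probability of epithelial cells.
#' @param immune A tibble describing the immune populations, one row per
#'   population, with columns `kind` (`"tcell"` or `"macrophage"`),
#'   `lambda` (cells/um^2), `theta`, `tau` (um), and marker positivity
#'   probabilities `p_cd8`, `p_pd1` (T cells) and `p_pdl1` (macrophages).
#' @return A list of class `image_params`.
#' @export
image_params <- function(n_clusters = 5, cells_per_cluster = 35,
                         cluster_sd = 40, p_pdl1_epi = 0.25,
                         immune = default_immune()) {
  stopifnot(n_clusters >= 0, cells_per_cluster >= 0, cluster_sd > 0,
            p_pdl1_epi >= 0, p_pdl1_epi <= 1)
  immune <- as_tibble(immune)
  stopifnot(all(c("kind", "lambda", "theta", "tau") %in% names(immune)),
            all(immune$kind %in% c("tcell", "macrophage")),
            all(immune$lambda >= 0), all(immune$theta >= 0),
            all(immune$theta <= 1), all(immune$tau > 0))
  structure(list(n_clusters = n_clusters,
                 cells_per_cluster = cells_per_cluster,
                 cluster_sd = cluster_sd, p_pdl1_epi = p_pdl1_epi,
                 immune = immune),
            class = "image_params")
}

#' @rdname image_params
#' @param lambda_t,lambda_mac Immune intensities (cells/um^2) of the
#'   default two-population layout.
#' @param theta_t,theta_mac Infiltration fractions.
#' @param tau Attraction scale (um), shared by both populations.
#' @param p_cd8,p_pd1,p_pdl1_mac Marker positivity probabilities.
#' @export
default_immune <- function(lambda_t = 6e-5, lambda_mac = 3e-5,
                           theta_t = 0.5, theta_mac = 0.3, tau = 15,
                           p_cd8 = 0.35, p_pd1 = 0.25, p_pdl1_mac = 0.3) {
  tibble(
    kind = c("tcell", "macrophage"),
    lambda = c(lambda_t, lambda_mac),
    theta = c(theta_t, theta_mac),
    tau = c(tau, tau),
    p_cd8 = c(p_cd8, 0),
    p_pd1 = c(p_pd1, 0),
    p_pdl1 = c(0, p_pdl1_mac)
  )
}

#' Simulate the cells of one image
#'
#' @param params An [image_params()] object.
#' @param window Observation window.
#' @param seed Optional seed; identical seeds give identical patterns.
#' @return A cell tibble (x, y in um, logical marker columns, phenotype
#'   columns) with the window attached.
#' @export
simulate_image <- function(params, window = obs_window(), seed = NULL) {
  stopifnot(inherits(params, "image_params"))
  if (!is.null(seed)) set.seed(seed)
  # epithelial cluster process
  ncl <- params$n_clusters
  ex <- ey <- numeric(0)
  if (ncl > 0) {
    cx <- runif(ncl, 0, window$width)
    cy <- runif(ncl, 0, window$height)
    sizes <- rpois(ncl, params$cells_per_cluster)
    ex <- rep(cx, sizes) + rnorm(sum(sizes), 0, params$cluster_sd)
    ey <- rep(cy, sizes) + rnorm(sum(sizes), 0, params$cluster_sd)
    inside <- ex >= 0 & ex <= window$width & ey >= 0 & ey <= window$height
    ex <- ex[inside]; ey <- ey[inside]
  }
  n_epi <- length(ex)
  epi <- tibble(x = ex, y = ey,
                AE1AE3 = TRUE,
                PDL1 = runif(n_epi) < params$p_pdl1_epi,
                CD3 = FALSE, CD8 = FALSE, PD1 = FALSE, CD68 = FALSE)

  pops <- lapply(seq_len(nrow(params$immune)), function(i) {
    pop <- params$immune[i, ]
    m <- rpois(1, pop$lambda * window$area)
    if (m == 0) return(NULL)
    attracted <- runif(m) < pop$theta & n_epi > 0
    xs <- runif(m, 0, window$width)
    ys <- runif(m, 0, window$height)
    todo <- which(attracted)
    while (length(todo)) {
      anchor <- sample.int(n_epi, length(todo), replace = TRUE)
      dist <- rexp(length(todo), rate = 1 / pop$tau)
      ang <- runif(length(todo), 0, 2 * pi)
      xs[todo] <- ex[anchor] + dist * cos(ang)
      ys[todo] <- ey[anchor] + dist * sin(ang)
      todo <- todo[xs[todo] < 0 | xs[todo] > window$width |
                     ys[todo] < 0 | ys[todo] > window$height]
    }
    if (pop$kind == "tcell") {
      tibble(x = xs, y = ys, AE1AE3 = FALSE, PDL1 = FALSE, CD3 = TRUE,
             CD8 = runif(m) < pop$p_cd8, PD1 = runif(m) < pop$p_pd1,
             CD68 = FALSE)
    } else {
      tibble(x = xs, y = ys, AE1AE3 = FALSE,
             PDL1 = runif(m) < pop$p_pdl1, CD3 = FALSE, CD8 = FALSE,
             PD1 = FALSE, CD68 = TRUE)
    }
  })
  cells <- bind_rows(c(list(epi), pops))
  cells <- add_phenotypes(cells)
  attr(cells, "window") <- window
  cells
}

#' Cohort-level simulation configuration
#'
#' A cohort mimics the structure of a graded surgical series: every
#' patient contributes `images_per_region` images of a low-grade region,
#' and a fraction of patients ("mixed") additionally contribute
#' `images_per_region` images of a concurrent high-grade region. Low- and
#' high-grade regions (and, optionally, the low-grade regions of mixed
#' patients) can use different image parameters, which is how
#' class-dependent infiltration is planted.
#'
#' @param n_patients Number of patients (>= 4 so cross-validation sees
#'   both classes).
#' @param n_mixed Number of patients with a concurrent high-grade region.
#' @param images_per_region Images captured per graded region.
#' @param window Observation window shared by all images.
#' @param params_low Image parameters of low-grade regions.
#' @param params_high Image parameters of high-grade regions.
#' @param params_low_mixed Optional distinct parameters for the low-grade
#'   regions of mixed patients (defaults to `params_low`); used to plant
#'   progression-risk signal.
#' @param seed Master seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 29, n_mixed = 17,
                          images_per_region = 5, window = obs_window(),
                          params_low = image_params(),
                          params_high = image_params(),
                          params_low_mixed = NULL, seed = 1) {
  if (n_patients < 4) {
    abort("A cohort needs at least 4 patients for cross-validation.")
  }
  if (n_mixed < 1 || n_mixed >= n_patients) {
    abort("`n_mixed` must be in [1, n_patients - 1].")
  }
  stopifnot(images_per_region >= 1)
  structure(list(n_patients = n_patients, n_mixed = n_mixed,
                 images_per_region = images_per_region, window = window,
                 params_low = params_low, params_high = params_high,
                 params_low_mixed = params_low_mixed %||% params_low,
                 seed = seed),
            class = "cohort_config")
}

#' Simulate a cohort of marked point patterns
#'
#' Deterministic given the config seed: patients `P01 ... Pnn`, the first
#' `n_mixed` of them mixed, image ids `<patient>_<grade>_<i>`.
#'
#' @param config A [cohort_config()].
#' @return A phenotyped cell tibble covering all images (window attached),
#'   with attribute `"truth"`: a per-image tibble of `image_id`,
#'   `patient_id`, `region_grade`, `patient_mixed`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  pts <- sprintf("P%02d", seq_len(config$n_patients))
  mixed <- pts[seq_len(config$n_mixed)]
  plan <- bind_rows(
    tidyr::expand_grid(patient_id = pts, region_grade = "low",
                       i = seq_len(config$images_per_region)),
    tidyr::expand_grid(patient_id = mixed, region_grade = "high",
                       i = seq_len(config$images_per_region))
  )
  plan$image_id <- sprintf("%s_%s_%d", plan$patient_id, plan$region_grade,
                           plan$i)
  img_seeds <- sample.int(.Machine$integer.max - 1L, nrow(plan))

  cells <- bind_rows(lapply(seq_len(nrow(plan)), function(j) {
    p <- if (plan$region_grade[j] == "high") {
      config$params_high
    } else if (plan$patient_id[j] %in% mixed) {
      config$params_low_mixed
    } else {
      config$params_low
    }
    ci <- simulate_image(p, config$window, seed = img_seeds[j])
    ci$image_id <- plan$image_id[j]
    ci$patient_id <- plan$patient_id[j]
    ci$region_grade <- factor(plan$region_grade[j], levels = c("low", "high"))
    ci[c("image_id", "patient_id", "region_grade",
         setdiff(names(ci), c("image_id", "patient_id", "region_grade")))]
  }))
  attr(cells, "window") <- config$window
  attr(cells, "truth") <- tibble(
    image_id = plan$image_id, patient_id = plan$patient_id,
    region_grade = factor(plan$region_grade, levels = c("low", "high")),
    patient_mixed = plan$patient_id %in% mixed)
  cells
}

#' Benchmark cohorts with known expected outcome
#'
#' Three stock cohorts for validating the pipeline end to end:
#' \describe{
#'   \item{`separable`}{high-grade regions have strong T-cell attraction
#'     to epithelium (`theta` 0.8 vs 0.2) and moderately higher T-cell
#'     intensity, so grade classification should reach AUC >= 0.9;}
#'   \item{`null`}{identical parameters for both grades, so any grade
#'     classifier should sit near AUC 0.5;}
#'   \item{`planted`}{class signal confined (as far as the construction
#'     allows) to the Epithelial -> Tcell interaction: only the CD8- PD-1-
#'     T-cell subpopulation changes its attraction between grades, while
#'     cytotoxic and antigen-experienced T cells and macrophages keep
#'     identical spatial behaviour and all intensities are
#'     class-independent, so that interaction should rank first in the
#'     importance table.}
#' }
#'
#' @param difficulty `"separable"`, `"null"` or `"planted"`.
#' @param n_patients,n_mixed,images_per_region Cohort structure.
#' @param seed Master seed.
#' @return A list: `cells` (the simulated cohort), `config`, and
#'   `expected` (a short description of the expected outcome).
#' @export
make_benchmark <- function(difficulty = c("separable", "null", "planted"),
                           n_patients = 29, n_mixed = 17,
                           images_per_region = 5, seed = 1) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "separable") {
    low <- image_params(immune = default_immune(theta_t = 0.2))
    high <- image_params(immune = default_immune(theta_t = 0.8,
                                                 lambda_t = 7.8e-5))
    expected <- list(task = "grade", auc_min = 0.9)
  } else if (difficulty == "null") {
    low <- image_params()
    high <- image_params()
    expected <- list(task = "grade", auc_range = c(0.35, 0.65))
  } else {
    # signal only in the plain (CD8- PD-1-) T-cell attraction; PD-L1
    # positivity kept rare so the PD-L1+ reference subsets, which share
    # their targets with the parent phenotypes, carry little information
    split_t <- function(theta_plain) tibble(
      kind = c("tcell", "tcell", "tcell", "macrophage"),
      lambda = c(3e-5, 1.5e-5, 1.5e-5, 3e-5),
      theta = c(theta_plain, 0.3, 0.3, 0.3),
      tau = 15,
      p_cd8 = c(0, 1, 0, 0),
      p_pd1 = c(0, 0, 1, 0),
      p_pdl1 = c(0, 0, 0, 0.05)
    )
    low <- image_params(immune = split_t(0.1), p_pdl1_epi = 0.05)
    high <- image_params(immune = split_t(0.85), p_pdl1_epi = 0.05)
    expected <- list(task = "grade", top_interaction = "Epithelial_Tcell")
  }
  config <- cohort_config(n_patients = n_patients, n_mixed = n_mixed,
                          images_per_region = images_per_region,
                          params_low = low, params_high = high, seed = seed)
  list(cells = simulate_cohort(config), config = config,
       expected = expected, difficulty = difficulty)
}
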