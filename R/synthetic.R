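# Synthetic-data generators with planted ground truth. Every generator is a
# pure function of its configuration and seed (the caller's RNG state is
# restored), and each dataset is accompanied by a truth table so downstream
# tests read truth only from there.

#' Canonical solubility-class archetype trajectories
#'
#' Median P_index trajectories for the five canonical classes over the
#' default germination grid (0h, 1h, 3h, 6h, vegetative). These are design
#' values that emulate the published trajectory shapes and satisfy the
#' class-labeling rules with margin.
#'
#' @param time_points time axis labels (length 5 by default).
#' @return matrix (5 classes x time points) with class labels as row names.
#' @export
solubility_archetypes <- function(time_points = c("0h", "1h", "3h", "6h", "veg")) {
  arch <- rbind(
    mostly_pellet            = c(0.85, 0.85, 0.85, 0.85, 0.85),
    mostly_supernatant       = c(0.15, 0.15, 0.15, 0.15, 0.15),
    transient_solubilization = c(0.80, 0.20, 0.70, 0.80, 0.80),
    gradual_desolubilization = c(0.20, 0.35, 0.50, 0.65, 0.80),
    gradual_solubilization   = c(0.80, 0.65, 0.50, 0.35, 0.20)
  )
  if (length(time_points) != ncol(arch))
    stopf("archetypes are defined over %d time points", ncol(arch),
          class = "solubilome_domain_error")
  colnames(arch) <- time_points
  arch
}

#' Default class counts matching the published proportions
#'
#' 359 mostly supernatant, 425 mostly in pellet, 15 transient
#' solubilization, 17 gradual desolubilization, 79 gradual solubilization:
#' 895 proteins in total, of which 111 change class.
#'
#' @return named integer vector.
#' @export
default_class_counts <- function() {
  c(mostly_pellet = 425L, mostly_supernatant = 359L,
    transient_solubilization = 15L, gradual_desolubilization = 17L,
    gradual_solubilization = 79L)
}

#' Generate a synthetic fractionation dataset with planted classes
#'
#' For each protein, the per-replicate per-time true P_index is its class
#' archetype plus Gaussian noise, clipped to \[0.01, 0.99\]. Total abundance
#' is drawn log-normal per protein (times a mild per-measurement log-normal
#' jitter) and split as `pellet = total * P`,
#' `supernatant = total * (1 - P)`. Coverage and peptide counts are drawn
#' to pass the detection filters, except for optional spiked proteins
#' designed to fail each filter (`n_fail_coverage`, `n_fail_peptides`
#' proteins with sub-threshold coverage/peptides, and `n_fail_incomplete`
#' proteins with one zeroed time x replicate total).
#'
#' @param class_counts named integer vector of proteins per class (names
#'   must match [solubility_archetypes()] rows); default
#'   [default_class_counts()].
#' @param time_points time axis labels.
#' @param n_replicates biological replicates (default 3).
#' @param noise_sd Gaussian noise on P_index, in \[0, 0.2\] (default 0.05).
#' @param abundance_meanlog,abundance_sdlog log-normal parameters of the
#'   per-protein total abundance (defaults emulate iBAQ magnitudes).
#' @param n_fail_coverage,n_fail_peptides,n_fail_incomplete spiked
#'   filter-failure proteins (defaults 0).
#' @param seed RNG seed (required for reproducibility).
#' @return list with `table` (a `fraction_quant_table`) and `truth`
#'   (data.table `protein_id`, `truth_class`, `truth_filter_fate`).
#' @export
gen_solubility_dataset <- function(class_counts = default_class_counts(),
                                   time_points = c("0h", "1h", "3h", "6h", "veg"),
                                   n_replicates = 3L, noise_sd = 0.05,
                                   abundance_meanlog = log(1e6),
                                   abundance_sdlog = 1.5,
                                   n_fail_coverage = 0L, n_fail_peptides = 0L,
                                   n_fail_incomplete = 0L, seed = 1L) {
  arch <- solubility_archetypes(time_points)
  unknown <- setdiff(names(class_counts), rownames(arch))
  if (length(unknown) > 0)
    stopf("unknown class(es): %s", paste(unknown, collapse = ", "),
          class = "solubilome_domain_error")
  if (any(class_counts < 0) || sum(class_counts) == 0)
    stopf("class counts must be non-negative and sum to > 0",
          class = "solubilome_domain_error")
  if (noise_sd < 0 || noise_sd > 0.2)
    stopf("noise_sd must lie in [0, 0.2]", class = "solubilome_domain_error")
  with_seed(seed, {
    nt <- length(time_points)
    classes <- rep(names(class_counts), class_counts)
    n_pass <- length(classes)
    n_extra <- n_fail_coverage + n_fail_peptides + n_fail_incomplete
    fate <- c(rep("pass", n_pass),
              rep("low_coverage", n_fail_coverage),
              rep("few_peptides", n_fail_peptides),
              rep("incomplete_series", n_fail_incomplete))
    classes <- c(classes, sample(names(class_counts), n_extra, replace = TRUE))
    n <- n_pass + n_extra
    ids <- sprintf("P%04d", seq_len(n))

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      meanlog_i <- rnorm(1, abundance_meanlog, abundance_sdlog)
      p_true <- matrix(pmin(pmax(
        arch[classes[i], ] + rnorm(nt * n_replicates, 0, noise_sd),
        0.01), 0.99), nrow = nt)
      total <- exp(meanlog_i + rnorm(nt * n_replicates, 0, 0.1))
      total <- matrix(total, nrow = nt)
      coverage <- if (fate[i] == "low_coverage") runif(1, 0.0, 0.08)
                  else runif(1, 0.15, 0.9)
      npep <- if (fate[i] == "few_peptides") 1L else 2L + rpois(1, 5)
      if (fate[i] == "incomplete_series") {
        drop_t <- sample(nt, 1); drop_r <- sample(n_replicates, 1)
        total[drop_t, drop_r] <- 0
      }
      grid <- expand.grid(time_point = time_points, replicate = seq_len(n_replicates),
                          stringsAsFactors = FALSE)
      rows[[i]] <- data.table::data.table(
        protein_id = ids[i],
        time_point = rep(grid$time_point, 2),
        replicate = rep(grid$replicate, 2),
        fraction = rep(c("pellet", "supernatant"), each = nrow(grid)),
        abundance = c(as.vector(total) * as.vector(p_true),
                      as.vector(total) * (1 - as.vector(p_true))),
        n_peptides = npep,
        coverage = coverage
      )
    }
    table <- data.table::rbindlist(rows)
    table[, time_point := factor(time_point, levels = time_points, ordered = TRUE)]
    data.table::setattr(table, "class",
                        c("fraction_quant_table", class(table)))
    truth <- data.table::data.table(protein_id = ids, truth_class = classes,
                                    truth_filter_fate = fate)
    list(table = table[], truth = truth)
  })
}

#' Generate 2-D Brownian particle tracks
#'
#' Per-axis increments are i.i.d. Gaussian with variance `2 D dt`
#' (`dt = 1/fps`), so the true ensemble MSD is `4 D tau`. Optional additive
#' localization noise (per-coordinate standard deviation `loc_noise`
#' microns, applied to each observed position) raises the measured curve by
#' a constant `4 * loc_noise^2`.
#'
#' @param D diffusion coefficient (um^2/s, >= 0).
#' @param n_particles,n_frames ensemble size and track length.
#' @param fps frames per second (default 2).
#' @param loc_noise localization noise sd per coordinate (um, default 0).
#' @param seed RNG seed.
#' @return data.frame `particle`, `frame`, `x_um`, `y_um`, `t_s` with
#'   `fps` attribute.
#' @export
gen_brownian_tracks <- function(D, n_particles, n_frames, fps = 2,
                                loc_noise = 0, seed = 1L) {
  if (D < 0) stopf("D must be >= 0", class = "solubilome_domain_error")
  with_seed(seed, {
    dt <- 1 / fps
    step_sd <- sqrt(2 * D * dt)
    out <- lapply(seq_len(n_particles), function(p) {
      x <- cumsum(c(runif(1, 0, 10), rnorm(n_frames - 1, 0, step_sd)))
      y <- cumsum(c(runif(1, 0, 10), rnorm(n_frames - 1, 0, step_sd)))
      if (loc_noise > 0) {
        x <- x + rnorm(n_frames, 0, loc_noise)
        y <- y + rnorm(n_frames, 0, loc_noise)
      }
      data.frame(particle = p, frame = seq_len(n_frames) - 1L,
                 x_um = x, y_um = y, t_s = (seq_len(n_frames) - 1L) * dt)
    })
    res <- do.call(rbind, out)
    attr(res, "fps") <- fps
    res
  })
}

#' Generate ratiometric pH calibration and per-cell cytometry data
#'
#' Calibration medians follow a four-parameter logistic in pH with
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`;
#' per-cell ratios at each planted true pH carry cv `cell_cv`.
#'
#' @param params list with `lower`, `upper`, `midpoint`, `slope`
#'   (`upper > lower`).
#' @param ph_grid calibration buffer pH values (default 5.0-9.0 by 0.5).
#' @param noise_cv multiplicative noise on calibration medians (default 0).
#' @param sample_ph named or unnamed vector of planted true pH values.
#' @param n_cells cells per sample (default 2000).
#' @param cell_cv multiplicative noise on per-cell ratios (default 0.05).
#' @param seed RNG seed.
#' @return list with `calibration` (data.frame `ph`, `ratio`) and `cells`
#'   (named list of per-cell ratio vectors, one per entry of `sample_ph`).
#' @export
gen_ph_calibration_data <- function(params = list(lower = 0.2, upper = 1.4,
                                                  midpoint = 7.0, slope = 1.1),
                                    ph_grid = seq(5, 9, by = 0.5),
                                    noise_cv = 0, sample_ph = numeric(0),
                                    n_cells = 2000L, cell_cv = 0.05,
                                    seed = 1L) {
  if (params$upper <= params$lower)
    stopf("upper asymptote must exceed lower", class = "solubilome_domain_error")
  with_seed(seed, {
    truth <- .fpl(ph_grid, params$lower, params$upper, params$midpoint, params$slope)
    ratio <- truth * (1 + rnorm(length(truth), 0, noise_cv))
    cells <- lapply(sample_ph, function(ph) {
      r <- .fpl(ph, params$lower, params$upper, params$midpoint, params$slope)
      r * (1 + rnorm(n_cells, 0, cell_cv))
    })
    names(cells) <- names(sample_ph) %||% as.character(sample_ph)
    list(calibration = data.frame(ph = ph_grid, ratio = ratio), cells = cells)
  })
}

#' Generate paired treated/untreated logistic growth curves
#'
#' The untreated culture follows logistic growth
#' `od(t) = K / (1 + ((K - N0) / N0) exp(-r t))`; heat treatment scales the
#' initial population by `1 - kill_fraction` and delays the curve by
#' `lag_delta` hours. Gaussian read noise is added to both.
#'
#' @param K carrying capacity (OD units, > 0).
#' @param r growth rate (per hour, > 0).
#' @param n0 untreated initial population (OD units).
#' @param lag_delta treatment-induced lag (hours, >= 0).
#' @param kill_fraction fraction of the population killed by treatment, in
#'   \[0, 1\].
#' @param noise_sd read noise sd (OD units, default 0).
#' @param times sampling grid in hours.
#' @param seed RNG seed.
#' @return list with `untreated` and `treated` data.frames
#'   (`time_h`, `od`).
#' @export
gen_growth_curves <- function(K = 1.0, r = 0.8, n0 = 0.01, lag_delta = 0,
                              kill_fraction = 0, noise_sd = 0,
                              times = seq(0, 24, by = 0.25), seed = 1L) {
  if (K <= 0 || r <= 0) stopf("K and r must be > 0", class = "solubilome_domain_error")
  if (kill_fraction < 0 || kill_fraction > 1)
    stopf("kill_fraction must lie in [0, 1]", class = "solubilome_domain_error")
  logistic <- function(t, n_init) {
    if (n_init <= 0) return(rep(0, length(t)))
    K / (1 + ((K - n_init) / n_init) * exp(-r * t))
  }
  with_seed(seed, {
    od_un <- logistic(times, n0)
    od_tr <- logistic(pmax(times - lag_delta, 0), n0 * (1 - kill_fraction))
    if (noise_sd > 0) {
      od_un <- pmax(od_un + rnorm(length(times), 0, noise_sd), 0)
      od_tr <- pmax(od_tr + rnorm(length(times), 0, noise_sd), 0)
    }
    list(untreated = data.frame(time_h = times, od = od_un),
         treated = data.frame(time_h = times, od = od_tr))
  })
}

#' Render a synthetic cell image with foci or diffuse signal
#'
#' A disk-shaped cell mask filled with diffuse signal plus `n_foci`
#' Gaussian foci at random interior positions, on a constant background,
#' with optional Poisson-like noise (Gaussian with variance proportional to
#' the signal). The total integrated signal inside the mask is reported so
#' foci/diffuse image pairs can be intensity-matched.
#'
#' @param shape image dimensions `c(ny, nx)` (default 64 x 64).
#' @param n_foci number of Gaussian foci (default 0).
#' @param focus_amplitude peak amplitude of each focus.
#' @param focus_sigma focus width in pixels (default 1.5).
#' @param diffuse_amplitude uniform signal inside the mask.
#' @param background constant background outside and inside the cell.
#' @param noise Poisson-like noise scale (0 = noise-free).
#' @param cell_radius mask radius in pixels (default 40% of the smaller
#'   dimension).
#' @param seed RNG seed.
#' @return list with `image` (matrix), `mask` (logical matrix),
#'   `total_signal` (sum of image minus background inside the mask).
#' @export
gen_cell_image <- function(shape = c(64L, 64L), n_foci = 0L,
                           focus_amplitude = 0, focus_sigma = 1.5,
                           diffuse_amplitude = 0, background = 0,
                           noise = 0, cell_radius = NULL, seed = 1L) {
  if (focus_amplitude < 0 || diffuse_amplitude < 0 || background < 0)
    stopf("amplitudes must be >= 0", class = "solubilome_domain_error")
  ny <- shape[1]; nx <- shape[2]
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  cell_radius <- cell_radius %||% (0.4 * min(ny, nx))
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  mask <- (yy - cy)^2 + (xx - cx)^2 <= cell_radius^2
  with_seed(seed, {
    img <- matrix(background, ny, nx)
    img[mask] <- img[mask] + diffuse_amplitude
    if (n_foci > 0) {
      inner <- which(((yy - cy)^2 + (xx - cx)^2) <= (0.7 * cell_radius)^2)
      pos <- sample(inner, n_foci)
      for (p in pos) {
        py <- yy[p]; px <- xx[p]
        img <- img + focus_amplitude *
          exp(-(((yy - py)^2 + (xx - px)^2) / (2 * focus_sigma^2))) *
          mask
      }
    }
    if (noise > 0)
      img <- pmax(img + rnorm(length(img), 0, noise * sqrt(pmax(img, 0))), 0)
    list(image = img, mask = mask,
         total_signal = sum(img[mask] - background))
  })
}
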