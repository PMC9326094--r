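#' Scene specification for a synthetic cytospin field
#'
#' Describes one simulated three-channel 20x-like field: DAPI nuclei
#' (ellipses), MPO-positive neutrophils (cytoplasmic annuli around their
#' nuclei), filamentous NETs (smoothed random-walk curves painted
#' identically in the MPO and Cit-H3 channels, modelling the
#' double-positive definition) and "primed" neutrophils (nuclear Cit-H3).
#' Painted masks are recorded as ground truth before the Gaussian PSF blur
#' and additive Gaussian noise are applied.
#'
#' Defaults are a scaled-down field (256 px square) with signal 200 over
#' background 10, noise sigma 8 and PSF sigma 0.75 px — a combination
#' calibrated so that Otsu thresholds recover the painted masks to within
#' 5% area error (thin filaments are the binding constraint: a stronger
#' blur widens their above-threshold contour).
#'
#' @param field_size_px square field edge, pixels.
#' @param n_cells number of nuclei.
#' @param n_neutrophils number of MPO-positive cells, <= `n_cells`.
#' @param n_nets_filaments number of NET filaments.
#' @param n_primed_neutrophils neutrophils with nuclear Cit-H3, <=
#'   `n_neutrophils`.
#' @param filament_length_px,filament_width_px,nucleus_radius_px
#'   `c(min, max)` ranges in pixels.
#' @param background_level,signal_level channel background and painted
#'   intensity.
#' @param noise_sigma additive Gaussian noise sd.
#' @param psf_sigma_px Gaussian point-spread sigma (0 disables blur).
#' @param seed integer seed; a fixed seed makes the generated field
#'   identical across calls.
#' @return An object of class `image_scene_spec`.
#' @export
image_scene_spec <- function(field_size_px = 256L,
                             n_cells = 30L,
                             n_neutrophils = 12L,
                             n_nets_filaments = 3L,
                             n_primed_neutrophils = 2L,
                             filament_length_px = c(40, 120),
                             filament_width_px = c(3, 4),
                             nucleus_radius_px = c(4, 7),
                             background_level = 10,
                             signal_level = 200,
                             noise_sigma = 8,
                             psf_sigma_px = 0.75,
                             seed = NULL) {
  if (n_neutrophils > n_cells) {
    stop("n_neutrophils must be <= n_cells", call. = FALSE)
  }
  if (n_primed_neutrophils > n_neutrophils) {
    stop("n_primed_neutrophils must be <= n_neutrophils", call. = FALSE)
  }
  if (min(n_cells, n_neutrophils, n_nets_filaments,
          n_primed_neutrophils) < 0) {
    stop("object counts must be non-negative", call. = FALSE)
  }
  structure(list(
    field_size_px = as.integer(field_size_px),
    n_cells = as.integer(n_cells),
    n_neutrophils = as.integer(n_neutrophils),
    n_nets_filaments = as.integer(n_nets_filaments),
    n_primed_neutrophils = as.integer(n_primed_neutrophils),
    filament_length_px = filament_length_px,
    filament_width_px = filament_width_px,
    nucleus_radius_px = nucleus_radius_px,
    background_level = background_level,
    signal_level = signal_level,
    noise_sigma = noise_sigma,
    psf_sigma_px = psf_sigma_px,
    seed = seed
  ), class = "image_scene_spec")
}

# separable Gaussian blur with edge replication
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- ceiling(3 * sigma)
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  blur1 <- function(m) {
    # convolve along rows (over row index), edge-replicated
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) {
      off <- i - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[i] * m[idx, , drop = FALSE]
    }
    out
  }
  t(blur1(t(blur1(img))))
}

paint_ellipse <- function(size, cx, cy, a, b, theta) {
  r <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy - r)):min(size, ceiling(cy + r))
  cols <- max(1L, floor(cx - r)):min(size, ceiling(cx + r))
  dy <- outer(rows - cy, rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - cx)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  list(rows = rows, cols = cols, inside = inside)
}

#' Generate a ground-truthed synthetic field
#'
#' Paints the scene described by an [image_scene_spec()]: non-touching
#' nuclei (placement by rejection sampling; an error is raised after bounded
#' retries when too many non-touching objects are requested), MPO annuli
#' for the first `n_neutrophils` nuclei, NET filaments painted identically
#' into MPO and Cit-H3, and nuclear Cit-H3 for primed neutrophils.
#' Filaments keep clear of non-neutrophil nuclei so that noiseless fields
#' are recovered exactly by [quantify_field()]. The PSF blur and noise are
#' applied after the ground truth is recorded.
#'
#' @param spec an [image_scene_spec()].
#' @return List with `field` (a [fluorescence_field()]) and `truth`: a list
#'   with `true_cell_count`, `true_neutrophil_count`, `true_coloc_area_px`,
#'   `nucleus_labels` (integer matrix), `filament_mask`, and the painted
#'   per-channel masks `dapi_mask`, `mpo_mask`, `cith3_mask`.
#' @export
generate_field <- function(spec = image_scene_spec()) {
  stopifnot(inherits(spec, "image_scene_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  size <- spec$field_size_px
  annulus_w <- 3
  dilate_r <- 3
  rmax <- spec$nucleus_radius_px[2]
  margin <- rmax + annulus_w + 2
  min_gap <- 2 * (annulus_w + dilate_r) + 2

  # --- place nuclei (rejection sampling, bounded retries) -------------------
  n <- spec$n_cells
  cx <- cy <- ra <- rb <- th <- numeric(n)
  if (n > 0) {
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(2000L)) {
        x <- runif(1, margin, size - margin)
        y <- runif(1, margin, size - margin)
        a <- runif(1, spec$nucleus_radius_px[1], rmax)
        b <- runif(1, spec$nucleus_radius_px[1], rmax)
        if (i == 1L || all(sqrt((cx[seq_len(i - 1)] - x)^2 +
                                (cy[seq_len(i - 1)] - y)^2) >
                           max(a, b) + pmax(ra[seq_len(i - 1)],
                                            rb[seq_len(i - 1)]) + min_gap)) {
          cx[i] <- x; cy[i] <- y; ra[i] <- a; rb[i] <- b
          th[i] <- runif(1, 0, pi)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("infeasible placement: could not fit ", n,
             " non-touching nuclei in a ", size, "px field", call. = FALSE)
      }
    }
  }

  dapi_mask <- matrix(FALSE, size, size)
  mpo_mask <- matrix(FALSE, size, size)
  cith3_mask <- matrix(FALSE, size, size)
  labels <- matrix(0L, size, size)
  for (i in seq_len(n)) {
    e <- paint_ellipse(size, cx[i], cy[i], ra[i], rb[i], th[i])
    sub <- dapi_mask[e$rows, e$cols]
    dapi_mask[e$rows, e$cols] <- sub | e$inside
    lsub <- labels[e$rows, e$cols]
    lsub[e$inside] <- i
    labels[e$rows, e$cols] <- lsub
    if (i <= spec$n_neutrophils) {
      eo <- paint_ellipse(size, cx[i], cy[i], ra[i] + annulus_w,
                          rb[i] + annulus_w, th[i])
      ann <- mpo_mask[eo$rows, eo$cols] | eo$inside
      mpo_mask[eo$rows, eo$cols] <- ann
      # carve the nucleus interior back out: MPO is cytoplasmic
      mpo_mask[e$rows, e$cols] <- mpo_mask[e$rows, e$cols] & !e$inside
      if (i <= spec$n_primed_neutrophils) {
        cith3_mask[e$rows, e$cols] <- cith3_mask[e$rows, e$cols] | e$inside
      }
    }
  }

  # --- NET filaments --------------------------------------------------------
  # clearance zones around non-neutrophil nuclei: a filament crossing the
  # dilated footprint of a plain cell would turn it MPO-positive
  plain <- setdiff(seq_len(n), seq_len(spec$n_neutrophils))
  clear_r <- if (length(plain)) {
    pmax(ra[plain], rb[plain]) + dilate_r + 2
  } else {
    numeric(0)
  }
  filament_mask <- matrix(FALSE, size, size)
  if (spec$n_nets_filaments > 0) {
    for (f in seq_len(spec$n_nets_filaments)) {
      ok <- FALSE
      for (try in seq_len(200L)) {
        L <- runif(1, spec$filament_length_px[1], spec$filament_length_px[2])
        w <- runif(1, spec$filament_width_px[1], spec$filament_width_px[2])
        hw <- max(1L, round(w / 2))
        nstep <- max(2L, ceiling(L / 2))
        px <- runif(1, margin, size - margin)
        py <- runif(1, margin, size - margin)
        heading <- runif(1, 0, 2 * pi)
        xs <- numeric(nstep); ys <- numeric(nstep)
        good <- TRUE
        for (s in seq_len(nstep)) {
          xs[s] <- px; ys[s] <- py
          if (length(plain) &&
              any(sqrt((cx[plain] - px)^2 + (cy[plain] - py)^2) <
                  clear_r + hw)) { good <- FALSE; break }
          if (px < hw + 2 || px > size - hw - 1 ||
              py < hw + 2 || py > size - hw - 1) { good <- FALSE; break }
          heading <- heading + rnorm(1, 0, 0.3)
          px <- px + 2 * cos(heading)
          py <- py + 2 * sin(heading)
        }
        if (!good) next
        for (s in seq_len(nstep)) {
          rows <- max(1L, round(ys[s]) - hw):min(size, round(ys[s]) + hw)
          cols <- max(1L, round(xs[s]) - hw):min(size, round(xs[s]) + hw)
          dy <- outer(rows - ys[s], rep(1, length(cols)))
          dx <- outer(rep(1, length(rows)), cols - xs[s])
          disk <- dx^2 + dy^2 <= hw^2
          filament_mask[rows, cols] <- filament_mask[rows, cols] | disk
        }
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("infeasible placement: could not route NET filament ", f,
             call. = FALSE)
      }
    }
  }
  mpo_mask <- mpo_mask | filament_mask
  cith3_mask <- cith3_mask | filament_mask

  true_coloc <- mpo_mask & cith3_mask
  render <- function(mask) {
    img <- spec$background_level + spec$signal_level * mask
    img <- gaussian_blur(img, spec$psf_sigma_px)
    if (spec$noise_sigma > 0) {
      img <- img + matrix(rnorm(size * size, 0, spec$noise_sigma), size, size)
    }
    pmax(img, 0)
  }
  field <- fluorescence_field(
    dapi = render(dapi_mask), mpo = render(mpo_mask),
    cith3 = render(cith3_mask)
  )
  list(
    field = field,
    truth = list(
      true_cell_count = n,
      true_neutrophil_count = spec$n_neutrophils,
      true_coloc_area_px = sum(true_coloc),
      nucleus_labels = labels,
      filament_mask = filament_mask,
      dapi_mask = dapi_mask, mpo_mask = mpo_mask, cith3_mask = cith3_mask
    )
  )
}

round_half <- function(x) round(x * 2) / 2

#' Cohort simulation specification
#'
#' Describes a synthetic cohort with the enrolled-group structure of the
#' study (12 healthy / 7 moderate / 14 severe by default) and the stated
#' effect structure: cf DNA and MPO-DNA OD lognormal with the severe group
#' shifted up, NETs area/cell zero-inflated (near zero for healthy and
#' moderate, positive lognormal for severe), BALF neutrophil % drawn per
#' group within the enrollment ranges, and WCS a monotone noisy function of
#' severity and neutrophilia. Readout magnitudes are calibrated only to
#' ordering and significance, not to the unpublished per-horse values.
#'
#' @param group_sizes named integer vector
#'   `c(healthy = , moderate = , severe = )`.
#' @param effect_scale multiplies all group effects; 0 collapses every
#'   group onto the healthy distributions (null simulation).
#' @param cfdna_meanlog,mpo_meanlog named per-group log-means (ug/ml; OD).
#' @param cfdna_sdlog,mpo_sdlog lognormal sd on the log scale.
#' @param mpo_floor additive background OD.
#' @param nets_meanlog,nets_sdlog severe-group NETs area/cell (px^2/cell)
#'   lognormal parameters.
#' @param nets_baseline_max upper bound of the near-zero NETs baseline.
#' @param seed integer seed.
#' @return An object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(group_sizes = c(healthy = 12L, moderate = 7L,
                                            severe = 14L),
                            effect_scale = 1,
                            cfdna_meanlog = c(healthy = log(0.04),
                                              moderate = log(0.06),
                                              severe = log(0.20)),
                            cfdna_sdlog = 0.5,
                            mpo_meanlog = c(healthy = log(0.05),
                                            moderate = log(0.07),
                                            severe = log(0.55)),
                            mpo_sdlog = 0.4,
                            mpo_floor = 0.08,
                            nets_meanlog = log(8),
                            nets_sdlog = 0.6,
                            nets_baseline_max = 0.3,
                            seed = NULL) {
  stopifnot(all(c("healthy", "moderate", "severe") %in% names(group_sizes)))
  if (any(group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  structure(list(
    group_sizes = group_sizes, effect_scale = effect_scale,
    cfdna_meanlog = cfdna_meanlog, cfdna_sdlog = cfdna_sdlog,
    mpo_meanlog = mpo_meanlog, mpo_sdlog = mpo_sdlog, mpo_floor = mpo_floor,
    nets_meanlog = nets_meanlog, nets_sdlog = nets_sdlog,
    nets_baseline_max = nets_baseline_max, seed = seed
  ), class = "cohort_sim_spec")
}

#' Generate a synthetic cohort with measurements
#'
#' Draws per-subject BALF cytology consistent with each group's enrollment
#' rules (so rule-based classification reproduces the intended groups),
#' clinical findings, WCS, and the three NETs readouts (cf DNA, MPO-DNA OD,
#' NETs area/cell).
#'
#' @param spec a [cohort_sim_spec()].
#' @return List with `cohort` (a `cohort_table` data frame, see
#'   [read_cohort_csv()]) and `measurements` (data frame `subject_id`,
#'   `group`, `cfdna_ug_ml`, `mpo_dna_od`, `nets_area_per_cell`).
#' @export
generate_cohort <- function(spec = cohort_sim_spec()) {
  stopifnot(inherits(spec, "cohort_sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  gs <- spec$group_sizes
  es <- spec$effect_scale
  rows <- list()
  meas <- list()
  make_cyt <- function(neut, eos, mast) {
    rest <- 100 - (neut + eos + mast)
    mac <- round_half(rest * runif(1, 0.35, 0.6))
    lym <- rest - mac
    c(macrophages = mac, lymphocytes = lym, neutrophils = neut,
      eosinophils = eos, mast_cells = mast)
  }
  idx <- 0L
  for (g in c("healthy", "moderate", "severe")) {
    for (i in seq_len(gs[[g]])) {
      idx <- idx + 1L
      if (g == "healthy") {
        neut <- round_half(runif(1, 0.5, 5))
        eos <- sample(c(0, 0.5), 1, prob = c(0.85, 0.15))
        mast <- round_half(runif(1, 0, 2))
        labored <- FALSE; ausc <- FALSE
        mucus <- sample(0:1, 1)
        wcs <- 0L
      } else if (g == "moderate") {
        lo <- runif(1) < 3 / 7
        if (lo) {
          neut <- round_half(runif(1, 0.5, 4.5))
          mast <- round_half(runif(1, 2.5, 4.5)) # mastocytic form
          eos <- sample(c(0, 1.5), 1, prob = c(0.7, 0.3))
        } else {
          neut <- round_half(runif(1, 5.5, 19))
          mast <- round_half(runif(1, 0, 2))
          eos <- sample(c(0, 0.5), 1, prob = c(0.8, 0.2))
        }
        labored <- FALSE; ausc <- FALSE
        mucus <- sample(2:3, 1, prob = c(0.85, 0.15))
        wcs <- as.integer(max(0, min(3, round(0.15 * neut +
                                                rnorm(1, 0, 0.8)))))
      } else {
        neut <- round_half(min(92, 14 + stats::rexp(1, rate = 1 / 22)))
        mast <- round_half(runif(1, 0, 2.5))
        eos <- 0
        labored <- runif(1) < 8 / 14
        ausc <- runif(1) < 6 / 14
        if (neut <= 20 && !labored && !ausc) labored <- TRUE
        mucus <- sample(2:5, 1, prob = c(0.1, 0.3, 0.35, 0.25))
        wcs <- as.integer(max(4, min(23, round(3 + 0.15 * neut +
                                                 rnorm(1, 0, 2)))))
      }
      cyt <- make_cyt(neut, eos, mast)
      sid <- sprintf("%s%02d", toupper(substr(g, 1, 1)), i)
      rows[[idx]] <- data.frame(
        subject_id = sid, group_label = g,
        labored_breathing = labored, abnormal_auscultation = ausc,
        mucus_score = mucus,
        tracheal_neut_gt20 = neut > 20,
        wcs = wcs,
        macrophages = cyt[["macrophages"]], lymphocytes = cyt[["lymphocytes"]],
        neutrophils = cyt[["neutrophils"]], eosinophils = cyt[["eosinophils"]],
        mast_cells = cyt[["mast_cells"]],
        stringsAsFactors = FALSE
      )
      base_cf <- spec$cfdna_meanlog[["healthy"]]
      base_mpo <- spec$mpo_meanlog[["healthy"]]
      cf_ml <- base_cf + es * (spec$cfdna_meanlog[[g]] - base_cf)
      mpo_ml <- base_mpo + es * (spec$mpo_meanlog[[g]] - base_mpo)
      nets <- runif(1, 0, spec$nets_baseline_max)
      if (g == "severe" && es > 0) {
        nets <- nets + es * stats::rlnorm(1, spec$nets_meanlog,
                                          spec$nets_sdlog)
      }
      meas[[idx]] <- data.frame(
        subject_id = sid, group = g,
        cfdna_ug_ml = stats::rlnorm(1, cf_ml, spec$cfdna_sdlog),
        mpo_dna_od = spec$mpo_floor + stats::rlnorm(1, mpo_ml, spec$mpo_sdlog),
        nets_area_per_cell = nets,
        stringsAsFactors = FALSE
      )
    }
  }
  cohort <- do.call(rbind, rows)
  class(cohort) <- c("cohort_table", "data.frame")
  attr(cohort, "provenance") <- "synthetic"
  list(cohort = cohort, measurements = do.call(rbind, meas))
}

#' Write a simulated field to per-channel image files
#'
#' Writes `dapi.pgm`, `mpo.pgm`, `cith3.pgm` and a `ground_truth.json`
#' (scalar truth values) into `dir`.
#'
#' @param sim result of [generate_field()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_field_images <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pgm(sim$field$dapi, file.path(dir, "dapi.pgm"))
  write_pgm(sim$field$mpo, file.path(dir, "mpo.pgm"))
  write_pgm(sim$field$cith3, file.path(dir, "cith3.pgm"))
  truth <- sim$truth[c("true_cell_count", "true_neutrophil_count",
                       "true_coloc_area_px")]
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
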