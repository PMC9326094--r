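#' Three-channel fluorescence field
#'
#' One acquired cytospin / culture-slide field: DAPI (nuclei, blue), MPO
#' (neutrophil granules, green) and Cit-H3 (citrullinated histone 3, red)
#' intensity planes of identical dimensions.
#'
#' @param dapi,mpo,cith3 numeric intensity matrices, identical dimensions,
#'   non-negative.
#' @param pixel_size_um micrometres per pixel, or `NULL` to report areas in
#'   pixels.
#' @param field_id,subject_id labels.
#' @return An object of class `fluorescence_field`.
#' @export
fluorescence_field <- function(dapi, mpo, cith3, pixel_size_um = NULL,
                               field_id = "field", subject_id = "subject") {
  stopifnot(is.matrix(dapi), is.matrix(mpo), is.matrix(cith3))
  if (!identical(dim(dapi), dim(mpo)) || !identical(dim(dapi), dim(cith3))) {
    stop("channel dimensions differ", call. = FALSE)
  }
  if (min(dapi, mpo, cith3) < 0) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(
    dapi = dapi, mpo = mpo, cith3 = cith3,
    pixel_size_um = pixel_size_um,
    field_id = as.character(field_id),
    subject_id = as.character(subject_id)
  ), class = "fluorescence_field")
}

#' Thresholding and counting configuration
#'
#' Per-channel intensity cutoffs (a number, or `"otsu"` to derive the cutoff
#' from the channel histogram), the minimum nucleus area, the minimum
#' colocalization object area (the original quantification applied no size
#' filter, so 0 is the default), and the rule identifying a nucleus as a
#' neutrophil: at least `neutrophil_overlap_fraction` of the nucleus
#' footprint, dilated by `nucleus_dilation_radius_px` to reach the
#' cytoplasm, must be MPO-positive.
#'
#' @param mpo_threshold,cith3_threshold,dapi_threshold numeric cutoff or
#'   `"otsu"`.
#' @param min_nucleus_area_px integer; components smaller than this are not
#'   counted as nuclei (default 30, a 20x-like scale).
#' @param min_coloc_object_area_px integer, default 0.
#' @param neutrophil_overlap_fraction fraction in \[0, 1\], default 0.1.
#' @param nucleus_dilation_radius_px integer, default 3.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(mpo_threshold = "otsu",
                             cith3_threshold = "otsu",
                             dapi_threshold = "otsu",
                             min_nucleus_area_px = 30L,
                             min_coloc_object_area_px = 0L,
                             neutrophil_overlap_fraction = 0.1,
                             nucleus_dilation_radius_px = 3L) {
  if (neutrophil_overlap_fraction < 0 || neutrophil_overlap_fraction > 1) {
    stop("neutrophil_overlap_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (min_nucleus_area_px < 0 || min_coloc_object_area_px < 0 ||
      nucleus_dilation_radius_px < 0) {
    stop("areas and radii must be >= 0", call. = FALSE)
  }
  structure(list(
    mpo_threshold = mpo_threshold,
    cith3_threshold = cith3_threshold,
    dapi_threshold = dapi_threshold,
    min_nucleus_area_px = as.integer(min_nucleus_area_px),
    min_coloc_object_area_px = as.integer(min_coloc_object_area_px),
    neutrophil_overlap_fraction = neutrophil_overlap_fraction,
    nucleus_dilation_radius_px = as.integer(nucleus_dilation_radius_px)
  ), class = "threshold_config")
}

#' Otsu threshold of an intensity image
#'
#' Histogram-based threshold maximizing the between-class variance of the
#' binary split `x > t`. Candidate cuts are the `nbins` histogram bin upper
#' edges over the intensity range.
#'
#' @param x numeric matrix or vector of intensities.
#' @param nbins number of histogram bins (default 256).
#' @return Numeric threshold; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- as.numeric(x)
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant image: Otsu threshold equals the constant, mask empty",
            call. = FALSE)
    return(rng[1])
  }
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(v, edges, rightmost.closed = TRUE),
                     nbins = nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  # between-class variance for cut after bin k (foreground = bins > k)
  valid <- w0 > 0 & w0 < 1
  bcv <- rep(-Inf, nbins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  k <- which.max(bcv)
  edges[k + 1L]
}

resolve_threshold <- function(channel, threshold) {
  if (identical(threshold, "otsu")) otsu_threshold(channel)
  else if (is.numeric(threshold) && length(threshold) == 1L) threshold
  else stop("threshold must be a single number or \"otsu\"", call. = FALSE)
}

#' Binarize a fluorescence channel
#'
#' Marks pixels whose intensity is strictly greater than the cutoff. With
#' `threshold = "otsu"` the cutoff is first resolved from the channel via
#' [otsu_threshold()].
#'
#' @param channel numeric intensity matrix.
#' @param threshold numeric cutoff or `"otsu"`.
#' @return Logical matrix with attribute `"threshold"` (the resolved cutoff).
#' @export
binarize_channel <- function(channel, threshold) {
  stopifnot(is.matrix(channel), length(channel) > 0)
  thr <- resolve_threshold(channel, threshold)
  mask <- channel > thr
  attr(mask, "threshold") <- thr
  mask
}

#' Remove small components from a binary mask
#'
#' @param mask logical matrix.
#' @param min_area_px components (8-connected) smaller than this are
#'   cleared.
#' @return Logical matrix.
#' @export
filter_small_objects <- function(mask, min_area_px) {
  if (min_area_px <= 1 || !any(mask)) return(mask)
  lab <- .cc_label(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area_px)
  out <- matrix(lab %in% keep, nrow = nrow(mask))
  out
}

#' MPO / Cit-H3 colocalization mask
#'
#' The "red inter green" image: pixelwise AND of the two binary channel
#' masks, with connected components (8-connectivity) smaller than
#' `min_object_area_px` removed. DAPI is deliberately not intersected:
#' requiring the triple overlap suppresses genuine filamentous NETs signal.
#'
#' @param mpo_mask,cith3_mask logical matrices of equal dimensions.
#' @param min_object_area_px minimum component area kept (default 0, i.e.
#'   no size filter).
#' @return Logical colocalization mask.
#' @export
coloc_mask <- function(mpo_mask, cith3_mask, min_object_area_px = 0L) {
  if (!identical(dim(mpo_mask), dim(cith3_mask))) {
    stop("mask dimensions differ", call. = FALSE)
  }
  filter_small_objects(mpo_mask & cith3_mask, min_object_area_px)
}

#' Area of a binary mask
#'
#' Count of true pixels; multiplied by `pixel_size_um^2` when a pixel size
#' is supplied, yielding square micrometres.
#'
#' @param mask logical matrix.
#' @param pixel_size_um micrometres per pixel or `NULL` (report pixels).
#' @return Numeric area.
#' @export
coloc_area <- function(mask, pixel_size_um = NULL) {
  a <- sum(mask)
  if (!is.null(pixel_size_um)) a <- a * pixel_size_um^2
  a
}

#' Count nuclei in the DAPI channel
#'
#' Nuclei are 8-connected components of the binarized DAPI mask with area at
#' least `cfg$min_nucleus_area_px`. Touching nuclei are not split (no
#' watershed); the count is of objects, matching the original script.
#'
#' @param dapi numeric DAPI intensity matrix.
#' @param cfg a [threshold_config()].
#' @return List with `count` (integer) and `labels` (integer matrix, 0 =
#'   background, labels renumbered 1..count after the size filter).
#' @export
count_cells <- function(dapi, cfg = threshold_config()) {
  mask <- binarize_channel(dapi, cfg$dapi_threshold)
  if (!any(mask)) {
    return(list(count = 0L, labels = matrix(0L, nrow(dapi), ncol(dapi))))
  }
  lab <- .cc_label(mask, 8L)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= cfg$min_nucleus_area_px)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  newlab <- matrix(0L, nrow(dapi), ncol(dapi))
  pos <- lab > 0L
  newlab[pos] <- remap[lab[pos]]
  list(count = length(keep), labels = newlab)
}

#' Count MPO-positive neutrophils among detected nuclei
#'
#' A nucleus counts as a neutrophil when, within its footprint dilated by
#' `cfg$nucleus_dilation_radius_px` (to capture the cytoplasmic MPO ring),
#' the fraction of MPO-positive pixels reaches
#' `cfg$neutrophil_overlap_fraction`.
#'
#' @param nucleus_labels integer label matrix from [count_cells()].
#' @param mpo_mask logical MPO mask.
#' @param cfg a [threshold_config()].
#' @return Integer count.
#' @export
count_neutrophils <- function(nucleus_labels, mpo_mask,
                              cfg = threshold_config()) {
  if (!identical(dim(nucleus_labels), dim(mpo_mask))) {
    stop("label map and MPO mask dimensions differ", call. = FALSE)
  }
  n <- max(nucleus_labels)
  if (n == 0L) return(0L)
  r <- cfg$nucleus_dilation_radius_px
  nr <- nrow(nucleus_labels); nc <- ncol(nucleus_labels)
  count <- 0L
  for (k in seq_len(n)) {
    idx <- which(nucleus_labels == k, arr.ind = TRUE)
    r1 <- max(1L, min(idx[, 1]) - r); r2 <- min(nr, max(idx[, 1]) + r)
    c1 <- max(1L, min(idx[, 2]) - r); c2 <- min(nc, max(idx[, 2]) + r)
    sub <- nucleus_labels[r1:r2, c1:c2] == k
    foot <- .binary_dilate(sub, r)
    frac <- sum(foot & mpo_mask[r1:r2, c1:c2]) / sum(foot)
    if (frac >= cfg$neutrophil_overlap_fraction) count <- count + 1L
  }
  count
}

#' Quantify NETs in one field
#'
#' Runs the full per-field analysis: binarize MPO and Cit-H3, intersect
#' ("red inter green"), measure the colocalization area, count DAPI nuclei
#' and MPO-positive neutrophils, and normalize the area per cell and per
#' neutrophil. With no cells detected, both normalized values are 0 (a blank
#' field carries no NETs evidence; warned). With positive colocalization but
#' no neutrophil detected, the per-neutrophil value is `NA` (missing, not
#' infinite).
#'
#' @param field a [fluorescence_field()].
#' @param cfg a [threshold_config()].
#' @return One-row data frame of class `field_quantification` with columns
#'   `subject_id`, `field_id`, `coloc_area`, `cell_count`,
#'   `neutrophil_count`, `nets_area_per_cell`, `nets_area_per_neutrophil`.
#'   Areas are in px^2, or um^2 when the field carries a pixel size.
#' @export
quantify_field <- function(field, cfg = threshold_config()) {
  stopifnot(inherits(field, "fluorescence_field"))
  mpo_mask <- binarize_channel(field$mpo, cfg$mpo_threshold)
  red_mask <- binarize_channel(field$cith3, cfg$cith3_threshold)
  cmask <- coloc_mask(mpo_mask, red_mask, cfg$min_coloc_object_area_px)
  area <- coloc_area(cmask, field$pixel_size_um)
  cells <- count_cells(field$dapi, cfg)
  neut <- count_neutrophils(cells$labels, mpo_mask, cfg)
  if (cells$count == 0L) {
    if (area > 0) {
      warning("field ", field$field_id,
              ": colocalization signal but no cells detected; ",
              "normalized areas set to 0", call. = FALSE)
    }
    per_cell <- 0
    per_neut <- 0
  } else {
    per_cell <- area / cells$count
    per_neut <- if (neut == 0L) {
      if (area > 0) NA_real_ else 0
    } else {
      area / neut
    }
  }
  structure(data.frame(
    subject_id = field$subject_id, field_id = field$field_id,
    coloc_area = area, cell_count = cells$count, neutrophil_count = neut,
    nets_area_per_cell = per_cell, nets_area_per_neutrophil = per_neut,
    stringsAsFactors = FALSE
  ), class = c("field_quantification", "data.frame"))
}

#' Per-individual NETs summary
#'
#' Arithmetic mean of the per-field normalized NETs areas over all fields of
#' one subject (typically six 20x fields per slide; any number >= 1 is
#' accepted). Missing per-neutrophil values are excluded from that mean.
#'
#' @param fields a data frame of per-field rows as returned by
#'   [quantify_field()] (rows may be `rbind`-ed).
#' @return One-row data frame: `subject_id`, `n_fields`,
#'   `mean_nets_area_per_cell`, `mean_nets_area_per_neutrophil`.
#' @export
summarize_individual <- function(fields) {
  if (is.null(fields) || nrow(fields) < 1L) {
    stop("summarize_individual() needs at least one field", call. = FALSE)
  }
  subj <- unique(fields$subject_id)
  if (length(subj) != 1L) {
    stop("summarize_individual() received fields from multiple subjects: ",
         paste(subj, collapse = ", "), call. = FALSE)
  }
  pn <- fields$nets_area_per_neutrophil
  data.frame(
    subject_id = subj,
    n_fields = nrow(fields),
    mean_nets_area_per_cell = mean(fields$nets_area_per_cell),
    mean_nets_area_per_neutrophil =
      if (all(is.na(pn))) NA_real_ else mean(pn, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Read a field from per-channel grayscale images
#'
#' @param dapi_path,mpo_path,cith3_path per-channel PGM files.
#' @inheritParams fluorescence_field
#' @return A [fluorescence_field()].
#' @export
read_field <- function(dapi_path, mpo_path, cith3_path,
                       pixel_size_um = NULL, field_id = "field",
                       subject_id = "subject") {
  fluorescence_field(
    dapi = read_pgm(dapi_path), mpo = read_pgm(mpo_path),
    cith3 = read_pgm(cith3_path), pixel_size_um = pixel_size_um,
    field_id = field_id, subject_id = subject_id
  )
}
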