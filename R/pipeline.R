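#' Run the NETs analysis pipeline end to end
#'
#' Orchestrates classification, optional image quantification, and the
#' statistics layer, writing a reproducible report bundle (CSV + JSON + run
#' log) to `out_dir`. Inputs are either real files (cohort CSV, image
#' manifest, plate CSV) or a simulation spec — per data stream, exactly one
#' source.
#'
#' The statistics stage runs, for every available readout (BALF neutrophil
#' % always; cf DNA, MPO-DNA OD and NETs area/cell when a measurement table
#' is present): the normality-dispatched three-group comparison, pooled
#' Spearman correlations against BALF neutrophil % and WCS, and empirical
#' ROC curves for severe (severe vs all others) and moderate (moderate vs
#' all others) asthma.
#'
#' @param out_dir output directory, created if needed.
#' @param cohort cohort CSV path or `cohort_table` data frame; mutually
#'   exclusive with `sim_spec`.
#' @param measurements optional measurement table (data frame or CSV with
#'   columns `subject_id`, `cfdna_ug_ml`, `mpo_dna_od`,
#'   `nets_area_per_cell`).
#' @param sim_spec optional [cohort_sim_spec()]; generates cohort and
#'   measurements.
#' @param image_manifest optional CSV/data frame with columns `subject_id`,
#'   `field_id`, `dapi`, `mpo`, `cith3` (per-channel image paths); fields
#'   are quantified with `threshold_cfg` and summarized per individual.
#' @param plate optional PicoGreen plate CSV/data frame (see
#'   [read_plate_csv()]); quantified via [quantify_cfdna_plate()].
#' @param threshold_cfg a [threshold_config()].
#' @param alpha significance level (default 0.05).
#' @param seed root seed for all randomness (applied before simulation).
#' @return Invisibly, a list with the computed tables
#'   (`classification`, `comparisons`, `correlations`, `roc`, and
#'   `field_quantification` / `cfdna` when inputs were given).
#' @export
run_pipeline <- function(out_dir, cohort = NULL, measurements = NULL,
                         sim_spec = NULL, image_manifest = NULL,
                         plate = NULL, threshold_cfg = threshold_config(),
                         alpha = 0.05, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("netscope %s", as.character(utils::packageVersion("netscope"))),
    sprintf("seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("alpha: %g", alpha)
  )
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  if (!is.null(seed)) set.seed(seed)

  # --- stage: inputs --------------------------------------------------------
  if (!is.null(sim_spec) && !is.null(cohort)) {
    stop("input stage: give either a cohort or a simulation spec, not both",
         call. = FALSE)
  }
  if (!is.null(sim_spec)) {
    sim <- generate_cohort(sim_spec)
    cohort <- sim$cohort
    measurements <- sim$measurements
    note("cohort: simulated (%d subjects)", nrow(cohort))
  } else if (is.character(cohort)) {
    cohort <- read_cohort_csv(cohort)
    note("cohort: read %d records from file", nrow(cohort))
  } else if (is.null(cohort)) {
    stop("input stage: no cohort given (path, data frame, or sim_spec)",
         call. = FALSE)
  }
  if (is.character(measurements)) {
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  }

  # --- stage: classification ------------------------------------------------
  cls <- withCallingHandlers(
    classify_cohort(cohort),
    warning = function(w) {
      note("classification warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  classification <- data.frame(
    subject_id = cohort$subject_id,
    group = cls,
    rule_group = classify_phenotype(cohort),
    neutrophils = cohort$neutrophils,
    wcs = cohort$wcs,
    stringsAsFactors = FALSE
  )
  mod <- classification$group == "moderate"
  classification$subgroup <- NA_character_
  if (any(mod)) {
    classification$subgroup[mod] <-
      ifelse(cohort$neutrophils[mod] < 5, "neu_lo", "neu_hi")
  }
  utils::write.csv(classification, file.path(out_dir, "classification.csv"),
                   row.names = FALSE)
  note("classification: %s", paste(sprintf(
    "%s=%d", names(table(cls)), as.integer(table(cls))), collapse = ", "))

  # --- stage: image quantification ------------------------------------------
  field_quant <- NULL
  if (!is.null(image_manifest)) {
    if (is.character(image_manifest)) {
      if (!file.exists(image_manifest)) {
        stop("image stage: manifest not found: ", image_manifest,
             call. = FALSE)
      }
      image_manifest <- utils::read.csv(image_manifest,
                                        stringsAsFactors = FALSE)
    }
    need_cols(image_manifest, c("subject_id", "field_id", "dapi", "mpo",
                                "cith3"), "image stage")
    fq <- lapply(seq_len(nrow(image_manifest)), function(i) {
      row <- image_manifest[i, ]
      f <- read_field(row$dapi, row$mpo, row$cith3,
                      field_id = row$field_id, subject_id = row$subject_id)
      quantify_field(f, threshold_cfg)
    })
    field_quant <- do.call(rbind, fq)
    utils::write.csv(field_quant, file.path(out_dir, "fields.csv"),
                     row.names = FALSE)
    indiv <- do.call(rbind, lapply(split(field_quant,
                                         field_quant$subject_id),
                                   summarize_individual))
    utils::write.csv(indiv, file.path(out_dir, "individuals.csv"),
                     row.names = FALSE)
    note("images: quantified %d fields, %d subjects",
         nrow(field_quant), nrow(indiv))
  }

  # --- stage: assays --------------------------------------------------------
  cfdna <- NULL
  if (!is.null(plate)) {
    if (is.character(plate)) plate <- read_plate_csv(plate)
    cfdna <- quantify_cfdna_plate(plate)
    utils::write.csv(cfdna$samples, file.path(out_dir, "cfdna.csv"),
                     row.names = FALSE)
    note("assay: cf DNA curve slope %.4g, r2 %.4f",
         cfdna$curve$fit_slope, cfdna$curve$r_squared)
  }

  # --- stage: statistics ----------------------------------------------------
  dat <- classification
  if (!is.null(measurements)) {
    keep <- setdiff(names(measurements), "group") # classification owns group
    dat <- merge(dat, measurements[, keep, drop = FALSE],
                 by = "subject_id", sort = FALSE)
  }
  readouts <- intersect(
    c("neutrophils", "cfdna_ug_ml", "mpo_dna_od", "nets_area_per_cell"),
    names(dat)
  )
  comparisons <- list()
  correlations <- list()
  rocs <- list()
  for (ro in readouts) {
    groups <- split(dat[[ro]], dat$group)
    groups <- groups[vapply(groups, length, integer(1)) >= 3]
    if (length(groups) >= 2) {
      cmp <- suppressWarnings(compare_groups(groups, alpha = alpha))
      comparisons[[ro]] <- cmp
      note("stats: %s -> %s (normality p: %s), omnibus p = %.3g", ro,
           cmp$test_used,
           paste(signif(cmp$normality_p, 3), collapse = "/"),
           cmp$omnibus_p)
    }
    if (ro != "neutrophils") {
      correlations[[paste0(ro, "_vs_neutrophils")]] <-
        spearman(dat[[ro]], dat$neutrophils)
    }
    has_wcs <- is.finite(dat$wcs)
    wcs_pool <- dat$wcs
    wcs_pool[!has_wcs & dat$group == "healthy"] <- 0 # healthy carry no score
    if (sum(is.finite(wcs_pool)) >= 3) {
      correlations[[paste0(ro, "_vs_wcs")]] <-
        spearman(dat[[ro]][is.finite(wcs_pool)],
                 wcs_pool[is.finite(wcs_pool)])
    }
    for (target in c("severe", "moderate")) {
      if (sum(dat$group == target) > 0 && sum(dat$group != target) > 0) {
        rocs[[paste0(ro, "_", target)]] <-
          roc_auc(dat[[ro]], dat$group, positive_class = target)
      }
    }
  }
  cmp_tab <- do.call(rbind, lapply(names(comparisons), function(ro) {
    cmp <- comparisons[[ro]]
    data.frame(readout = ro, test_used = cmp$test_used,
               pair = names(cmp$pairwise_p),
               p = unname(cmp$pairwise_p),
               significance = unname(cmp$significance),
               omnibus_p = cmp$omnibus_p,
               stringsAsFactors = FALSE)
  }))
  cor_tab <- do.call(rbind, lapply(names(correlations), function(nm) {
    co <- correlations[[nm]]
    data.frame(pair = nm, rho = co$rho, p = co$p_value, n = co$n,
               significance = sig_code(co$p_value),
               stringsAsFactors = FALSE)
  }))
  roc_tab <- do.call(rbind, lapply(names(rocs), function(nm) {
    r <- rocs[[nm]]
    data.frame(contrast = nm, positive_class = r$positive_class,
               auc = r$auc, n_pos = r$n_pos, n_neg = r$n_neg,
               stringsAsFactors = FALSE)
  }))
  for (nm in c("comparisons", "correlations", "roc")) {
    tab <- switch(nm, comparisons = cmp_tab, correlations = cor_tab,
                  roc = roc_tab)
    if (!is.null(tab)) {
      utils::write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
      jsonlite::write_json(tab, file.path(out_dir, paste0(nm, ".json")),
                           dataframe = "rows", auto_unbox = TRUE,
                           digits = NA)
    }
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(
    classification = classification,
    comparisons = cmp_tab, correlations = cor_tab, roc = roc_tab,
    comparison_objects = comparisons, correlation_objects = correlations,
    roc_objects = rocs,
    field_quantification = field_quant, cfdna = cfdna,
    log = log_lines
  ))
}

#' Recompute the printed-cohort consistency checks
#'
#' Re-derives, from the packaged enrollment tables, every count the source
#' narrative prints about its cohort: group sizes from the classification
#' rules, the neutrophil subgrouping of moderate cases, the labored-breathing
#' count among severe cases, the maximum healthy BALF neutrophil %, and the
#' moderate records at tracheal mucus score 3.
#'
#' @return Data frame with columns `check`, `expected`, `computed`, `pass`.
#' @export
reproduce_paper_counts <- function() {
  asth <- read_cohort_csv(cohort_fixture_path("asthmatic"))
  healthy <- read_cohort_csv(cohort_fixture_path("healthy"))
  cls <- classify_phenotype(asth)
  mod <- asth[cls == "moderate", , drop = FALSE]
  sub <- subgroup_moderate(mod)
  checks <- data.frame(
    check = c(
      "asthmatic records", "classified severe", "classified moderate",
      "healthy records", "moderate neu_lo", "moderate neu_hi",
      "severe with labored breathing at rest",
      "max healthy BALF neutrophil %",
      "moderate records with mucus score 3"
    ),
    expected = c(21, 14, 7, 12, 3, 4, 8, 8, 1),
    computed = c(
      nrow(asth), sum(cls == "severe"), sum(cls == "moderate"),
      nrow(healthy), sum(sub == "neu_lo"), sum(sub == "neu_hi"),
      sum(asth$labored_breathing[cls == "severe"]),
      max(healthy$neutrophils),
      sum(mod$mucus_score == 3, na.rm = TRUE)
    ),
    stringsAsFactors = FALSE
  )
  checks$pass <- checks$expected == checks$computed
  checks
}
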