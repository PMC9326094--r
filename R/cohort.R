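#' BALF differential cytology
#'
#' Constructs a validated BALF differential cytology record. Percentages are
#' of total nucleated cells, counted on 300 cells (so values land on halves);
#' the five populations must each lie in \[0, 100\] and sum to within
#' \[95, 105\].
#'
#' @param macrophages_pct,lymphocytes_pct,neutrophils_pct,eosinophils_pct,mast_cells_pct
#'   percentages of total nucleated cells.
#' @return An object of class `balf_cytology` (named list of the five
#'   percentages).
#' @export
#' @examples
#' balf_cytology(63, 33.5, 1.5, 0, 2)
balf_cytology <- function(macrophages_pct, lymphocytes_pct, neutrophils_pct,
                          eosinophils_pct, mast_cells_pct) {
  cyt <- list(
    macrophages_pct = macrophages_pct, lymphocytes_pct = lymphocytes_pct,
    neutrophils_pct = neutrophils_pct, eosinophils_pct = eosinophils_pct,
    mast_cells_pct = mast_cells_pct
  )
  validate_cytology(cyt)
  structure(cyt, class = "balf_cytology")
}

validate_cytology <- function(cyt, where = "cytology") {
  vals <- unlist(cyt[c(
    "macrophages_pct", "lymphocytes_pct", "neutrophils_pct",
    "eosinophils_pct", "mast_cells_pct"
  )])
  if (any(!is.finite(vals))) {
    stop(sprintf("%s: non-numeric or missing percentage", where), call. = FALSE)
  }
  if (any(vals < 0 | vals > 100)) {
    stop(sprintf("%s: percentages must lie in [0, 100]", where), call. = FALSE)
  }
  total <- sum(vals)
  if (total < 95 || total > 105) {
    stop(sprintf(
      "%s: differential percentages sum to %.1f, outside [95, 105]",
      where, total
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Single-subject clinical record
#'
#' One horse: identity, group label as enrolled, the exam findings used by
#' the severity rules, tracheal findings, weighted clinical score (WCS,
#' 0-23) and BALF differential cytology.
#'
#' @param subject_id opaque subject label.
#' @param cytology a [balf_cytology()] object.
#' @param group_label one of `"healthy"`, `"moderate"`, `"severe"`,
#'   `"unknown"` (the label as enrolled, which may override rule-based
#'   classification at cohort level).
#' @param labored_breathing_at_rest logical.
#' @param abnormal_lung_auscultation logical; `TRUE` iff the physical exam
#'   notes crackles, wheezes or increased lung sounds.
#' @param tracheal_mucus_score integer 0-5 or `NA`.
#' @param tracheal_neutrophilia_gt20 logical or `NA` (tracheal wash
#'   neutrophils above 20%).
#' @param wcs integer 0-23 or `NA`.
#' @return An object of class `horse_record`.
#' @export
horse_record <- function(subject_id, cytology, group_label = "unknown",
                         labored_breathing_at_rest = FALSE,
                         abnormal_lung_auscultation = FALSE,
                         tracheal_mucus_score = NA_integer_,
                         tracheal_neutrophilia_gt20 = NA,
                         wcs = NA_integer_) {
  stopifnot(inherits(cytology, "balf_cytology"))
  group_label <- match.arg(group_label,
                           c("healthy", "moderate", "severe", "unknown"))
  if (!is.na(tracheal_mucus_score) &&
      !(tracheal_mucus_score %in% 0:5)) {
    stop("tracheal_mucus_score must be an integer in 0..5 or NA",
         call. = FALSE)
  }
  if (!is.na(wcs) && (wcs < 0 || wcs > 23)) {
    stop("wcs must lie in [0, 23] or be NA", call. = FALSE)
  }
  structure(list(
    subject_id = as.character(subject_id),
    group_label = group_label,
    labored_breathing_at_rest = isTRUE(labored_breathing_at_rest),
    abnormal_lung_auscultation = isTRUE(abnormal_lung_auscultation),
    tracheal_mucus_score = as.integer(tracheal_mucus_score),
    tracheal_neutrophilia_gt20 = if (is.na(tracheal_neutrophilia_gt20)) NA
      else isTRUE(tracheal_neutrophilia_gt20),
    wcs = as.integer(wcs),
    cytology = cytology
  ), class = "horse_record")
}

#' Is a BALF cytology consistent with equine asthma?
#'
#' A horse qualifies as asthmatic when at least one granulocytic population
#' is increased: neutrophils > 5%, eosinophils > 1% or mast cells > 2%
#' (all strict inequalities; values exactly at a cutoff do not qualify).
#'
#' @param x a [balf_cytology()], a [horse_record()], or a cohort data frame
#'   with columns `neutrophils`, `eosinophils`, `mast_cells`.
#' @return Logical (vector for cohort input).
#' @export
#' @examples
#' is_asthmatic(balf_cytology(60, 34, 1.5, 0, 4.5)) # mast cells elevated
#' is_asthmatic(balf_cytology(63, 33.5, 1.5, 0, 2)) # all at/below cutoffs
is_asthmatic <- function(x) {
  UseMethod("is_asthmatic")
}

#' @export
is_asthmatic.balf_cytology <- function(x) {
  x$neutrophils_pct > 5 || x$eosinophils_pct > 1 || x$mast_cells_pct > 2
}

#' @export
is_asthmatic.horse_record <- function(x) is_asthmatic(x$cytology)

#' @export
is_asthmatic.data.frame <- function(x) {
  need_cols(x, c("neutrophils", "eosinophils", "mast_cells"), "is_asthmatic")
  x$neutrophils > 5 | x$eosinophils > 1 | x$mast_cells > 2
}

#' Rule-based severity phenotype
#'
#' Applies the enrollment rules: not asthmatic by cytology -> `healthy`;
#' otherwise `severe` when labored breathing at rest, abnormal lung
#' auscultation or BALF neutrophilia > 20% is present; otherwise `moderate`.
#'
#' @param rec a [horse_record()] or a cohort data frame (see
#'   [read_cohort_csv()] for the column contract).
#' @return Character scalar (or vector for cohort input) in
#'   `c("healthy", "moderate", "severe")`.
#' @seealso [classify_cohort()] for label-respecting cohort classification,
#'   [subgroup_moderate()] for the neutrophil subgrouping of moderate cases.
#' @export
classify_phenotype <- function(rec) {
  UseMethod("classify_phenotype")
}

#' @export
classify_phenotype.horse_record <- function(rec) {
  if (!is_asthmatic(rec$cytology)) return("healthy")
  severe <- rec$labored_breathing_at_rest ||
    rec$abnormal_lung_auscultation || rec$cytology$neutrophils_pct > 20
  if (severe) "severe" else "moderate"
}

#' @export
classify_phenotype.data.frame <- function(rec) {
  need_cols(rec, c(
    "labored_breathing", "abnormal_auscultation",
    "neutrophils", "eosinophils", "mast_cells"
  ), "classify_phenotype")
  asthmatic <- is_asthmatic(rec)
  severe <- rec$labored_breathing | rec$abnormal_auscultation |
    rec$neutrophils > 20
  ifelse(!asthmatic, "healthy", ifelse(severe, "severe", "moderate"))
}

#' Neutrophil subgroup of a moderate asthmatic
#'
#' Splits moderate asthma into neutrophil-low (`neu_lo`, < 5% BALF
#' neutrophils) and neutrophil-high (`neu_hi`, >= 5%). Exactly 5% is
#' assigned to `neu_hi`.
#'
#' @param rec a [horse_record()] classified as moderate, or a cohort data
#'   frame (rows must all classify as moderate).
#' @return `"neu_lo"` or `"neu_hi"` (vector for cohort input).
#' @export
subgroup_moderate <- function(rec) {
  UseMethod("subgroup_moderate")
}

#' @export
subgroup_moderate.horse_record <- function(rec) {
  if (classify_phenotype(rec) != "moderate") {
    stop("subgroup_moderate() requires a record classifying as moderate",
         call. = FALSE)
  }
  if (rec$cytology$neutrophils_pct < 5) "neu_lo" else "neu_hi"
}

#' @export
subgroup_moderate.data.frame <- function(rec) {
  cls <- classify_phenotype(rec)
  if (any(cls != "moderate")) {
    stop("subgroup_moderate() requires records classifying as moderate",
         call. = FALSE)
  }
  ifelse(rec$neutrophils < 5, "neu_lo", "neu_hi")
}

#' Classify a cohort, honoring explicit enrollment labels
#'
#' Applies [classify_phenotype()] to every row; where the table carries an
#' explicit `group_label` (not `"unknown"`/`NA`) that label wins, and any
#' disagreement with the rule-based call is reported as a warning (e.g. a
#' healthy-labeled horse whose cytology exceeds reference values).
#'
#' @param tab cohort data frame.
#' @param prefer_label keep explicit labels over rule-based calls
#'   (default `TRUE`).
#' @return Character vector of group labels, one per row.
#' @export
classify_cohort <- function(tab, prefer_label = TRUE) {
  rule <- classify_phenotype(tab)
  if (!prefer_label || is.null(tab$group_label)) return(rule)
  lab <- as.character(tab$group_label)
  keep <- !is.na(lab) & lab != "unknown"
  clash <- keep & lab != rule
  if (any(clash)) {
    warning(sprintf(
      "%d record(s) keep their enrollment label against the cytology rule: %s",
      sum(clash),
      paste(tab$subject_id[clash], collapse = ", ")
    ), call. = FALSE)
  }
  ifelse(keep, lab, rule)
}

cohort_columns <- c(
  "subject_id", "group_label", "labored_breathing", "abnormal_auscultation",
  "mucus_score", "tracheal_neut_gt20", "wcs",
  "macrophages", "lymphocytes", "neutrophils", "eosinophils", "mast_cells"
)

cytology_columns <- c(
  "macrophages", "lymphocytes", "neutrophils", "eosinophils", "mast_cells"
)

need_cols <- function(df, cols, fn) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s): %s", fn,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "yes", "1")] <- TRUE
  out[x %in% c("false", "no", "0")] <- FALSE
  out
}

#' Read / write a cohort table
#'
#' CSV dialect: comma-separated, UTF-8, header
#' `subject_id,group_label,labored_breathing,abnormal_auscultation,`
#' `mucus_score,tracheal_neut_gt20,wcs,macrophages,lymphocytes,neutrophils,`
#' `eosinophils,mast_cells`; an empty cell means missing. Cytology rows are
#' validated on read; parse failures name the offending row and column.
#' `write_cohort_csv()` then `read_cohort_csv()` reproduces all fields.
#'
#' @param path file path.
#' @param validate validate cytology rows on read (default `TRUE`).
#' @return `read_cohort_csv()`: a data frame of class `cohort_table` with the
#'   columns above, one row per horse. `write_cohort_csv()`: `path`,
#'   invisibly.
#' @export
read_cohort_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need_cols(raw, cohort_columns, "read_cohort_csv")
  n <- nrow(raw)
  out <- data.frame(
    subject_id = raw$subject_id,
    group_label = ifelse(trimws(raw$group_label) == "", "unknown",
                         raw$group_label),
    labored_breathing = parse_bool(raw$labored_breathing),
    abnormal_auscultation = parse_bool(raw$abnormal_auscultation),
    mucus_score = suppressWarnings(as.integer(raw$mucus_score)),
    tracheal_neut_gt20 = parse_bool(raw$tracheal_neut_gt20),
    wcs = suppressWarnings(as.integer(raw$wcs)),
    stringsAsFactors = FALSE
  )
  for (col in cytology_columns) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & trimws(raw[[col]]) != "")
    if (length(bad)) {
      stop(sprintf("read_cohort_csv: non-numeric value in column '%s', row %d",
                   col, bad[1]), call. = FALSE)
    }
    out[[col]] <- v
  }
  if (n > 0 && anyDuplicated(out$subject_id)) {
    stop("read_cohort_csv: duplicated subject_id", call. = FALSE)
  }
  if (validate && n > 0) {
    for (i in seq_len(n)) {
      cyt <- list(
        macrophages_pct = out$macrophages[i],
        lymphocytes_pct = out$lymphocytes[i],
        neutrophils_pct = out$neutrophils[i],
        eosinophils_pct = out$eosinophils[i],
        mast_cells_pct = out$mast_cells[i]
      )
      validate_cytology(cyt, where = sprintf(
        "row %d (subject %s)", i, out$subject_id[i]))
    }
  }
  structure(out, class = c("cohort_table", "data.frame"),
            provenance = path)
}

#' @rdname read_cohort_csv
#' @param tab cohort data frame as returned by [read_cohort_csv()].
#' @export
write_cohort_csv <- function(tab, path) {
  need_cols(tab, cohort_columns, "write_cohort_csv")
  out <- as.data.frame(tab)[, cohort_columns]
  for (col in c("labored_breathing", "abnormal_auscultation",
                "tracheal_neut_gt20")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(out[[col]], "true", "false"))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Packaged cohort fixtures
#'
#' Paths to the transcribed enrollment tables shipped with the package:
#' `"healthy"` (12 control horses, cytology only) and `"asthmatic"`
#' (21 horses with clinical findings, tracheal scores, WCS and cytology).
#'
#' @param which `"healthy"` or `"asthmatic"`.
#' @return File path to the packaged CSV.
#' @export
cohort_fixture_path <- function(which = c("asthmatic", "healthy")) {
  which <- match.arg(which)
  fname <- if (which == "healthy") "table1_healthy.csv" else
    "table2_asthmatic.csv"
  system.file("extdata", fname, package = "netscope", mustWork = TRUE)
}
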