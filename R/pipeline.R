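#' Measure the RBC areas in one smear field
#'
#' Runs the full single-image pipeline: HSV conversion and Otsu
#' segmentation of the saturation channel, optional edge refinement,
#' outer-contour extraction, pending/candidate partition, S_mean-relative
#' selection of effective single cells, G/Mg gray-ratio classification,
#' and per-cell minimum-enclosing-circle area computation (Si, Pmean, Sr)
#' with the roundness recall gate.
#'
#' @param img a [smear_image] (its own calibration is used; the config
#'   calibration applies when images are loaded from paths).
#' @param config an [rbc_config()].
#' @return An object of class `smear_measurement`: list with `cells` (one
#'   row per effective single cell: contour area, convexity, `g`,
#'   `g_ratio`, `cell_class`, circle center/radius, `pmean`, `si_um2`,
#'   `sr_um2`, `recall`), `contours` (all contours with final statuses),
#'   `s_mean_um2`, `mg`, `summary` (a [summarize_smear()] row), `config`,
#'   `source_id`.
#' @export
measure_smear <- function(img, config = rbc_config()) {
  stopifnot(inherits(img, "smear_image"))
  seg <- config$segmentation
  empty_cells <- data.frame(
    cell_id = integer(), area_um2 = numeric(), convexity_ratio = numeric(),
    g = numeric(), g_ratio = numeric(), cell_class = character(),
    circle_row = numeric(), circle_col = numeric(),
    circle_radius_px = numeric(), pmean = numeric(), si_um2 = numeric(),
    sr_um2 = numeric(), recall = logical(), stringsAsFactors = FALSE)

  finish <- function(cells, contours, s_mean, mg) {
    structure(
      list(cells = cells, contours = contours, s_mean_um2 = s_mean, mg = mg,
           summary = summarize_smear(cells, img$source_id,
                                     config$area$include_non_recall),
           config = config, source_id = img$source_id),
      class = "smear_measurement")
  }

  hsv <- rgb_to_hsv(img)
  gray <- rgb_to_gray(img)
  mask <- otsu_segment(hsv, seg$otsu_channel)
  if (isTRUE(seg$edge_refine)) mask <- edge_refine(mask, gray)
  contours <- extract_outer_contours(mask, img$microns_per_pixel)
  contours <- flag_pending(contours, seg$noise_floor_um2,
                           seg$pending_ceiling_um2)
  if (!any(vapply(contours, `[[`, character(1), "stage") == "candidate"))
    return(finish(empty_cells, contours, NA_real_, NA_real_))
  s_mean <- compute_s_mean(contours)$s_mean_um2
  contours <- select_effective_contours(contours, s_mean, seg$a, seg$b,
                                        seg$convexity_min)
  eff <- which(vapply(contours, `[[`, character(1), "status") == "effective")
  if (!length(eff)) return(finish(empty_cells, contours, s_mean, NA_real_))

  g <- vapply(contours[eff], function(ct) mean_gray_of_cell(gray, ct),
              numeric(1))
  mg <- cohort_mean_gray(g)
  cells <- do.call(rbind, lapply(seq_along(eff), function(k) {
    ct <- contours[[eff[k]]]
    cls <- classify_cell(g[k], mg, config$classification$ratio_threshold)
    mec <- min_enclosing_circle(ct)
    rp <- roundness_profile(ct, mec$center, mec$radius)
    si <- area_si(mec$radius, img$microns_per_pixel)
    recall <- is_recall_rbc(rp$ratios, si, s_mean, seg$a, seg$b,
                            config$area$roundness_min)
    sr <- if (recall || config$area$include_non_recall)
      area_sr(si, rp$pmean) else NA_real_
    data.frame(cell_id = eff[k], area_um2 = ct$area_um2,
               convexity_ratio = ct$convexity_ratio, g = g[k],
               g_ratio = g[k] / mg, cell_class = cls,
               circle_row = mec$center[1], circle_col = mec$center[2],
               circle_radius_px = mec$radius, pmean = rp$pmean,
               si_um2 = si, sr_um2 = sr, recall = recall,
               stringsAsFactors = FALSE)
  }))
  finish(cells, contours, s_mean, mg)
}

#' @export
print.smear_measurement <- function(x, ...) {
  st <- table(factor(vapply(x$contours, `[[`, character(1), "status"),
                     levels = c("effective", "merged", "pending", "rejected")))
  cat(sprintf("<smear_measurement> '%s': %d contours (%d effective, %d merged, %d pending, %d rejected)\n",
              x$source_id, length(x$contours), st["effective"], st["merged"],
              st["pending"], st["rejected"]))
  cat(sprintf("  S_mean = %.2f um^2, Mg = %.1f\n", x$s_mean_um2, x$mg))
  s <- x$summary
  if (s$n_rbc_measured > 1)
    cat(sprintf("  %d recall RBCs: mean Sr = %.2f um^2, SD = %.2f, CV = %.2f%%\n",
                s$n_rbc_measured, s$mean_area_um2, s$sd_area_um2, s$cv_percent))
  else cat(sprintf("  %d recall RBC(s) measured\n", s$n_rbc_measured))
  invisible(x)
}

#' @export
summary.smear_measurement <- function(object, ...) object$summary

#' Overlay measured contours on the smear image
#'
#' @param x a `smear_measurement`.
#' @param img the [smear_image] it was computed from.
#' @param ... passed to [graphics::plot()].
#' @export
plot.smear_measurement <- function(x, img, ...) {
  d <- dim(img$pixels)
  graphics::plot(NA, xlim = c(1, d[2]), ylim = c(d[1], 1), asp = 1,
                 xlab = "col (px)", ylab = "row (px)",
                 main = x$source_id, ...)
  graphics::rasterImage(grDevices::as.raster(img$pixels / 255),
                        1, d[1], d[2], 1)
  cols <- c(effective = "green3", merged = "red", pending = "orange",
            rejected = "gray50")
  for (ct in x$contours) {
    col <- cols[[ct$status]]
    graphics::lines(ct$points[c(seq_len(nrow(ct$points)), 1), 2],
                    ct$points[c(seq_len(nrow(ct$points)), 1), 1], col = col)
  }
  if (nrow(x$cells))
    graphics::text(x$cells$circle_col, x$cells$circle_row,
                   labels = sprintf("%.1f", x$cells$sr_um2), cex = 0.6,
                   col = "blue")
  invisible(x)
}

#' Measure smears for a set of subjects
#'
#' Runs [measure_smear()] on every field of view and pools the per-cell
#' records of each subject before summarizing, so a subject imaged over
#' several fields contributes a single row. Stage failures (unreadable
#' file, empty field) mark the subject as failed in the manifest instead
#' of aborting the run.
#'
#' @param inputs named list: one entry per subject, each a character
#'   vector of image paths or a list of [smear_image] objects.
#' @param config an [rbc_config()]; its calibration applies to images
#'   loaded from paths.
#' @param output_csv optional path; per-subject summaries are written as
#'   CSV.
#' @param manifest_json optional path for the JSON run manifest (config,
#'   per-image cell counts, failures).
#' @return Object of class `measure_run`: list with `summaries` (data
#'   frame, one row per subject incl. `failed` flag) and `manifest`.
#' @export
run_measure <- function(inputs, config = rbc_config(), output_csv = NULL,
                        manifest_json = NULL) {
  stopifnot(length(inputs) >= 1, !is.null(names(inputs)))
  per_image <- list()
  rows <- lapply(names(inputs), function(subj) {
    imgs <- inputs[[subj]]
    if (is.character(imgs)) imgs <- as.list(imgs)
    cells <- NULL
    err <- NULL
    for (im in imgs) {
      res <- tryCatch({
        simg <- if (inherits(im, "smear_image")) im
        else load_image(im, config$calibration$microns_per_pixel)
        meas <- measure_smear(simg, config)
        per_image[[length(per_image) + 1]] <<- list(
          subject = subj, source = simg$source_id,
          n_contours = length(meas$contours),
          n_effective = nrow(meas$cells),
          n_recall_rbc = meas$summary$n_rbc_measured)
        meas$cells
      }, error = function(e) e)
      if (inherits(res, "error")) {
        err <- conditionMessage(res)
        per_image[[length(per_image) + 1]] <<- list(
          subject = subj,
          source = if (is.character(im)) im else im$source_id,
          error = err)
      } else cells <- rbind(cells, res)
    }
    if (is.null(cells) && !is.null(err)) {
      out <- summarize_smear(
        data.frame(cell_class = character(), recall = logical(),
                   sr_um2 = numeric()), subj)
      out$failed <- TRUE
    } else {
      out <- summarize_smear(cells, subj, config$area$include_non_recall)
      out$failed <- FALSE
    }
    out
  })
  summaries <- do.call(rbind, rows)
  class(summaries) <- "data.frame"
  manifest <- list(package = "rbcmorph",
                   version = as.character(utils::packageVersion("rbcmorph")),
                   config = unclass(config), images = per_image)
  if (!is.null(output_csv))
    utils::write.csv(summaries, output_csv, row.names = FALSE)
  if (!is.null(manifest_json))
    jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  structure(list(summaries = summaries, manifest = manifest),
            class = "measure_run")
}

#' @export
print.measure_run <- function(x, ...) {
  cat(sprintf("<measure_run> %d subject(s), %d failed\n",
              nrow(x$summaries), sum(x$summaries$failed)))
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' Validates the schema expected by [analyze_cohort()]: required columns
#' `subject_id`, `group`, `mean_area_um2`; optional CBC columns `mcv_fl`,
#' `mch_pg`, `mchc_g_per_l`, `rdw_percent`. Group labels must come from
#' {normal, AA, MDS, MA} and subject ids must be unique.
#'
#' @param path CSV path.
#' @return A data frame of class `rbc_cohort`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "mean_area_um2")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("cohort CSV lacks required column(s): ",
         paste(missing, collapse = ", "))
  bad <- !df$group %in% c("normal", "AA", "MDS", "MA")
  if (any(bad))
    stop("invalid group label(s) in rows: ",
         paste(utils::head(which(bad), 10), collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  df$group <- factor(df$group, levels = c("normal", "AA", "MDS", "MA"))
  class(df) <- c("rbc_cohort", "data.frame")
  df
}

#' Cohort-level statistical analysis
#'
#' The full statistical workflow on a per-subject table: per-group
#' summaries with coefficients of variation, all pairwise group
#' comparisons dispatched on normality (see [compare_groups()]),
#' within-group correlations of area with each available CBC index, and
#' per-disease ROC analyses (each disease vs the normal group) for three
#' markers: RBC area, MCV, and the logistic-combined predicted
#' probability.
#'
#' @param cohort an `rbc_cohort` data frame (see [read_cohort()] /
#'   [generate_cohort()]).
#' @param config an [rbc_config()]; `stats$holm` applies a Holm
#'   adjustment across the pairwise comparisons.
#' @return Object of class `rbc_cohort_analysis`: list with
#'   `group_summaries`, `comparisons`, `correlations`, `roc`, `notes`.
#' @export
analyze_cohort <- function(cohort, config = rbc_config()) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort),
            "mean_area_um2" %in% names(cohort))
  alpha <- config$stats$alpha_normality
  groups <- levels(factor(cohort$group))
  groups <- groups[vapply(groups, function(g)
    sum(cohort$group == g) >= 2, logical(1))]
  notes <- character()
  area_of <- function(g) cohort$mean_area_um2[cohort$group == g]

  group_summaries <- do.call(rbind, lapply(groups, function(g) {
    a <- area_of(g)
    data.frame(group = g, n = length(a), mean_area_um2 = mean(a),
               sd_area_um2 = stats::sd(a), median_area_um2 = stats::median(a),
               iqr_area_um2 = stats::IQR(a),
               cv_percent = cv_percent(mean(a), stats::sd(a)),
               shapiro_p = tryCatch(shapiro_wilk(a)$p_value,
                                    error = function(e) NA_real_),
               stringsAsFactors = FALSE)
  }))

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  comparisons <- lapply(pairs, function(pr) {
    cmp <- compare_groups(area_of(pr[1]), area_of(pr[2]), alpha)
    cmp$groups <- pr
    cmp
  })
  names(comparisons) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  comparison_table <- data.frame(
    group_1 = vapply(pairs, `[`, character(1), 1),
    group_2 = vapply(pairs, `[`, character(1), 2),
    test_used = vapply(comparisons, `[[`, character(1), "test_used"),
    statistic = vapply(comparisons, `[[`, numeric(1), "statistic"),
    p_value = vapply(comparisons, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  if (isTRUE(config$stats$holm))
    comparison_table$p_holm <- stats::p.adjust(comparison_table$p_value,
                                               "holm")

  cbc_cols <- intersect(c("mcv_fl", "mch_pg", "mchc_g_per_l", "rdw_percent"),
                        names(cohort))
  skipped <- setdiff(c("mcv_fl", "mch_pg", "mchc_g_per_l", "rdw_percent"),
                     cbc_cols)
  if (length(skipped))
    notes <- c(notes, paste0("CBC column(s) absent, correlations skipped: ",
                             paste(skipped, collapse = ", ")))
  correlations <- NULL
  for (g in setdiff(groups, "normal")) {
    for (idx in cbc_cols) {
      sub <- cohort[cohort$group == g, ]
      ok <- is.finite(sub$mean_area_um2) & is.finite(sub[[idx]])
      if (sum(ok) < 4) next
      ct <- correlate(sub$mean_area_um2[ok], sub[[idx]][ok], alpha)
      correlations <- rbind(correlations, data.frame(
        group = g, index = idx, method = ct$method, r = ct$r,
        p_value = ct$p_value, n = sum(ok), stringsAsFactors = FALSE))
    }
  }

  roc <- NULL
  diseases <- intersect(c("AA", "MDS", "MA"), groups)
  if (!"normal" %in% groups) {
    notes <- c(notes, "no normal group: ROC analyses skipped")
  } else for (g in diseases) {
    sub <- cohort[cohort$group %in% c(g, "normal"), ]
    lab <- sub$group == g
    add <- function(res) {
      roc <<- rbind(roc, data.frame(
        disease = g, marker = res$marker, auc = res$auc,
        p_value = res$p_value, n_cases = res$n_cases,
        n_controls = res$n_controls, stringsAsFactors = FALSE))
    }
    add(roc_auc(sub$mean_area_um2, lab, TRUE, "area"))
    if ("mcv_fl" %in% cbc_cols && all(is.finite(sub$mcv_fl))) {
      add(roc_auc(sub$mcv_fl, lab, TRUE, "mcv"))
      comb <- combined_predictor(sub$mean_area_um2, sub$mcv_fl, lab, TRUE)
      if (comb$separation)
        notes <- c(notes, paste0(g, ": perfect separation in the combined ",
                                 "logistic model; AUC valid, coefficients not"))
      res <- roc_auc(comb$scores, lab, TRUE, "predicted_probability")
      add(res)
    } else {
      notes <- c(notes, paste0(g, ": MCV unavailable, single-marker ROC only"))
    }
  }

  structure(
    list(group_summaries = group_summaries, comparisons = comparisons,
         comparison_table = comparison_table, correlations = correlations,
         roc = roc, notes = notes),
    class = "rbc_cohort_analysis")
}

#' @export
print.rbc_cohort_analysis <- function(x, digits = 3, ...) {
  cat("Cohort analysis of RBC area\n\nGroup summaries:\n")
  print(format(x$group_summaries, digits = digits), row.names = FALSE)
  cat("\nPairwise comparisons:\n")
  print(format(x$comparison_table, digits = digits), row.names = FALSE)
  if (!is.null(x$correlations)) {
    cat("\nArea vs CBC correlations:\n")
    print(format(x$correlations, digits = digits), row.names = FALSE)
  }
  if (!is.null(x$roc)) {
    cat("\nROC (disease vs normal):\n")
    print(format(x$roc, digits = digits), row.names = FALSE)
  }
  if (length(x$notes)) cat("\nNotes:\n", paste("-", x$notes, collapse = "\n"),
                           "\n")
  invisible(x)
}

#' Run the cohort statistics stage from a CSV file
#'
#' Thin file-level wrapper over [read_cohort()] and [analyze_cohort()]
#' that optionally serializes the full report to JSON.
#'
#' @param cohort_csv path to a cohort CSV (see [read_cohort()]).
#' @param config an [rbc_config()].
#' @param report_json optional output path for the JSON report.
#' @return The `rbc_cohort_analysis`, invisibly when writing a report.
#' @export
run_stats <- function(cohort_csv, config = rbc_config(),
                      report_json = NULL) {
  res <- analyze_cohort(read_cohort(cohort_csv), config)
  if (!is.null(report_json)) {
    payload <- list(
      group_summaries = res$group_summaries,
      comparisons = res$comparison_table,
      correlations = res$correlations, roc = res$roc, notes = res$notes)
    jsonlite::write_json(payload, report_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, dataframe = "rows")
    return(invisible(res))
  }
  res
}
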