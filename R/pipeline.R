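#' Analysis run configuration
#'
#' Bundles the analysis constants applied to every section. Defaults are the
#' package's standard protocol: 0.61 um pixels, a 50 um sub-epidermal
#' expansion, a 5 um vessel-nerve proximity radius, marker MFIs normalized
#' to the pan-neuronal PGP9.5 reference, and per-subject aggregation as the
#' arithmetic mean over images (missing images dropped).
#'
#' @param pixel_size_um Isotropic pixel size in micrometers.
#' @param expansion_um Sub-epidermal band depth (default 50).
#' @param proximity_um Vessel-nerve proximity radius (default 5).
#' @param markers Marker channels to quantify.
#' @param reference_marker Normalization reference (pan-neuronal marker).
#' @param aggregate Per-subject aggregation over images: `"mean"` or
#'   `"median"`.
#' @param alpha Significance level for normality routing and tests.
#' @param exact_max_n Largest combined n for exact Mann-Whitney p-values.
#' @param seed Optional integer seed for any stochastic step.
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size_um = 0.61, expansion_um = 50, proximity_um = 5,
                       markers = c("PGP9.5", "TrkA", "CGRP", "GAP43"),
                       reference_marker = "PGP9.5",
                       aggregate = c("mean", "median"),
                       alpha = 0.05, exact_max_n = 20L, seed = NULL) {
  aggregate <- match.arg(aggregate)
  stopifnot(pixel_size_um > 0, expansion_um >= 0, proximity_um > 0)
  structure(list(
    pixel_size_um = pixel_size_um, expansion_um = expansion_um,
    proximity_um = proximity_um, markers = markers,
    reference_marker = reference_marker, aggregate = aggregate,
    alpha = alpha, exact_max_n = as.integer(exact_max_n), seed = seed
  ), class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' The configuration round-trips losslessly through YAML.
#'
#' @param config A [run_config].
#' @param path File path.
#' @return `read_run_config` returns a [run_config].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  run_config(
    pixel_size_um = doc$pixel_size_um, expansion_um = doc$expansion_um,
    proximity_um = doc$proximity_um, markers = unlist(doc$markers),
    reference_marker = doc$reference_marker, aggregate = doc$aggregate,
    alpha = doc$alpha, exact_max_n = doc$exact_max_n, seed = doc$seed
  )
}

#' Quantify one annotated section
#'
#' Runs the full per-image pipeline: ROI derivation (sub-epidermis,
#' basement membrane), IENFD per fiber marker, fiber areas and CGRP+/total
#' area ratios per region, marker MFIs within nerve fibers per region with
#' normalization to the reference marker, and dermal vessel-nerve metrics.
#'
#' @param section An `annotated_section` (from [generate_section] or
#'   [read_section]) with at least `epidermis`, `dermis` and `nerve` masks.
#' @param config A [run_config].
#' @return A one-row data.frame of section metrics; missing quantities
#'   (e.g. MFI where no fiber pixels fall in a region) are `NA`.
#' @export
quantify_section <- function(section, config = run_config()) {
  stopifnot(inherits(section, "annotated_section") || is.list(section))
  masks <- section$masks
  for (need in c("epidermis", "dermis", "nerve")) {
    if (is.null(masks[[need]])) {
      stop(sprintf("section lacks required mask '%s'", need), call. = FALSE)
    }
  }
  roi <- roi_set(masks$epidermis, masks$dermis, config$expansion_um)
  out <- list(length_mm = roi$membrane$length_mm)

  ien <- ienfd(masks$nerve, roi, marker = "PGP9.5")
  out$crossings_pgp95 <- ien$crossings
  out$ienfd_pgp95 <- ien$fibers_per_mm
  if (!is.null(masks$nerve_cgrp)) {
    ien_c <- ienfd(masks$nerve_cgrp, roi, marker = "CGRP")
    out$crossings_cgrp <- ien_c$crossings
    out$ienfd_cgrp <- ien_c$fibers_per_mm
  }

  regions <- list(epi = roi$epidermis, sub = roi$subepidermis)
  for (rn in names(regions)) {
    reg <- regions[[rn]]
    out[[paste0("nerve_area_", rn, "_um2")]] <- mask_area(masks$nerve, reg)
    if (!is.null(masks$nerve_cgrp)) {
      out[[paste0("cgrp_area_", rn, "_um2")]] <- mask_area(masks$nerve_cgrp, reg)
      out[[paste0("cgrp_area_ratio_", rn)]] <-
        area_ratio(masks$nerve_cgrp, masks$nerve, reg)
    }
  }

  ref_marker <- config$reference_marker
  for (rn in names(regions)) {
    reg <- regions[[rn]]
    roi_label <- if (rn == "epi") "epidermis" else "subepidermis"
    ref_rec <- NULL
    if (ref_marker %in% names(section$channels)) {
      ref_rec <- mfi(section$channels[[ref_marker]], masks$nerve, reg, roi_label)
    }
    for (marker in intersect(config$markers, names(section$channels))) {
      rec <- mfi(section$channels[[marker]], masks$nerve, reg, roi_label)
      key <- gsub("[^A-Za-z0-9]", "", tolower(marker))
      out[[paste0("mfi_", key, "_", rn)]] <- rec$mfi
      if (!identical(marker, ref_marker) && !is.null(ref_rec)) {
        nrec <- normalized_mfi(rec, ref_rec)
        out[[paste0("norm_mfi_", key, "_", rn)]] <- nrec$normalized_mfi
      }
    }
  }

  if (!is.null(masks$vessels)) {
    vm <- interaction_area(masks$vessels, masks$nerve, masks$dermis,
                           config$proximity_um)
    out$vessel_area_um2 <- vm$vessel_area_um2
    out$interaction_area_um2 <- vm$interaction_area_um2
    out$proximity_radius_um <- vm$proximity_radius_um
  }

  as.data.frame(out, stringsAsFactors = FALSE)
}

aggregate_images <- function(images_df, how = "mean") {
  num <- vapply(images_df, is.numeric, logical(1))
  f <- if (how == "median") {
    function(v) stats::median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  out <- lapply(images_df[num], function(v) {
    r <- f(v)
    if (is.nan(r)) NA_real_ else r
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Quantify all images of one subject
#'
#' @param sections List of `annotated_section`s (the subject's images).
#' @param subject Subject identifier.
#' @param config A [run_config].
#' @return List with `images` (one row per image) and `subject` (the
#'   aggregated row; arithmetic mean of per-image metrics by default,
#'   missing values dropped pairwise).
#' @export
run_subject <- function(sections, subject = "S001", config = run_config()) {
  if (inherits(sections, "annotated_section")) sections <- list(sections)
  rows <- lapply(seq_along(sections), function(i) {
    r <- quantify_section(sections[[i]], config)
    cbind(data.frame(subject = subject, image = i, stringsAsFactors = FALSE), r)
  })
  images <- do.call(rbind, rows)
  agg <- aggregate_images(images[setdiff(names(images), c("image"))],
                          config$aggregate)
  list(images = images,
       subject = cbind(data.frame(subject = subject, stringsAsFactors = FALSE), agg))
}

#' Quantify a whole synthetic cohort
#'
#' Generates each image from its stored [section_spec] and runs
#' [quantify_section], streaming so that only one section is in memory at a
#' time. A subject whose section cannot be built or quantified is skipped
#' with a message and the run continues.
#'
#' @param cohort A `skin_cohort` from [generate_cohort].
#' @param config A [run_config].
#' @param verbose Print progress.
#' @return List with `images` (per-image metric rows) and `subjects`
#'   (aggregated per subject, with group labels).
#' @export
quantify_cohort <- function(cohort, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(cohort, "skin_cohort"))
  rows <- list()
  for (entry in cohort$image_specs) {
    res <- tryCatch({
      section <- generate_section(entry$spec)
      r <- quantify_section(section, config)
      cbind(data.frame(subject = entry$subject, image = entry$image,
                       stringsAsFactors = FALSE), r)
    }, error = function(e) {
      message(sprintf("skipping %s image %d: %s", entry$subject, entry$image,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    if (verbose && length(rows) %% 20L == 0L) {
      message(sprintf("quantified %d / %d images", length(rows),
                      length(cohort$image_specs)))
    }
  }
  images <- do.call(rbind, rows)
  subj_rows <- lapply(split(images, images$subject), function(d) {
    agg <- aggregate_images(d[setdiff(names(d), "image")], config$aggregate)
    cbind(data.frame(subject = d$subject[1L], stringsAsFactors = FALSE), agg)
  })
  subjects <- do.call(rbind, subj_rows)
  rownames(subjects) <- NULL
  subjects <- merge(cohort$subjects[c("subject", "group")], subjects,
                    by = "subject", sort = TRUE)
  list(images = images, subjects = subjects)
}

contrast_pairs <- function(groups) {
  have <- unique(groups)
  pairs <- list(
    control_vs_bipn = list(x = "control", y = c("painless", "painful")),
    painless_vs_painful = list(x = "painless", y = "painful"),
    control_vs_painless = list(x = "control", y = "painless"),
    control_vs_painful = list(x = "control", y = "painful")
  )
  keep <- vapply(pairs, function(p) {
    all(p$x %in% have) && any(p$y %in% have)
  }, logical(1))
  pairs[keep]
}

comparison_row <- function(variable, contrast, x, y, config) {
  cmp <- compare_groups(x, y, alpha = config$alpha,
                        exact_max_n = config$exact_max_n)
  dx <- cmp$descriptives$x
  dy <- cmp$descriptives$y
  data.frame(
    variable = variable, contrast = contrast,
    n_x = dx$n, n_y = dy$n, route = cmp$route,
    statistic = cmp$statistic, p_value = cmp$p_value,
    median_x = dx$median, iqr_x = dx$iqr, median_y = dy$median, iqr_y = dy$iqr,
    mean_x = dx$mean, sd_x = dx$sd, mean_y = dy$mean, sd_y = dy$sd,
    stringsAsFactors = FALSE
  )
}

#' Cohort-level statistics report
#'
#' The statistics layer applied to per-subject metrics and ancillary tables:
#' normality-routed two-group comparisons for every numeric metric over the
#' standard contrast families (control vs all patients, painless vs painful,
#' and each subgroup vs control), contingency analyses of abnormality rates
#' with Yates/Fisher routing and odds ratios, QST z-score contrasts, and
#' qPCR fold-change contrasts against the control calibrator.
#'
#' @param subject_metrics Data.frame of per-subject metrics with columns
#'   `subject`, `group` plus numeric metric columns (from
#'   [quantify_cohort]`$subjects`).
#' @param clinical Optional list with elements `qst` (long raw QST), `ncs`
#'   (with `measure`, `value`, `ref_low`, `ref_high`) and `nrs`.
#' @param ct Optional qPCR Ct table (see [fold_change]).
#' @param norms QST norms table (required when `clinical$qst` is given).
#' @param config A [run_config].
#' @return List: `stats_report`, `contingency_report`, `folds`,
#'   `qst_scores`. Contrasts whose groups are absent are skipped with a
#'   message.
#' @export
run_cohort <- function(subject_metrics, clinical = NULL, ct = NULL,
                       norms = NULL, config = run_config()) {
  if (is.null(subject_metrics) || !nrow(subject_metrics)) {
    stop("empty subject metrics table: run quantify_cohort() first", call. = FALSE)
  }
  stopifnot(all(c("subject", "group") %in% names(subject_metrics)))
  pairs <- contrast_pairs(subject_metrics$group)
  if (!length(pairs)) {
    stop("no usable group contrast (need at least control plus one patient group)",
         call. = FALSE)
  }

  metric_cols <- names(subject_metrics)[vapply(subject_metrics, is.numeric, logical(1))]
  metric_cols <- setdiff(metric_cols, c("image", "proximity_radius_um"))

  report <- list()
  add_metric <- function(variable, values, groups) {
    for (cn in names(pairs)) {
      p <- pairs[[cn]]
      x <- values[groups %in% p$x]
      y <- values[groups %in% p$y]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      if (length(x) < 1L || length(y) < 1L) next
      report[[length(report) + 1L]] <<- comparison_row(variable, cn, x, y, config)
    }
  }
  for (m in metric_cols) {
    add_metric(m, subject_metrics[[m]], subject_metrics$group)
  }

  # qPCR fold changes
  folds <- NULL
  if (!is.null(ct)) {
    targets <- setdiff(unique(ct$gene), "RPL13A")
    fold_list <- lapply(targets, function(g) {
      fold_change(ct, target = g, calibrator_group = "control")
    })
    folds <- do.call(rbind, fold_list)
    for (g in targets) {
      d <- folds[folds$gene == g, ]
      add_metric(paste0("fold_", g), d$fold, d$group)
    }
  }

  # QST z-scores and abnormality rates
  qst_scores <- NULL
  contingency <- list()
  if (!is.null(clinical$qst)) {
    if (is.null(norms)) {
      stop("norms table required to score QST data", call. = FALSE)
    }
    qst_scores <- score_qst(clinical$qst, norms)
    qst_scores <- merge(qst_scores,
                        unique(clinical$qst[c("subject", "group")]),
                        by = "subject", sort = FALSE)
    for (p in unique(qst_scores$param)) {
      d <- qst_scores[qst_scores$param == p, ]
      add_metric(paste0("qst_z_", p), d$z, d$group)
      tab <- abnormal_table(d$status, d$group)
      if (!is.null(tab)) {
        contingency[[length(contingency) + 1L]] <-
          contingency_row(paste0("qst_", p), tab)
      }
    }
  }

  if (!is.null(clinical$ncs)) {
    ncs <- clinical$ncs
    ncs$status <- ifelse(is.na(ncs$value), "missing",
                         ifelse(ncs$value < ncs$ref_low | ncs$value > ncs$ref_high,
                                "abnormal", "normal"))
    for (m in unique(ncs$measure)) {
      d <- ncs[ncs$measure == m, ]
      add_metric(paste0("ncs_", m), d$value, d$group)
      tab <- abnormal_table(d$status, d$group)
      if (!is.null(tab)) {
        contingency[[length(contingency) + 1L]] <- contingency_row(paste0("ncs_", m), tab)
      }
    }
  }

  list(
    stats_report = if (length(report)) do.call(rbind, report) else NULL,
    contingency_report = if (length(contingency)) do.call(rbind, contingency) else NULL,
    folds = folds,
    qst_scores = qst_scores
  )
}

# painful vs painless 2x2 abnormality table (abnormal / normal columns)
abnormal_table <- function(status, group) {
  ok <- status != "missing"
  status <- status[ok]; group <- group[ok]
  if (!all(c("painful", "painless") %in% group)) return(NULL)
  contingency2x2(
    sum(group == "painful" & status == "abnormal"),
    sum(group == "painful" & status == "normal"),
    sum(group == "painless" & status == "abnormal"),
    sum(group == "painless" & status == "normal"),
    rows = c("painful", "painless")
  )
}

contingency_row <- function(variable, tab) {
  v <- as.numeric(t(tab))
  n <- sum(v)
  expected_min <- if (n > 0) {
    min(outer(rowSums(tab), colSums(tab)) / n)
  } else 0
  if (expected_min < 5) {
    ft <- fisher_exact(tab)
    test <- "fisher_exact"
    statistic <- NA_real_
    p <- ft$p_value
  } else {
    cy <- chi2_yates(tab)
    test <- "chi2_yates"
    statistic <- cy$statistic
    p <- cy$p_value
  }
  or <- odds_ratio(tab)
  data.frame(
    variable = variable, a = v[1], b = v[2], c = v[3], d = v[4],
    test = test, statistic = statistic, p_value = p,
    or = or$or, or_low = or$ci[1], or_high = or$ci[2],
    or_corrected = or$corrected,
    stringsAsFactors = FALSE
  )
}
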