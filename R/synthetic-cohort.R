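#' Specification of a synthetic study cohort
#'
#' Defines a three-group cohort (healthy controls, painless neuropathy,
#' painful neuropathy) with planted group effects on every readout the
#' pipeline measures: intraepidermal fiber density, TrkA fiber intensity,
#' dermal vessel area, vessel-nerve interaction (elevated in the painless
#' subgroup only), qPCR fold changes, sensory-loss shifts in QST, and
#' nerve-conduction abnormality rates. Every subject receives two images.
#'
#' @param n_control,n_painless,n_painful Subjects per group (>= 3 each, the
#'   minimum for downstream normality testing).
#' @param section_template A [section_spec] used for every image; per-image
#'   seeds, fiber counts, TrkA intensity and vessels are derived from it.
#' @param ienfd_multiplier Patient-group multiplier on the crossing-fiber
#'   rate (both subgroups).
#' @param trka_multiplier Patient-group multiplier on TrkA fiber intensity.
#' @param vessel_multiplier Patient-group multiplier on vessel cross-section
#'   area (applied to vessel radii as its square root).
#' @param interaction_multiplier_painless,interaction_multiplier_painful
#'   Multiplier on the number of near (interacting) vessels per image.
#' @param ngf_fold_painless,ngf_fold_painful,trka_rna_fold Planted qPCR fold
#'   changes versus the control calibrator group.
#' @param base_crossings_per_image Control-group mean crossing fibers per
#'   image.
#' @param subject_cv Lognormal inter-subject coefficient of variation applied
#'   to fiber rate, TrkA intensity and vessel size.
#' @param base_near_vessels,near_vessel_dist_um Near-vessel count per image
#'   and their planted center-to-fiber distance (inside the proximity
#'   region).
#' @param far_vessels,far_vessel_dist_um Non-interacting vessel count and
#'   distance.
#' @param vessel_radius_um Base vessel radius.
#' @param qst_loss_shift Mean loss-of-function z-shift planted on detection
#'   thresholds (CDT, WDT, TSL, MDT, VDT) in patients.
#' @param snap_abnormal_rate Named vector of sural-SNAP abnormality
#'   probabilities per group.
#' @param ct_base_dct Named base delta-Ct (target minus reference) per gene.
#' @param ct_subject_sd,ct_replicate_sd Ct noise (cycles) between subjects /
#'   between replicates.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 20L, n_painless = 20L, n_painful = 20L,
                        section_template = section_spec(),
                        ienfd_multiplier = 0.5,
                        trka_multiplier = 5,
                        vessel_multiplier = 1.4,
                        interaction_multiplier_painless = 3,
                        interaction_multiplier_painful = 1,
                        ngf_fold_painless = 0.65,
                        ngf_fold_painful = 0.92,
                        trka_rna_fold = 0.66,
                        base_crossings_per_image = 8,
                        subject_cv = 0.15,
                        base_near_vessels = 2L,
                        near_vessel_dist_um = 4,
                        far_vessels = 3L,
                        far_vessel_dist_um = 20,
                        vessel_radius_um = 3,
                        qst_loss_shift = 1.5,
                        snap_abnormal_rate = c(control = 0.02, painless = 0.5,
                                               painful = 0.84),
                        ct_base_dct = c(TrkA = 8, NGF = 10),
                        ct_subject_sd = 0.25,
                        ct_replicate_sd = 0.1,
                        seed = 1L) {
  ns <- c(control = n_control, painless = n_painless, painful = n_painful)
  if (any(ns < 3L)) {
    stop("need at least 3 subjects per group (normality-test minimum)", call. = FALSE)
  }
  mult <- c(ienfd_multiplier, trka_multiplier, vessel_multiplier,
            interaction_multiplier_painless, interaction_multiplier_painful,
            ngf_fold_painless, ngf_fold_painful, trka_rna_fold)
  if (any(mult <= 0)) stop("all multipliers must be > 0", call. = FALSE)
  structure(as.list(environment()), class = "cohort_spec")
}

group_mult <- function(group, patient_value) {
  ifelse(group == "control", 1, patient_value)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Builds the subject table, two per-image [section_spec]s per subject
#' (images are generated lazily by [quantify_cohort] to bound memory),
#' clinical tables (QST raw values against the packaged synthetic norms,
#' nerve-conduction values with planted abnormality rates, pain ratings) and
#' qPCR Ct triplicates with planted group folds, plus a truth manifest of
#' every planted parameter.
#'
#' The two images of a subject carry `floor(rate)` and `ceiling(rate)`
#' crossing fibers so the subject mean tracks the subject's continuous fiber
#' rate without per-image count noise.
#'
#' @param spec A [cohort_spec].
#' @param norms QST norms table; default the packaged synthetic norms.
#' @return An object of class `skin_cohort`: `subjects`, `image_specs` (list
#'   of `(subject, image, spec)`), `clinical` (`qst`, `ncs`, `nrs`), `ct`,
#'   and `truth`.
#' @export
generate_cohort <- function(spec, norms = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(norms)) {
    norms <- read_qst_norms(system.file("extdata", "synthetic_qst_norms.yaml",
                                        package = "skinquant"))
  } else {
    norms <- validate_qst_norms(norms)
  }
  with_seed(spec$seed, generate_cohort_impl(spec, norms))
}

generate_cohort_impl <- function(spec, norms) {
  groups <- rep(c("control", "painless", "painful"),
                times = c(spec$n_control, spec$n_painless, spec$n_painful))
  n_sub <- length(groups)
  subjects <- data.frame(
    subject = sprintf("S%03d", seq_len(n_sub)),
    group = groups,
    stringsAsFactors = FALSE
  )

  sdlog <- sqrt(log(1 + spec$subject_cv^2))
  rln <- function(n) stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  subjects$f_ienfd <- rln(n_sub)
  subjects$f_trka <- rln(n_sub)
  subjects$f_vessel <- rln(n_sub)
  subjects$btz_cycles <- ifelse(groups == "control", NA_integer_,
                                sample(2:8, n_sub, replace = TRUE))

  template <- spec$section_template
  base_trka <- template$channels[["TrkA"]]$fiber_mean %||% 400

  image_specs <- vector("list", 2L * n_sub)
  ii <- 0L
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    rate <- spec$base_crossings_per_image *
      group_mult(g, spec$ienfd_multiplier) * subjects$f_ienfd[i]
    counts <- c(floor(rate), ceiling(rate))
    trka_mean <- base_trka * group_mult(g, spec$trka_multiplier) * subjects$f_trka[i]
    r_scale <- sqrt(group_mult(g, spec$vessel_multiplier) * subjects$f_vessel[i])
    n_near <- round(spec$base_near_vessels * switch(
      g, painless = spec$interaction_multiplier_painless,
      painful = spec$interaction_multiplier_painful, 1
    ))
    # near vessels keep the base radius so the interaction area tracks the
    # planted interaction multiplier alone; the patient vessel-area increase
    # is carried by the far (non-interacting) vessels
    vessels <- data.frame(
      radius_um = c(rep(spec$vessel_radius_um, n_near),
                    rep(spec$vessel_radius_um * r_scale, spec$far_vessels)),
      target_dist_um = c(rep(spec$near_vessel_dist_um, n_near),
                         rep(spec$far_vessel_dist_um, spec$far_vessels))
    )
    for (img in 1:2) {
      s <- template
      s$n_crossing_fibers <- as.integer(counts[img])
      s$channels[["TrkA"]]$fiber_mean <- trka_mean
      s$vessels <- vessels
      s$seed <- derive_seed(spec$seed, i * 13L + img)
      ii <- ii + 1L
      image_specs[[ii]] <- list(subject = subjects$subject[i], image = img, spec = s)
    }
  }

  # ---- QST raw values -----------------------------------------------------
  loss_params <- c("CDT", "WDT", "TSL", "MDT", "VDT")
  qst_rows <- list()
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    for (j in seq_len(nrow(norms))) {
      p <- norms$param[j]
      shift <- if (g != "control" && p %in% loss_params) -spec$qst_loss_shift else 0
      z_true <- stats::rnorm(1, shift, 1)
      dx <- norms$mean[j] + norms$sign[j] * z_true * norms$sd[j]
      raw <- if (norms$domain[j] == "log10") 10^dx else dx
      qst_rows[[length(qst_rows) + 1L]] <- data.frame(
        subject = subjects$subject[i], group = g, param = p,
        stratum = norms$stratum[j], value = raw, stringsAsFactors = FALSE
      )
    }
  }
  qst <- do.call(rbind, qst_rows)

  # ---- nerve conduction (sural / median SNAP) -----------------------------
  ncs_ref <- data.frame(
    measure = c("sural_snap_uV", "median_snap_uV"),
    ref_low = c(6, 10),
    ref_high = c(50, 60),
    stringsAsFactors = FALSE
  )
  median_rate <- c(control = 0.02, painless = 0.17, painful = 0.26)
  ncs_rows <- list()
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    for (j in seq_len(nrow(ncs_ref))) {
      rate <- if (ncs_ref$measure[j] == "sural_snap_uV") {
        spec$snap_abnormal_rate[[g]]
      } else {
        median_rate[[g]]
      }
      abn <- stats::runif(1) < rate
      lowv <- ncs_ref$ref_low[j]
      value <- if (abn) {
        stats::runif(1, 0, lowv * 0.9)
      } else {
        stats::runif(1, lowv * 1.1, lowv * 1.1 + (ncs_ref$ref_high[j] - lowv))
      }
      ncs_rows[[length(ncs_rows) + 1L]] <- data.frame(
        subject = subjects$subject[i], group = g,
        measure = ncs_ref$measure[j], value = value,
        ref_low = lowv, ref_high = ncs_ref$ref_high[j],
        stringsAsFactors = FALSE
      )
    }
  }
  ncs <- do.call(rbind, ncs_rows)

  # ---- pain ratings -------------------------------------------------------
  nrs <- data.frame(
    subject = subjects$subject,
    group = groups,
    nrs_max_week = vapply(groups, function(g) {
      switch(g,
             painful = sample(4:10, 1L),
             painless = sample(c(0L, 0L, 0L, 1L, 2L, 3L), 1L),
             0L)
    }, integer(1)),
    stringsAsFactors = FALSE
  )

  # ---- qPCR Ct triplicates ------------------------------------------------
  fold_of <- function(gene, g) {
    if (g == "control") return(1)
    switch(gene,
           TrkA = spec$trka_rna_fold,
           NGF = if (g == "painless") spec$ngf_fold_painless else spec$ngf_fold_painful)
  }
  ct_rows <- list()
  for (i in seq_len(n_sub)) {
    g <- groups[i]
    ref_ct <- 18 + stats::rnorm(1, 0, 0.15)
    for (gene in names(spec$ct_base_dct)) {
      dct_true <- spec$ct_base_dct[[gene]] - log2(fold_of(gene, g)) +
        stats::rnorm(1, 0, spec$ct_subject_sd)
      for (rep_i in 1:3) {
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          sample = subjects$subject[i], group = g, gene = gene, replicate = rep_i,
          ct = ref_ct + dct_true + stats::rnorm(1, 0, spec$ct_replicate_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    for (rep_i in 1:3) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        sample = subjects$subject[i], group = g, gene = "RPL13A", replicate = rep_i,
        ct = ref_ct + stats::rnorm(1, 0, spec$ct_replicate_sd),
        stringsAsFactors = FALSE
      )
    }
  }
  ct <- do.call(rbind, ct_rows)

  structure(list(
    spec = spec,
    subjects = subjects[c("subject", "group", "btz_cycles")],
    image_specs = image_specs,
    clinical = list(qst = qst, ncs = ncs, nrs = nrs),
    ct = ct,
    norms = norms,
    truth = list(
      ienfd_multiplier = spec$ienfd_multiplier,
      trka_multiplier = spec$trka_multiplier,
      vessel_multiplier = spec$vessel_multiplier,
      interaction_multiplier_painless = spec$interaction_multiplier_painless,
      interaction_multiplier_painful = spec$interaction_multiplier_painful,
      ngf_fold_painless = spec$ngf_fold_painless,
      ngf_fold_painful = spec$ngf_fold_painful,
      trka_rna_fold = spec$trka_rna_fold,
      subject_factors = subjects[c("subject", "group", "f_ienfd", "f_trka", "f_vessel")]
    )
  ), class = "skin_cohort")
}

#' @export
print.skin_cohort <- function(x, ...) {
  cat(sprintf("<skin_cohort> %d subjects (%s), %d images\n",
              nrow(x$subjects),
              paste(sprintf("%s=%d", names(table(x$subjects$group)),
                            table(x$subjects$group)), collapse = ", "),
              length(x$image_specs)))
  invisible(x)
}
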