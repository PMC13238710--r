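#' Relative gene expression by the 2^-ddCt method
#'
#' Livak relative quantification from qPCR Ct triplicates: per sample,
#' `dCt = mean(Ct_target) - mean(Ct_reference)`; `ddCt = dCt - mean(dCt over
#' the calibrator group)`; `fold = 2^-ddCt`. The calibrator-group baseline is
#' the arithmetic mean of calibrator dCts, so the geometric mean of
#' calibrator fold changes is 1 by construction.
#'
#' @param ct Data.frame with columns `sample`, `gene`, `ct`, `group` and
#'   optionally `replicate`. Ct values must lie in (0, 40].
#' @param target Target gene name (e.g. `"TrkA"`, `"NGF"`).
#' @param reference Reference (housekeeping) gene name; default `"RPL13A"`.
#' @param calibrator_group Group label whose mean dCt is the baseline
#'   (e.g. `"control"`).
#' @param sd_flag_threshold Replicate SD (cycles) above which a sample is
#'   flagged for review (common lab QC; flagged samples are retained).
#' @return Data.frame, one row per sample: `sample`, `group`, `gene`,
#'   `ct_target`, `ct_reference`, `dct`, `ddct`, `fold`, `replicate_sd_flag`.
#'   Samples missing a usable reference or target Ct are excluded with a
#'   message.
#' @export
fold_change <- function(ct, target, reference = "RPL13A", calibrator_group,
                        sd_flag_threshold = 0.5) {
  stopifnot(all(c("sample", "gene", "ct", "group") %in% names(ct)))
  bad <- !is.na(ct$ct) & (ct$ct <= 0 | ct$ct > 40)
  if (any(bad)) {
    warning(sprintf("%d Ct value(s) outside (0, 40] dropped", sum(bad)),
            call. = FALSE)
    ct$ct[bad] <- NA_real_
  }
  ct <- ct[!is.na(ct$ct), , drop = FALSE]

  agg_gene <- function(gene) {
    d <- ct[ct$gene == gene, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("no Ct values for gene '%s'", gene), call. = FALSE)
    means <- tapply(d$ct, d$sample, mean)
    sds <- tapply(d$ct, d$sample, function(x) if (length(x) > 1L) stats::sd(x) else 0)
    data.frame(sample = names(means), mean_ct = as.numeric(means),
               sd_ct = as.numeric(sds), stringsAsFactors = FALSE)
  }
  tg <- agg_gene(target)
  rf <- agg_gene(reference)

  groups <- unique(ct[c("sample", "group")])
  if (anyDuplicated(groups$sample)) {
    stop("a sample is assigned to more than one group", call. = FALSE)
  }

  m <- merge(merge(tg, rf, by = "sample", suffixes = c("_target", "_reference")),
             groups, by = "sample", sort = FALSE)
  dropped <- setdiff(union(tg$sample, rf$sample), m$sample)
  if (length(dropped)) {
    message("excluded sample(s) missing target or reference Ct: ",
            paste(dropped, collapse = ", "))
  }

  if (!any(m$group == calibrator_group)) {
    stop(sprintf("calibrator group '%s' is empty", calibrator_group), call. = FALSE)
  }

  m$dct <- m$mean_ct_target - m$mean_ct_reference
  baseline <- mean(m$dct[m$group == calibrator_group])
  m$ddct <- m$dct - baseline
  m$fold <- 2^(-m$ddct)
  m$replicate_sd_flag <- m$sd_ct_target > sd_flag_threshold |
    m$sd_ct_reference > sd_flag_threshold

  out <- data.frame(
    sample = m$sample,
    group = m$group,
    gene = target,
    ct_target = m$mean_ct_target,
    ct_reference = m$mean_ct_reference,
    dct = m$dct,
    ddct = m$ddct,
    fold = m$fold,
    replicate_sd_flag = m$replicate_sd_flag,
    stringsAsFactors = FALSE
  )
  out[order(out$sample), ]
}
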