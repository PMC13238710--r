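#' Quantitative sensory testing parameter set
#'
#' The standardized QST battery parameters and which of them are z-scored in
#' the log10 domain. CPT and HPT are scored in the linear domain; all other
#' parameters are log10-transformed before z-scoring.
#'
#' @return A data.frame with columns `param` and `domain`
#'   (`"log10"`/`"linear"`).
#' @export
qst_parameters <- function() {
  log10_params <- c("CDT", "WDT", "TSL", "PPT", "MPT", "MPS", "WUR", "MDT", "VDT")
  linear_params <- c("CPT", "HPT")
  data.frame(
    param = c(log10_params, linear_params),
    domain = c(rep("log10", length(log10_params)),
               rep("linear", length(linear_params))),
    stringsAsFactors = FALSE
  )
}

#' Read a QST reference-norms table
#'
#' Norms are supplied by the user (published normative values are not
#' bundled); a synthetic norms table with the same schema ships with the
#' package for testing (`system.file("extdata", "synthetic_qst_norms.yaml",
#' package = "skinquant")`).
#'
#' Schema (one entry per parameter x age/sex stratum; stratum keys are
#' free-form): `param`, `stratum`, `domain` (`log10`/`linear`), `sign`
#' (+1 = larger transformed value means gain of function), `mean`, `sd` in
#' the analysis domain, and optional `ref_low`/`ref_high` 95% reference
#' bounds in the analysis domain (default `mean +/- 1.96 sd`).
#'
#' @param path Path to a YAML file with a top-level `parameters` list.
#' @return A validated data.frame of norms.
#' @export
read_qst_norms <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$parameters)) {
    stop("norms file must contain a top-level `parameters` list", call. = FALSE)
  }
  rows <- lapply(doc$parameters, function(p) {
    data.frame(
      param = as.character(p$param),
      stratum = as.character(p$stratum %||% "all"),
      domain = as.character(p$domain %||% "linear"),
      sign = as.numeric(p$sign %||% 1),
      mean = as.numeric(p$mean),
      sd = as.numeric(p$sd),
      ref_low = as.numeric(p$ref_low %||% NA),
      ref_high = as.numeric(p$ref_high %||% NA),
      stringsAsFactors = FALSE
    )
  })
  norms <- do.call(rbind, rows)
  validate_qst_norms(norms)
}

#' @rdname read_qst_norms
#' @param norms A data.frame following the norms schema.
#' @export
validate_qst_norms <- function(norms) {
  needed <- c("param", "stratum", "domain", "sign", "mean", "sd")
  missing_cols <- setdiff(needed, names(norms))
  if (length(missing_cols)) {
    stop("norms table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(!norms$domain %in% c("log10", "linear"))) {
    stop("norms `domain` must be 'log10' or 'linear'", call. = FALSE)
  }
  if (any(!norms$sign %in% c(-1, 1))) {
    stop("norms `sign` must be +1 or -1", call. = FALSE)
  }
  if (any(!is.finite(norms$sd)) || any(norms$sd <= 0)) {
    stop("norms `sd` must be positive", call. = FALSE)
  }
  if (!"ref_low" %in% names(norms)) norms$ref_low <- NA_real_
  if (!"ref_high" %in% names(norms)) norms$ref_high <- NA_real_
  z95 <- stats::qnorm(0.975)
  norms$ref_low <- ifelse(is.na(norms$ref_low), norms$mean - z95 * norms$sd, norms$ref_low)
  norms$ref_high <- ifelse(is.na(norms$ref_high), norms$mean + z95 * norms$sd, norms$ref_high)
  if (any(norms$ref_low >= norms$ref_high)) {
    stop("norms reference interval must have lower < upper", call. = FALSE)
  }
  if (anyDuplicated(norms[c("param", "stratum")])) {
    stop("duplicated (param, stratum) entries in norms", call. = FALSE)
  }
  norms
}

# Transform a raw value into the analysis domain; non-positive values where
# log10 is mandated become NA (flagged by the caller).
to_domain <- function(x, domain) {
  if (domain == "log10") {
    out <- rep(NA_real_, length(x))
    ok <- !is.na(x) & x > 0
    out[ok] <- log10(x[ok])
    out
  } else {
    x
  }
}

#' DFNS-style z-score of a sensory parameter
#'
#' `z = sign * (domain(x) - mean) / sd`, where `domain(x)` is `log10(x)` for
#' log-normal parameters and `x` otherwise, and `sign` flips the axis so a
#' positive z-score always indicates gain of sensory function and a negative
#' z-score loss of function.
#'
#' @param x Raw parameter value(s).
#' @param mean,sd Reference mean and SD in the analysis domain (`sd > 0`).
#' @param sign +1 or -1 (gain/loss axis multiplier).
#' @param domain `"linear"` or `"log10"`.
#' @return Numeric z-score(s); `NA` (with a warning) where a log10 transform
#'   is required but `x <= 0`.
#' @examples
#' z_score(2.0, mean = 0.1, sd = 0.2, sign = -1, domain = "log10")  # about -1
#' @export
z_score <- function(x, mean, sd, sign = 1, domain = c("linear", "log10")) {
  domain <- match.arg(domain)
  if (!is_scalar_number(sd) || sd <= 0) stop("`sd` must be > 0", call. = FALSE)
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1", call. = FALSE)
  dx <- to_domain(x, domain)
  if (domain == "log10" && any(!is.na(x) & x <= 0)) {
    warning("non-positive value(s) under log10 transform scored as missing",
            call. = FALSE)
  }
  sign * (dx - mean) / sd
}

#' Classify a value against a 95% reference interval
#'
#' Both tails are abnormal (hyper- and hyposensitivity alike); boundary
#' values count as normal (closed interval). Missing values propagate as
#' `"missing"` and are excluded from denominators downstream.
#'
#' @param x Value(s) in the same domain as the interval.
#' @param lower,upper Reference interval bounds (`lower < upper`).
#' @return Character vector in `{"normal", "abnormal", "missing"}`.
#' @export
classify_reference_range <- function(x, lower, upper) {
  if (!is_scalar_number(lower) || !is_scalar_number(upper) || lower >= upper) {
    stop("need a valid interval with lower < upper", call. = FALSE)
  }
  out <- ifelse(is.na(x), "missing",
                ifelse(x < lower | x > upper, "abnormal", "normal"))
  as.character(out)
}

#' Categorize numerical pain rating scale values
#'
#' Bands the 0-10 NRS (maximum rating in the last week) into
#' none (0), mild (1-3), moderate (4-6) and severe (>= 7). When an adjusted
#' NRS (corrected for reported relief under pain medication) is available it
#' should be supplied as `x`; the adjustment itself is an upstream clinical
#' step, flagged here via `adjusted`.
#'
#' @param x Integer NRS value(s) in 0..10.
#' @param adjusted Logical flag(s): value already medication-adjusted
#'   (metadata only).
#' @return Factor with levels `none < mild < moderate < severe` and an
#'   `adjusted` attribute.
#' @export
nrs_category <- function(x, adjusted = FALSE) {
  if (any(is.na(x)) || any(x != round(x)) || any(x < 0) || any(x > 10)) {
    stop("NRS values must be integers in 0..10", call. = FALSE)
  }
  lev <- c("none", "mild", "moderate", "severe")
  cat <- cut(x, breaks = c(-0.5, 0.5, 3.5, 6.5, 10.5), labels = lev,
             ordered_result = TRUE)
  attr(cat, "adjusted") <- rep_len(as.logical(adjusted), length(x))
  cat
}

#' Score a QST table against reference norms
#'
#' Joins long-format raw QST data with a norms table, computes the signed
#' z-score of each value, and classifies it against the stratum's 95%
#' reference interval.
#'
#' @param raw Data.frame with columns `subject`, `param`, `value` and
#'   optionally `stratum` (default `"all"`).
#' @param norms A norms table ([read_qst_norms] / [validate_qst_norms]).
#' @return Data.frame with columns `subject`, `param`, `stratum`, `value`,
#'   `z`, `direction` (`"gain"`/`"loss"`/`NA`) and `status`
#'   (`normal`/`abnormal`/`missing`).
#' @export
score_qst <- function(raw, norms) {
  norms <- validate_qst_norms(norms)
  stopifnot(all(c("subject", "param", "value") %in% names(raw)))
  if (!"stratum" %in% names(raw)) raw$stratum <- "all"
  m <- merge(raw, norms, by = c("param", "stratum"), all.x = TRUE, sort = FALSE)
  if (anyNA(m$mean)) {
    miss <- unique(m$param[is.na(m$mean)])
    stop("no norms entry for: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  dx <- numeric(nrow(m))
  for (i in seq_len(nrow(m))) dx[i] <- to_domain(m$value[i], m$domain[i])
  m$z <- m$sign * (dx - m$mean) / m$sd
  m$status <- ifelse(is.na(dx), "missing",
                     ifelse(dx < m$ref_low | dx > m$ref_high, "abnormal", "normal"))
  m$direction <- ifelse(is.na(m$z), NA_character_,
                        ifelse(m$z > 0, "gain", "loss"))
  m[order(m$subject, m$param),
    c("subject", "param", "stratum", "value", "z", "direction", "status")]
}

#' Abnormality rate with explicit missing-data denominator
#'
#' Fraction abnormal among non-missing values, reported together with the
#' evaluable denominator (missing values are excluded, not counted as
#' normal).
#'
#' @param status Character vector from [classify_reference_range] or
#'   [score_qst].
#' @return List with `n_abnormal`, `n_evaluable`, `n_missing`, `rate`.
#' @export
abnormality_rate <- function(status) {
  n_missing <- sum(status == "missing")
  n_eval <- sum(status != "missing")
  n_abn <- sum(status == "abnormal")
  list(
    n_abnormal = n_abn,
    n_evaluable = n_eval,
    n_missing = n_missing,
    rate = if (n_eval > 0) n_abn / n_eval else NA_real_
  )
}
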