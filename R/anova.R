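#' Repeated-measures ANOVA of the cell table
#'
#' Fits the fully within-subject design with the 3-day cycle as the
#' observational unit: day condition (3 levels) and time-of-day interval
#' (3 levels) as within factors, with cycle number — and, for variable
#' day-length phases, day length — entered as centred continuous covariates
#' whose interactions with each factor are estimated inside that factor's
#' error stratum. Sum-to-zero contrasts and the balanced within grid make
#' the sequential sums of squares equal the marginal (Type III) ones.
#' Partial eta-squared for each effect uses the residual of its own stratum.
#'
#' The printed error degrees of freedom follow the usual repeated-measures
#' accounting: a stratum for a `df_f`-df factor starts with
#' `(n_units - 1) * df_f` df, and each covariate interaction estimated in
#' the stratum consumes `df_f` of them (see [rm_error_df()]).
#'
#' @param cells A `cell_table` from [cell_means()]; all cells entering the
#'   design must be non-missing.
#' @param covariates Character vector among `"cycle"` and `"day_length"`.
#' @param response Name of the response column.
#' @return An `anova_result` tibble: `stratum`, `effect`, `sum_sq`, `df`,
#'   `mean_sq`, `f_value`, `p_value`, `partial_eta_sq` (residual rows have
#'   effect `"Residual"`).
#' @export
rm_anova <- function(cells, covariates = "cycle", response = "mean_motion") {
  rm_anova_engine(cells, within = c("condition", "interval"),
                  covariates = covariates, response = response)
}

#' Simple-effects ANOVA at one time-of-day interval
#'
#' Restricts the cell table to a single time-of-day interval and analyses
#' the remaining condition-by-cycle design with the same engine as
#' [rm_anova()].
#'
#' @inheritParams rm_anova
#' @param interval One of `"pre-light"`, `"light-on"`, `"post-light"`.
#' @return An `anova_result` tibble.
#' @export
simple_effects <- function(cells, interval, covariates = "cycle",
                           response = "mean_motion") {
  if (!interval %in% INTERVALS) {
    stop_domain("`interval` must be one of pre-light, light-on, post-light.",
                "stats_error")
  }
  sub <- cells[cells$interval == interval, , drop = FALSE]
  rm_anova_engine(sub, within = "condition", covariates = covariates,
                  response = response)
}

rm_anova_engine <- function(cells, within, covariates, response) {
  stopifnot(all(within %in% names(cells)))
  covariates <- match.arg(covariates, c("cycle", "day_length"),
                          several.ok = TRUE)
  d <- as.data.frame(cells)
  d$y <- d[[response]]
  if (any(!is.finite(d$y))) {
    stop_domain("Missing cells in the design; repeated-measures ANOVA needs a complete table.",
                "stats_error")
  }
  units <- sort(unique(d$cycle))
  if (length(units) < 2L) {
    stop_domain("Need >= 2 observational units (cycles).", "stats_error")
  }
  d$subj <- factor(d$cycle)
  d$condition <- factor(d$condition, levels = CONDITIONS)
  if ("interval" %in% within) {
    d$interval <- factor(d$interval, levels = INTERVALS)
  }
  cov_cols <- character(0)
  if ("cycle" %in% covariates) {
    d$cycle_c <- d$cycle - mean(units)
    cov_cols <- c(cov_cols, "cycle_c")
  }
  if ("day_length" %in% covariates) {
    if (is.null(d$day_length_h) || any(is.na(d$day_length_h))) {
      stop_domain("Cell table has no day_length_h column for the day_length covariate.",
                  "stats_error")
    }
    d$day_length_c <- d$day_length_h - mean(d$day_length_h)
    cov_cols <- c(cov_cols, "day_length_c")
  }
  w <- paste(within, collapse = " * ")
  rhs <- if (length(cov_cols)) {
    sprintf("(%s) * (%s)", w, paste(cov_cols, collapse = " + "))
  } else {
    w
  }
  form <- stats::as.formula(
    sprintf("y ~ %s + Error(subj/(%s))", rhs, w)
  )
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fit <- aov(form, data = d)
  tidy_aov_strata(fit)
}

# Flatten a multistratum aov summary into one tidy table with partial
# eta-squared computed against each stratum's residual.
tidy_aov_strata <- function(fit) {
  s <- summary(fit)
  rows <- list()
  for (stratum_name in names(s)) {
    tab <- s[[stratum_name]][[1]]
    if (is.null(tab)) next
    nm <- trimws(rownames(tab))
    stratum <- sub("^Error: ", "", stratum_name)
    stratum <- gsub("subj", "unit", stratum)
    res_i <- which(nm == "Residuals")
    ss_res <- if (length(res_i)) tab[res_i, "Sum Sq"] else NA_real_
    for (i in seq_len(nrow(tab))) {
      eff <- pretty_effect(nm[i])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        stratum = stratum,
        effect = eff,
        sum_sq = tab[i, "Sum Sq"],
        df = tab[i, "Df"],
        mean_sq = tab[i, "Mean Sq"],
        f_value = if ("F value" %in% colnames(tab)) tab[i, "F value"] else NA_real_,
        p_value = if ("Pr(>F)" %in% colnames(tab)) tab[i, "Pr(>F)"] else NA_real_,
        partial_eta_sq = if (eff != "Residual" && length(res_i) &&
                             (tab[i, "Sum Sq"] + ss_res) > 0) {
          tab[i, "Sum Sq"] / (tab[i, "Sum Sq"] + ss_res)
        } else {
          NA_real_
        }
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("anova_result", class(out))
  out
}

pretty_effect <- function(x) {
  if (x == "Residuals") return("Residual")
  x <- gsub("cycle_c", "cycle", x)
  x <- gsub("day_length_c", "day_length", x)
  x
}

#' Stratify per-cycle anticipation differences by day length
#'
#' Partitions cycles into those whose randomly drawn day length falls inside
#' the band (default 12-24 h, both ends inclusive) and those outside it, and
#' summarises the anticipation statistic in each group. A learning-curve fit
#' is attached for the in-band group when at least two in-band cycles exist.
#'
#' @param differences Tibble from [motion_difference()] with columns
#'   `cycle`, `day_length_h`, `motion_diff`.
#' @param band Length-2 numeric, inclusive day-length band in hours.
#' @param log_base Base for the in-band learning-curve fit.
#' @return A list with elements `in_band`, `out_of_band` (each `n_cycles`,
#'   `mean_diff`, `sem`, `cycles`) plus `band` and `in_band_fit` (a
#'   `learning_curve_fit` or `NULL`).
#' @export
stratify_by_day_length <- function(differences, band = c(12, 24),
                                   log_base = exp(1)) {
  if (nrow(differences) == 0L) {
    stop_domain("No differences supplied.", "stats_error")
  }
  if (any(is.na(differences$day_length_h))) {
    stop_domain("Every cycle needs a day length.", "stats_error")
  }
  in_band <- differences$day_length_h >= band[1] &
    differences$day_length_h <= band[2]
  summarise_group <- function(g) {
    d <- g$motion_diff[is.finite(g$motion_diff)]
    list(
      n_cycles = nrow(g),
      mean_diff = if (length(d)) mean(d) else NA_real_,
      sem = if (length(d) > 1) sd(d) / sqrt(length(d)) else NA_real_,
      cycles = g$cycle
    )
  }
  gi <- differences[in_band, , drop = FALSE]
  go <- differences[!in_band, , drop = FALSE]
  fit <- NULL
  if (sum(is.finite(gi$motion_diff)) >= 2L &&
      length(unique(gi$cycle[is.finite(gi$motion_diff)])) >= 2L) {
    fit <- fit_log_curve(gi, log_base = log_base)
  }
  list(
    in_band = summarise_group(gi),
    out_of_band = summarise_group(go),
    band = band,
    in_band_fit = fit
  )
}
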