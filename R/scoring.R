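#' Score encounters at admission and discharge
#'
#' Applies a pair of fitted models of the same variant -- one trained on
#' admission features and outcome, one on discharge -- to every encounter,
#' yielding the admission score (J_Score_POA, from POA/exempt diagnoses
#' only) and the discharge score (J_Score, from all diagnoses), plus the
#' predicted class at each phase's stored cutoff. A higher J_Score than
#' J_Score_POA is the usual empirical pattern (problems are found and
#' coded during the stay) but is not enforced.
#'
#' @param model_poa,model_discharge fitted `severity_model`s sharing a
#'   variant; phases `"admission"` and `"discharge"` respectively.
#' @param maps a [reference_maps] object.
#' @param encset an [encounter_set()].
#' @param cutoffs list with finite elements `poa` and `discharge`.
#' @return data.frame of class `jscore_records`: one row per encounter
#'   with `encounter_id`, `j_score_poa`, `j_score`,
#'   `predicted_class_poa`, `predicted_class`, `facility`,
#'   `discharge_month`, `cds_reviewed`, `cds_queried`.
#' @export
score_encounters <- function(model_poa, model_discharge, maps, encset,
                             cutoffs) {
  if (!identical(model_poa$variant, model_discharge$variant)) {
    stop_fatal("the two models must share a variant (got '",
               model_poa$variant, "' and '", model_discharge$variant, "')")
  }
  stopifnot(is.finite(cutoffs$poa), is.finite(cutoffs$discharge))
  f_adm <- build_features(encset, maps, "admission")
  f_dis <- build_features(encset, maps, "discharge")
  p_poa <- predict_probability(model_poa, f_adm)
  p_dis <- predict_probability(model_discharge, f_dis)
  cls <- function(p, cut) ifelse(p >= cut, "high", "low")
  enc <- encset$encounters
  out <- data.frame(
    encounter_id = enc$encounter_id,
    j_score_poa = p_poa,
    j_score = p_dis,
    predicted_class_poa = cls(p_poa, cutoffs$poa),
    predicted_class = cls(p_dis, cutoffs$discharge),
    facility = enc$facility,
    discharge_month = enc$discharge_month,
    cds_reviewed = enc$cds_reviewed,
    cds_queried = enc$cds_queried,
    stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- cutoffs
  class(out) <- c("jscore_records", "data.frame")
  out
}

#' Read and write scored-encounter files
#'
#' Scored output is a delimited text file with one row per encounter;
#' every downstream report can be reproduced from this file alone.
#'
#' @param records a `jscore_records` data.frame.
#' @param path CSV path.
#' @return `write_jscores`: `path` invisibly; `read_jscores`: the records.
#' @export
write_jscores <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_jscores
#' @export
read_jscores <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  for (col in c("j_score_poa", "j_score")) df[[col]] <- as.numeric(df[[col]])
  for (col in c("cds_reviewed", "cds_queried")) {
    if (col %in% names(df)) {
      df[[col]] <- ifelse(df[[col]] %in% c("TRUE", "true"), TRUE,
                          ifelse(df[[col]] %in% c("FALSE", "false"),
                                 FALSE, NA))
    }
  }
  class(df) <- c("jscore_records", "data.frame")
  df
}

#' Histogram summary of the score distributions
#'
#' Fixed-width binning of both scores (default width 0.01) plus the
#' proportion of scores that display as 1 under two-decimal rounding
#' (score >= `saturation`, default 0.995): a logistic probability never
#' equals 1 exactly, but strongly separated cohorts pile up at the ends,
#' giving the characteristic bimodal shape.
#'
#' @param records a `jscore_records` data.frame.
#' @param binwidth histogram bin width on \[0, 1\].
#' @param saturation threshold above which a score is reported "at 1".
#' @return List with `breaks`, `counts_poa`, `counts` (bin counts summing
#'   to the record count), `prop_at_one_poa`, `prop_at_one`, and the
#'   Sarle bimodality coefficients `bimodality_poa`, `bimodality`.
#' @export
score_distribution <- function(records, binwidth = 0.01,
                               saturation = 0.995) {
  stopifnot(nrow(records) >= 1)
  breaks <- seq(0, 1, by = binwidth)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  cnt <- function(x) {
    as.vector(table(cut(x, breaks = breaks, include.lowest = TRUE,
                        right = FALSE)))
  }
  list(breaks = breaks,
       counts_poa = cnt(records$j_score_poa),
       counts = cnt(records$j_score),
       prop_at_one_poa = mean(records$j_score_poa >= saturation),
       prop_at_one = mean(records$j_score >= saturation),
       bimodality_poa = bimodality_coefficient(records$j_score_poa),
       bimodality = bimodality_coefficient(records$j_score))
}

#' Sarle's bimodality coefficient
#'
#' (skewness^2 + 1) / (kurtosis + small-sample correction); values above
#' ~0.555 (the uniform distribution's value) suggest bimodality. Used to
#' quantify the two-peaked shape of well-separated severity scores.
#'
#' @param x numeric vector, n >= 4.
#' @return The coefficient in (0, 1].
#' @export
bimodality_coefficient <- function(x) {
  n <- length(x)
  stopifnot(n >= 4)
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) return(NA_real_)
  g1 <- sum((x - m)^3) / n / s^3
  g2 <- sum((x - m)^4) / n / s^4 - 3
  (g1^2 + 1) / (g2 + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}

#' Per-period score trend
#'
#' Mean J_Score and J_Score_POA per discharge month, with the per-period
#' gap (J_Score - J_Score_POA). The gap measures non-POA capture: the
#' severity added by problems found and documented during the stay.
#' Months inside the observed range with no records are omitted with a
#' warning.
#'
#' @param records a `jscore_records` data.frame with `discharge_month`
#'   populated (YYYY-MM).
#' @return data.frame with `period`, `n`, `mean_j_score`,
#'   `mean_j_score_poa`, `gap`, ordered by period.
#' @export
trend_report <- function(records) {
  if (all(is.na(records$discharge_month))) {
    stop_fatal("discharge_month is not populated")
  }
  per <- records$discharge_month
  agg <- do.call(rbind, lapply(split(records, per), function(g) {
    data.frame(period = g$discharge_month[1], n = nrow(g),
               mean_j_score = mean(g$j_score),
               mean_j_score_poa = mean(g$j_score_poa))
  }))
  agg$gap <- agg$mean_j_score - agg$mean_j_score_poa
  agg <- agg[order(agg$period), , drop = FALSE]
  rownames(agg) <- NULL
  rng <- range(as.Date(paste0(agg$period, "-01")))
  full <- format(seq(rng[1], rng[2], by = "month"), "%Y-%m")
  missing <- setdiff(full, agg$period)
  if (length(missing)) {
    warning("period(s) with zero records omitted: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  agg
}

#' Compare scores between CDI review/query groups
#'
#' Mean J_Score and J_Score_POA within each level of a clinical
#' documentation flag, plus the within-group gap. In a working CDI
#' program, reviewed cases show a higher admission score (specialists
#' target severe cases) and a larger gap (review captures additional
#' non-POA diagnoses).
#'
#' @param records a `jscore_records` data.frame.
#' @param group_field `"cds_reviewed"` or `"cds_queried"`.
#' @return data.frame with `group`, `n`, `mean_j_score`,
#'   `mean_j_score_poa`, `gap`; groups with zero members are absent.
#' @export
group_comparison <- function(records,
                             group_field = c("cds_reviewed",
                                             "cds_queried")) {
  group_field <- match.arg(group_field)
  g <- records[[group_field]]
  if (all(is.na(g))) stop_fatal(group_field, " is not populated")
  keep <- !is.na(g)
  out <- do.call(rbind, lapply(split(records[keep, ], g[keep]), function(d) {
    data.frame(group = as.character(d[[group_field]][1]), n = nrow(d),
               mean_j_score = mean(d$j_score),
               mean_j_score_poa = mean(d$j_score_poa))
  }))
  out$gap <- out$mean_j_score - out$mean_j_score_poa
  rownames(out) <- NULL
  out
}

#' Per-facility high-severity proportions
#'
#' The benchmarking view: per facility, the proportion of encounters
#' predicted high severity at admission and at discharge. When the
#' original encounters (with observed SOI) are supplied, the observed
#' proportions with SOI >= 3 are reported side by side for comparison
#' with the grouper-based assignment.
#'
#' @param records a `jscore_records` data.frame with `facility` labels.
#' @param encounters optional encounters data.frame (from an
#'   [encounter_set()]) with `encounter_id`, `admit_soi`,
#'   `discharge_soi`.
#' @return data.frame with one row per facility.
#' @export
high_severity_proportion <- function(records, encounters = NULL) {
  if (all(is.na(records$facility))) {
    stop_fatal("facility labels are not populated")
  }
  out <- do.call(rbind, lapply(split(records, records$facility),
                               function(d) {
    data.frame(facility = d$facility[1], n = nrow(d),
               predicted_high_poa = mean(d$predicted_class_poa == "high"),
               predicted_high = mean(d$predicted_class == "high"))
  }))
  if (!is.null(encounters)) {
    i <- match(records$encounter_id, encounters$encounter_id)
    obs <- data.frame(facility = records$facility,
                      adm = binarize_outcome(encounters$admit_soi[i]),
                      dis = binarize_outcome(encounters$discharge_soi[i]))
    agg <- do.call(rbind, lapply(split(obs, obs$facility), function(d) {
      data.frame(facility = d$facility[1],
                 observed_high_admit = mean(d$adm),
                 observed_high_discharge = mean(d$dis))
    }))
    out <- merge(out, agg, by = "facility")
  }
  rownames(out) <- NULL
  out[order(out$facility), , drop = FALSE]
}
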