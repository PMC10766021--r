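#' Read a per-patient survival table
#'
#' CSV with columns `patient_id`, `time_months`, `event`, `marker`, plus any
#' number of covariate columns. Time is in months from diagnosis; `event` is
#' 1 for the endpoint (e.g. breast-cancer death for BCSS, distant metastasis
#' for DMFS) and 0 for censoring.
#'
#' @param path CSV file path.
#' @return data.frame of class `"survival_table"` with canonical columns
#'   `patient_id`, `time`, `event`, `marker` plus covariates.
#' @export
read_survival <- function(path) {
  if (!file.exists(path))
    ki67cl_stop("missing_file", "survival table not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_months", "event", "marker")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ki67cl_stop("missing_column", "survival table lacks column(s): %s",
                paste(miss, collapse = ", "))
  names(df)[names(df) == "time_months"] <- "time"
  survival_table(df)
}

#' Validate a survival table
#' @param df data.frame with columns `patient_id`, `time`, `event`, `marker`.
#' @return The validated data.frame, classed `"survival_table"`.
#' @export
survival_table <- function(df) {
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    ki67cl_stop("survival_table", "times must be finite and positive")
  if (!all(df$event %in% c(0, 1)))
    ki67cl_stop("survival_table", "event must be 0 (censored) or 1 (event)")
  class(df) <- unique(c("survival_table", class(df)))
  df
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator over the distinct event times. An all-censored
#' sample yields the constant function 1.
#'
#' @param time,event survival times (months) and event indicators.
#' @return data.frame with columns `time`, `surv`, `n_risk`, `n_event`;
#'   the curve starts at `S(0) = 1` and is non-increasing.
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) == 0L) ki67cl_stop("empty_input", "no survival records")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(length(time), fit$n.risk),
             n_event = c(0, fit$n.event))
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with the hypergeometric variance;
#' p-value from the upper chi-square tail. When the pooled sample has no
#' events the statistic is 0 and p is 1.
#'
#' @param time,event survival times and event indicators.
#' @param group two-level grouping (logical, factor or character).
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L)
    ki67cl_stop("logrank", "log-rank test needs exactly two non-empty groups")
  if (sum(event) == 0) return(list(statistic = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- sd$chisq
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Rank correlation between a risk marker and survival time over admissible
#' patient pairs; tied markers contribute 1/2, with time ties handled per
#' Harrell's convention. With `higher_is_worse = TRUE` (the default for a
#' risk score) a perfectly risk-ordered marker gives C = 1.
#'
#' @param time,event survival times and event indicators.
#' @param marker continuous risk marker (or a binarized group via
#'   `as.numeric`).
#' @param higher_is_worse direction of the marker.
#' @return C-index in `[0, 1]`, or `NA` when no pair is comparable.
#' @export
concordance_index <- function(time, event, marker, higher_is_worse = TRUE) {
  df <- data.frame(time = time, event = event, marker = marker)
  fit <- tryCatch(
    survival::concordance(survival::Surv(time, event) ~ marker, data = df,
                          reverse = higher_is_worse),
    error = function(e) NULL)
  if (is.null(fit) || (fit$count[["concordant"]] + fit$count[["discordant"]] +
                       fit$count[["tied.x"]]) == 0)
    return(NA_real_)
  unname(fit$concordance)
}

#' Find the log-rank-optimal marker cutoff
#'
#' Evaluates each candidate cutoff by the two-group log-rank p-value of the
#' induced low/high split, subject to both groups holding at least
#' `min_group_frac` of the patients. Returns the feasible candidate with the
#' smallest p; exact ties go to the smaller cutoff. The default candidate
#' grid is the 10%-90% deciles of the marker distribution.
#'
#' @param time,event,marker aligned survival data and marker values.
#' @param candidates numeric cutoff grid; `NULL` for the decile default.
#' @param min_group_frac minimum fraction of patients per group (default 0.1).
#' @return list with `cutoff`, `p`, and the evaluated `grid` (data.frame of
#'   `cutoff`, `p`, `feasible`).
#' @export
find_optimal_cutoff <- function(time, event, marker, candidates = NULL,
                                min_group_frac = 0.1) {
  if (is.null(candidates))
    candidates <- unique(stats::quantile(marker, probs = seq(0.1, 0.9, 0.1),
                                         names = FALSE, type = 7))
  n <- length(marker)
  min_n <- ceiling(min_group_frac * n)
  rows <- lapply(candidates, function(ct) {
    high <- marker > ct
    feasible <- sum(high) >= min_n && sum(!high) >= min_n
    p <- if (feasible) logrank_test(time, event, high)$p else NA_real_
    data.frame(cutoff = ct, p = p, feasible = feasible)
  })
  grid <- do.call(rbind, rows)
  ok <- which(grid$feasible)
  if (length(ok) == 0L)
    ki67cl_stop("no_feasible_cutoff",
                "no candidate cutoff satisfies the minimum group fraction")
  best <- ok[order(grid$p[ok], grid$cutoff[ok])][1]
  list(cutoff = grid$cutoff[best], p = grid$p[best], grid = grid)
}

#' Event-stratified fold assignment
#'
#' Seeded k-fold split that distributes events and censored records
#' separately across folds, so every fold contains events whenever
#' `#events >= k`.
#'
#' @param event event indicators.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per record.
#' @export
make_folds <- function(event, k = 3, seed = 1L) {
  n <- length(event)
  fold <- integer(n)
  with_seed(seed, {
    for (lev in unique(event)) {
      idx <- sample(which(event == lev))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Cross-validated cutoff selection and marker evaluation
#'
#' For each of `k` folds the cutoff is selected on the training part with
#' [find_optimal_cutoff()] and the held-out part is evaluated: log-rank p of
#' the induced split and C-index of the continuous marker. The combined
#' p-value is the conservative `min(1, 2 x median)` of the fold p-values;
#' the combined C-index is the fold mean and standard deviation; the cutoff
#' reported to users is the median of the fold cutoffs.
#'
#' @param records a [survival_table()] (columns `time`, `event`, `marker`).
#' @param k number of folds (default 3).
#' @param seed fold-assignment seed.
#' @param candidates cutoff grid passed to [find_optimal_cutoff()].
#' @param min_group_frac minimum per-group fraction for cutoff feasibility.
#' @return Object of class `"cv_summary"`: list with `per_fold` (data.frame
#'   `fold`, `cutoff`, `p`, `c_index`), `combined_p`, `combined_c` (named
#'   `mean`/`sd`), `chosen_cutoff`.
#' @export
cross_validate_marker <- function(records, k = 3, seed = 1L,
                                  candidates = NULL, min_group_frac = 0.1) {
  if (k < 2) ki67cl_stop("config", "k must be at least 2")
  fold <- make_folds(records$event, k = k, seed = seed)
  per <- lapply(seq_len(k), function(f) {
    tr <- records[fold != f, , drop = FALSE]
    te <- records[fold == f, , drop = FALSE]
    if (sum(te$event) == 0 || sum(tr$event) == 0)
      ki67cl_stop("fold_without_events",
                  "fold %d has no events; use stratified folding or fewer folds", f)
    sel <- find_optimal_cutoff(tr$time, tr$event, tr$marker,
                               candidates = candidates,
                               min_group_frac = min_group_frac)
    high <- te$marker > sel$cutoff
    p <- if (length(unique(high)) == 2L)
      logrank_test(te$time, te$event, high)$p else 1
    ci <- concordance_index(te$time, te$event, te$marker)
    data.frame(fold = f, cutoff = sel$cutoff, p = p, c_index = ci)
  })
  per <- do.call(rbind, per)
  summarize_cv(per)
}

#' Combine per-fold statistics
#'
#' The protocol arithmetic on its own: combined p = `min(1, 2 x median fold
#' p)`, combined C = mean and standard deviation of the fold C-indices,
#' chosen cutoff = median of the fold cutoffs.
#'
#' @param per_fold data.frame with columns `fold`, `cutoff`, `p`, `c_index`.
#' @return `"cv_summary"` object (see [cross_validate_marker()]).
#' @export
summarize_cv <- function(per_fold) {
  structure(list(
    per_fold = per_fold,
    combined_p = min(1, 2 * stats::median(per_fold$p)),
    combined_c = c(mean = mean(per_fold$c_index),
                   sd = stats::sd(per_fold$c_index)),
    chosen_cutoff = stats::median(per_fold$cutoff)),
    class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  cat(sprintf("<cv_summary> %d folds: combined p = %.4g, combined C = %.3f +/- %.3f, cutoff = %.4g\n",
              nrow(x$per_fold), x$combined_p,
              x$combined_c[["mean"]], x$combined_c[["sd"]], x$chosen_cutoff))
  invisible(x)
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit (Efron handling of tied times). `UNIVARIATE` fits
#' one single-term model per requested term; `MULTIVARIATE` fits all terms
#' simultaneously. Constant covariates are dropped with hazard ratio 1 by
#' convention; non-convergence or a rank-deficient design raises a named
#' error.
#'
#' @param records a [survival_table()]; terms are column names in it.
#' @param terms character vector of covariate columns (e.g. `"marker"`,
#'   grade, tumor size, age).
#' @param model_type `"UNIVARIATE"` or `"MULTIVARIATE"`.
#' @return Object of class `"cox_result"`: data.frame with one row per term
#'   (`term`, `coef`, `hr`, `lower`, `upper`, `p`) and a `model_type`
#'   attribute. `lower`/`upper` are the Wald 95% confidence bounds of the
#'   hazard ratio.
#' @export
cox_fit <- function(records, terms,
                    model_type = c("UNIVARIATE", "MULTIVARIATE")) {
  model_type <- match.arg(model_type)
  if (sum(records$event) == 0)
    ki67cl_stop("cox", "no events: Cox model is undefined")
  constant <- terms[vapply(terms, function(t)
    length(unique(records[[t]])) <= 1L, logical(1))]
  live <- setdiff(terms, constant)
  fit_one <- function(tms) {
    fo <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(tms, collapse = " + ")))
    fit <- tryCatch(survival::coxph(fo, data = records, ties = "efron"),
                    warning = function(w) w, error = function(e) e)
    if (inherits(fit, "condition"))
      ki67cl_stop("cox_convergence", "Cox fit failed for [%s]: %s",
                  paste(tms, collapse = ", "), conditionMessage(fit))
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               lower = s$conf.int[, "lower .95"],
               upper = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE)
  }
  rows <- if (model_type == "UNIVARIATE") {
    do.call(rbind, lapply(live, fit_one))
  } else if (length(live)) fit_one(live) else NULL
  if (length(constant)) {
    rows <- rbind(rows, data.frame(term = constant, coef = 0, hr = 1,
                                   lower = NA_real_, upper = NA_real_,
                                   p = NA_real_, stringsAsFactors = FALSE))
  }
  rownames(rows) <- NULL
  attr(rows, "model_type") <- model_type
  class(rows) <- c("cox_result", "data.frame")
  rows
}

#' Fixed-cutoff stratification
#'
#' Splits patients at a fixed marker cutoff into low/high risk groups and
#' reports the Kaplan-Meier curves, log-rank p and C-index of the
#' continuous marker.
#'
#' @param records a [survival_table()].
#' @param cutoff marker cutoff; patients with `marker > cutoff` are high
#'   risk.
#' @return Object of class `"stratification_result"`: list with `cutoff`,
#'   `group` (factor low/high), `logrank_p`, `statistic`, `c_index`,
#'   `km_curves` (named list of [kaplan_meier()] curves).
#' @export
stratify_at_cutoff <- function(records, cutoff) {
  high <- records$marker > cutoff
  if (!any(high) || all(high))
    ki67cl_stop("stratification", "cutoff %.4g leaves an empty group", cutoff)
  lr <- logrank_test(records$time, records$event, high)
  structure(list(
    cutoff = cutoff,
    group = factor(ifelse(high, "high", "low"), levels = c("low", "high")),
    logrank_p = lr$p, statistic = lr$statistic,
    c_index = concordance_index(records$time, records$event, records$marker),
    km_curves = list(
      low = kaplan_meier(records$time[!high], records$event[!high]),
      high = kaplan_meier(records$time[high], records$event[high]))),
    class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  cat(sprintf("<stratification_result> cutoff %.4g: %d low / %d high, log-rank p = %.4g, C = %.3f\n",
              x$cutoff, sum(x$group == "low"), sum(x$group == "high"),
              x$logrank_p, x$c_index))
  invisible(x)
}
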