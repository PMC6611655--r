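#' Score members with a fitted model
#'
#' Logistic inverse-link of the linear predictor. Model features missing
#' from the matrix contribute zero (the vocabulary-freeze convention:
#' unseen features are absent, not imputed).
#'
#' @param model an `adrd_model`.
#' @param fm a [build_feature_matrix()] result.
#' @return numeric vector of probabilities in (0, 1), one per row.
#' @export
score_members <- function(model, fm) {
  stopifnot(inherits(model, "adrd_model"), inherits(fm, "feature_matrix"))
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(fm$matrix))
  present <- intersect(model$features, fm$vocabulary)
  if (length(present)) {
    beta <- model$coefficients[present]
    eta <- eta + as.numeric(fm$matrix[, present, drop = FALSE] %*% beta)
  }
  plogis(eta)
}

#' @export
predict.adrd_model <- function(object, fm, ...) score_members(object, fm)

#' Prevalence-matched classification threshold
#'
#' Chooses the score cutoff so the fraction of scores at or above it
#' equals the case prevalence: with `m = ceiling(prevalence * n)`, the
#' threshold is the m-th largest score (nearest rank). The classification
#' rule is `score >= threshold` means at-risk, so ties at the threshold
#' are all flagged; when ties inflate the flagged fraction beyond the
#' prevalence a warning is raised rather than silently corrected.
#'
#' @param scores numeric scores (non-empty).
#' @param prevalence target flagged fraction, in (0, 1).
#' @return numeric threshold.
#' @export
prevalence_threshold <- function(scores, prevalence) {
  if (length(scores) == 0L) stop("`scores` must be non-empty")
  if (is.na(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly inside (0, 1)")
  }
  n <- length(scores)
  m <- max(1L, as.integer(ceiling(prevalence * n)))
  thr <- sort(scores, decreasing = TRUE)[m]
  flagged <- sum(scores >= thr)
  if (flagged > m) {
    warning(sprintf(
      "score ties at the threshold: %d flagged instead of %d (fraction %.4f)",
      flagged, m, flagged / n
    ))
  }
  thr
}

#' Confusion counts and rates at a threshold
#'
#' Applies the at-or-above rule and tabulates the confusion matrix.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case); both classes must be present.
#' @param threshold classification threshold.
#' @return list: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `prevalence`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    ppv = if (tp + fp > 0L) tp / (tp + fp) else NA_real_,
    prevalence = mean(labels)
  )
}

#' Lift: fold enrichment of flagged members over random outreach
#'
#' `lift = PPV / prevalence`. A lift of 5 at 1\% prevalence means an
#' outreach list built from the model needs only 200 people to contain 10
#' true cases, versus 1000 at random.
#'
#' @param ppv positive predictive value at the chosen threshold.
#' @param prevalence case prevalence of the evaluated population (> 0).
#' @return numeric lift.
#' @export
lift <- function(ppv, prevalence) {
  if (any(is.na(prevalence)) || any(prevalence <= 0)) {
    stop("`prevalence` must be positive")
  }
  ppv / prevalence
}

#' Positive predictive value from sensitivity, specificity and prevalence
#'
#' Bayes' identity
#' `PPV = s * pi / (s * pi + (1 - c) * (1 - pi))`
#' for sensitivity `s`, specificity `c` and prevalence `pi`. Used to audit
#' published operating points: the printed lift must equal
#' `lift(ppv_from_rates(s, c, pi), pi)` up to rounding of the inputs.
#'
#' @param sensitivity,specificity,prevalence rates in (0, 1); vectorised.
#' @return numeric PPV.
#' @export
ppv_from_rates <- function(sensitivity, specificity, prevalence) {
  num <- sensitivity * prevalence
  num / (num + (1 - specificity) * (1 - prevalence))
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' The probability that a randomly chosen case scores above a randomly
#' chosen control, with ties counted one half. Computed from midranks, so
#' it equals the all-pairs concordance proportion exactly.
#'
#' @param scores numeric scores.
#' @param labels binary labels (1 = case); both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("labels contain a single class")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Age strata definition
#'
#' Parses strata like `"15-64,65-74,75-99"` into ordered, non-overlapping,
#' inclusive age ranges. The default follows the convention of reporting a
#' broad working-age band, young-elderly and old-elderly.
#'
#' @param spec character scalar `"lo-hi,lo-hi,..."` or a data.frame with
#'   `label`, `lower`, `upper`.
#' @return `data.table` of class `age_strata` with `label`, `lower`,
#'   `upper`.
#' @export
age_strata <- function(spec = "15-64,65-74,75-99") {
  if (is.character(spec)) {
    parts <- strsplit(strsplit(spec, ",")[[1L]], "-")
    st <- data.table(
      label = vapply(parts, paste, "", collapse = "-"),
      lower = as.integer(vapply(parts, `[`, "", 1L)),
      upper = as.integer(vapply(parts, `[`, "", 2L))
    )
  } else {
    st <- as.data.table(spec)[, .(label, lower = as.integer(lower),
                                  upper = as.integer(upper))]
  }
  setorderv(st, "lower")
  if (any(st$lower > st$upper)) stop("stratum with lower > upper")
  if (nrow(st) > 1L && any(st$lower[-1L] <= st$upper[-nrow(st)])) {
    stop("age strata overlap")
  }
  structure(st[], class = c("age_strata", class(st)))
}

stratum_of <- function(ages, strata) {
  idx <- rep(NA_integer_, length(ages))
  for (i in seq_len(nrow(strata))) {
    idx[ages >= strata$lower[i] & ages <= strata$upper[i]] <- i
  }
  if (anyNA(idx)) {
    stop("age(s) not covered by the strata: ",
         paste(head(unique(ages[is.na(idx)]), 5L), collapse = ", "))
  }
  idx
}

one_row_report <- function(stratum, scores, labels, threshold = NULL) {
  prev <- mean(labels)
  thr <- if (is.null(threshold)) prevalence_threshold(scores, prev) else threshold
  cm <- confusion_metrics(scores, labels, thr)
  data.table(
    stratum = stratum, n = length(labels), prevalence = prev,
    threshold = thr, sensitivity = cm$sensitivity,
    specificity = cm$specificity, ppv = cm$ppv,
    lift = lift(cm$ppv, prev),
    tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn
  )
}

#' Evaluation at a single prevalence-matched threshold
#'
#' @param scores,labels scores and binary labels of one cohort.
#' @param stratum label for the report row (default `"all"`).
#' @return one-row `data.table` with prevalence, threshold, sensitivity,
#'   specificity, PPV, lift and the confusion counts.
#' @export
evaluate_cohort <- function(scores, labels, stratum = "all") {
  one_row_report(stratum, scores, as.integer(labels))
}

#' Age-stratified evaluation with per-stratum thresholds
#'
#' Splits the cohort by age stratum, computes a prevalence-matched
#' threshold inside each stratum, reports per-stratum metrics, and adds a
#' pooled `"computed"` row whose confusion counts are the element-wise
#' sums of the stratum counts (i.e. the whole cohort classified with the
#' stratum-specific thresholds).
#'
#' @param scores,labels scores and binary labels.
#' @param ages integer age per row.
#' @param strata an [age_strata()] (or spec string).
#' @return An `evaluation_report`: `data.table` with one row per stratum
#'   plus the pooled row, columns as in [evaluate_cohort()], and the
#'   overall AUC as attribute `"auc"`.
#' @export
stratified_evaluation <- function(scores, labels, ages,
                                  strata = age_strata()) {
  if (is.character(strata)) strata <- age_strata(strata)
  labels <- as.integer(labels)
  idx <- stratum_of(ages, strata)
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    sel <- idx == i
    one_row_report(strata$label[i], scores[sel], labels[sel])
  })
  rep_dt <- rbindlist(rows)
  pooled <- data.table(
    stratum = "computed", n = sum(rep_dt$n), prevalence = mean(labels),
    threshold = NA_real_,
    sensitivity = sum(rep_dt$tp) / (sum(rep_dt$tp) + sum(rep_dt$fn)),
    specificity = sum(rep_dt$tn) / (sum(rep_dt$tn) + sum(rep_dt$fp)),
    ppv = sum(rep_dt$tp) / (sum(rep_dt$tp) + sum(rep_dt$fp)),
    tp = sum(rep_dt$tp), fp = sum(rep_dt$fp), tn = sum(rep_dt$tn),
    fn = sum(rep_dt$fn)
  )
  pooled[, lift := ppv / prevalence]
  setcolorder(pooled, names(rep_dt))
  out <- rbind(rep_dt, pooled)[]
  setattr(out, "auc", auc_mw(scores, labels))
  setattr(out, "class", c("evaluation_report", "data.table", "data.frame"))
  out
}

#' Full evaluation report for one cohort
#'
#' The single-threshold row (`"all"`), the per-stratum rows and the pooled
#' `"computed"` row, mirroring the usual presentation of
#' prevalence-threshold classification results.
#'
#' @inheritParams stratified_evaluation
#' @return An `evaluation_report` with the `"all"` row prepended.
#' @export
evaluation_report <- function(scores, labels, ages, strata = age_strata()) {
  labels <- as.integer(labels)
  strat <- stratified_evaluation(scores, labels, ages, strata)
  out <- rbind(evaluate_cohort(scores, labels), strat)[]
  setattr(out, "auc", attr(strat, "auc"))
  setattr(out, "class", c("evaluation_report", "data.table", "data.frame"))
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  y <- copy(x)
  setattr(y, "class", c("data.table", "data.frame"))
  fmt <- y[, .(stratum, n,
               prevalence = sprintf("%.2f%%", 100 * prevalence),
               threshold = ifelse(is.na(threshold), "", sprintf("%.2f", threshold)),
               sensitivity = sprintf("%.1f%%", 100 * sensitivity),
               specificity = sprintf("%.1f%%", 100 * specificity),
               lift = sprintf("%.1f", lift))]
  print(as.data.frame(fmt), row.names = FALSE)
  if (!is.null(attr(x, "auc"))) {
    cat(sprintf("AUC: %.4f\n", attr(x, "auc")))
  }
  invisible(x)
}
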