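#' Patient-disjoint nested split plan
#'
#' Repeated random subsampling (not folds): `n_outer` independent 80:20
#' train/test divisions of the patients, and for each outer training set
#' `n_inner` further 80:20 train/validation divisions. Splits are by patient,
#' so lesions of one patient never appear on both sides of any division.
#' Deterministic for a fixed seed.
#'
#' @param patient_ids character vector of unique patient ids (>= 5).
#' @param n_outer,n_inner numbers of outer and inner splits (default 30, 30).
#' @param train_frac training fraction (default 0.8); the training side gets
#'   `round(train_frac * n)` patients, clamped so both sides are nonempty.
#' @param seed integer seed.
#' @return a `split_plan`: list of `n_outer` elements, each with
#'   `train_patients`, `test_patients`, and `inner` (list of `n_inner`
#'   train/validation pairs).
#' @export
make_split_plan <- function(patient_ids, n_outer = 30, n_inner = 30,
                            train_frac = 0.8, seed = 1L) {
  patient_ids <- unique(as.character(patient_ids))
  n <- length(patient_ids)
  if (n < 5) stop("need at least 5 patients for a nested split plan")
  if (train_frac <= 0 || train_frac >= 1) stop("train_frac must be in (0, 1)")
  two_sided <- function(ids) {
    k <- min(max(round(train_frac * length(ids)), 1L), length(ids) - 1L)
    tr <- sample(ids, k)
    list(train = sort(tr), test = sort(setdiff(ids, tr)))
  }
  plan <- with_seed(seed, {
    lapply(seq_len(n_outer), function(o) {
      outer <- two_sided(patient_ids)
      if (length(outer$train) < 2) stop("too few patients to split the inner loop")
      inner <- lapply(seq_len(n_inner), function(i) {
        s <- two_sided(outer$train)
        list(train = s$train, validation = s$test)
      })
      list(train_patients = outer$train, test_patients = outer$test,
           inner = inner)
    })
  })
  structure(plan, class = "split_plan",
            seed = as.integer(seed), train_frac = train_frac)
}

#' Outlier-trimmed mean of ensemble member risk scores
#'
#' For one lesion, member scores beyond `trim_k` population SDs of their mean
#' are excluded ("beyond" is strict: a score at exactly `trim_k` SD is kept)
#' and the rest are averaged. With zero SD, or if everything were excluded,
#' the plain mean is returned.
#'
#' @param scores numeric member scores for one lesion (>= 1).
#' @param trim_k exclusion threshold in SD units (default 2).
#' @return the trimmed mean.
#' @export
trimmed_mean_risk <- function(scores, trim_k = 2.0) {
  if (length(scores) == 0L) stop("empty score list")
  m <- mean(scores)
  s <- sqrt(mean((scores - m)^2))
  if (s == 0) return(m)
  keep <- abs(scores - m) <= trim_k * s
  if (!any(keep)) return(m)
  mean(scores[keep])
}

#' Score lesions with an ensemble of Cox models
#'
#' Each member scores every lesion with its own frozen standardization; the
#' per-lesion member scores are then combined by the trimmed mean. No
#' cross-model rescaling is applied.
#' @noRd
ensemble_scores <- function(members, newdata, trim_k = 2.0,
                            ensemble_id = NA_character_) {
  S <- vapply(seq_along(members), function(k) {
    tryCatch(risk_score(members[[k]], newdata),
             error = function(e) {
               stop(sprintf("ensemble %s, member %d: %s",
                            ensemble_id, k, conditionMessage(e)), call. = FALSE)
             })
  }, numeric(nrow(newdata)))
  S <- matrix(S, nrow = nrow(newdata))
  apply(S, 1, trimmed_mean_risk, trim_k = trim_k)
}

#' Run the nested cross-validation ensemble pipeline
#'
#' For every outer split: each inner split runs the three-stage feature
#' elimination on its inner-training lesions only, then greedy forward Cox
#' selection scored on the inner-validation lesions; the per-inner-loop best
#' model (one member per successful inner loop) joins the outer split's
#' ensemble. The ensemble scores the outer-test lesions by the ±`trim_k` SD
#' trimmed mean of the member risk scores, and the Harrell c-index against
#' the outer-test outcomes is recorded. Outer splits whose inner loops all
#' fail contribute no c-index. Only outcomes of training-side lesions are
#' ever read during training.
#'
#' @param variant_tables named list (incl. `"manual"`) of radiomic feature
#'   data.frames, rows = lesion ids (rownames), identical layout across
#'   variants. Pass tables with 0 columns to run without radiomic features.
#' @param covariates data.frame of clinical/dosimetric columns, same rows.
#' @param outcomes data.frame `lesion_id`, `time_months`, `event`.
#' @param meta data.frame `lesion_id`, `patient_id`.
#' @param plan a `split_plan` over the patient ids in `meta`.
#' @param feature_groups subset of `c("radiomic", "clinical", "dosimetric")`;
#'   covariate columns are assigned via `covariate_groups`.
#' @param covariate_groups named character vector column -> "clinical" or
#'   "dosimetric" (defaults to "clinical" for all covariate columns).
#' @param config list of thresholds as in [run_config()].
#' @return list with `ensembles` (per outer split: members + ids) and
#'   `report` (per-outer c-indices, mean ± SD, member success fraction,
#'   feature inclusion frequencies, per-feature hazard-ratio mean ± SD).
#' @export
run_nested_cv <- function(variant_tables, covariates, outcomes, meta, plan,
                          feature_groups = c("radiomic", "clinical"),
                          covariate_groups = NULL, config = run_config()) {
  manual <- variant_tables[["manual"]]
  ids <- rownames(manual)
  stopifnot(!is.null(ids),
            identical(sort(ids), sort(as.character(outcomes$lesion_id))),
            identical(sort(ids), sort(as.character(meta$lesion_id))))
  outcomes <- outcomes[match(ids, outcomes$lesion_id), ]
  meta <- meta[match(ids, meta$lesion_id), ]
  if (is.null(covariates)) covariates <- manual[, 0, drop = FALSE]
  if (is.null(covariate_groups)) {
    covariate_groups <- stats::setNames(rep("clinical", ncol(covariates)),
                                        colnames(covariates))
  }
  use_radiomic <- "radiomic" %in% feature_groups
  cov_use <- colnames(covariates)[covariate_groups[colnames(covariates)] %in%
                                    feature_groups]
  rad_tables <- if (use_radiomic) variant_tables else
    lapply(variant_tables, function(tb) tb[, 0, drop = FALSE])
  model_table <- cbind(rad_tables[["manual"]],
                       covariates[, cov_use, drop = FALSE])

  lesion_rows <- function(pats) which(meta$patient_id %in% pats)

  ensembles <- list()
  outer_c <- rep(NA_real_, length(plan))
  n_members_total <- 0L
  all_members <- list()
  for (o in seq_along(plan)) {
    sp <- plan[[o]]
    members <- list()
    for (i in seq_along(sp$inner)) {
      tr <- lesion_rows(sp$inner[[i]]$train)
      va <- lesion_rows(sp$inner[[i]]$validation)
      if (sum(outcomes$event[tr]) < 2 || sum(outcomes$event[va]) < 1) next
      elim <- tryCatch(suppressWarnings(run_feature_elimination(
        variant_tables = lapply(rad_tables, function(tb) tb[tr, , drop = FALSE]),
        covariates = covariates[tr, cov_use, drop = FALSE],
        time = outcomes$time_months[tr], event = outcomes$event[tr],
        alpha_contour = config$alpha_contour, alpha_univ = config$alpha_univ,
        rho_threshold = config$rho_threshold, min_unique = config$min_unique,
        min_cv = config$min_cv)), error = function(e) NULL)
      if (is.null(elim) || length(elim$surviving) == 0L) next
      model <- forward_select(
        candidates = elim$surviving,
        train = list(X = model_table[tr, , drop = FALSE],
                     time = outcomes$time_months[tr],
                     event = outcomes$event[tr]),
        validation = list(X = model_table[va, , drop = FALSE],
                          time = outcomes$time_months[va],
                          event = outcomes$event[va]),
        max_features = config$max_features,
        split_id = sprintf("outer%02d/inner%02d", o, i))
      if (!is.null(model)) members <- c(members, list(model))
    }
    n_members_total <- n_members_total + length(members)
    if (length(members) == 0L) {
      ensembles[o] <- list(NULL)
      next
    }
    ens <- structure(list(members = members, trim_k = config$trim_k,
                          outer_split = o),
                     class = "ensemble_model")
    ensembles[[o]] <- ens
    te <- lesion_rows(sp$test_patients)
    sc <- ensemble_scores(members, model_table[te, , drop = FALSE],
                          trim_k = config$trim_k,
                          ensemble_id = as.character(o))
    outer_c[o] <- tryCatch(
      concordance_index(sc, outcomes$time_months[te], outcomes$event[te]),
      error = function(e) NA_real_)
    all_members <- c(all_members, members)
  }

  n_inner_total <- sum(vapply(plan, function(sp) length(sp$inner), integer(1)))
  feat_by_member <- lapply(all_members, `[[`, "features")
  inclusion <- if (length(feat_by_member)) {
    tab <- table(unlist(feat_by_member))
    sort(stats::setNames(as.numeric(tab) / length(feat_by_member),
                         names(tab)), decreasing = TRUE)
  } else stats::setNames(numeric(0), character(0))
  hr <- hr_summary(all_members)

  report <- list(
    outer_c_index = outer_c,
    mean_c_index = mean(outer_c, na.rm = TRUE),
    sd_c_index = stats::sd(outer_c[!is.na(outer_c)]),
    n_outer_evaluated = sum(!is.na(outer_c)),
    member_success_fraction = n_members_total / n_inner_total,
    feature_inclusion = as.list(inclusion),
    hazard_ratios = hr,
    feature_groups = feature_groups,
    n_lesions = nrow(model_table)
  )
  list(ensembles = ensembles, report = report)
}

#' Mean ± SD hazard ratio per feature across ensemble members (per training SD)
#' @noRd
hr_summary <- function(members) {
  if (!length(members)) return(list())
  rows <- do.call(rbind, lapply(members, function(m)
    data.frame(feature = m$features, hr = exp(m$coef))))
  out <- lapply(split(rows$hr, rows$feature), function(h)
    list(mean = mean(h), sd = if (length(h) > 1) stats::sd(h) else NA_real_,
         n = length(h)))
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model>", length(x$members), "member(s), trim_k =", x$trim_k, "\n")
  invisible(x)
}

#' Validate trained ensembles on an external cohort
#'
#' Each ensemble scores every external lesion (members use their frozen
#' standardization; no refitting) and the per-ensemble Harrell c-index is
#' computed against the external outcomes.
#'
#' @param ensembles list of `ensemble_model` (NULL entries from failed outer
#'   splits are skipped).
#' @param table external feature data.frame containing every feature used by
#'   any member (rows aligned with `outcomes`).
#' @param outcomes data.frame `time_months`, `event` for the external lesions.
#' @return list `per_ensemble_c`, `mean_c`, `sd_c`.
#' @export
external_validate <- function(ensembles, table, outcomes) {
  keep <- !vapply(ensembles, is.null, logical(1))
  ensembles <- ensembles[keep]
  if (!length(ensembles)) stop("no trained ensembles to validate")
  cs <- vapply(seq_along(ensembles), function(k) {
    ens <- ensembles[[k]]
    sc <- ensemble_scores(ens$members, table, trim_k = ens$trim_k,
                          ensemble_id = as.character(ens$outer_split))
    concordance_index(sc, outcomes$time_months, outcomes$event)
  }, numeric(1))
  list(per_ensemble_c = cs, mean_c = mean(cs),
       sd_c = if (length(cs) > 1) stats::sd(cs) else NA_real_)
}

#' Risk-group stratification and log-rank comparison
#'
#' Splits lesions into high- and low-risk arms at a threshold (by default the
#' median of the training-cohort ensemble scores), estimates a Kaplan-Meier
#' LF-free curve per arm, and compares the arms with a log-rank test.
#'
#' @param scores ensemble risk scores of the lesions to stratify.
#' @param time,event their outcomes.
#' @param threshold split value; default `median(scores)`.
#' @return list `km_high`, `km_low` (`km_curve`), `logrank` (statistic, p),
#'   `threshold`, `n_high`, `n_low`.
#' @export
stratify_and_test <- function(scores, time, event, threshold = stats::median(scores)) {
  high <- scores > threshold
  if (sum(high) < 2 || sum(!high) < 2) {
    stop("each risk arm needs at least 2 lesions")
  }
  list(km_high = km_estimate(time[high], event[high]),
       km_low = km_estimate(time[!high], event[!high]),
       logrank = logrank_test(time[high], event[high], time[!high], event[!high]),
       threshold = threshold, n_high = sum(high), n_low = sum(!high))
}
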