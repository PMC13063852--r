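#' Contour-dependence filter
#'
#' Features that change systematically when the contour is perturbed are
#' unreliable under inter-observer variability. For every radiomic feature,
#' the values on the manual contour are compared against each perturbed
#' variant with a paired two-sided Wilcoxon signed-rank test; the feature is
#' dropped if any comparison has p < `alpha` (default 0.10, a deliberately
#' permissive threshold that removes more features). All-zero differences
#' give p = 1 by convention (the feature is contour-stable). Clinical and
#' dosimetric columns are exempt.
#'
#' @param tables named list of feature data.frames, one per contour variant,
#'   with the manual variant named `"manual"`; identical row order (lesions)
#'   and columns.
#' @param alpha significance threshold (default 0.10).
#' @param exempt character vector of column names to pass through untested
#'   (clinical/dosimetric covariates).
#' @return list with `kept`, `dropped`, and the per-feature minimum p-values.
#' @export
filter_contour_dependent <- function(tables, alpha = 0.10, exempt = character(0)) {
  if (length(tables) < 2L) stop("need at least 2 contour variants")
  if (!"manual" %in% names(tables)) stop("`tables` must contain a 'manual' variant")
  manual <- tables[["manual"]]
  ids <- rownames(manual)
  for (nm in names(tables)) {
    if (!identical(rownames(tables[[nm]]), ids) ||
        !identical(colnames(tables[[nm]]), colnames(manual))) {
      stop("misaligned lesion ids or columns across contour variants")
    }
  }
  feats <- setdiff(colnames(manual), exempt)
  others <- tables[setdiff(names(tables), "manual")]
  pmin_feat <- vapply(feats, function(f) {
    ps <- vapply(others, function(tb) {
      paired_signed_rank_p(manual[[f]], tb[[f]])
    }, numeric(1))
    min(ps)
  }, numeric(1))
  dropped <- feats[pmin_feat < alpha]
  kept <- c(setdiff(feats, dropped), intersect(exempt, colnames(manual)))
  list(kept = kept[order(match(kept, colnames(manual)))],
       dropped = dropped, min_p = pmin_feat)
}

#' Paired two-sided Wilcoxon signed-rank p, with p = 1 for all-zero diffs
#' @noRd
paired_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) == 0L || all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(x, y, paired = TRUE)$p.value)
}

#' Low-variability filter
#'
#' Drops features that carry (almost) no information across lesions: fewer
#' than `min_unique` distinct values, or a coefficient of variation below
#' `min_cv`. Near-zero-mean features (e.g. z-scored intensities), for which
#' the CV is unstable, use an absolute SD floor instead.
#'
#' @param table feature data.frame (rows = lesions).
#' @param min_unique minimum number of distinct values (default 3).
#' @param min_cv minimum |SD / mean| (default 1e-3).
#' @param sd_floor minimum SD used when |mean| < `mean_eps`.
#' @param mean_eps threshold below which a mean counts as zero.
#' @return list with `kept` and `dropped` feature names.
#' @export
filter_low_variability <- function(table, min_unique = 3, min_cv = 1e-3,
                                   sd_floor = 1e-8, mean_eps = 1e-8) {
  keep <- vapply(colnames(table), function(f) {
    v <- table[[f]]
    if (length(unique(v)) < min_unique) return(FALSE)
    s <- stats::sd(v)
    m <- mean(v)
    if (abs(m) < mean_eps) s >= sd_floor else (s / abs(m)) >= min_cv
  }, logical(1))
  list(kept = colnames(table)[keep], dropped = colnames(table)[!keep])
}

#' Redundancy clustering of correlated features
#'
#' Complete-linkage hierarchical clustering on the distance 1 - |Spearman
#' rho|, cut at height 1 - `rho_threshold`: features whose pairwise absolute
#' rank correlation all exceed the threshold end up in one cluster. Each
#' cluster is represented by the feature with the best univariate
#' discrimination of the outcome, measured as max(c, 1 - c) of the raw
#' feature used as a risk score (so protective and hazardous features compete
#' on equal footing); ties break to the lexicographically smallest name.
#'
#' @param table feature data.frame (rows = lesions).
#' @param time,event outcomes aligned with the rows.
#' @param rho_threshold absolute Spearman correlation above which features are
#'   considered redundant (default 0.8).
#' @return list with `representatives`, `cluster_map` (named character:
#'   feature -> representative), `dropped`.
#' @export
cluster_correlated <- function(table, time, event, rho_threshold = 0.8) {
  feats <- colnames(table)
  if (length(feats) <= 1L) {
    return(list(representatives = feats,
                cluster_map = stats::setNames(feats, feats),
                dropped = character(0)))
  }
  rho <- suppressWarnings(stats::cor(as.matrix(table), method = "spearman"))
  rho[!is.finite(rho)] <- 0
  d <- stats::as.dist(1 - abs(rho))
  hc <- stats::hclust(d, method = "complete")
  grp <- stats::cutree(hc, h = 1 - rho_threshold + 1e-12)
  disc <- vapply(feats, function(f) {
    ci <- tryCatch(concordance_index(table[[f]], time, event),
                   error = function(e) NA_real_)
    if (is.na(ci)) 0 else max(ci, 1 - ci)
  }, numeric(1))
  reps <- vapply(split(feats, grp), function(members) {
    members <- members[order(-disc[members], members)]
    members[1]
  }, character(1))
  cluster_map <- stats::setNames(unname(reps[as.character(grp)]), feats)
  list(representatives = unname(reps[order(match(reps, feats))]),
       cluster_map = cluster_map,
       dropped = setdiff(feats, reps))
}

#' Univariate Cox association filter
#'
#' Keeps features whose univariate Cox Wald p-value against local failure is
#' below `alpha` (default 0.05). A feature whose fit does not converge is
#' dropped with a warning.
#'
#' @param table feature data.frame (rows = lesions).
#' @param time,event outcomes aligned with the rows.
#' @param alpha significance level (default 0.05).
#' @return list with `kept`, `dropped`, and per-feature `p`.
#' @export
univariate_filter <- function(table, time, event, alpha = 0.05) {
  if (sum(event) < 2) stop("univariate_filter needs at least 2 events")
  srv <- survival::Surv(time, event)
  p <- vapply(colnames(table), function(f) {
    v <- table[[f]]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) {
      warning("univariate Cox fit failed for feature ", f, "; dropped",
              call. = FALSE)
      return(NA_real_)
    }
    z <- (v - mean(v)) / s
    diverged <- FALSE
    fit <- tryCatch(withCallingHandlers(
      survival::coxph(srv ~ z, ties = "efron"),
      warning = function(w) {
        if (grepl("converged before|infinite|did not converge",
                  conditionMessage(w), ignore.case = TRUE)) diverged <<- TRUE
        invokeRestart("muffleWarning")
      }), error = function(e) NULL)
    beta <- if (is.null(fit)) NA_real_ else stats::coef(fit)[1]
    if (is.null(fit) || diverged || !is.finite(beta) || abs(beta) > 15) {
      warning("univariate Cox fit failed for feature ", f, "; dropped",
              call. = FALSE)
      return(NA_real_)
    }
    se <- sqrt(diag(fit$var))[1]
    2 * stats::pnorm(-abs(beta / se))
  }, numeric(1))
  kept <- colnames(table)[!is.na(p) & p < alpha]
  list(kept = kept, dropped = setdiff(colnames(table), kept), p = p)
}

#' Three-stage feature elimination on an inner training split
#'
#' Radiomic features pass, in order: the contour-dependence filter (paired
#' Wilcoxon vs each perturbed contour, alpha 0.10), the low-variability
#' filter, redundancy clustering (one representative per cluster of
#' |Spearman| > 0.8), and the univariate Cox filter (alpha 0.05). Clinical
#' and dosimetric covariates are filtered by univariate analysis only. The
#' returned report reconstructs the full audit trail; the four drop sets plus
#' the survivors partition the input.
#'
#' Only the training partition may be passed in: the interface takes the
#' rows, not split indices, so no statistic of a validation or test lesion
#' can leak into selection.
#'
#' @param variant_tables named list (incl. `"manual"`) of radiomic feature
#'   data.frames on the training lesions, identical layout.
#' @param covariates data.frame of clinical/dosimetric columns on the same
#'   rows (may have 0 columns).
#' @param time,event training outcomes.
#' @param alpha_contour,alpha_univ,rho_threshold,min_unique,min_cv thresholds.
#' @return an `elimination_report` list: `input_features`,
#'   `dropped_contour_dependent`, `dropped_low_variability`, `cluster_map`,
#'   `dropped_redundant`, `dropped_univariate`, `surviving`, `thresholds`.
#' @export
run_feature_elimination <- function(variant_tables, covariates, time, event,
                                    alpha_contour = 0.10, alpha_univ = 0.05,
                                    rho_threshold = 0.8, min_unique = 3,
                                    min_cv = 1e-3) {
  manual <- variant_tables[["manual"]]
  rad_feats <- colnames(manual)
  cov_feats <- if (is.null(covariates)) character(0) else colnames(covariates)

  st1 <- filter_contour_dependent(variant_tables, alpha = alpha_contour)
  tab1 <- manual[, st1$kept, drop = FALSE]

  st2 <- filter_low_variability(tab1, min_unique = min_unique, min_cv = min_cv)
  tab2 <- tab1[, st2$kept, drop = FALSE]

  st3 <- cluster_correlated(tab2, time, event, rho_threshold = rho_threshold)
  tab3 <- tab2[, st3$representatives, drop = FALSE]

  # clinical/dosimetric covariates join here: univariate filtering only
  tab4 <- tab3
  if (length(cov_feats)) {
    tab4 <- cbind(tab3, covariates[, cov_feats, drop = FALSE])
  }
  st4 <- if (ncol(tab4) > 0) univariate_filter(tab4, time, event, alpha = alpha_univ)
         else list(kept = character(0), dropped = character(0), p = numeric(0))

  structure(list(
    input_features = c(rad_feats, cov_feats),
    dropped_contour_dependent = st1$dropped,
    dropped_low_variability = st2$dropped,
    cluster_map = st3$cluster_map,
    dropped_redundant = st3$dropped,
    dropped_univariate = st4$dropped,
    surviving = st4$kept,
    thresholds = list(alpha_contour = alpha_contour, alpha_univ = alpha_univ,
                      rho_threshold = rho_threshold, min_unique = min_unique,
                      min_cv = min_cv)
  ), class = "elimination_report")
}
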