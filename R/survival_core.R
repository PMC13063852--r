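#' Fit a Cox proportional hazards model on standardized features
#'
#' Thin wrapper around [survival::coxph()] (Efron tie handling) that freezes
#' the training-split standardization: each feature is centered and scaled by
#' its training mean and sample SD before fitting, and the stored
#' (mean, SD) pair is reused verbatim at scoring time. Hazard ratios are
#' therefore per training-SD of the feature. Monotone likelihood (perfect
#' separation) and singular information raise errors rather than returning a
#' silently diverged fit.
#'
#' @param X numeric matrix or data.frame of features (columns named).
#' @param time positive event/censoring times.
#' @param event 0/1 event indicator (1 = local failure).
#' @param split_id optional identifier of the training split.
#' @return an object of class `cox_model`: list with `features`, `coef`,
#'   `center`, `scale`, `split_id`.
#' @export
fit_cox <- function(X, time, event, split_id = NA_character_) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("feature columns must be named")
  if (sum(event) < 2) stop("fit_cox needs at least 2 events")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(!is.finite(scl)) || any(scl < 1e-12)) {
    stop("constant feature column: ",
         paste(colnames(X)[scl < 1e-12], collapse = ", "))
  }
  Z <- scale(X, center = ctr, scale = scl)
  df <- data.frame(Z, check.names = FALSE)
  df$..time <- time
  df$..event <- event
  fml <- stats::as.formula(paste(
    "survival::Surv(..time, ..event) ~",
    paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = "efron",
                    control = survival::coxph.control(iter.max = 100, eps = 1e-9)),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converged before|infinite|out of iterations|did not converge",
                msg, ignore.case = TRUE)) {
        diverged <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  if (diverged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    stop("non-convergent Cox fit (monotone likelihood or separation)")
  }
  if (any(is.na(beta))) stop("singular information matrix")
  structure(list(features = colnames(X), coef = unname(beta),
                 center = unname(ctr), scale = unname(scl),
                 split_id = split_id),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat("<cox_model>", length(x$features), "feature(s)\n")
  print(stats::setNames(round(x$coef, 4), x$features))
  invisible(x)
}

#' Linear risk score of a Cox model
#'
#' `sum(coef * (x - mean) / SD)` using the model's frozen training
#' standardization; higher scores mean higher hazard of local failure.
#'
#' @param model a `cox_model`.
#' @param newdata data.frame or matrix containing all model features.
#' @return numeric vector of risk scores (one per row).
#' @export
risk_score <- function(model, newdata) {
  newdata <- as.data.frame(newdata, check.names = FALSE)
  missing <- setdiff(model$features, colnames(newdata))
  if (length(missing)) {
    stop("missing feature(s): ", paste(missing, collapse = ", "))
  }
  Z <- sweep(sweep(as.matrix(newdata[, model$features, drop = FALSE]),
                   2, model$center), 2, model$scale, `/`)
  drop(Z %*% model$coef)
}

#' Harrell's concordance index
#'
#' Over all pairs comparable under right censoring (the earlier time carries
#' an event; pairs with tied event times for two events are not comparable;
#' at a tied time an event precedes a censoring), the fraction for which the
#' subject failing earlier has the higher score, with score ties counted as
#' 1/2.
#'
#' @param scores numeric risk scores (higher = higher predicted risk).
#' @param time event/censoring times.
#' @param event 0/1 event indicator.
#' @return c-index in \[0, 1\].
#' @export
concordance_index <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  ti <- matrix(time, n, n)
  tj <- t(ti)
  ei <- matrix(as.logical(event), n, n)
  ej <- t(ei)
  comparable <- (ei & (ti < tj | (ti == tj & !ej)))
  diag(comparable) <- FALSE
  npairs <- sum(comparable)
  if (npairs == 0L) stop("no comparable pairs under censoring")
  si <- matrix(scores, n, n)
  sj <- t(si)
  conc <- sum(comparable & (si > sj))
  ties <- sum(comparable & (si == sj))
  (conc + 0.5 * ties) / npairs
}

#' Greedy forward feature selection for Cox models
#'
#' Univariate models are fitted on the training split for every candidate and
#' ranked by c-index on the validation split; the seed feature is the best
#' (ties broken by name order). Each round, the remaining candidate giving
#' the largest strictly positive improvement of the validation c-index is
#' added, stopping at no improvement or `max_features`. Candidates whose fit
#' does not converge are skipped. Returns `NULL` (a failure value, not an
#' error) when no univariate model can be fitted — the situation where
#' nothing survives feature elimination must be representable.
#'
#' @param candidates character vector of candidate feature names.
#' @param train list with `X` (data.frame/matrix), `time`, `event`.
#' @param validation list with the same fields.
#' @param max_features maximum model size (default 4).
#' @param split_id optional id stored in the returned model.
#' @return a `cox_model`, or `NULL` on failure. The attribute `"trace"`
#'   records the validation c-index after each accepted feature.
#' @export
forward_select <- function(candidates, train, validation, max_features = 4,
                           split_id = NA_character_) {
  candidates <- sort(unique(candidates))
  if (length(candidates) == 0L) return(NULL)
  trainX <- as.data.frame(train$X, check.names = FALSE)
  valX <- as.data.frame(validation$X, check.names = FALSE)

  val_c <- function(feats) {
    m <- tryCatch(fit_cox(trainX[, feats, drop = FALSE], train$time,
                          train$event, split_id = split_id),
                  error = function(e) NULL)
    if (is.null(m)) return(NULL)
    s <- risk_score(m, valX)
    ci <- tryCatch(concordance_index(s, validation$time, validation$event),
                   error = function(e) NULL)
    if (is.null(ci)) return(NULL)
    list(model = m, c = ci)
  }

  uni <- lapply(candidates, function(f) val_c(f))
  ok <- !vapply(uni, is.null, logical(1))
  if (!any(ok)) return(NULL)
  cs <- vapply(uni[ok], `[[`, numeric(1), "c")
  best_i <- which(ok)[which.max(cs)]  # candidates pre-sorted: ties -> name order
  selected <- candidates[best_i]
  best <- uni[[best_i]]
  trace <- best$c

  while (length(selected) < max_features) {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0L) break
    trials <- lapply(remaining, function(f) val_c(c(selected, f)))
    ok <- !vapply(trials, is.null, logical(1))
    if (!any(ok)) break
    cs <- vapply(trials[ok], `[[`, numeric(1), "c")
    if (max(cs) <= best$c) break
    add_i <- which(ok)[which.max(cs)]
    selected <- c(selected, remaining[add_i])
    best <- trials[[add_i]]
    trace <- c(trace, best$c)
  }
  structure(best$model, trace = trace)
}

#' Kaplan-Meier estimate of the LF-free probability
#'
#' Product-limit estimator via [survival::survfit()]; at tied times events
#' precede censorings (the standard convention).
#'
#' @param time event/censoring times.
#' @param event 0/1 event indicator.
#' @return object of class `km_curve`: list with `time`, `surv`, `n_risk`.
#' @export
km_estimate <- function(time, event) {
  if (length(time) == 0L) stop("km_estimate: empty input")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk),
            class = "km_curve")
}

#' Two-group log-rank test
#'
#' Standard 1-df log-rank chi-square with hypergeometric variance, via
#' [survival::survdiff()].
#'
#' @param time_a,event_a outcomes of group A.
#' @param time_b,event_b outcomes of group B.
#' @return list with `statistic` and `p`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) == 0L || length(time_b) == 0L) stop("both groups must be nonempty")
  if (sum(event_a) + sum(event_b) == 0) stop("no events in either group")
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c("A", "B"), c(length(time_a), length(time_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}
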