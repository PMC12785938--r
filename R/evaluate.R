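# Metrics, cross-validation and the experiment harness (model x strategy x
# adulterant-scope matrix).

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y_true,y_pred numeric vectors, equal length >= 2; `y_true` must not
#'   be constant.
#' @return scalar R2.
#' @export
r2 <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true is constant; R2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean square error
#'
#' @param y_true,y_pred numeric vectors of equal length >= 1.
#' @return scalar RMSE.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (!length(y_true)) stop("empty vectors")
  sqrt(mean((y_true - y_pred)^2))
}

#' Residual predictive deviation
#'
#' `RPD = sd(y_true) / RMSE(y_true, y_pred)` using the sample (n-1) standard
#' deviation. The attached `label` attribute classifies the value: below 2.4
#' "poor", 2.4 to below 3.0 "acceptable", 3.0 and above "excellent".
#'
#' @param y_true,y_pred numeric vectors, length >= 2.
#' @return scalar RPD with attribute `label`; `Inf` (flagged
#'   `zero_rmse = TRUE`) when the fit is exact.
#' @export
rpd <- function(y_true, y_pred) {
  if (length(y_true) < 2L) stop("need at least 2 observations")
  e <- rmse(y_true, y_pred)
  s <- sd(y_true)
  if (e == 0) {
    out <- Inf
    attr(out, "zero_rmse") <- TRUE
    attr(out, "label") <- "excellent"
    return(out)
  }
  out <- s / e
  attr(out, "label") <- rpd_label(out)
  out
}

#' @rdname rpd
#' @param x an RPD value.
#' @export
rpd_label <- function(x) {
  if (x >= 3.0) "excellent" else if (x >= 2.4) "acceptable" else "poor"
}

.predict_any <- function(model, data) {
  if (is.numeric(model)) model
  else if (inherits(model, "TrainedNet")) predict_net(model, data)
  else if (is.function(model)) model(data)
  else predict(model, data)
}

#' Cross-validated RMSE of an arbitrary fitting procedure
#'
#' `fit_fun(cal_subset)` must return a predictor: a fitted object with a
#' `predict` method, a `TrainedNet`, or a plain function of a `SpectraSet`.
#' Any preprocessing the procedure needs must happen inside `fit_fun`, so it
#' is refit per fold (leak-free). Held-out predictions are pooled before the
#' RMSE is taken.
#'
#' @param fit_fun fitting function taking a `SpectraSet`.
#' @param calibration a `SpectraSet`.
#' @param folds number of folds.
#' @param seed fold-shuffle seed.
#' @return scalar RMSECV.
#' @export
rmsecv <- function(fit_fun, calibration, folds = 5L, seed = 1L) {
  n <- n_samples(calibration)
  if (n <= folds) stop("need more samples than folds")
  fl <- .make_folds(n, folds, seed)
  se <- 0
  for (f in fl) {
    if (length(unique(calibration$target[-f])) == 1L)
      warning("fold with constant training targets; kept")
    m <- fit_fun(calibration[-f, ])
    pred <- .predict_any(m, calibration[f, ])
    se <- se + sum((calibration$target[f] - pred)^2)
  }
  sqrt(se / n)
}

#' Per-sample residual table
#'
#' @param model predictor (fitted object, `TrainedNet`, prediction function,
#'   or a numeric vector of ready-made predictions).
#' @param prediction_set a `SpectraSet` (already carrying whatever
#'   preprocessing the model expects).
#' @return data.frame with columns `sample_id`, `target`, `prediction`,
#'   `residual` (prediction - target); attributes `mean_residual` and
#'   `rank_cor` (Spearman correlation of residual vs target, a
#'   systematic-bias indicator).
#' @export
residual_table <- function(model, prediction_set) {
  pred <- .predict_any(model, prediction_set)
  out <- data.frame(sample_id = prediction_set$sample_id,
                    target = prediction_set$target,
                    prediction = pred,
                    residual = pred - prediction_set$target)
  attr(out, "mean_residual") <- mean(out$residual)
  attr(out, "rank_cor") <- suppressWarnings(
    cor(out$residual, out$target, method = "spearman"))
  out
}

# ---- experiment harness ----------------------------------------------------

.strategies <- c("raw", "msc+cars", "snv+cars", "msc+spa", "snv+spa")

# Apply one preprocessing+selection strategy; everything fit on cal only.
# Returns list(cal, pred, subset)
.apply_strategy <- function(strategy, cal, pred, seed,
                            cars_args = list(), spa_args = list()) {
  parts <- strsplit(strategy, "+", fixed = TRUE)[[1]]
  if (identical(parts, "raw"))
    return(list(cal = cal, pred = pred, subset = NULL))
  prep <- parts[1]; selm <- parts[2]
  if (prep == "msc") {
    t <- msc_fit(cal)
    cal <- msc_apply(t, cal); pred <- msc_apply(t, pred)
  } else if (prep == "snv") {
    cal <- snv(cal); pred <- snv(pred)
  } else stop("unknown preprocessing: ", prep)
  vs <- if (selm == "cars") {
    do.call(cars_select, c(list(cal, seed = seed), cars_args))
  } else if (selm == "spa") {
    do.call(spa_select, c(list(cal), spa_args))
  } else stop("unknown selector: ", selm)
  list(cal = cal[, vs$indices], pred = pred[, vs$indices], subset = vs)
}

# fit one model on a (preprocessed) calibration set; returns
# list(predict = function(SpectraSet) numeric, refit = function(SpectraSet) predictor)
.make_fitter <- function(model, seed, net_args = list(),
                         plsr_args = list(), svr_args = list()) {
  arch_variant <- strsplit(model, ":", fixed = TRUE)[[1]]
  arch <- arch_variant[1]
  variant <- if (length(arch_variant) > 1L) arch_variant[2] else "full"
  if (arch == "plsr") {
    function(cal) do.call(fit_plsr_cv, c(list(cal, seed = seed), plsr_args))
  } else if (arch == "svr") {
    function(cal) do.call(fit_svr_gridsearch, c(list(cal, seed = seed), svr_args))
  } else {
    function(cal) {
      tf <- minmax_fit(cal)
      cfg <- do.call(net_config,
                     c(list(architecture = arch, variant = variant,
                            input_length = n_wavelengths(cal), seed = seed),
                       net_args))
      trained <- train_net(build_network(cfg), minmax_apply(tf, cal), cfg)
      structure(list(trained = trained, tf = tf), class = "NormalizedNet")
    }
  }
}

#' @export
predict.NormalizedNet <- function(object, newdata, ...) {
  predict_net(object$trained, minmax_apply(object$tf, newdata))
}

#' Run the full evaluation matrix
#'
#' Executes models x strategies x adulterant scopes x seeds, producing one
#' evaluation row per cell: calibration R2 (`rc2`), 5-fold `rmsecv`
#' (preprocessing refit per fold), prediction R2 (`rp2`), `rmsep` and `rpd`.
#' Per-cell failures are recorded in the `error` column, not fatal.
#'
#' @param config a list with elements:
#'   \describe{
#'     \item{data}{a `SpectraSet`; or `NULL` to simulate the default dataset
#'       with seed `sim_seed`.}
#'     \item{sim_seed}{seed for the built-in simulator (default 7).}
#'     \item{models}{character vector from `plsr`, `svr`, `cnn1d`,
#'       `deepspectra`, `incepspect_cbam` (optionally
#'       `incepspect_cbam:<variant>`).}
#'     \item{strategies}{subset of `raw`, `msc+cars`, `snv+cars`, `msc+spa`,
#'       `snv+spa` (default `raw`).}
#'     \item{scopes}{`"combined"` and/or individual adulterant names.}
#'     \item{seeds}{integer vector of model seeds (default 1).}
#'     \item{fraction}{calibration fraction (default 0.8).}
#'     \item{folds}{CV folds for rmsecv (default 5).}
#'     \item{compute_rmsecv}{logical (default TRUE); expensive for networks.}
#'     \item{net_args, plsr_args, svr_args, cars_args, spa_args}{optional
#'       argument lists forwarded to the respective fitters.}
#'   }
#' @return data.frame of evaluation rows; attribute `residuals` holds one
#'   residual table per successful cell, named `model|strategy|scope|seed`.
#' @export
run_experiment <- function(config) {
  data <- config$data
  if (is.null(data))
    data <- simulate_dataset(noise = noise_model(seed = config$sim_seed %||% 7L))
  models <- config$models %||% "plsr"
  strategies <- config$strategies %||% "raw"
  stopifnot(all(strategies %in% .strategies))
  scopes <- config$scopes %||% "combined"
  seeds <- config$seeds %||% 1L
  fraction <- config$fraction %||% 0.8
  folds <- config$folds %||% 5L
  compute_rmsecv <- config$compute_rmsecv %||% TRUE
  rows <- list(); residuals <- list()
  for (scope in scopes) {
    sub <- if (scope == "combined") data
           else data[data$adulterant == scope, ]
    split <- split_multi(sub, fraction)
    cal0 <- sub[split$calibration_idx, ]
    pred0 <- sub[split$prediction_idx, ]
    for (strategy in strategies) {
      for (model in models) {
        deterministic <- model %in% c("plsr")
        use_seeds <- if (deterministic) seeds[1] else seeds
        for (seed in use_seeds) {
          key <- paste(model, strategy, scope, seed, sep = "|")
          res <- tryCatch({
            st <- .apply_strategy(strategy, cal0, pred0, seed,
                                  cars_args = config$cars_args %||% list(),
                                  spa_args = config$spa_args %||% list())
            fitter <- .make_fitter(model, seed,
                                   net_args = config$net_args %||% list(),
                                   plsr_args = config$plsr_args %||% list(),
                                   svr_args = config$svr_args %||% list())
            fit <- fitter(st$cal)
            yhat_cal <- .predict_any(fit, st$cal)
            yhat_pred <- .predict_any(fit, st$pred)
            cv <- if (compute_rmsecv) {
              # refit preprocessing and model inside every fold
              refit <- function(cal_fold) {
                stf <- .apply_strategy_fixed(strategy, cal_fold,
                                             st$subset)
                m <- fitter(stf)
                function(newd) {
                  ndp <- .apply_strategy_apply(strategy, cal_fold, newd,
                                               st$subset)
                  .predict_any(m, ndp)
                }
              }
              rmsecv(refit, cal0, folds = folds, seed = seed)
            } else NA_real_
            residuals[[key]] <- residual_table(yhat_pred, pred0)
            data.frame(model = model, strategy = strategy, scope = scope,
                       seed = seed,
                       rc2 = r2(st$cal$target, yhat_cal),
                       rmsecv = cv,
                       rp2 = r2(st$pred$target, yhat_pred),
                       rmsep = rmse(st$pred$target, yhat_pred),
                       rpd = as.numeric(rpd(st$pred$target, yhat_pred)),
                       n_cal = n_samples(st$cal), n_pred = n_samples(st$pred),
                       error = NA_character_)
          }, error = function(e) {
            data.frame(model = model, strategy = strategy, scope = scope,
                       seed = seed, rc2 = NA_real_, rmsecv = NA_real_,
                       rp2 = NA_real_, rmsep = NA_real_, rpd = NA_real_,
                       n_cal = NA_integer_, n_pred = NA_integer_,
                       error = conditionMessage(e))
          })
          rows[[key]] <- res
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "residuals") <- residuals
  out
}

# For rmsecv refits: re-fit the preprocessing on the fold-train set but keep
# the variable subset selected on the full calibration set (selection is a
# modelling choice, preprocessing a transform; see the methods vignette).
.apply_strategy_fixed <- function(strategy, cal, subset) {
  if (strategy == "raw") return(cal)
  prep <- strsplit(strategy, "+", fixed = TRUE)[[1]][1]
  cal <- if (prep == "msc") msc_apply(msc_fit(cal), cal) else snv(cal)
  if (!is.null(subset)) cal[, subset$indices] else cal
}

.apply_strategy_apply <- function(strategy, cal, newd, subset) {
  if (strategy == "raw") return(newd)
  prep <- strsplit(strategy, "+", fixed = TRUE)[[1]][1]
  newd <- if (prep == "msc") msc_apply(msc_fit(cal), newd) else snv(newd)
  if (!is.null(subset)) newd[, subset$indices] else newd
}
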