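#' Tidy and glance generics
#'
#' Broom-style accessors for the package's fitted objects.
#' @param x A fitted object.
#' @param ... Method-specific arguments.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Unseen-substituent train/test split
#'
#' Partitions a dataset so that every test structure carries at least one
#' substituent identity absent from the whole training set, which forces
#' the fitted models to extrapolate to genuinely new substituents. The
#' split holds out whole substituent identities: a randomized greedy search
#' (with restarts and an exact-size fill step) selects identities whose
#' covered structures total the requested test fraction; all structures
#' containing a held-out identity go to the test set, so the predicate
#' holds by construction and is re-verified exhaustively before returning.
#'
#' @param data Tibble with a list-column `sub_ids` of substituent identity
#'   strings per structure.
#' @param fraction Nominal test fraction (default 0.1).
#' @param seed Integer seed (mandatory; the split is deterministic in it).
#' @param max_tries Greedy restarts.
#' @param test_size Exact test count; overrides `round(n * fraction)`
#'   (useful to match protocols whose printed counts differ from the
#'   nominal fraction, e.g. 30 test structures out of 425).
#' @return List with `train`, `test` (row subsets of `data`), `holdout`
#'   (identities held out), `target_size`, `verified` (logical).
#' @export
split_unseen_substituent <- function(data, fraction = 0.1, seed,
                                     max_tries = 500, test_size = NULL) {
  stopifnot(fraction > 0, fraction < 1, "sub_ids" %in% names(data))
  n <- nrow(data)
  target <- if (is.null(test_size)) round(n * fraction) else as.integer(test_size)
  ids <- sort(unique(unlist(data$sub_ids)))
  cover <- lapply(ids, function(id)
    which(vapply(data$sub_ids, function(s) id %in% s, TRUE)))
  names(cover) <- ids
  sizes <- lengths(cover)
  if (!length(ids) || all(sizes >= n) || all(sizes == 0)) {
    stop("unseen-substituent split infeasible: every substituent occurs in every structure",
         call. = FALSE)
  }
  usable <- ids[sizes < n]
  if (!length(usable)) {
    stop("unseen-substituent split infeasible", call. = FALSE)
  }

  best <- NULL
  rng <- withr_seed_sequence(seed, max_tries)
  for (t in seq_len(max_tries)) {
    set.seed(rng[t])
    ord <- sample(usable)
    hold <- character(0)
    covered <- rep(FALSE, n)
    for (id in ord) {
      cand <- covered | seq_len(n) %in% cover[[id]]
      if (sum(cand) <= target) {
        hold <- c(hold, id); covered <- cand
        if (sum(covered) == target) break
      }
    }
    if (sum(covered) < target) {  # exact-size fill step
      for (id in setdiff(usable, hold)) {
        cand <- covered | seq_len(n) %in% cover[[id]]
        if (sum(cand) == target) { hold <- c(hold, id); covered <- cand; break }
      }
    }
    sz <- sum(covered)
    if (is.null(best) || abs(sz - target) < abs(best$sz - target)) {
      best <- list(hold = hold, covered = covered, sz = sz)
    }
    if (sz == target) break
  }
  if (best$sz == 0 || best$sz == n) {
    stop("unseen-substituent split infeasible at this fraction", call. = FALSE)
  }
  test_idx <- which(best$covered)
  train_idx <- setdiff(seq_len(n), test_idx)
  train_ids <- unique(unlist(data$sub_ids[train_idx]))
  verified <- !any(best$hold %in% train_ids) &&
    all(vapply(data$sub_ids[test_idx],
               function(s) any(!s %in% train_ids), TRUE))
  list(train = data[train_idx, ], test = data[test_idx, ],
       holdout = best$hold, target_size = target,
       test_size = length(test_idx), verified = verified)
}

# derived per-try seeds, kept inside 32-bit integer range
withr_seed_sequence <- function(seed, k) {
  (as.numeric(seed) * 10007 + 17 * seq_len(k)) %% 2147483647
}

#' Fit a LASSO model with cross-validated regularization
#'
#' Features are z-scored on the training statistics; the L1 penalty is
#' chosen on a 50-point logarithmic grid by five-fold cross validation
#' minimizing the mean absolute error. Coefficients are reported on the
#' standardized scale, so their magnitudes are directly comparable across
#' features. Constant feature columns are dropped with a warning.
#'
#' @param data Training tibble.
#' @param target Response column name.
#' @param features Feature column names.
#' @param folds CV folds (default 5).
#' @param seed Seed controlling the fold assignment.
#' @return A `porph_lasso` object (supports `predict`, [tidy()],
#'   [glance()]).
#' @export
fit_lasso_cv <- function(data, target, features, folds = 5, seed = 1) {
  X <- as.matrix(data[, features])
  y <- data[[target]]
  stopifnot(nrow(X) >= folds)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  dropped <- names(which(scl == 0 | !is.finite(scl)))
  if (length(dropped)) {
    rlang::warn(paste("dropping constant feature column(s):",
                      paste(dropped, collapse = ", ")))
    features <- setdiff(features, dropped)
    X <- X[, features, drop = FALSE]
    ctr <- ctr[features]; scl <- scl[features]
  }
  Xs <- scale(X, center = ctr, scale = scl)
  n <- nrow(Xs)
  if (stats::sd(y) == 0 || length(features) == 0) {
    # degenerate problems: the L1 solution is the constant model
    return(structure(list(cv = NULL, lambda = NA_real_,
                          intercept = mean(y),
                          coef = stats::setNames(rep(0, length(features)),
                                                 features),
                          center = ctr, scale = scl, features = features,
                          dropped = dropped, target = target, n = n,
                          folds = folds, seed = seed),
                     class = "porph_lasso"))
  }
  lmax <- max(abs(crossprod(Xs, y - mean(y)))) / n
  lmax <- max(lmax, 1e-8)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 50))
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  Xfit <- if (ncol(Xs) == 1) cbind(Xs, `.dummy` = 0) else Xs
  cv <- glmnet::cv.glmnet(Xfit, y, alpha = 1, lambda = grid, foldid = foldid,
                          type.measure = "mae", standardize = FALSE)
  co <- as.numeric(stats::coef(cv, s = "lambda.min"))[seq_len(1 + length(features))]
  structure(list(cv = cv, lambda = cv$lambda.min,
                 intercept = co[1],
                 coef = stats::setNames(co[-1], features),
                 center = ctr, scale = scl,
                 features = features, dropped = dropped,
                 target = target, n = n, folds = folds, seed = seed),
            class = "porph_lasso")
}

#' @export
predict.porph_lasso <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features])
  Xs <- scale(X, center = object$center, scale = object$scale)
  drop(object$intercept + Xs %*% object$coef)
}

#' @export
tidy.porph_lasso <- function(x, ...) {
  tibble::tibble(target = x$target, feature = names(x$coef),
                 estimate = unname(x$coef))
}

#' @export
glance.porph_lasso <- function(x, ...) {
  tibble::tibble(target = x$target, lambda = x$lambda,
                 n = x$n, folds = x$folds,
                 n_nonzero = sum(x$coef != 0))
}

#' Fit a random forest with permutation importances
#'
#' @inheritParams fit_lasso_cv
#' @param seed Seed (the ensemble is deterministic in it).
#' @param ntree Number of trees.
#' @return A `porph_rf` object (supports `predict`, [tidy()]).
#' @export
fit_rf <- function(data, target, features, seed = 1, ntree = 300) {
  X <- as.data.frame(data[, features])
  y <- data[[target]]
  keep <- vapply(X, function(v) stats::sd(v) > 0, TRUE)
  if (any(!keep)) {
    rlang::warn(paste("dropping constant feature column(s):",
                      paste(features[!keep], collapse = ", ")))
  }
  features <- features[keep]
  X <- X[, features, drop = FALSE]
  set.seed(seed)
  fit <- randomForest::randomForest(X, y, ntree = ntree, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  structure(list(fit = fit, features = features, target = target,
                 importance = imp, seed = seed),
            class = "porph_rf")
}

#' @export
predict.porph_rf <- function(object, newdata, ...) {
  as.numeric(stats::predict(object$fit,
                            as.data.frame(newdata[, object$features])))
}

#' @export
tidy.porph_rf <- function(x, ...) {
  tibble::tibble(target = x$target, feature = names(x$importance),
                 importance = unname(x$importance))
}

mae <- function(obs, pred) mean(abs(obs - pred))

#' Bootstrap model evaluation
#'
#' Repeats the full protocol -- unseen-substituent split, model fit,
#' test-set mean absolute error -- `B` times with distinct derived seeds,
#' and summarizes MAE, LASSO coefficients and RF importances by their mean
#' and a percentile confidence interval. By default each replicate redraws
#' the train/test split ("resplit"); row resampling with out-of-bag testing
#' is available via `resample = "rows"`.
#'
#' @param data Dataset tibble (features + targets + `sub_ids`).
#' @param targets Response column names.
#' @param features Feature column names (e.g. [feature_names()]).
#' @param models Subset of `c("lasso", "rf")`.
#' @param B Bootstrap replicates (default 10).
#' @param ci Confidence level (default 0.95).
#' @param seed Base seed.
#' @param fraction Test fraction.
#' @param resample `"resplit"` or `"rows"`.
#' @param variant Label stored in the report.
#' @return A `porph_model_report`.
#' @export
bootstrap_evaluate <- function(data, targets, features,
                               models = c("lasso", "rf"), B = 10, ci = 0.95,
                               seed = 1, fraction = 0.1,
                               resample = c("resplit", "rows"),
                               variant = "cone_angles") {
  resample <- match.arg(resample)
  models <- match.arg(models, several.ok = TRUE)
  mae_rows <- list(); coef_rows <- list(); imp_rows <- list()
  for (b in seq_len(B)) {
    sb <- (seed * 1000 + b) %% 2147483647
    if (resample == "resplit") {
      sp <- split_unseen_substituent(data, fraction = fraction, seed = sb)
      train <- sp$train; test <- sp$test
    } else {
      set.seed(sb)
      idx <- sample(nrow(data), replace = TRUE)
      train <- data[idx, ]
      oob <- setdiff(seq_len(nrow(data)), unique(idx))
      test <- data[oob, ]
    }
    for (tg in targets) {
      if ("lasso" %in% models) {
        m <- fit_lasso_cv(train, tg, features, seed = sb)
        mae_rows[[length(mae_rows) + 1]] <- tibble::tibble(
          model = "lasso", target = tg, rep = b,
          mae = mae(test[[tg]], predict(m, test)))
        coef_rows[[length(coef_rows) + 1]] <-
          dplyr::mutate(tidy(m), rep = b)
      }
      if ("rf" %in% models) {
        m <- fit_rf(train, tg, features, seed = sb)
        mae_rows[[length(mae_rows) + 1]] <- tibble::tibble(
          model = "rf", target = tg, rep = b,
          mae = mae(test[[tg]], predict(m, test)))
        imp_rows[[length(imp_rows) + 1]] <-
          dplyr::mutate(tidy(m), rep = b)
      }
    }
  }
  qlo <- (1 - ci) / 2; qhi <- 1 - qlo
  summarize_ci <- function(df, value) {
    if (!length(df)) return(NULL)
    df <- dplyr::bind_rows(df)
    dplyr::summarise(
      dplyr::group_by(df, dplyr::across(dplyr::any_of(c("model", "target", "feature")))),
      mean = mean(.data[[value]]),
      lo = stats::quantile(.data[[value]], qlo, names = FALSE),
      hi = stats::quantile(.data[[value]], qhi, names = FALSE),
      .groups = "drop")
  }
  structure(list(
    mae = summarize_ci(mae_rows, "mae"),
    coef = summarize_ci(coef_rows, "estimate"),
    importance = summarize_ci(imp_rows, "importance"),
    raw = list(mae = dplyr::bind_rows(mae_rows),
               coef = if (length(coef_rows)) dplyr::bind_rows(coef_rows),
               importance = if (length(imp_rows)) dplyr::bind_rows(imp_rows)),
    meta = list(B = B, ci = ci, seed = seed, fraction = fraction,
                resample = resample, variant = variant,
                features = features, targets = targets)),
    class = "porph_model_report")
}

#' @export
print.porph_model_report <- function(x, ...) {
  cat(sprintf("<model report> %s | %d bootstrap reps, %.0f%% CI (%s)\n",
              x$meta$variant, x$meta$B, 100 * x$meta$ci, x$meta$resample))
  print(x$mae)
  invisible(x)
}

#' @export
tidy.porph_model_report <- function(x, ...) coefficient_table(x, ...)

#' @export
glance.porph_model_report <- function(x, ...) {
  dplyr::mutate(x$mae, variant = x$meta$variant, B = x$meta$B, ci = x$meta$ci)
}

#' Heatmap-ready coefficient table
#'
#' Long-format table of LASSO coefficients (and RF importances when
#' present) per target, feature and representation. HOMA-score targets are
#' excluded by default: their prediction error is comparatively high and
#' those models are not interpreted.
#'
#' @param reports A `porph_model_report` or list of them (e.g. one per
#'   representation).
#' @param include_homa Keep HOMA targets (default FALSE).
#' @return Tibble: `variant`, `model`, `target`, `feature`, `mean`,
#'   `lo`, `hi`.
#' @export
coefficient_table <- function(reports, include_homa = FALSE) {
  if (inherits(reports, "porph_model_report")) reports <- list(reports)
  out <- dplyr::bind_rows(lapply(reports, function(r) {
    dplyr::bind_rows(
      if (!is.null(r$coef)) dplyr::mutate(r$coef, model = "lasso"),
      if (!is.null(r$importance)) dplyr::mutate(r$importance, model = "rf")
    ) |> dplyr::mutate(variant = r$meta$variant)
  }))
  if (!include_homa) out <- dplyr::filter(out, !grepl("^homa", .data$target))
  dplyr::select(out, dplyr::any_of(c("variant", "model", "target", "feature",
                                     "mean", "lo", "hi")))
}
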