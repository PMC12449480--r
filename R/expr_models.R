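# Cis predictive models of expression: covariate residualization, 10-fold
# cross-validated training (elastic net and a multi-response joint-sparsity
# family via glmnet), and retention at CV R^2 > 0.01.

#' Residualize expression on covariates
#'
#' Least-squares residuals of each expression column on the covariate
#' matrix plus an intercept. Collinear covariate columns are dropped with a
#' warning (QR pivoting).
#'
#' @param expr An `expression_set` or a numeric matrix (individuals x
#'   features).
#' @param covariates Numeric covariate matrix (individuals x c); `NULL`
#'   means intercept only (mean-centering).
#' @return Same shape as the input values; an `expression_set` input is
#'   returned with its `values` replaced.
#' @export
residualize_expression <- function(expr, covariates = NULL) {
  is_set <- inherits(expr, "expression_set")
  Y <- if (is_set) expr$values else as.matrix(expr)
  n <- nrow(Y)
  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    dropped <- colnames(C)[qrC$pivot[(qrC$rank + 1):ncol(C)]]
    warning("dropping collinear covariate column(s): ",
            paste(dropped, collapse = ", "))
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(C)
  }
  res <- Y - C %*% qr.coef(qrC, Y)
  dimnames(res) <- dimnames(Y)
  if (is_set) {
    expr$values <- res
    expr
  } else res
}

#' @noRd
.cv_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' @noRd
.cv_r2 <- function(obs, pred) {
  # Squared out-of-fold correlation, truncated at zero for negative
  # correlations: an anti-correlated predictor has no predictive value, and
  # near-null models otherwise inherit a spurious R^2 from the negative
  # coupling between leave-fold-out means and held-out fold means.
  if (stats::sd(obs) == 0 || stats::sd(pred) == 0) return(0)
  r <- stats::cor(obs, pred)
  if (r <= 0) 0 else r^2
}

#' Train cross-validated cis SNP-weight model(s) for a feature or gene
#'
#' Fits each requested model family with the same deterministic k-fold
#' split, scores out-of-fold predictions by squared Pearson correlation
#' with the observed values (one `cv_r2` per response; negative
#' correlations are truncated to zero), picks the best
#' family per response (ties broken by fewest nonzero weights), and refits
#' that family on all samples for the reported weights. SNP columns are
#' standardized internally; weights are stored on the standardized-genotype
#' scale.
#'
#' Families: `"enet"` is a univariate elastic net (mixing 0.5, penalty by
#' inner cross-validation); `"multi"` is a multi-response elastic net with
#' a joint (group) penalty across a gene's isoforms, borrowing strength
#' through shared row sparsity. `"multi"` needs a matrix `Y` with >= 2
#' columns.
#'
#' @param X_cis Dosage matrix restricted to the feature's cis window
#'   (individuals x SNPs, columns named).
#' @param Y Numeric vector (one feature) or matrix (a gene's isoforms,
#'   columns named by transcript id).
#' @param feature_ids Feature id(s); defaults to `colnames(Y)` or
#'   `"feature1"`.
#' @param level `"gene"` or `"isoform"`.
#' @param families Subset of `c("enet", "multi")`.
#' @param k_folds Outer cross-validation folds (default 10).
#' @param enet_alpha Elastic-net mixing parameter (default 0.5).
#' @param seed Integer seed; the fold assignment is deterministic given it.
#' @return A list of `weight_model` objects (one per response), each with
#'   `feature_id`, `level`, `snp_ids`, `weights` (named, nonzero,
#'   standardized-genotype scale), `cv_r2`, `family`, `n_train`,
#'   `fold_seed`.
#' @export
train_feature_model <- function(X_cis, Y, feature_ids = NULL,
                                level = c("isoform", "gene"),
                                families = c("enet", "multi"),
                                k_folds = 10L, enet_alpha = 0.5, seed = 1L) {
  level <- match.arg(level)
  families <- match.arg(families, several.ok = TRUE)
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(nrow(X_cis) == n)
  if (n < 2 * k_folds) stop("need at least 2 samples per fold")
  if (is.null(feature_ids)) {
    feature_ids <- colnames(Y)
    if (is.null(feature_ids)) feature_ids <- paste0("feature", seq_len(ncol(Y)))
  }
  colnames(Y) <- feature_ids
  Xs <- .standardize(X_cis)
  if (ncol(Y) < 2) families <- setdiff(families, "multi")
  if (!length(families)) families <- "enet"
  folds <- .cv_folds(n, k_folds, seed)

  zero_var <- apply(Y, 2, stats::sd) == 0
  fit_family <- function(fam) {
    pred <- matrix(NA_real_, n, ncol(Y))
    for (f in seq_len(k_folds)) {
      tr <- folds != f
      pred[!tr, ] <- .glmnet_predict(Xs[tr, , drop = FALSE],
                                     Y[tr, , drop = FALSE],
                                     Xs[!tr, , drop = FALSE],
                                     fam, enet_alpha, seed + f)
    }
    r2 <- vapply(seq_len(ncol(Y)),
                 function(j) .cv_r2(Y[, j], pred[, j]), numeric(1))
    full <- .glmnet_fit(Xs, Y, fam, enet_alpha, seed)
    list(r2 = r2, weights = full)
  }
  fits <- lapply(stats::setNames(families, families), fit_family)

  lapply(seq_len(ncol(Y)), function(j) {
    if (zero_var[j]) {
      return(structure(list(feature_id = feature_ids[j], level = level,
                            snp_ids = colnames(Xs), weights = numeric(0),
                            cv_r2 = NA_real_, family = NA_character_,
                            n_train = n, fold_seed = seed),
                       class = "weight_model"))
    }
    r2s <- vapply(fits, function(f) f$r2[j], numeric(1))
    nnz <- vapply(fits, function(f) sum(f$weights[, j] != 0), numeric(1))
    # Best family by cv_r2; ties broken by fewest nonzero weights.
    best <- names(fits)[order(-r2s, nnz)][1]
    w <- fits[[best]]$weights[, j]
    w <- w[w != 0]
    structure(list(feature_id = feature_ids[j], level = level,
                   snp_ids = colnames(Xs), weights = w,
                   cv_r2 = unname(r2s[best]), family = best,
                   n_train = n, fold_seed = seed),
              class = "weight_model")
  })
}

#' @noRd
.glmnet_fit <- function(Xs, Y, fam, enet_alpha, seed) {
  # Returns an m x K coefficient matrix (no intercept rows).
  set.seed(seed)
  m <- ncol(Xs)
  if (fam == "enet") {
    W <- vapply(seq_len(ncol(Y)), function(j) {
      if (stats::sd(Y[, j]) == 0) return(numeric(m))
      cv <- glmnet::cv.glmnet(Xs, Y[, j], alpha = enet_alpha, nfolds = 5,
                              standardize = FALSE)
      as.numeric(stats::coef(cv, s = "lambda.min"))[-1]
    }, numeric(m))
  } else {
    cv <- glmnet::cv.glmnet(Xs, Y, family = "mgaussian", alpha = enet_alpha,
                            nfolds = 5, standardize = FALSE)
    cf <- stats::coef(cv, s = "lambda.min")
    W <- vapply(cf, function(cc) as.numeric(cc)[-1], numeric(m))
  }
  rownames(W) <- colnames(Xs)
  W
}

#' @noRd
.glmnet_predict <- function(Xtr, Ytr, Xte, fam, enet_alpha, seed) {
  set.seed(seed)
  K <- ncol(Ytr)
  if (fam == "enet") {
    vapply(seq_len(K), function(j) {
      if (stats::sd(Ytr[, j]) == 0) return(rep(mean(Ytr[, j]), nrow(Xte)))
      cv <- glmnet::cv.glmnet(Xtr, Ytr[, j], alpha = enet_alpha, nfolds = 5,
                              standardize = FALSE)
      as.numeric(stats::predict(cv, Xte, s = "lambda.min"))
    }, numeric(nrow(Xte)))
  } else {
    cv <- glmnet::cv.glmnet(Xtr, Ytr, family = "mgaussian", alpha = enet_alpha,
                            nfolds = 5, standardize = FALSE)
    pr <- stats::predict(cv, Xte, s = "lambda.min")
    matrix(pr, nrow(Xte), K)
  }
}

#' @export
print.weight_model <- function(x, ...) {
  cat("weight_model ", x$feature_id, " (", x$level, "): ",
      length(x$weights), " nonzero weights, cv_r2 = ",
      formatC(x$cv_r2, digits = 3), ", family = ", x$family, "\n", sep = "")
  invisible(x)
}

#' Collect weight models into a model database
#'
#' @param models List of `weight_model` objects.
#' @return A `model_db`: the model list plus a summary data.frame.
#' @export
model_db <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1), "weight_model")))
  names(models) <- vapply(models, function(m) paste(m$feature_id, m$level, sep = "/"),
                          character(1))
  summary <- data.frame(
    feature_id = vapply(models, `[[`, character(1), "feature_id"),
    level = vapply(models, `[[`, character(1), "level"),
    cv_r2 = vapply(models, `[[`, numeric(1), "cv_r2"),
    family = vapply(models, `[[`, character(1), "family"),
    retained = NA,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(models = models, summary = summary), class = "model_db")
}

#' Retain models predicting expression at CV R^2 above a threshold
#'
#' Retention uses the strict inequality `cv_r2 > threshold`; a model at
#' exactly the threshold (or with an undefined cv_r2) is dropped.
#'
#' @param db A `model_db`.
#' @param threshold Retention threshold (default 0.01).
#' @return The `model_db` with the `retained` flag populated.
#' @export
select_models <- function(db, threshold = 0.01) {
  stopifnot(inherits(db, "model_db"))
  r2 <- db$summary$cv_r2
  db$summary$retained <- !is.na(r2) & r2 > threshold
  db
}

#' @rdname select_models
#' @export
retained_models <- function(db) {
  if (all(is.na(db$summary$retained))) db <- select_models(db)
  db$models[db$summary$retained]
}

#' @export
print.model_db <- function(x, ...) {
  cat("model_db:", nrow(x$summary), "models (",
      sum(x$summary$retained, na.rm = TRUE), "retained )\n")
  invisible(x)
}

#' Serialize / read a model database as TSV
#'
#' One row per (feature, SNP) weight with the model-level columns repeated;
#' a feature with no nonzero weights keeps one row with an `NA` snp_id so
#' the round trip preserves it.
#'
#' @param db A `model_db`.
#' @param path Output TSV path.
#' @export
write_model_db <- function(db, path) {
  stopifnot(inherits(db, "model_db"))
  rows <- lapply(db$models, function(m) {
    if (length(m$weights)) {
      data.table::data.table(feature_id = m$feature_id, level = m$level,
                             snp_id = names(m$weights), weight = unname(m$weights),
                             cv_r2 = m$cv_r2, family = m$family,
                             n_train = m$n_train)
    } else {
      data.table::data.table(feature_id = m$feature_id, level = m$level,
                             snp_id = NA_character_, weight = NA_real_,
                             cv_r2 = m$cv_r2, family = m$family,
                             n_train = m$n_train)
    }
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t")
  invisible(path)
}

#' @rdname write_model_db
#' @param snp_universe Optional full cis snp_id vector per feature (list
#'   keyed by feature_id); defaults to the stored nonzero SNPs.
#' @export
read_model_db <- function(path, snp_universe = NULL) {
  dt <- data.table::fread(path, sep = "\t", colClasses = list(character = "snp_id"))
  split_keys <- paste(dt$feature_id, dt$level, sep = "/")
  models <- lapply(split(dt, split_keys), function(d) {
    has_snp <- !is.na(d$snp_id) & d$snp_id != "" & d$snp_id != "NA"
    w <- d$weight[has_snp]
    names(w) <- d$snp_id[has_snp]
    if (!length(w)) w <- numeric(0)
    ids <- if (!is.null(snp_universe)) snp_universe[[d$feature_id[1]]] else names(w)
    structure(list(feature_id = d$feature_id[1], level = d$level[1],
                   snp_ids = ids, weights = w, cv_r2 = d$cv_r2[1],
                   family = d$family[1], n_train = d$n_train[1],
                   fold_seed = NA_integer_),
              class = "weight_model")
  })
  model_db(unname(models))
}

#' Cache a model database as an R binary object
#'
#' @param db A `model_db`.
#' @param path Cache path (RDS).
#' @export
cache_model_db <- function(db, path) {
  saveRDS(db, path)
  invisible(path)
}

#' @rdname cache_model_db
#' @export
load_model_db <- function(path) readRDS(path)
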