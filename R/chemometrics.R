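## Multivariate chemometrics, implemented from scratch:
##  - PCA via singular value decomposition of the column-centered matrix;
##  - PLS-DA via NIPALS on a one-hot response;
##  - OPLS-DA (single predictive component + orthogonal signal filtering)
##    for two-group contrasts;
##  - VIP scores, stratified k-fold cross-validated Q2, and label
##    permutation testing.
## Component signs follow the convention that the largest-magnitude loading
## (weight) of each component is positive, so fits are fully deterministic.

.nipals_tol <- 1e-10
.nipals_maxit <- 500L

#' Principal component analysis by SVD
#'
#' Equivalent to the truncated singular value decomposition of the
#' column-centered matrix: scores are `U %*% D`, loadings are `V`, and the
#' explained variance of each component is its squared singular value over
#' the total variance.
#'
#' @param x Numeric sample-by-feature matrix (typically autoscaled).
#' @param n_components Number of components, at most
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return A `pca_result`: `scores`, `loadings`, `explained_variance`,
#'   `center`, `total_variance` (sum of per-feature variances).
#' @export
fit_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  n_components <- fm_count(n_components, "n_components")
  fm_assert(n_components <= min(nrow(x) - 1L, ncol(x)),
            "'n_components' must be <= min(samples - 1, features)")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc)
  expl <- sv$d^2 / sum(sv$d^2)
  idx <- seq_len(n_components)
  scores <- sv$u[, idx, drop = FALSE] %*% diag(sv$d[idx], n_components)
  loadings <- sv$v[, idx, drop = FALSE]
  for (a in idx) {  # sign convention: largest-magnitude loading positive
    j <- which.max(abs(loadings[, a]))
    if (loadings[j, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(scores) <- list(rownames(x), sprintf("PC%d", idx))
  dimnames(loadings) <- list(colnames(x), sprintf("PC%d", idx))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = expl[idx], center = center,
                 total_variance = sum(xc^2) / max(nrow(x) - 1L, 1L)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", ncol(x$scores), "components;",
      paste(sprintf("PC%d %.1f%%", seq_along(x$explained_variance),
                    100 * x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

one_hot <- function(labels) {
  labels <- as.factor(labels)
  y <- matrix(0, length(labels), nlevels(labels),
              dimnames = list(NULL, levels(labels)))
  y[cbind(seq_along(labels), as.integer(labels))] <- 1
  y
}

#' Partial least squares discriminant analysis (NIPALS)
#'
#' Fits a PLS2 model of the feature matrix against the one-hot-encoded
#' group labels using the NIPALS algorithm; successive components maximize
#' covariance with the response and are extracted by deflation, so their
#' score vectors are mutually orthogonal.
#'
#' @param x Numeric sample-by-feature matrix (typically autoscaled).
#' @param labels Group labels (>= 2 groups).
#' @param n_components Number of predictive components.
#' @return A `plsda_model` (also class `da_model`) with weights `W`, scores
#'   `T`, X-loadings `P`, Y-loadings `Q`, `R2X`, `R2Y`, per-component
#'   explained response variance `ssy`, and `vip`.
#' @export
fit_plsda <- function(x, labels, n_components = 2) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  fm_assert(nlevels(labels) >= 2, "PLS-DA requires >= 2 groups")
  fm_assert(length(labels) == nrow(x), "labels must match rows of x")
  n_components <- fm_count(n_components, "n_components")

  x_center <- colMeans(x)
  y0 <- one_hot(labels)
  y_center <- colMeans(y0)
  Xa <- sweep(x, 2, x_center)
  Ya <- sweep(y0, 2, y_center)
  ssx_tot <- sum(Xa^2)
  ssy_tot <- sum(Ya^2)

  p <- ncol(x); q <- ncol(y0)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(x), n_components)
  Q <- matrix(0, q, n_components)
  ssy <- numeric(n_components)
  converged <- logical(n_components)

  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(apply(Ya, 2, stats::var))]
    t_old <- rep(0, nrow(x))
    for (it in seq_len(.nipals_maxit)) {
      w <- crossprod(Xa, u)
      w <- w / sqrt(sum(w^2))
      t <- drop(Xa %*% w)
      qv <- crossprod(Ya, t) / sum(t^2)
      u <- drop(Ya %*% qv) / sum(qv^2)
      if (sum((t - t_old)^2) / max(sum(t^2), .Machine$double.eps) <
            .nipals_tol^2) {
        converged[a] <- TRUE
        break
      }
      t_old <- t
    }
    if (!converged[a]) {
      message(sprintf("fit_plsda: NIPALS did not converge for component %d", a))
    }
    pv <- crossprod(Xa, t) / sum(t^2)
    # sign convention on the weight vector
    j <- which.max(abs(w))
    if (w[j] < 0) {
      w <- -w; t <- -t; pv <- -pv; qv <- -qv
    }
    ssy[a] <- sum(tcrossprod(t, qv)^2)
    Xa <- Xa - tcrossprod(t, pv)
    Ya <- Ya - tcrossprod(t, qv)
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; Q[, a] <- qv
  }

  dimnames(W) <- dimnames(P) <-
    list(colnames(x), sprintf("comp%d", seq_len(n_components)))
  model <- structure(
    list(W = W, P = P, T = Tm, Q = Q,
         ssy = ssy,
         R2X = 1 - sum(Xa^2) / ssx_tot,
         R2Y = 1 - sum(Ya^2) / ssy_tot,
         x_center = x_center, y_center = y_center,
         levels = levels(labels), n_components = n_components,
         converged = converged),
    class = c("plsda_model", "da_model"))
  model$vip <- compute_vip(model)
  model
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d components, %d groups: R2X %.3f, R2Y %.3f\n",
              x$n_components, length(x$levels), x$R2X, x$R2Y))
  invisible(x)
}

#' Predict method for PLS-DA models
#'
#' @param object A `plsda_model`.
#' @param newdata Numeric matrix with the same features as the training
#'   matrix.
#' @param ... Unused.
#' @return List with `y_hat` (predicted class-membership matrix on the
#'   one-hot scale) and `class` (label of the largest prediction).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  xc <- sweep(newdata, 2, object$x_center)
  B <- object$W %*% solve(crossprod(object$P, object$W), t(object$Q))
  y_hat <- sweep(xc %*% B, 2, object$y_center, `+`)
  colnames(y_hat) <- object$levels
  list(y_hat = y_hat,
       class = object$levels[max.col(y_hat, ties.method = "first")])
}

#' Orthogonal PLS discriminant analysis for two groups
#'
#' Splits the predictive variation from label-orthogonal variation: the
#' response-correlated weight vector is computed first, then
#' `n_orthogonal` components orthogonal to the response are removed from
#' the feature matrix (orthogonal signal correction), and a single
#' predictive component is fitted to the filtered matrix. Predictive and
#' orthogonal score vectors are uncorrelated by construction.
#'
#' With `n_orthogonal = "auto"`, orthogonal components are added while the
#' stratified cross-validated Q2 improves by more than 0.01, up to 5.
#'
#' @param x Numeric sample-by-feature matrix (typically autoscaled).
#' @param labels Exactly two groups. For more groups, fit pairwise models.
#' @param n_orthogonal Number of orthogonal components (>= 0), or `"auto"`.
#' @param k,seed Cross-validation folds and seed, used only by `"auto"`.
#' @return An `oplsda_model` (also class `da_model`) with predictive
#'   `w`/`t`/`p`/`q`, orthogonal `W_ortho`/`T_ortho`/`P_ortho`, `R2X`,
#'   `R2Y`, and `vip` (predictive component only).
#' @export
fit_oplsda <- function(x, labels, n_orthogonal = 1, k = 7, seed = 1) {
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) {
    fm_stop("OPLS-DA is defined for exactly 2 groups; run pairwise comparisons for more",
            "invalid_argument")
  }
  fm_assert(length(labels) == nrow(x), "labels must match rows of x")

  if (identical(n_orthogonal, "auto")) {
    n_orthogonal <- select_n_orthogonal(x, labels, k = k, seed = seed)
  }
  n_orthogonal <- fm_count(n_orthogonal, "n_orthogonal", min = 0L)

  x_center <- colMeans(x)
  y0 <- as.numeric(labels == levels(labels)[2])
  y_center <- mean(y0)
  Xa <- sweep(x, 2, x_center)
  y <- y0 - y_center
  ssx_tot <- sum(Xa^2)
  ssy_tot <- sum(y^2)

  w <- drop(crossprod(Xa, y)) / sum(y^2)
  if (sum(w^2) < .Machine$double.eps) {
    fm_stop("the feature matrix carries no covariance with the group labels",
            "invalid_input")
  }
  w <- w / sqrt(sum(w^2))

  p_feat <- ncol(x)
  W_o <- matrix(0, p_feat, n_orthogonal)
  P_o <- matrix(0, p_feat, n_orthogonal)
  T_o <- matrix(0, nrow(x), n_orthogonal)
  n_used <- 0L
  for (i in seq_len(n_orthogonal)) {
    t <- drop(Xa %*% w)
    pv <- drop(crossprod(Xa, t)) / sum(t^2)
    wo <- pv - drop(crossprod(w, pv)) * w
    nrm <- sqrt(sum(wo^2))
    if (nrm < 1e-12) break  # no orthogonal variation left
    wo <- wo / nrm
    to <- drop(Xa %*% wo)
    po <- drop(crossprod(Xa, to)) / sum(to^2)
    Xa <- Xa - tcrossprod(to, po)
    n_used <- n_used + 1L
    W_o[, n_used] <- wo; P_o[, n_used] <- po; T_o[, n_used] <- to
  }
  W_o <- W_o[, seq_len(n_used), drop = FALSE]
  P_o <- P_o[, seq_len(n_used), drop = FALSE]
  T_o <- T_o[, seq_len(n_used), drop = FALSE]

  t <- drop(Xa %*% w)
  j <- which.max(abs(w))
  if (w[j] < 0) {
    w <- -w; t <- -t
  }
  pv <- drop(crossprod(Xa, t)) / sum(t^2)
  qv <- sum(y * t) / sum(t^2)
  y_fit <- t * qv

  model <- structure(
    list(w = stats::setNames(w, colnames(x)), t = t, p = pv, q = qv,
         W_ortho = W_o, P_ortho = P_o, T_ortho = T_o,
         n_orthogonal = n_used,
         R2X = 1 - sum((Xa - tcrossprod(t, pv))^2) / ssx_tot,
         R2Y = 1 - sum((y - y_fit)^2) / ssy_tot,
         x_center = x_center, y_center = y_center,
         levels = levels(labels)),
    class = c("oplsda_model", "da_model"))
  model$vip <- compute_vip(model)
  model
}

#' @export
print.oplsda_model <- function(x, ...) {
  cat(sprintf("<oplsda_model> 1 predictive + %d orthogonal: R2X %.3f, R2Y %.3f\n",
              x$n_orthogonal, x$R2X, x$R2Y))
  invisible(x)
}

select_n_orthogonal <- function(x, labels, cap = 5L, k = 7, seed = 1) {
  k <- min(k, nrow(x))
  best_q2 <- cross_validate_q2(x, labels,
                               model_spec("oplsda", n_orthogonal = 0),
                               k = k, seed = seed)
  n_best <- 0L
  for (n in seq_len(cap)) {
    q2 <- cross_validate_q2(x, labels,
                            model_spec("oplsda", n_orthogonal = n),
                            k = k, seed = seed)
    if (q2 > best_q2 + 0.01) {
      best_q2 <- q2
      n_best <- n
    } else break
  }
  n_best
}

#' Predict method for OPLS-DA models
#'
#' New observations are first filtered through the orthogonal components
#' and then projected onto the predictive component.
#'
#' @param object An `oplsda_model`.
#' @param newdata Numeric matrix with the training features.
#' @param ... Unused.
#' @return List with `y_hat` (predicted membership of the second group, on
#'   the 0/1 scale), `score` (predictive score t), and `class`.
#' @export
predict.oplsda_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  Xn <- sweep(newdata, 2, object$x_center)
  for (i in seq_len(object$n_orthogonal)) {
    to <- drop(Xn %*% object$W_ortho[, i])
    Xn <- Xn - tcrossprod(to, object$P_ortho[, i])
  }
  t_new <- drop(Xn %*% object$w)
  y_hat <- t_new * object$q + object$y_center
  list(y_hat = y_hat, score = t_new,
       class = object$levels[1 + (y_hat > 0.5)])
}

#' Variable importance in projection (VIP)
#'
#' Standard VIP over the predictive components: the squared, weight-based
#' contribution of each feature, weighted by the response variance each
#' component explains, scaled so the mean squared VIP is 1 (hence
#' `sum(VIP^2) == n_features`). For OPLS-DA the VIP of the single
#' predictive component is `sqrt(p) * |w| / ||w||`.
#'
#' @param model A fitted `plsda_model` or `oplsda_model`.
#' @return Named numeric vector of VIP scores (one per feature).
#' @export
compute_vip <- function(model) {
  UseMethod("compute_vip")
}

#' @export
compute_vip.plsda_model <- function(model) {
  W <- model$W
  p <- nrow(W)
  wn2 <- sweep(W^2, 2, colSums(W^2), `/`)  # normalized squared weights
  ssy <- model$ssy
  vip <- sqrt(p * drop(wn2 %*% ssy) / sum(ssy))
  stats::setNames(vip, rownames(W))
}

#' @export
compute_vip.oplsda_model <- function(model) {
  w <- model$w
  sqrt(length(w)) * abs(w) / sqrt(sum(w^2))
}

#' @export
compute_vip.default <- function(model) {
  fm_stop("compute_vip requires a fitted plsda_model or oplsda_model",
          "invalid_state")
}

#' Describe a discriminant model for cross-validation / permutation
#'
#' @param method `"plsda"` or `"oplsda"`.
#' @param n_components Predictive components (PLS-DA).
#' @param n_orthogonal Orthogonal components (OPLS-DA).
#' @return A `model_spec` list.
#' @export
model_spec <- function(method = c("plsda", "oplsda"), n_components = 1,
                       n_orthogonal = 0) {
  method <- match.arg(method)
  structure(list(method = method, n_components = n_components,
                 n_orthogonal = n_orthogonal), class = "model_spec")
}

fit_spec <- function(x, labels, spec) {
  if (spec$method == "plsda") {
    fit_plsda(x, labels, n_components = spec$n_components)
  } else {
    fit_oplsda(x, labels, n_orthogonal = spec$n_orthogonal)
  }
}

## Response matrix used for PRESS/TSS accounting.
spec_response <- function(labels, spec) {
  if (spec$method == "plsda") one_hot(labels)
  else matrix(as.numeric(as.factor(labels) == levels(as.factor(labels))[2]),
              ncol = 1)
}

spec_predict <- function(model, newdata) {
  pr <- predict(model, newdata)
  if (inherits(model, "plsda_model")) pr$y_hat else matrix(pr$y_hat, ncol = 1)
}

## Stratified fold assignment: indices are shuffled within group and fold
## labels dealt round-robin, so tiny groups are spread across folds and all
## k folds are non-empty.
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  fm_assert(k >= 2 && k <= n, "'k' must satisfy 2 <= k <= number of samples")
  set.seed(seed)
  ord <- unlist(lapply(split(seq_len(n), labels), function(ix) {
    if (length(ix) > 1) sample(ix) else ix
  }), use.names = FALSE)
  fold <- integer(n)
  fold[ord] <- rep_len(sample.int(k), n)
  fold
}

#' Cross-validated predictive ability (Q2)
#'
#' Stratified k-fold cross-validation (default 7-fold): the model is refit
#' on each training split and the held-out response predicted;
#' `Q2 = 1 - PRESS / TSS`, where TSS is taken against the training-split
#' response means.
#'
#' @param x Numeric sample-by-feature matrix.
#' @param labels Group labels.
#' @param spec A [model_spec()].
#' @param k Number of folds (default 7, at most the number of samples).
#' @param seed Mandatory seed for the fold assignment.
#' @return Q2 (a real number `<= 1`).
#' @export
cross_validate_q2 <- function(x, labels, spec = model_spec("plsda", 1),
                              k = 7, seed) {
  seed <- fm_check_seed(seed)
  x <- as.matrix(x)
  labels <- as.factor(labels)
  if (k > nrow(x)) fm_stop("'k' cannot exceed the number of samples",
                           "invalid_argument")
  fold <- make_folds(labels, k, seed)
  y_full <- spec_response(labels, spec)
  press <- 0; tss <- 0
  for (f in sort(unique(fold))) {
    test <- fold == f
    model <- fit_spec(x[!test, , drop = FALSE], labels[!test], spec)
    y_hat <- spec_predict(model, x[test, , drop = FALSE])
    y_test <- y_full[test, , drop = FALSE]
    y_bar <- colMeans(y_full[!test, , drop = FALSE])
    press <- press + sum((y_test - y_hat)^2)
    tss <- tss + sum(sweep(y_test, 2, y_bar)^2)
  }
  1 - press / tss
}

#' Label permutation test for a discriminant model
#'
#' Refits the model `n_perm` times with randomly permuted group labels and
#' records R2Y and cross-validated Q2 for each permutation. The empirical
#' p-value uses the add-one convention
#' `p = (1 + #\{permuted >= observed\}) / (n_perm + 1)`, so the smallest
#' attainable p with 200 permutations is 1/201.
#'
#' @param x Numeric sample-by-feature matrix.
#' @param labels Group labels.
#' @param spec A [model_spec()].
#' @param n_perm Number of permutations (default 200).
#' @param k Cross-validation folds for Q2.
#' @param seed Mandatory seed.
#' @return A `permutation_record`: `n_perm`, `observed` (R2Y, Q2),
#'   `permuted` (data.frame of permuted R2Y/Q2), `p_value` (list with
#'   `R2Y` and `Q2`).
#' @export
permutation_test <- function(x, labels, spec = model_spec("plsda", 1),
                             n_perm = 200, k = 7, seed) {
  seed <- fm_check_seed(seed)
  n_perm <- fm_count(n_perm, "n_perm")
  x <- as.matrix(x)
  labels <- as.factor(labels)
  k <- min(k, nrow(x))

  obs_r2y <- fit_spec(x, labels, spec)$R2Y
  obs_q2 <- cross_validate_q2(x, labels, spec, k = k, seed = seed)

  perm_r2y <- numeric(n_perm)
  perm_q2 <- numeric(n_perm)
  set.seed(seed)
  perm_seeds <- sample.int(.Machine$integer.max - 1L, n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(perm_seeds[b])
    lab_b <- sample(labels)
    perm_r2y[b] <- fit_spec(x, lab_b, spec)$R2Y
    perm_q2[b] <- cross_validate_q2(x, lab_b, spec, k = k,
                                    seed = perm_seeds[b])
  }
  structure(
    list(n_perm = n_perm,
         observed = list(R2Y = obs_r2y, Q2 = obs_q2),
         permuted = data.frame(R2Y = perm_r2y, Q2 = perm_q2),
         p_value = list(
           R2Y = (1 + sum(perm_r2y >= obs_r2y)) / (n_perm + 1),
           Q2 = (1 + sum(perm_q2 >= obs_q2)) / (n_perm + 1))),
    class = "permutation_record")
}

#' @export
print.permutation_record <- function(x, ...) {
  cat(sprintf("<permutation_record> %d permutations: observed R2Y %.3f (p = %.4g), Q2 %.3f (p = %.4g)\n",
              x$n_perm, x$observed$R2Y, x$p_value$R2Y,
              x$observed$Q2, x$p_value$Q2))
  invisible(x)
}
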