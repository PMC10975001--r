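#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' two-class response: `n_orthogonal` components orthogonal to the class
#' vector are estimated and removed from the predictor block, then a
#' single predictive PLS component is fitted on the deflated block.
#' Features are centred and unit-variance scaled internally; the class
#' vector is centred. With the response known, every weight vector has a
#' closed-form (`w = X'y / ||X'y||`), so the fit is fully deterministic —
#' no iterative NIPALS start is needed.
#'
#' @param x Predictor block: a features x samples numeric matrix, or a
#'   [feature_table] (missing cells treated as 0).
#' @param y Class labels: numeric +/-1, or a 2-level factor/character
#'   vector, one per sample.
#' @param n_orthogonal Number of orthogonal components (>= 0). Deflation
#'   stops early (with a message in the model) if no orthogonal variation
#'   remains, e.g. for a single-feature block.
#' @return An object of class `opls_model` with elements `weights`
#'   (predictive weight vector, unit norm, named by feature), `scores`
#'   (predictive scores, one per sample), `loadings`, `c` (inner
#'   regression coefficient), `orthogonal` (list with `weights`, `scores`,
#'   `loadings` matrices), `ssy` (explained sum of squares of the centred
#'   response per component, predictive first), `r2y`, `center`, `scale`,
#'   `excluded` (zero-variance features dropped, with a warning),
#'   `n_orthogonal` (number actually fitted).
#' @export
fit_opls_da <- function(x, y, n_orthogonal = 1L) {
  if (is_feature_table(x)) {
    v <- x$values
    v[is.na(v)] <- 0
    x <- v
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  X <- t(x)                                  # samples x features
  n <- nrow(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- encode_classes(y, n)
  if (n_orthogonal > n - 2L)
    stop("n_orthogonal must be <= n_samples - 2 (", n - 2L, ")")
  sds <- apply(X, 2L, stats::sd)
  excluded <- colnames(X)[sds == 0 | is.na(sds)]
  if (length(excluded)) {
    warning("excluding ", length(excluded),
            " zero-variance feature(s): ",
            paste(utils::head(excluded, 5L), collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0L) stop("no feature with non-zero variance")
  ctr <- colMeans(X)
  X <- sweep(sweep(X, 2L, ctr), 2L, sds, "/")
  yc <- y - mean(y)
  ssy_tot <- sum(yc^2)

  orth_w <- orth_t <- orth_p <- NULL
  k <- 0L
  while (k < n_orthogonal) {
    w <- crossprod(X, yc)[, 1L]
    w <- w / sqrt(sum(w^2))
    t_pred <- X %*% w
    p_load <- crossprod(X, t_pred)[, 1L] / sum(t_pred^2)
    wo <- p_load - sum(w * p_load) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-10) break                   # no orthogonal variation left
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to)[, 1L] / sum(to^2)
    X <- X - to %*% t(po)
    orth_w <- cbind(orth_w, wo)
    orth_t <- cbind(orth_t, to)
    orth_p <- cbind(orth_p, po)
    k <- k + 1L
  }

  w <- crossprod(X, yc)[, 1L]
  w <- w / sqrt(sum(w^2))
  t_pred <- (X %*% w)[, 1L]
  p_load <- crossprod(X, t_pred)[, 1L] / sum(t_pred^2)
  c_coef <- sum(yc * t_pred) / sum(t_pred^2)
  ssy <- c(pred = c_coef^2 * sum(t_pred^2))
  if (k > 0L) {
    ssy_orth <- vapply(seq_len(k), function(a) {
      ta <- orth_t[, a]
      (sum(yc * ta)^2) / sum(ta^2)
    }, numeric(1L))
    ssy <- c(ssy, stats::setNames(ssy_orth, paste0("orth", seq_len(k))))
  }
  structure(list(weights = w, scores = t_pred, loadings = p_load,
                 c = c_coef,
                 orthogonal = list(weights = orth_w, scores = orth_t,
                                   loadings = orth_p),
                 ssy = ssy, r2y = unname(ssy[1L]) / ssy_tot,
                 center = ctr, scale = sds, y = yc,
                 excluded = excluded, n_orthogonal = k),
            class = "opls_model")
}

encode_classes <- function(y, n) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric y must be +/-1")
  } else {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) stop("y must have exactly two classes")
    y <- ifelse(as.character(y) == lev[2L], 1, -1)
  }
  if (length(y) != n) stop("length(y) must equal the number of samples")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  y
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: %d features, %d samples, 1 predictive + %d orthogonal; R2Y = %.4f\n",
    length(x$weights), length(x$scores), x$n_orthogonal, x$r2y))
  invisible(x)
}

#' Variable importance in projection
#'
#' Standard PLS-VIP: `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)`
#' over the retained components, with unit-norm weight vectors `w_a` and
#' `SSY_a` the response sum of squares explained by component `a`. By
#' default only the predictive component enters (orthogonal components
#' are class-uncorrelated by construction); the normalisation identity
#' `mean(VIP^2) = 1` holds either way.
#'
#' @param model A fitted [fit_opls_da()] model.
#' @param include_orthogonal Also weight in the orthogonal components by
#'   their (near-zero) explained response sums of squares.
#' @return Named numeric vector of VIP scores for the retained features.
#'   Features excluded for zero variance are absent.
#' @export
vip_scores <- function(model, include_orthogonal = FALSE) {
  W <- matrix(model$weights, ncol = 1L)
  ssy <- model$ssy[1L]
  if (include_orthogonal && model$n_orthogonal > 0L) {
    W <- cbind(W, model$orthogonal$weights)
    ssy <- model$ssy
  }
  p <- nrow(W)
  vip2 <- p * as.numeric(W^2 %*% ssy) / sum(ssy)
  stats::setNames(sqrt(vip2), names(model$weights))
}
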