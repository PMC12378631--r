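#' Fit a PLS1 regression of potency on contact occupancies (NIPALS)
#'
#' Partial least squares with a single response: X columns are centered and
#' (by default) scaled to unit variance, y is centered, and components are
#' extracted by the NIPALS weight-score-loading-deflation iteration. With a
#' single response each component's weight vector has a closed form
#' (the normalized covariance X'y), so one pass per component is exact.
#'
#' Zero-variance X columns get scale 1 and contribute zero weight. A constant
#' y yields an all-zero coefficient vector with a warning.
#'
#' @param X Numeric matrix (or `occupancy_matrix`): rows observations,
#'   columns predictors (contacts). Column names label the coefficients.
#' @param y Numeric response vector (pIC50), one value per row of X.
#' @param n_components Number of latent components; at most
#'   `min(nrow(X) - 1, ncol(X))`. Default `min(2, nrow(X) - 1)`.
#' @param scale Autoscale X columns to unit variance (default TRUE).
#' @return A `pls_sar` model: list with `n_components`, `x_mean`, `x_scale`,
#'   `y_mean`, `weights` (p x A, unit-norm columns), `x_loadings`,
#'   `y_loadings`, `scores`, `beta_standardized`, `beta_raw`, `intercept_raw`,
#'   `contact_ids`, `scaled`.
#' @export
fit_pls <- function(X, y, n_components = NULL, scale = TRUE) {
  X <- unclass(as.matrix(X))
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n < 2) stop("need at least 2 observations")
  if (is.null(n_components)) n_components <- min(2L, n - 1L)
  if (n_components < 1 || n_components > min(n - 1L, p))
    stop(sprintf("n_components must be in 1..%d", min(n - 1L, p)))
  contact_ids <- colnames(X)
  if (is.null(contact_ids)) contact_ids <- paste0("x", seq_len(p))

  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_scale <- if (scale) ifelse(x_sd > 0, x_sd, 1) else rep(1, p)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  y_mean <- mean(y)
  yc <- y - y_mean

  W <- P <- matrix(0, p, n_components)
  Tm <- matrix(0, n, n_components)
  q <- numeric(n_components)
  Xd <- Xc; yd <- yc
  a_done <- 0L
  if (stats::sd(y) == 0) {
    warning("constant response: all PLS coefficients are zero")
  } else {
    for (a in seq_len(n_components)) {
      w <- crossprod(Xd, yd)               # p x 1 covariance direction
      nw <- sqrt(sum(w^2))
      if (nw < 1e-12) break                # residual X carries no covariance
      w <- w / nw
      t_ <- Xd %*% w
      tt <- sum(t_^2)
      if (tt < 1e-12) break
      p_ <- crossprod(Xd, t_) / tt
      q_ <- sum(yd * t_) / tt
      Xd <- Xd - t_ %*% t(p_)
      yd <- yd - q_ * t_
      W[, a] <- w; P[, a] <- p_; Tm[, a] <- t_; q[a] <- q_
      a_done <- a
    }
  }
  if (a_done > 0L) {
    Wa <- W[, seq_len(a_done), drop = FALSE]
    Pa <- P[, seq_len(a_done), drop = FALSE]
    qa <- q[seq_len(a_done)]
    beta_std <- as.numeric(Wa %*% solve(crossprod(Pa, Wa), qa))
  } else {
    beta_std <- numeric(p)
  }
  beta_raw <- beta_std / x_scale
  structure(list(n_components = n_components, n_components_used = a_done,
                 x_mean = x_mean, x_scale = x_scale, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 beta_standardized = beta_std, beta_raw = beta_raw,
                 intercept_raw = y_mean - sum(x_mean * beta_raw),
                 contact_ids = contact_ids, scaled = scale),
            class = "pls_sar")
}

#' @export
print.pls_sar <- function(x, ...) {
  cat(sprintf("<pls_sar> %d predictor(s), %d component(s) (%d used)%s\n",
              length(x$contact_ids), x$n_components, x$n_components_used,
              if (x$scaled) ", autoscaled X" else ""))
  ord <- order(abs(x$beta_standardized), decreasing = TRUE)
  top <- utils::head(ord, 5)
  for (i in top)
    cat(sprintf("  %-30s beta_std %+8.4f\n", x$contact_ids[i],
                x$beta_standardized[i]))
  invisible(x)
}

#' Predict potency from an occupancy matrix
#'
#' @param object A `pls_sar` model.
#' @param newdata Matrix with the model's predictor columns (matched by
#'   column name when present, otherwise by position).
#' @param ... Unused.
#' @return Predicted response vector.
#' @export
predict.pls_sar <- function(object, newdata, ...) {
  X <- unclass(as.matrix(newdata))
  if (!is.null(colnames(X))) {
    if (!setequal(colnames(X), object$contact_ids) ||
        ncol(X) != length(object$contact_ids))
      stop("newdata columns do not match the model's contacts")
    X <- X[, object$contact_ids, drop = FALSE]
  } else if (ncol(X) != length(object$contact_ids)) {
    stop("newdata has wrong number of columns")
  }
  Xs <- sweep(sweep(X, 2, object$x_mean), 2, object$x_scale, "/")
  as.numeric(object$y_mean + Xs %*% object$beta_standardized)
}

#' @export
coef.pls_sar <- function(object, standardized = TRUE, ...) {
  b <- if (standardized) object$beta_standardized else object$beta_raw
  names(b) <- object$contact_ids
  b
}

#' Ranked contact weights of one PLS component
#'
#' @param model A `pls_sar` model.
#' @param component Component number (default 1).
#' @param ligand_group Optional filter: keep only contacts whose id starts
#'   with one of these ligand-side labels (e.g. the C-terminal carboxylate
#'   carbon), matching the contact_id prefix before the `-`.
#' @return data.frame `contact_id`, `weight`, sorted by absolute weight,
#'   descending.
#' @export
contact_weights <- function(model, component = 1L, ligand_group = NULL) {
  if (component < 1 || component > model$n_components)
    stop(sprintf("unknown component %d (model has %d)", component,
                 model$n_components))
  w <- model$weights[, component]
  out <- data.frame(contact_id = model$contact_ids, weight = w,
                    stringsAsFactors = FALSE)
  if (!is.null(ligand_group)) {
    lig_part <- sub("-.*$", "", out$contact_id)
    out <- out[lig_part %in% ligand_group, , drop = FALSE]
  }
  out <- out[order(abs(out$weight), decreasing = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}
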