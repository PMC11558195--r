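#' Fit a PCA latent-variable model on the unfolded matrix
#'
#' Eigen-decomposes the sample covariance `B = Xc' Xc / (n - 1)` of the
#' (column-centered) unfolded matrix via singular value decomposition,
#' `B = U Lambda^2 U'`.  Scores are defined as `S = Xc U Lambda^-1`, so
#' the training-score covariance is exactly the identity and the
#' chi-square control-chart distributions apply directly.  Columns are
#' re-centered before the decomposition because the fixed SpO2 anchor can
#' leave a nonzero mean; the training mean is stored and applied to new
#' observations.  Each loading column's largest-magnitude entry is made
#' positive so results are reproducible across SVD backends.
#'
#' @param X an [variable_wise_unfold()] result or a plain numeric matrix
#'   with more rows than columns.
#' @param c retained components; `NULL` (default) selects the knee of the
#'   eigenvalue scree by [select_components_lcurve()].
#' @param coverage cumulative-variance fallback for the L-curve (default
#'   0.98).
#' @param center center columns before the decomposition (default TRUE).
#' @return Object of class `pca_model`: `U` (J x J orthonormal loadings),
#'   `Lambda` (descending), `c`, `var_explained`, `col_means`, `n_train`,
#'   `usable` (components with `Lambda` above the rank floor),
#'   `signal_labels`.
#' @export
fit_pca <- function(X, c = NULL, coverage = 0.98, center = TRUE) {
  uf <- if (inherits(X, "unfolded_matrix")) X else NULL
  Xm <- if (is.null(uf)) as.matrix(X) else uf$X
  n <- nrow(Xm); J <- ncol(Xm)
  if (n <= J)
    stop_data("need more training rows (%d) than columns (%d)", n, J)
  if (anyNA(Xm)) stop_data("unfolded matrix contains NA entries")
  col_means <- if (center) colMeans(Xm) else rep(0, J)
  Xc <- sweep(Xm, 2L, col_means)
  sv <- svd(Xc, nu = 0L)
  U <- sv$v
  Lambda <- sv$d / sqrt(n - 1)
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(J)) {
    i0 <- which.max(abs(U[, j]))
    if (U[i0, j] < 0) U[, j] <- -U[, j]
  }
  usable <- Lambda > 1e-8 * Lambda[1L]
  ev <- Lambda^2
  var_explained <- ev / sum(ev)
  if (is.null(c)) c <- select_components_lcurve(ev, coverage)
  if (!is_count(c, 1L) || c > J)
    stop_contract("c must be an integer in 1..%d", J)
  if (!all(usable[seq_len(c)]))
    warning("retained components extend beyond the numerical rank of X")
  structure(list(U = U, Lambda = Lambda, c = as.integer(c),
                 var_explained = var_explained, col_means = col_means,
                 n_train = n, usable = usable,
                 signal_labels = colnames(Xm) %||% if (!is.null(uf))
                   uf$signal_labels else NULL),
            class = "pca_model")
}

#' Choose the retained-component count by the L-curve knee
#'
#' Finds the knee of the scree curve (component index versus log
#' eigenvalue) as the index of maximum discrete curvature, evaluated by
#' brute force over all interior candidates; ties resolve to the smaller
#' count.  A monotone-flat spectrum (no curvature) falls back to the
#' smallest count whose cumulative variance reaches `coverage`.
#'
#' @param eigenvalues non-negative, non-increasing spectrum (length >= 3).
#' @param coverage cumulative-variance fallback target (default 0.98).
#' @return Integer component count.
#' @export
select_components_lcurve <- function(eigenvalues, coverage = 0.98) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 3L) stop_contract("need at least 3 eigenvalues")
  fallback <- function() {
    cum <- cumsum(ev) / sum(ev)
    hit <- which(cum >= coverage)
    as.integer(if (length(hit)) hit[1L] else length(ev))
  }
  y <- log(ev[ev > 0])          # curvature on the positive spectrum
  m <- length(y)
  if (m < 3L) return(fallback())
  i <- 2:(m - 1L)
  d2 <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  d1 <- (y[i + 1L] - y[i - 1L]) / 2
  curv <- abs(d2) / (1 + d1^2)^1.5
  if (!any(is.finite(curv)) || max(curv, na.rm = TRUE) < 1e-8)
    return(fallback())
  as.integer(i[which.max(curv)])
}

#' Score observations with a PCA model
#'
#' Computes `s = (x - mean)' U Lambda^-1` on the variance-consistent scale
#' (training-score covariance is the identity).  All J scores are
#' returned so charts can split the retained block `1..c` from the
#' residual block `c+1..J`.  Components whose singular value is at the
#' rank floor get score 0.
#'
#' @param x numeric J-vector or matrix with J columns, already normalized
#'   with the training [fit_normalization()] model.
#' @param model a `pca_model`.
#' @return Score vector or matrix matching the shape of `x`.
#' @export
pca_scores <- function(x, model) {
  stopifnot(inherits(model, "pca_model"))
  vec <- is.null(dim(x))
  Xm <- if (vec) matrix(x, 1L) else as.matrix(x)
  if (ncol(Xm) != nrow(model$U))
    stop_contract("x has %d columns, model expects %d", ncol(Xm),
                  nrow(model$U))
  inv <- ifelse(model$usable, 1 / model$Lambda, 0)
  S <- sweep(Xm, 2L, model$col_means) %*% model$U %*% diag(inv, length(inv))
  if (vec) drop(S) else S
}

#' Fit a slow feature analysis model
#'
#' The unfolded data are sphered with the PCA factors,
#' `Z = Xc U Lambda^-1`, the covariance `A` of the first backward
#' differences of `Z` is formed, and its eigen-decomposition
#' `A = P Omega P'` yields slow features `S = Z P` ordered by increasing
#' slowness (mean squared derivative).  Differences are taken only within
#' a patient's contiguous valid spans — never across patient boundaries or
#' across gaps, which would fabricate derivatives.  `A` is scaled by
#' `1/(n_deriv - 1)` so the training slow-feature covariance stays the
#' identity.
#'
#' @param X an `unfolded_matrix` (its `row_index` orders rows within each
#'   patient), or a plain matrix treated as one contiguous series.
#' @param pca optional pre-fitted `pca_model` for the sphering step; fitted
#'   from `X` when omitted.
#' @param d slow-feature count; defaults to the PCA model's `c`.
#' @return Object of class `sfa_model`: `pca`, `P` (J x J orthonormal),
#'   `Omega` (ascending), `d`, `n_deriv`.
#' @export
fit_sfa <- function(X, pca = NULL, d = NULL) {
  uf <- inherits(X, "unfolded_matrix")
  Xm <- if (uf) X$X else as.matrix(X)
  if (is.null(pca)) pca <- fit_pca(X)
  Z <- pca_scores(Xm, pca)
  if (is.null(dim(Z))) Z <- matrix(Z, 1L)
  if (uf) {
    ri <- X$row_index
    new_run <- c(TRUE, ri$patient_id[-1L] != ri$patient_id[-nrow(ri)] |
                   diff(ri$minute) != 1L)
  } else {
    new_run <- c(TRUE, rep(FALSE, nrow(Z) - 1L))
  }
  keep <- which(!new_run)
  if (length(keep) < 2L)
    stop_data("no contiguous samples to form derivatives")
  Zdot <- Z[keep, , drop = FALSE] - Z[keep - 1L, , drop = FALSE]
  n_d <- nrow(Zdot)
  A <- crossprod(Zdot) / (n_d - 1)
  eg <- eigen(A, symmetric = TRUE)
  ord <- rev(seq_along(eg$values))      # ascending slowness
  Omega <- pmax(eg$values[ord], 0)
  P <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(P))) {
    i0 <- which.max(abs(P[, j]))
    if (P[i0, j] < 0) P[, j] <- -P[, j]
  }
  d <- d %||% pca$c
  if (!is_count(d, 1L) || d > ncol(P))
    stop_contract("d must be an integer in 1..%d", ncol(P))
  structure(list(pca = pca, P = P, Omega = Omega, d = as.integer(d),
                 n_deriv = n_d),
            class = "sfa_model")
}

#' Score observations with an SFA model
#'
#' `s = (x - mean)' U Lambda^-1 P`, split by convention into the slow
#' block `1..d` and the fast block `d+1..J`.
#'
#' @param x numeric J-vector or matrix, normalized like the training data.
#' @param model an `sfa_model`.
#' @return Score vector or matrix.
#' @export
sfa_scores <- function(x, model) {
  stopifnot(inherits(model, "sfa_model"))
  Z <- pca_scores(x, model$pca)
  vec <- is.null(dim(Z))
  S <- (if (vec) matrix(Z, 1L) else Z) %*% model$P
  if (vec) drop(S) else S
}

#' Empirical slowness of a feature series
#'
#' Mean squared backward difference; for a unit-variance feature this is
#' the quantity by which slow features are ordered.  `NA` entries are
#' dropped before differencing.
#'
#' @param series numeric vector (>= 2 non-missing samples).
#' @return Numeric scalar.
#' @export
slowness <- function(series) {
  s <- series[!is.na(series)]
  if (length(s) < 2L) stop_data("need at least 2 samples")
  mean(diff(s)^2)
}

#' Serialize latent models to a JSON bundle
#'
#' Stores the loading matrices, spectrum, retained counts, training row
#' count and training column means; [read_latent_models()] restores them.
#'
#' @param pca a `pca_model`.
#' @param sfa an `sfa_model` fitted with the same PCA step (optional).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_latent_models <- function(pca, sfa = NULL, path) {
  bundle <- list(
    pca = list(U = pca$U, Lambda = pca$Lambda, c = pca$c,
               var_explained = pca$var_explained, col_means = pca$col_means,
               n_train = pca$n_train, usable = pca$usable,
               signal_labels = pca$signal_labels))
  if (!is.null(sfa))
    bundle$sfa <- list(P = sfa$P, Omega = sfa$Omega, d = sfa$d,
                       n_deriv = sfa$n_deriv)
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_latent_models
#' @export
read_latent_models <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  pca <- structure(list(U = as.matrix(b$pca$U),
                        Lambda = b$pca$Lambda, c = as.integer(b$pca$c),
                        var_explained = b$pca$var_explained,
                        col_means = b$pca$col_means,
                        n_train = b$pca$n_train, usable = b$pca$usable,
                        signal_labels = b$pca$signal_labels),
                   class = "pca_model")
  sfa <- if (!is.null(b$sfa))
    structure(list(pca = pca, P = as.matrix(b$sfa$P), Omega = b$sfa$Omega,
                   d = as.integer(b$sfa$d), n_deriv = b$sfa$n_deriv),
              class = "sfa_model")
  list(pca = pca, sfa = sfa)
}
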