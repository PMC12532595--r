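#' @keywords internal
"_PACKAGE"

# Competition ranking: ties share the best rank, subsequent ranks skipped.
# `score` is ranked so the LARGEST score gets rank 1 when decreasing = TRUE.
competition_rank <- function(score, decreasing = TRUE) {
  s <- if (decreasing) -score else score
  rank(s, ties.method = "min")
}

# Pearson r^2 between dosage columns; rows = individuals.
dosage_r2 <- function(dosages) {
  r <- suppressWarnings(stats::cor(dosages))
  r[!is.finite(r)] <- 0
  r^2
}

# Residualize columns of `x` on covariate matrix `C` (intercept added).
# Returns the residual matrix; uses one QR decomposition for all columns.
residualize <- function(x, C = NULL) {
  x <- as.matrix(x)
  if (is.null(C)) C <- matrix(1, nrow(x), 1) else C <- cbind(1, as.matrix(C))
  qrC <- qr(C)
  x - qr.fitted(qrC, x)
}

# Build a design matrix from a covariate data.frame: factors/characters are
# expanded to treatment-coded dummies, numerics kept as-is.
covariate_matrix <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  if (ncol(covariates) == 0L) return(NULL)
  mm <- stats::model.matrix(~., data = covariates)
  mm[, -1, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
}
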