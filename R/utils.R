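# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
.chol_psd <- function(S, ridge = 1e-8, max_tries = 6L) {
  # Cholesky with escalating diagonal ridge for matrices that are PSD only
  # up to floating-point error. Returns the factor plus the ridge applied.
  r <- 0
  for (i in seq_len(max_tries)) {
    L <- tryCatch(chol(S + diag(r, nrow(S))), error = function(e) NULL)
    if (!is.null(L)) return(structure(L, ridge = r))
    r <- if (r == 0) ridge else r * 100
  }
  stop("matrix is not positive semidefinite (ridge up to ", r, " failed)")
}

#' @noRd
.log_dmvnorm0 <- function(z, S) {
  # log density of MVN(0, S) at z, via Cholesky.
  L <- .chol_psd(S)
  u <- backsolve(L, z, transpose = TRUE)
  -0.5 * length(z) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(u^2)
}

#' @noRd
.is_square_corr <- function(V, tol = 1e-6) {
  is.matrix(V) && nrow(V) == ncol(V) &&
    max(abs(diag(V) - 1)) < tol && max(abs(V - t(V))) < tol
}

#' @noRd
.standardize <- function(X) {
  # Column-standardize, guarding zero-variance columns (left at 0).
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- Inf
  scale(X, center = mu, scale = sd)[, , drop = FALSE]
}

#' Percent increase of one count over another
#'
#' Computes `100 * (count_new / count_ref - 1)`, the convention used when
#' reporting how many more discoveries one method makes than another.
#'
#' @param count_new Numerator quantity (e.g. discoveries of the new method).
#' @param count_ref Reference quantity; must be nonzero.
#' @return Percent increase as a plain number (e.g. 52.4 for +52.4%).
#' @examples
#' percent_increase(439, 288) # 52.43
#' @export
percent_increase <- function(count_new, count_ref) {
  stopifnot(is.numeric(count_new), is.numeric(count_ref))
  if (any(count_ref == 0)) stop("percent increase undefined for a zero reference")
  100 * (count_new / count_ref - 1)
}
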