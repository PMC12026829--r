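# Genomic relationship matrix (VanRaden method 1).

#' Per-marker allele frequencies from dosages
#'
#' @param markers Lines x markers dosage matrix (values 0/1/2, NA allowed).
#' @return Numeric vector of frequencies p_j = mean(dosage_j) / 2 in [0, 1],
#'   named by marker.
#' @export
allele_frequencies <- function(markers) {
  colMeans(markers, na.rm = TRUE) / 2
}

#' Compute the genomic relationship matrix
#'
#' VanRaden's first method: with dosages x_ij and allele frequencies p_j
#' estimated from all lines, the centered matrix W has entries
#' w_ij = x_ij - 2 p_j and
#' \deqn{G = W W' / (2 \sum_j p_j (1 - p_j)).}
#' Missing dosages are mean-imputed per marker before centering (which leaves
#' the allele-frequency estimates unchanged). Monomorphic markers contribute
#' nothing to the numerator and, under the default policy, are dropped so the
#' denominator reflects informative markers only.
#'
#' @param markers Lines x markers dosage matrix with line IDs as rownames.
#' @param monomorphic_policy `"drop"` (default) removes monomorphic markers
#'   before the computation; `"keep"` retains them (they still contribute 0
#'   to both numerator and denominator).
#' @param epsilon Non-negative ridge added to the diagonal when a strictly
#'   positive-definite G is required downstream (stored, not applied to
#'   `values`).
#' @return An object of class `gblupqm_grm`: list with `values` (the n x n
#'   matrix G), `line_ids`, `regularization_epsilon`, `allele_freqs`, and
#'   `n_markers_used`.
#' @examples
#' X <- matrix(c(0, 2, 1, 2, 0, 1), nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("m1", "m2")))
#' compute_grm(X)$values
#' @export
compute_grm <- function(markers,
                        monomorphic_policy = c("drop", "keep"),
                        epsilon = 1e-6) {
  monomorphic_policy <- match.arg(monomorphic_policy)
  stopifnot(is.matrix(markers), epsilon >= 0)
  if (nrow(markers) < 2L || ncol(markers) < 2L) {
    stop("need at least 2 lines and 2 markers", call. = FALSE)
  }
  ids <- rownames(markers)
  if (is.null(ids)) ids <- sprintf("L%04d", seq_len(nrow(markers)))

  X <- markers
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- mu[na_idx[, 2]]
  }

  p <- colMeans(X) / 2
  # polymorphic = the dosage actually varies (a constant all-heterozygote
  # column has p = 0.5 yet carries no information)
  poly <- colMeans(X^2) - colMeans(X)^2 > 0
  if (!any(poly)) {
    stop("all markers are monomorphic; G is undefined", call. = FALSE)
  }
  if (monomorphic_policy == "drop") {
    X <- X[, poly, drop = FALSE]
    p <- p[poly]
  }
  if (sum(poly) < 2L) {
    stop("need at least 2 polymorphic markers", call. = FALSE)
  }

  W <- sweep(X, 2L, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(ids, ids)

  structure(
    list(values = G,
         line_ids = ids,
         regularization_epsilon = epsilon,
         allele_freqs = p,
         n_markers_used = ncol(X)),
    class = "gblupqm_grm"
  )
}

# Regularized copy G + epsilon * I used wherever invertibility is required.
grm_regularized <- function(grm) {
  grm$values + diag(grm$regularization_epsilon, nrow(grm$values))
}

#' @export
print.gblupqm_grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d lines, %d markers used, eps = %g\n",
              length(x$line_ids), x$n_markers_used,
              x$regularization_epsilon))
  cat(sprintf("diagonal mean %.4f, range [%.4f, %.4f]\n",
              mean(diag(x$values)), min(x$values), max(x$values)))
  invisible(x)
}
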