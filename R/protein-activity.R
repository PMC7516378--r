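# Protein signaling activity by Exponential Ranking
#
# A node-ranking method for signed, directed, weighted networks based on
# discrete choice theory: "trust" (activity) flows along edges, and signed
# weights let inhibitory links subtract trust. The transition matrix is
# augmented with expression so that only expressed interactors conduct:
# A = x x^T o B (elementwise on edges), and the iteration
#   p(t+1) = exp((1/mu) A^T p(t)) / || exp((1/mu) A^T p(t)) ||_1
# is run to a fixed point with mu = max(A) - min(A), a choice inside the
# range that guarantees convergence.

#' Build the expression-augmented transition matrix
#'
#' `A[i, j] = x_i * x_j * sign_ij * weight_ij` for each edge i -> j, zero
#' elsewhere; `mu = max(A) - min(A)` over all entries (structural zeros
#' included).
#'
#' @param net A [signed_network].
#' @param expr Named nonnegative numeric vector of expression covering all
#'   proteins of the network.
#' @return Object of class `transition_matrix`: list with `A` (dense
#'   protein x protein matrix) and `mu`.
#' @export
build_transition_matrix <- function(net, expr) {
  prots <- net$proteins
  missing <- setdiff(prots, names(expr))
  if (length(missing))
    stop("expression missing for proteins: ",
         paste(utils::head(missing, 10), collapse = ", "))
  x <- expr[prots]
  if (any(x < 0)) stop("expression must be nonnegative")
  A <- matrix(0, length(prots), length(prots), dimnames = list(prots, prots))
  ed <- net$edges
  A[cbind(ed$src, ed$dst)] <- x[ed$src] * x[ed$dst] * ed$sign * ed$weight
  mu <- max(A) - min(A)
  if (mu == 0) stop("transition matrix is constant; cannot rank")
  structure(list(A = A, mu = mu), class = "transition_matrix")
}

#' Exponential Ranking of protein activity
#'
#' Iterates `p <- exp((1/mu) A^T p) / ||.||_1` from a positive, sum-one
#' start vector until the l2 norm of consecutive differences falls below
#' `tolerance` (the Frobenius norm of a vector equals its l2 norm). The
#' exponential is stabilized by max-subtraction, which leaves the
#' normalized iterate unchanged; after every step `||p||_1 = 1`.
#'
#' @param trans A `transition_matrix` from [build_transition_matrix].
#' @param p0 Positive start vector over the proteins (defaults to uniform);
#'   typically expression predicted by the regulatory models scaled to sum
#'   1. Normalized internally.
#' @param tolerance Convergence tolerance (default 1e-6).
#' @param max_iter Iteration cap.
#' @return Object of class `activity_scores`: list with `p` (named score
#'   vector), `transformed` (signed-log scores, see [transform_scores]),
#'   `iterations`, `converged`, `mu`.
#' @export
exponential_ranking <- function(trans, p0 = NULL, tolerance = 1e-6,
                                max_iter = 10000L) {
  A <- trans$A; mu <- trans$mu
  n <- nrow(A)
  if (is.null(p0)) p0 <- rep(1 / n, n)
  if (!is.null(names(p0))) p0 <- p0[rownames(A)]
  if (any(p0 <= 0)) stop("p0 entries must be positive")
  p <- p0 / sum(p0)
  At <- t(A)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    v <- as.numeric(At %*% p) / mu
    v <- v - max(v)
    e <- exp(v)
    p_new <- e / sum(e)
    delta <- sqrt(sum((p_new - p)^2))
    p <- p_new
    if (delta < tolerance) { converged <- TRUE; break }
  }
  names(p) <- rownames(A)
  structure(list(p = p, transformed = transform_scores(p),
                 iterations = iter, converged = converged, mu = mu),
            class = "activity_scores")
}

#' Signed-log transform of activity scores
#'
#' Positive scores map to `log(p)`, negative scores to `-log(|p|)` (the
#' sign is preserved so inhibition stays interpretable), zeros map to 0
#' with a warning. Strictly monotone on positives.
#'
#' @param p Numeric vector (typically converged rank scores).
#' @return Numeric vector of transformed scores (names kept).
#' @export
transform_scores <- function(p) {
  out <- numeric(length(p)); names(out) <- names(p)
  if (any(p == 0)) warning("zero scores transformed to 0")
  pos <- p > 0; neg <- p < 0
  out[pos] <- log(p[pos])
  out[neg] <- -log(-p[neg])
  out
}

#' Perturbation-induced activity deltas
#'
#' Difference of signed-log transformed activity between a perturbed and a
#' baseline ranking run, per protein.
#'
#' @param baseline,perturbed `activity_scores` objects over the same
#'   protein universe.
#' @return Named numeric vector `transformed_perturbed -
#'   transformed_baseline`.
#' @export
activity_delta <- function(baseline, perturbed) {
  if (!identical(names(baseline$p), names(perturbed$p)))
    stop("protein universes differ between the two score sets")
  perturbed$transformed - baseline$transformed
}
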