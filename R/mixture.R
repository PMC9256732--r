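## Normal-mixture prior on SNP effects: component variances, the
## component-indicator multinomial, and Dirichlet updates of the mixing
## proportions (per class for BayesRC).

#' Construct a mixture prior
#'
#' @param alloc allocation scalars multiplying sigma_g^2; strictly
#'   increasing with the zero spike first. The historical default is
#'   (0, 1e-4, 1e-3, 1e-2); more components (e.g. adding 1e-5) are
#'   allowed.
#' @param alpha Dirichlet concentration: a vector (recycled per class)
#'   or a matrix with one row per class. Default uninformative
#'   (1, 1, ..., 1).
#' @param snpClass integer class label per marker (1..nClasses); NULL or
#'   all-1 gives plain BayesR, more classes give BayesRC with mixing
#'   proportions estimated separately per class.
#' @param nClasses number of classes (defaults to max(snpClass)).
#' @return a [MixturePrior-class].
#' @examples
#' mixturePrior()                       # plain BayesR, 4 components
#' mixturePrior(snpClass = c(1, 1, 2))  # two-class BayesRC
#' @export
mixturePrior <- function(alloc = c(0, 1e-4, 1e-3, 1e-2), alpha = NULL,
                         snpClass = NULL, nClasses = NULL) {
  K <- length(alloc)
  if (is.null(snpClass)) snpClass <- integer(0)
  snpClass <- as.integer(snpClass)
  if (is.null(nClasses))
    nClasses <- if (length(snpClass)) max(snpClass) else 1L
  if (is.null(alpha)) alpha <- rep(1, K)
  if (is.null(dim(alpha)))
    alpha <- matrix(alpha, nrow = nClasses, ncol = K, byrow = TRUE)
  new("MixturePrior", alloc = as.numeric(alloc), alpha = alpha,
      snpClass = snpClass, nClasses = as.integer(nClasses))
}

#' Component variances from the genetic variance
#'
#' sigma_k^2 = a_k * sigma_g^2 for each allocation scalar a_k; refreshed
#' at the end of every outer cycle after sigma_g^2 is sampled.
#'
#' @param sigmaG2 additive genetic variance (>= 0).
#' @param alloc allocation scalars.
#' @return numeric vector of component variances.
#' @examples
#' componentVariances(625)   # c(0, 0.0625, 0.625, 6.25)
#' @export
componentVariances <- function(sigmaG2, alloc = c(0, 1e-4, 1e-3, 1e-2)) {
  if (sigmaG2 < 0) stop("sigmaG2 must be non-negative")
  alloc * sigmaG2
}

#' Sample a mixture-component indicator
#'
#' Draws the latent component k for one marker from its conditional
#' multinomial given the least-squares effect estimate gBar. The
#' unnormalised weight is p_k = pi_k * exp(-0.5 gBar^2 / v_k) / sqrt(v_k)
#' with v_k = sigma_k^2 + sigma_e^2/d_jj (\code{"sampling"}, the
#' default: the marginal variance of the least-squares estimate when
#' the marker sits in component k), or v_k = sigma_k^2 + sigma_e^2
#' (\code{"residual"}). The draw uses a single uniform x in [0, 1) and
#' returns the smallest k whose cumulative normalised weight reaches x.
#'
#' @param gBar least-squares estimate of the marker effect.
#' @param pi mixing-proportion vector for the marker's class.
#' @param sigmaK2 component variances.
#' @param sigmaE2 residual variance (> 0).
#' @param djj weighted diagonal element (V'WV)_jj, used by
#'   \code{"sampling"}.
#' @param likelihood \code{"sampling"} (default) or \code{"residual"}.
#' @return integer component index.
#' @export
sampleComponent <- function(gBar, pi, sigmaK2, sigmaE2, djj = 1,
                            likelihood = c("sampling", "residual")) {
  likelihood <- match.arg(likelihood)
  if (!is.finite(gBar)) stop("non-finite least-squares estimate")
  stopifnot(sigmaE2 > 0)
  v <- sigmaK2 + if (likelihood == "residual") sigmaE2 else sigmaE2 / djj
  logp <- log(pi) - 0.5 * gBar^2 / v - 0.5 * log(v)
  logp[pi == 0] <- -Inf
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  x <- runif(1)
  which(cumsum(p) >= x)[1]
}

#' Exact conditional component probabilities
#'
#' The normalised multinomial weights used by [sampleComponent()];
#' exposed for diagnostics and testing.
#'
#' @inheritParams sampleComponent
#' @return numeric probability vector summing to 1.
#' @export
componentProbabilities <- function(gBar, pi, sigmaK2, sigmaE2, djj = 1,
                                   likelihood = c("sampling", "residual")) {
  likelihood <- match.arg(likelihood)
  v <- sigmaK2 + if (likelihood == "residual") sigmaE2 else sigmaE2 / djj
  logp <- log(pi) - 0.5 * gBar^2 / v - 0.5 * log(v)
  logp[pi == 0] <- -Inf
  p <- exp(logp - max(logp))
  p / sum(p)
}

#' Sample mixing proportions from their Dirichlet posterior
#'
#' pi ~ Dirichlet(alpha + beta), one independent draw per class, where
#' beta holds the current per-class counts of markers per component.
#'
#' @param beta counts matrix (classes x components) or vector for one
#'   class.
#' @param alpha concentration matrix or vector, matching beta.
#' @return matrix of per-class mixing proportions (rows sum to 1).
#' @export
sampleMixingProportions <- function(beta, alpha) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  if (is.null(dim(alpha)))
    alpha <- matrix(alpha, nrow = nrow(beta), ncol = ncol(beta),
                    byrow = TRUE)
  stopifnot(all(beta >= 0))
  out <- matrix(0, nrow(beta), ncol(beta))
  for (cl in seq_len(nrow(beta))) {
    gdraw <- rgamma(ncol(beta), shape = alpha[cl, ] + beta[cl, ], rate = 1)
    out[cl, ] <- gdraw / sum(gdraw)
  }
  out
}

#' Read a SNP-class file
#'
#' Tab-separated \code{marker_id <tab> class_integer}, no header
#' required (a header line is detected and skipped if the second column
#' is non-numeric). Markers absent from the file default to class 1.
#'
#' @param path file path.
#' @param markerIds marker ids of the analysis panel, in order.
#' @return integer class vector aligned to \code{markerIds}.
#' @export
readSnpClasses <- function(path, markerIds) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = "auto",
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("class file needs two columns: ", path)
  cls <- rep(1L, length(markerIds))
  idx <- match(as.character(dt[[1]]), markerIds)
  ok <- !is.na(idx)
  cls[idx[ok]] <- as.integer(dt[[2]][ok])
  if (any(cls < 1L)) stop("class labels must be positive integers")
  cls
}
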