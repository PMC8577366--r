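#' @rdname summarizeDistribution
setMethod("summarizeDistribution", "numeric", function(object, ...) {
  x <- object[is.finite(object)]
  if (length(x) < 2) stop("need at least 2 valid values")
  s <- stats::sd(x)
  data.frame(mean = mean(x), sd = s,
             skewness = if (s == 0) 0 else skewnessAdj(x),
             nPixels = length(x))
})

#' @rdname summarizeDistribution
setMethod("summarizeDistribution", "PredictionMap", function(object, ...) {
  v <- object@em[object@mask]
  if (length(v) < 2) stop("fewer than 2 masked-valid pixels")
  summarizeDistribution(v)
})

#' @rdname summarizeDistribution
setMethod("summarizeDistribution", "EMField", function(object, ...) {
  summarizeDistribution(as.vector(object@values))
})

#' Select the number of clusters by the gap criterion
#'
#' Gap-statistic model selection (Tibshirani et al.) over k = 1..kMax on the
#' distribution-summary features, with squared-Euclidean within-cluster
#' dispersion (k-means clustering), B uniform reference datasets sampled over
#' the feature bounding box, and the one-standard-error rule: the smallest k
#' with Gap(k) >= Gap(k+1) - s(k+1). Degenerate feature sets (all rows
#' identical) return 1.
#'
#' @param features n x d numeric matrix (rows = samples); n must exceed
#'   \code{kMax}.
#' @param kMax maximum number of clusters considered.
#' @param B reference datasets.
#' @param seed integer seed (reference sampling and k-means restarts).
#' @param nstart k-means random restarts.
#' @return a list: \code{k} (selected), \code{gap} data.frame (logW, gap,
#'   SE) per k.
#' @export
selectK <- function(features, kMax = 6L, B = 100L, seed = 1L, nstart = 20L) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < kMax + 1) stop("need at least kMax + 1 samples")
  if (all(apply(features, 2, function(x) diff(range(x))) < 1e-12))
    return(list(k = 1L, gap = NULL))
  gs <- withSeed(seed,
    cluster::clusGap(features,
                     FUNcluster = function(x, k)
                       list(cluster = stats::kmeans(x, k, nstart = nstart,
                                                    iter.max = 100)$cluster),
                     K.max = kMax, B = B, d.power = 2,
                     spaceH0 = "original", verbose = FALSE))
  tab <- as.data.frame(gs$Tab)
  k <- cluster::maxSE(tab$gap, tab$SE.sim, method = "Tibs2001SEmax")
  list(k = as.integer(k), gap = tab)
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' Expectation-maximisation fit of a k-component Gaussian mixture with
#' diagonal covariance matrices to the summary features, in the manner of
#' MATLAB's \code{fitgmdist}: a regularisation value is added to every
#' variance, convergence is declared when the relative log-likelihood change
#' drops below \code{tol}, starting values are chosen at random (component
#' means drawn from the data) with uniform initial mixing proportions, and
#' the best of \code{replicates} restarts by log-likelihood is returned. If
#' no replicate converges the best model is returned with
#' \code{converged = FALSE} and a warning.
#'
#' @param features n x d numeric matrix.
#' @param k number of components (default 3).
#' @param tol relative log-likelihood tolerance.
#' @param reg variance regularisation floor.
#' @param replicates random restarts.
#' @param maxIter EM iterations per replicate.
#' @param seed integer seed.
#' @return a \linkS4class{MixtureModel}.
#' @export
fitMixture <- function(features, k = 3L, tol = 1e-6, reg = 0.01,
                       replicates = 10L, maxIter = 500L, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  if (n < k) stop("need at least k samples")
  bestLL <- -Inf; best <- NULL; anyConv <- FALSE
  traces <- vector("list", replicates)
  withSeed(seed, {
    for (rep in seq_len(replicates)) {
      mu <- X[sample.int(n, k), , drop = FALSE]
      va <- matrix(rep(apply(X, 2, stats::var) + reg, each = k), k, d)
      va[!is.finite(va) | va < reg] <- reg
      w <- rep(1 / k, k)
      ll <- -Inf; conv <- FALSE; llTrace <- numeric()
      for (it in seq_len(maxIter)) {
        # E step: log responsibilities
        logp <- sapply(seq_len(k), function(j)
          log(w[j]) + rowSums(stats::dnorm(X,
            matrix(mu[j, ], n, d, byrow = TRUE),
            matrix(sqrt(va[j, ]), n, d, byrow = TRUE), log = TRUE)))
        if (is.null(dim(logp))) logp <- matrix(logp, n, k)
        mx <- apply(logp, 1, max)
        pse <- exp(logp - mx)
        rs <- rowSums(pse)
        llNew <- sum(mx + log(rs))
        llTrace <- c(llTrace, llNew)
        R <- pse / rs
        # M step
        nk <- colSums(R)
        nk <- pmax(nk, 1e-12)
        w <- nk / n
        for (j in seq_len(k)) {
          mu[j, ] <- colSums(R[, j] * X) / nk[j]
          va[j, ] <- colSums(R[, j] * sweep(X, 2, mu[j, ])^2) / nk[j] + reg
        }
        if (is.finite(ll) && abs(llNew - ll) <= tol * abs(llNew)) {
          ll <- llNew; conv <- TRUE; break
        }
        ll <- llNew
      }
      anyConv <- anyConv || conv
      traces[[rep]] <- llTrace
      if (ll > bestLL) {
        bestLL <- ll
        best <- list(w = w, mu = mu, va = va, conv = conv)
      }
    }
  })
  if (!anyConv) warning("no EM replicate converged; returning best model")
  out <- new("MixtureModel", k = as.integer(k), weights = best$w / sum(best$w),
             means = best$mu, variances = best$va, logLik = bestLL,
             converged = best$conv)
  attr(out, "logLikTrace") <- traces
  out
}

# per-sample posterior cluster assignment under a MixtureModel
mixtureAssign <- function(model, features) {
  X <- as.matrix(features)
  n <- nrow(X); d <- ncol(X)
  logp <- sapply(seq_len(model@k), function(j)
    log(model@weights[j]) + rowSums(stats::dnorm(X,
      matrix(model@means[j, ], n, d, byrow = TRUE),
      matrix(sqrt(model@variances[j, ]), n, d, byrow = TRUE), log = TRUE)))
  if (is.null(dim(logp))) logp <- matrix(logp, n, model@k)
  apply(logp, 1, which.max)
}

# fixed precedence for naming ties
.labelOrder <- c("tumour", "no_tumour", "necrotic", "fibrotic")

#' Assign clusters and name them from member labels
#'
#' Assigns each sample its maximum-posterior mixture component, then names
#' every cluster by the most frequent pathology label among its members
#' (compound sample labels contribute each of their tokens). Frequency ties
#' break by the fixed order tumour > no_tumour > necrotic > fibrotic. When
#' two clusters would receive the same name, later (smaller) clusters get a
#' compound name with their next-most-frequent distinct label prepended
#' (e.g. \code{"necrotic/no_tumour"}), mirroring how a second non-tumour
#' cluster is distinguished from the first. Empty clusters are named
#' \code{"unassigned"}.
#'
#' @param model a fitted \linkS4class{MixtureModel}.
#' @param records data.frame with columns \code{sampleId} and \code{labels}
#'   ("/"-separated label tokens), plus the feature columns \code{mean},
#'   \code{sd}, \code{skewness}.
#' @param features optional n x d matrix overriding the feature columns.
#' @return \code{records} with added columns \code{cluster} and
#'   \code{predictedName}.
#' @export
assignAndName <- function(model, records, features = NULL) {
  if (is.null(features))
    features <- as.matrix(records[, c("mean", "sd", "skewness")])
  cl <- mixtureAssign(model, features)
  labTokens <- strsplit(records$labels, "/", fixed = TRUE)
  clusterName <- character(model@k)
  # name clusters in decreasing size so the dominant cluster keeps the plain name
  sizes <- tabulate(cl, model@k)
  for (ci in order(-sizes)) {
    members <- which(cl == ci)
    if (!length(members)) { clusterName[ci] <- "unassigned"; next }
    tok <- unlist(labTokens[members])
    counts <- table(factor(tok, levels = .labelOrder))
    ranked <- names(counts)[order(-as.numeric(counts))]  # stable: ties keep .labelOrder
    ranked <- ranked[counts[ranked] > 0]
    nm <- ranked[1]
    if (nm %in% clusterName && length(ranked) > 1) {
      alt <- setdiff(ranked, nm)[1]
      nm <- paste(alt, nm, sep = "/")
    } else if (nm %in% clusterName) {
      nm <- paste0(nm, "/", ci)
    }
    clusterName[ci] <- nm
  }
  records$cluster <- cl
  records$predictedName <- clusterName[cl]
  records
}

#' Classification accuracy against pathology labels
#'
#' A prediction is correct when the predicted cluster name matches at least
#' one part of the pathological assessment: any "/"-token of the predicted
#' name being a member of the record's label set counts as correct.
#'
#' @param records data.frame with columns \code{predictedName} and
#'   \code{labels} ("/"-separated tokens).
#' @return fraction of correct predictions.
#' @examples
#' r <- data.frame(predictedName = c("no_tumour", "tumour"),
#'                 labels = c("necrotic/tumour/no_tumour", "no_tumour"))
#' scoreAccuracy(r)   # 0.5
#' @export
scoreAccuracy <- function(records) {
  stopifnot(all(c("predictedName", "labels") %in% names(records)))
  ok <- mapply(function(p, l) {
    pt <- strsplit(p, "/", fixed = TRUE)[[1]]
    lt <- strsplit(l, "/", fixed = TRUE)[[1]]
    any(pt %in% lt)
  }, records$predictedName, records$labels)
  mean(ok)
}
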