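# Bayesian hyperparameter optimization over the discrete tuning grid:
# a Gaussian-process (RBF kernel) surrogate with expected improvement,
# evaluated on the stepped search space.

#' The hyperparameter search space
#'
#' @return List of candidate values: message-passing iterations T in 2..6,
#'   inter-atomic scaler lambda in [0, 0.5] step 0.05, hidden dimension d
#'   in [300, 2400] step 100, dropout p in [0, 0.4] step 0.05.
#' @export
hyperparamGrid <- function() {
  list(T = 2:6,
       lambda = seq(0, 0.5, by = 0.05),
       d = seq(300L, 2400L, by = 100L),
       p = seq(0, 0.4, by = 0.05))
}

.encodeConfig <- function(cfg, space) {
  vapply(names(space), function(nm) {
    v <- space[[nm]]
    if (length(v) == 1) return(0.5)
    (match(cfg[[nm]], v) - 1) / (length(v) - 1)
  }, numeric(1))
}

.gpFit <- function(X, y, ell = 0.3, noise = 1e-4) {
  n <- nrow(X)
  d2 <- as.matrix(stats::dist(X)) ^ 2
  K <- exp(-d2 / (2 * ell ^ 2)) + diag(noise, n)
  mu <- mean(y)
  list(X = X, alpha = solve(K, y - mu), K = K, mu = mu, ell = ell)
}

.gpPredict <- function(fit, Xnew) {
  d2 <- outer(rowSums(Xnew ^ 2), rowSums(fit$X ^ 2), "+") -
    2 * Xnew %*% t(fit$X)
  ks <- exp(-pmax(d2, 0) / (2 * fit$ell ^ 2))
  mean <- fit$mu + ks %*% fit$alpha
  # predictive variance via the kernel diagonal
  Kinv_ks <- solve(fit$K, t(ks))
  var <- pmax(1 - colSums(t(ks) * Kinv_ks), 1e-12)
  list(mean = as.numeric(mean), sd = sqrt(var))
}

.expectedImprovement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian hyperparameter search
#'
#' Sequential model-based optimization on the discrete grid: an initial
#' seeded random design, then a Gaussian-process surrogate proposing the
#' expected-improvement maximizer among random grid candidates. At most
#' \code{iters} objective evaluations are performed; the budget convention
#' is 20 iterations of 30-epoch trainings.
#'
#' @param objective Function taking a named config list (\code{T},
#'   \code{lambda}, \code{d}, \code{p}) and returning a scalar score.
#' @param space Named list of candidate value vectors (default
#'   \code{\link{hyperparamGrid}}).
#' @param iters Total objective evaluations (default 20).
#' @param nInit Random initial design size.
#' @param maximize Maximize (TRUE) or minimize the objective.
#' @param seed Integer seed; the full trial sequence is deterministic.
#' @return List with \code{best} (config), \code{bestScore}, and
#'   \code{trials} (data.frame of all evaluations).
#' @export
bayesianHyperopt <- function(objective, space = hyperparamGrid(),
                             iters = 20L, nInit = 5L, maximize = FALSE,
                             seed = 0L) {
  set.seed(seed)
  gridSize <- prod(vapply(space, length, numeric(1)))
  iters <- min(iters, gridSize)
  nInit <- min(nInit, iters)
  sampleCfg <- function() lapply(space, function(v) v[sample.int(length(v), 1)])
  key <- function(cfg) paste(unlist(cfg), collapse = "|")

  evaluated <- character(0)
  X <- NULL
  ys <- numeric(0)
  trials <- list()
  runTrial <- function(cfg) {
    sc <- objective(cfg)
    evaluated <<- c(evaluated, key(cfg))
    X <<- rbind(X, .encodeConfig(cfg, space))
    ys <<- c(ys, if (maximize) -sc else sc)
    trials[[length(trials) + 1L]] <<- c(cfg, score = sc)
    sc
  }

  while (length(ys) < nInit) {
    cfg <- sampleCfg()
    tries <- 0L
    while (key(cfg) %in% evaluated && tries < 100L) {
      cfg <- sampleCfg(); tries <- tries + 1L
    }
    if (key(cfg) %in% evaluated) break
    runTrial(cfg)
  }

  while (length(ys) < iters) {
    fit <- .gpFit(X, ys)
    cand <- list()
    while (length(cand) < 256L) {
      cfg <- sampleCfg()
      if (!key(cfg) %in% evaluated) cand[[length(cand) + 1L]] <- cfg
      if (length(cand) + length(evaluated) >= gridSize) break
    }
    if (length(cand) == 0L) break
    Xc <- t(vapply(cand, .encodeConfig, numeric(length(space)), space = space))
    pr <- .gpPredict(fit, Xc)
    ei <- .expectedImprovement(pr$mean, pr$sd, min(ys))
    runTrial(cand[[which.max(ei)]])
  }

  scores <- vapply(trials, function(tr) tr$score, numeric(1))
  bi <- if (maximize) which.max(scores) else which.min(scores)
  best <- trials[[bi]]
  best$score <- NULL
  list(best = best, bestScore = scores[bi],
       trials = do.call(rbind, lapply(trials, function(tr)
         as.data.frame(tr, stringsAsFactors = FALSE))))
}
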