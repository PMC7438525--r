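#' Transition-risk modelling
#'
#' Multinomial logistic regression of per-pixel land-cover transitions with
#' staying in the source category as the baseline outcome.  Each source
#' category (forest, shrubland, agriculture/developed) has exactly three
#' outcomes: stay or convert to one of the two alternative vegetated
#' categories; pixels transitioning into alpine or "other" are excluded and
#' counted.  To blunt spatial autocorrelation the model is refitted on
#' repeated random 10\% subsamples (1,000 replicates in the reference
#' design); coefficient means, 2.5/97.5 percentile confidence bounds and
#' relative risk ratios RRR = exp(beta) are reported.
#'
#' Continuous covariates are z-score standardized (once, on the full
#' observation set); categorical covariates are one-hot coded against their
#' first level.
#'
#' @name transition_drivers
NULL

driver_covariates <- function() {
  c("slope", "elevation", "landform", "soil", "temperature",
    "precipitation", "degradation", "dist_village", "dist_town",
    "dist_road", "dist_river")
}

#' Assemble per-pixel transition observations
#'
#' @param epoch1,epoch2 aligned category-coded \code{land_grid}s
#'   (\code{\link{category_scheme}}).
#' @param covariates a \code{covariate_stack}.
#' @param source source category: "forest", "shrubland" or
#'   "agriculture_developed".
#' @param covariate_names predictor layers to extract; categorical layers
#'   are taken from the stack's \code{categorical} names.
#' @return a \code{transition_observations} list: \code{outcome} (factor,
#'   levels stay/alt1/alt2), \code{X} raw covariate matrix, \code{cells}
#'   linear indices, \code{excluded} counts (to alpine/other, missing
#'   covariates).
#' @export
assemble_observations <- function(epoch1, epoch2, covariates,
                                  source = "forest",
                                  covariate_names = NULL) {
  check_aligned(epoch1, epoch2)
  lev <- category_levels()
  src_code <- match(source, lev)
  if (is.na(src_code) || !source %in% c("forest", "shrubland",
                                        "agriculture_developed"))
    stop("source must be forest, shrubland or agriculture_developed")
  if (is.null(covariate_names))
    covariate_names <- intersect(driver_covariates(),
                                 names(covariates$layers))
  alts <- setdiff(c("forest", "shrubland", "agriculture_developed"), source)
  cells <- which(epoch1$values == src_code & !is.na(epoch2$values))
  if (!length(cells)) stop("no cells of source category ", source)
  to <- lev[epoch2$values[cells]]
  in_space <- to %in% c(source, alts)
  n_out <- sum(!in_space)
  cells <- cells[in_space]; to <- to[in_space]
  if (length(covariate_names)) {
    X <- stack_matrix(covariates, covariate_names)[cells, , drop = FALSE]
    ok <- rowSums(!is.finite(X)) == 0
  } else {
    X <- matrix(numeric(0), length(cells), 0)
    ok <- rep(TRUE, length(cells))
  }
  n_na <- sum(!ok)
  cells <- cells[ok]; to <- to[ok]; X <- X[ok, , drop = FALSE]
  outcome <- factor(ifelse(to == source, "stay", to),
                    levels = c("stay", alts))
  structure(list(outcome = outcome, X = X,
                 covariate_names = covariate_names,
                 categorical = intersect(covariates$categorical,
                                         covariate_names),
                 source = source, cells = cells,
                 excluded = c(outside_outcome_space = n_out,
                              missing_covariates = n_na)),
            class = "transition_observations")
}

#' @export
print.transition_observations <- function(x, ...) {
  cat(sprintf("<transition_observations> source %s, n = %d\n",
              x$source, length(x$outcome)))
  print(table(x$outcome))
  invisible(x)
}

# design matrix: intercept + standardized continuous + one-hot categorical
build_design <- function(obs, center = NULL, scale_ = NULL) {
  cont <- setdiff(obs$covariate_names, obs$categorical)
  Xc <- if (length(cont)) obs$X[, cont, drop = FALSE]
        else matrix(numeric(0), nrow(obs$X), 0)
  if (is.null(center)) {
    center <- colMeans(Xc)
    scale_ <- apply(Xc, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  }
  Xs <- scale(Xc, center, scale_)
  parts <- list(`(Intercept)` = rep(1, nrow(Xs)), Xs)
  for (cc in obs$categorical) {
    f <- factor(obs$X[, cc])
    if (nlevels(f) > 1) {
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cc, levels(f)[-1])
      parts[[cc]] <- mm
    }
  }
  D <- do.call(cbind, parts)
  colnames(D)[1] <- "(Intercept)"
  list(D = D, y = as.integer(obs$outcome), levels = levels(obs$outcome),
       center = center, scale = scale_)
}

# multinomial logit MLE with outcome 1 as baseline.  Newton-Raphson with
# analytic score/Hessian and step halving; falls back to BFGS with analytic
# gradient if the Hessian turns singular.
fit_mlogit_core <- function(D, y, K, tol = 1e-10, maxit = 60L) {
  n <- nrow(D); P <- ncol(D)
  nA <- K - 1L
  Y <- matrix(0, n, nA)
  for (k in seq_len(nA)) Y[, k] <- as.numeric(y == k + 1L)
  cnt <- tabulate(y, K)
  if (any(cnt == 0)) return(list(converged = FALSE, reason = "missing outcome"))

  probs <- function(B) {            # n x nA non-baseline probabilities
    eta <- D %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    exp(eta - m) / (exp(-m) + rowSums(exp(eta - m)))
  }
  nll_of <- function(B) {
    eta <- D %*% t(B)
    m <- pmax(apply(eta, 1, max), 0)
    -(sum(eta * Y) - sum(m + log(exp(-m) + rowSums(exp(eta - m)))))
  }

  B <- matrix(0, nA, P)
  B[, 1] <- log(cnt[-1] / cnt[1])
  f <- nll_of(B)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    Pk <- probs(B)
    score <- t(t(D) %*% (Y - Pk))             # nA x P
    H <- matrix(0, nA * P, nA * P)
    for (k in seq_len(nA)) for (l in seq_len(k)) {
      w <- if (k == l) Pk[, k] * (1 - Pk[, k]) else -Pk[, k] * Pk[, l]
      blk <- crossprod(D, D * w)
      H[(k - 1) * P + seq_len(P), (l - 1) * P + seq_len(P)] <- blk
      H[(l - 1) * P + seq_len(P), (k - 1) * P + seq_len(P)] <- blk
    }
    step <- tryCatch(solve(H, as.vector(t(score))), error = function(e) NULL)
    if (is.null(step)) break
    step <- matrix(step, nA, P, byrow = TRUE)
    lam <- 1
    repeat {
      Bn <- B + lam * step
      fn <- nll_of(Bn)
      if (is.finite(fn) && fn <= f + 1e-12) break
      lam <- lam / 2
      if (lam < 1e-6) { Bn <- B; fn <- f; break }
    }
    done <- abs(f - fn) < tol * (abs(f) + 1)
    B <- Bn; f <- fn
    if (done) { converged <- TRUE; break }
  }
  if (!converged) {                 # fall back to BFGS from current point
    nll <- function(par) nll_of(matrix(par, nA, P))
    gr <- function(par) {
      Pk <- probs(matrix(par, nA, P))
      as.vector(-t(t(D) %*% (Y - Pk)))
    }
    fit <- stats::optim(as.vector(B), nll, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    B <- matrix(fit$par, nA, P)
    f <- fit$value
    converged <- fit$convergence == 0
  }
  dimnames(B) <- list(NULL, colnames(D))
  list(coefficients = B, loglik = -f, converged = converged, reason = NULL)
}

#' Fit a multinomial transition model
#'
#' Maximum-likelihood multinomial logit with "stay" as the reference
#' outcome, fitted by BFGS with analytic gradients.
#'
#' @param obs a \code{transition_observations}.
#' @return list with \code{coefficients} (2 x P matrix, rows = non-stay
#'   outcomes), \code{loglik}, \code{converged}, \code{levels},
#'   \code{center}/\code{scale} of the standardization.
#' @export
fit_multinomial <- function(obs) {
  d <- build_design(obs)
  if (length(unique(d$y)) < 2) stop("need at least 2 observed outcomes")
  f <- fit_mlogit_core(d$D, d$y, length(d$levels))
  if (!isTRUE(f$converged) && !is.null(f$reason))
    stop("multinomial fit failed: ", f$reason)
  rownames(f$coefficients) <- d$levels[-1]
  c(f, list(levels = d$levels, center = d$center, scale = d$scale,
            design_names = colnames(d$D), source = obs$source))
}

#' Subsample-replicated transition model
#'
#' Draws \code{replicates} random subsamples of
#' \code{floor(fraction * n)} observations without replacement,
#' fits the multinomial model on each (with the standardization computed
#' once on the full data), and summarises coefficients by their mean and
#' 2.5/97.5 percentiles.  Non-converged replicates (including subsamples
#' missing an outcome) are excluded and counted.
#'
#' @param obs a \code{transition_observations}.
#' @param fraction subsample fraction (design value 0.10).
#' @param replicates number of replicates (design value 1,000).
#' @param seed RNG seed.
#' @return a \code{transition_model_fit}: \code{replicates} (array R x 2 x
#'   P), \code{mean_coefficients}, \code{ci_low}, \code{ci_high},
#'   \code{rrr}, \code{n_failed}, metadata.
#' @export
fit_subsampled <- function(obs, fraction = 0.10, replicates = 1000L,
                           seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  d <- build_design(obs)
  K <- length(d$levels)
  n <- nrow(d$D)
  m <- max(1L, floor(fraction * n))
  P <- ncol(d$D)
  reps <- array(NA_real_, c(replicates, K - 1L, P),
                dimnames = list(NULL, d$levels[-1], colnames(d$D)))
  failed <- 0L
  for (r in seq_len(replicates)) {
    take <- sample.int(n, m)
    f <- fit_mlogit_core(d$D[take, , drop = FALSE], d$y[take], K)
    if (isTRUE(f$converged)) reps[r, , ] <- f$coefficients
    else failed <- failed + 1L
  }
  ok <- !is.na(reps[, 1, 1])
  if (!any(ok)) stop("no replicate converged")
  mean_b <- apply(reps[ok, , , drop = FALSE], c(2, 3), mean)
  ci_lo <- apply(reps[ok, , , drop = FALSE], c(2, 3),
                 stats::quantile, 0.025)
  ci_hi <- apply(reps[ok, , , drop = FALSE], c(2, 3),
                 stats::quantile, 0.975)
  structure(list(replicates = reps, mean_coefficients = mean_b,
                 ci_low = ci_lo, ci_high = ci_hi, rrr = exp(mean_b),
                 n_replicates = replicates, n_failed = failed,
                 subsample_fraction = fraction, seed = seed,
                 levels = d$levels, center = d$center, scale = d$scale,
                 design_names = colnames(d$D), source = obs$source),
            class = "transition_model_fit")
}

#' @export
print.transition_model_fit <- function(x, ...) {
  cat(sprintf(
    "<transition_model_fit> source %s: %d/%d replicates at fraction %.2f\n",
    x$source, x$n_replicates - x$n_failed, x$n_replicates,
    x$subsample_fraction))
  print(round(x$mean_coefficients, 3))
  invisible(x)
}

#' Relative risk ratios of a fitted transition model
#'
#' RRR = exp(beta) of the mean coefficients, with exp-transformed percentile
#' confidence bounds; RRR > 1 means the transition is more likely than
#' staying per unit (standardized) covariate.
#'
#' @param fit a \code{transition_model_fit}.
#' @return data frame: outcome, covariate, rrr, rrr_low, rrr_high, beta.
#' @export
relative_risk_ratios <- function(fit) {
  stopifnot(inherits(fit, "transition_model_fit"))
  out <- expand.grid(outcome = rownames(fit$mean_coefficients),
                     covariate = colnames(fit$mean_coefficients),
                     stringsAsFactors = FALSE)
  idx <- cbind(match(out$outcome, rownames(fit$mean_coefficients)),
               match(out$covariate, colnames(fit$mean_coefficients)))
  out$beta <- fit$mean_coefficients[idx]
  out$rrr <- exp(out$beta)
  out$rrr_low <- exp(fit$ci_low[idx])
  out$rrr_high <- exp(fit$ci_high[idx])
  out
}

#' Predicted transition-probability surfaces
#'
#' Softmax probabilities for (stay, alt1, alt2) from the mean coefficients,
#' evaluated on every source cell.
#'
#' @param fit a \code{transition_model_fit} (or \code{fit_multinomial}
#'   result).
#' @param covariates a \code{covariate_stack}.
#' @param source_mask logical matrix of source cells.
#' @return list of three probability matrices named by outcome; bands sum to
#'   1 on source cells.
#' @export
predict_transition_probabilities <- function(fit, covariates, source_mask) {
  B <- if (inherits(fit, "transition_model_fit")) fit$mean_coefficients
       else fit$coefficients
  cells <- which(source_mask)
  cont <- names(fit$center)
  cats <- setdiff(fit$design_names, c("(Intercept)", cont))
  if (length(cont)) {
    Xc <- stack_matrix(covariates, cont)[cells, , drop = FALSE]
    D <- cbind(1, scale(Xc, fit$center, fit$scale))
  } else {
    D <- matrix(1, length(cells), 1)
  }
  colnames(D) <- c("(Intercept)", cont)
  if (length(cats)) {
    # rebuild one-hot columns from the categorical layers
    catlay <- covariates$categorical
    mm <- matrix(0, length(cells), length(cats),
                 dimnames = list(NULL, cats))
    for (cc in catlay) {
      vals <- stack_matrix(covariates, cc)[cells, 1]
      for (colname in grep(paste0("^", cc), cats, value = TRUE)) {
        levv <- sub(paste0("^", cc), "", colname)
        mm[, colname] <- as.numeric(as.character(vals) == levv)
      }
    }
    D <- cbind(D, mm)
  }
  D <- D[, fit$design_names, drop = FALSE]
  eta <- D %*% t(B)
  mx <- pmax(apply(eta, 1, max), 0)
  den <- exp(-mx) + rowSums(exp(eta - mx))
  p_stay <- exp(-mx) / den
  probs <- cbind(p_stay, exp(eta - mx) / den)
  colnames(probs) <- fit$levels
  out <- lapply(seq_len(ncol(probs)), function(k) {
    m <- matrix(NA_real_, nrow(source_mask), ncol(source_mask))
    m[cells] <- probs[, k]
    m
  })
  names(out) <- fit$levels
  out
}
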