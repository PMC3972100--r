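## The quantitative core: fraction-bound algebra, the combined linear score,
## bootstrap refitting, binder classification, site preference.

#' The published combined-model coefficients
#'
#' \code{score = 25.41 - 1.95 * xp_score + 7.68 * logP}: the linear
#' combination of the best induced-fit docking score from the two-site
#' fatty-acid model and the octanol/water logP that best separated strong
#' from weak HSA binders. Because docking scores are negative for favorable
#' binding (alpha < 0) and lipophilicity promotes albumin binding
#' (beta > 0), higher combined scores mean stronger predicted binding, on
#' the \%HSA scale.
#'
#' @return a \linkS4class{CombinedModel}.
#' @examples
#' combinedScore(defaultCombinedModel(), xpScore = -12.33, logp = 2)
#' @export
defaultCombinedModel <- function() {
  new("CombinedModel", intercept = 25.41, alpha = -1.95, beta = 7.68,
      fitMeta = list())
}

#' Construct a CombinedModel from coefficients
#' @param intercept,alpha,beta finite coefficients (alpha weights the
#'   docking score, beta the logP).
#' @return a \linkS4class{CombinedModel}.
#' @export
CombinedModel <- function(intercept, alpha, beta) {
  new("CombinedModel", intercept = intercept, alpha = alpha, beta = beta,
      fitMeta = list())
}

#' Model coefficient accessor
#' @param object a \linkS4class{CombinedModel}.
#' @param ... ignored.
#' @return named numeric vector (intercept, alpha, beta).
#' @export
setMethod("coef", "CombinedModel", function(object, ...)
  c(intercept = object@intercept, alpha = object@alpha, beta = object@beta))

#' Evaluate the combined binding score
#'
#' @param model a \linkS4class{CombinedModel}.
#' @param xpScore docking score(s), kcal/mol, more negative = better.
#' @param logp logP value(s).
#' @return numeric combined score(s); higher = stronger predicted binding.
#' @export
combinedScore <- function(model, xpScore, logp) {
  stopifnot(is(model, "CombinedModel"))
  if (any(!is.finite(xpScore)) || any(!is.finite(logp)))
    stop("non-finite input to combinedScore")
  model@intercept + model@alpha * xpScore + model@beta * logp
}

#' Fit the combined model by least squares with bootstrap intervals
#'
#' Ordinary least squares of \%HSA on the docking score and logP with an
#' intercept, followed by case resampling (rows with replacement) to obtain
#' percentile confidence intervals for each coefficient. The bootstrap is
#' seeded and its random-number state is restored afterwards.
#'
#' @param xpScore,logp,hsaPercent equal-length numeric vectors
#'   (>= 3 complete records).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed integer seed for resampling.
#' @param level confidence level for the percentile intervals.
#' @return a \linkS4class{CombinedModel} with \code{fitMeta} carrying
#'   \code{n}, \code{nBoot}, \code{seed}, \code{ci} (coefficient intervals),
#'   and the residual standard error.
#' @export
fitCombined <- function(xpScore, logp, hsaPercent, nBoot = 1000L,
                        seed = 1L, level = 0.95) {
  n <- length(hsaPercent)
  if (length(xpScore) != n || length(logp) != n)
    stop("input vectors must have equal length")
  keep <- is.finite(xpScore) & is.finite(logp) & is.finite(hsaPercent)
  xp <- xpScore[keep]; lp <- logp[keep]; y <- hsaPercent[keep]
  if (length(y) < 3) stop("need at least 3 complete records to fit")
  X <- cbind(1, xp, lp)
  if (qr(X)$rank < 3) stop("predictors are exactly collinear")
  fit <- stats::lm.fit(X, y)
  co <- unname(fit$coefficients)
  ci <- NULL
  if (nBoot > 0) {
    boot <- matrix(NA_real_, nBoot, 3)
    withr_seed <- function(code) {  # local seed, restore global RNG state
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      code
    }
    boot <- withr_seed({
      m <- length(y)
      b <- matrix(NA_real_, nBoot, 3)
      for (k in seq_len(nBoot)) {
        idx <- sample.int(m, m, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank < 3) next  # degenerate resample, skip
        b[k, ] <- stats::lm.fit(Xb, y[idx])$coefficients
      }
      b
    })
    a2 <- (1 - level) / 2
    ci <- t(apply(boot, 2, stats::quantile,
                  probs = c(a2, 1 - a2), na.rm = TRUE))
    rownames(ci) <- c("intercept", "alpha", "beta")
  }
  rse <- sqrt(sum(fit$residuals^2) / max(1, length(y) - 3))
  new("CombinedModel", intercept = co[1], alpha = co[2], beta = co[3],
      fitMeta = list(n = length(y), nBoot = nBoot, seed = seed,
                     level = level, ci = ci, sigma = rse))
}

#' Serialize / read a combined model as key-value text
#' @param model a \linkS4class{CombinedModel}.
#' @param path file path.
#' @return \code{path} (write) or a \linkS4class{CombinedModel} (read).
#' @export
writeCombinedModel <- function(model, path) {
  lines <- c(sprintf("intercept %.10g", model@intercept),
             sprintf("alpha %.10g", model@alpha),
             sprintf("beta %.10g", model@beta))
  if (length(model@fitMeta))
    lines <- c(lines,
               sprintf("n %d", model@fitMeta$n),
               sprintf("n_boot %d", model@fitMeta$nBoot),
               sprintf("seed %d", model@fitMeta$seed))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCombinedModel
#' @export
readCombinedModel <- function(path) {
  kv <- utils::read.table(path, col.names = c("key", "value"))
  g <- function(k) kv$value[match(k, kv$key)]
  CombinedModel(g("intercept"), g("alpha"), g("beta"))
}

## ---- fraction-bound equilibrium algebra -----------------------------------
## Single-site isotherm at constant albumin concentration (0.6 mM):
##   fb = Ka [HSA] / (1 + Ka [HSA]),   Ki = 1 / Ka,   %HSA = 100 fb.

#' Fraction bound / \%HSA / binding-constant conversions
#'
#' \code{fbFromPercent} and \code{percentFromFb} convert between the
#' fraction of ligand bound at equilibrium and the \%HSA scale
#' (\code{\%HSA = 100 fb}). \code{kaFromFb} inverts the single-site binding
#' isotherm at fixed albumin concentration to an association constant;
#' \code{fbFromKa} is its inverse, and \code{kiFromKa}/\code{kaFromKi}
#' relate the association and dissociation-type constants reciprocally.
#' All round trips are exact identities on their domains.
#'
#' @param hsaPercent \%HSA in [0, 100].
#' @param fb fraction bound in [0, 1] ([0, 1) where a finite Ka is needed).
#' @param ka association constant, inverse molar.
#' @param ki dissociation-type constant, molar.
#' @param albuminConc albumin concentration in molar; default 0.6 mM.
#' @return numeric vector.
#' @examples
#' fbFromPercent(25)                    # the weak-binder cutoff, 0.25
#' kaFromFb(0.5)                        # 1 / 0.6 mM = 1666.7 per molar
#' fbFromKa(kaFromFb(0.8))              # identity
#' @name bindingMath
NULL

#' @rdname bindingMath
#' @export
fbFromPercent <- function(hsaPercent) {
  if (any(!is.finite(hsaPercent) | hsaPercent < 0 | hsaPercent > 100))
    stop("hsaPercent must be in [0, 100]")
  hsaPercent / 100
}

#' @rdname bindingMath
#' @export
percentFromFb <- function(fb) {
  if (any(!is.finite(fb) | fb < 0 | fb > 1))
    stop("fb must be in [0, 1]")
  100 * fb
}

#' @rdname bindingMath
#' @export
kaFromFb <- function(fb, albuminConc = 6e-4) {
  if (any(!is.finite(fb) | fb < 0 | fb >= 1))
    stop("fb must be in [0, 1) for a finite Ka")
  if (any(albuminConc <= 0)) stop("albumin concentration must be positive")
  fb / ((1 - fb) * albuminConc)
}

#' @rdname bindingMath
#' @export
fbFromKa <- function(ka, albuminConc = 6e-4) {
  if (any(!is.finite(ka) | ka < 0)) stop("ka must be non-negative")
  if (any(albuminConc <= 0)) stop("albumin concentration must be positive")
  ka * albuminConc / (1 + ka * albuminConc)
}

#' @rdname bindingMath
#' @export
kiFromKa <- function(ka) {
  if (any(!is.finite(ka) | ka <= 0)) stop("ka must be positive")
  1 / ka
}

#' @rdname bindingMath
#' @export
kaFromKi <- function(ki) {
  if (any(!is.finite(ki) | ki <= 0)) stop("ki must be positive")
  1 / ki
}

## ---- classification -------------------------------------------------------

#' Classify compounds as weak, intermediate, or binder from \%HSA
#'
#' Weak/non-binders are compounds with fraction bound below 0.25
#' (\%HSA < 25); strong binders are above 80 \%HSA. Compounds between the
#' cutoffs are intermediate and are excluded from the strict evaluation
#' set. Inequalities are strict; compounds sitting exactly on a cutoff are
#' flagged with a message so boundary handling stays auditable.
#'
#' @param hsaPercent numeric \%HSA values in [0, 100].
#' @param weakCutoff,binderCutoff class boundaries (defaults 25 and 80).
#' @return factor with levels weak, intermediate, binder.
#' @examples
#' classifyBinder(c(10, 50, 85))
#' @export
classifyBinder <- function(hsaPercent, weakCutoff = 25, binderCutoff = 80) {
  if (any(!is.finite(hsaPercent) | hsaPercent < 0 | hsaPercent > 100))
    stop("hsaPercent must be in [0, 100]")
  onBoundary <- hsaPercent == weakCutoff | hsaPercent == binderCutoff
  if (any(onBoundary))
    message(sum(onBoundary), " value(s) exactly on a class boundary ",
            "classified as intermediate (strict inequalities)")
  cls <- ifelse(hsaPercent < weakCutoff, "weak",
                ifelse(hsaPercent > binderCutoff, "binder", "intermediate"))
  factor(cls, levels = c("weak", "intermediate", "binder"))
}

#' Site I / site II preference from the docking-score difference
#'
#' The decision statistic is \code{delta = best_site_II - best_site_I}
#' (kcal/mol). A minimal absolute difference indicates a site I binder; a
#' significant gap in favor of site II (delta well below zero, site II
#' score more favorable) indicates a site II binder. The default threshold
#' on |delta| is 2 kcal/mol; the raw delta is always returned so that
#' ROC-optimal cutoffs can be applied instead. A missing site score yields
#' \code{indeterminate}.
#'
#' @param ensembleScores output of \code{\link{aggregateBest}} (or any
#'   data.frame with \code{ligand_id}, \code{best_site_I},
#'   \code{best_site_II}).
#' @param threshold kcal/mol on |delta| separating the calls.
#' @return \code{DataFrame} with \code{ligand_id}, \code{delta},
#'   \code{predicted_site} (site_I / site_II / indeterminate).
#' @export
sitePreference <- function(ensembleScores, threshold = 2.0) {
  stopifnot(all(c("ligand_id", "best_site_I", "best_site_II") %in%
                colnames(ensembleScores)))
  if (threshold < 0) stop("threshold must be non-negative")
  dI <- ensembleScores$best_site_I
  dII <- ensembleScores$best_site_II
  delta <- dII - dI
  pred <- ifelse(is.na(delta), "indeterminate",
                 ifelse(abs(delta) <= threshold, "site_I", "site_II"))
  DataFrame(ligand_id = ensembleScores$ligand_id,
            delta = delta,
            predicted_site = factor(pred, levels = c("site_I", "site_II",
                                                     "indeterminate")))
}
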