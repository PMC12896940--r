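#' Binary maturity from a phase or stage label
#'
#' Projects the five stereological maturity phases and the four macroscopic
#' stages onto a binary mature/immature state. A fish leaves the sexually
#' immature state when cortical alveoli oocytes are produced, so only phase
#' A (and macroscopic stage 1) is immature; developing (B), spawning (C),
#' regressing/regenerating (D) and omitted spawning (E) — and stages 2-4 —
#' are all within the sexually mature state.
#'
#' @param x vector of phase labels (`"A".."E"`) or stage labels
#'   (`1..4`, numeric or character).
#' @return logical vector, `TRUE` = mature.
#' @examples
#' toBinaryMaturity(c("A", "E"))  # FALSE TRUE
#' toBinaryMaturity(c(1, 4))      # FALSE TRUE
#' @export
toBinaryMaturity <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), c(.PHASES, .STAGES))
  if (length(bad))
    stop("unknown maturity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  !(x %in% c("A", "1"))
}

# Bernoulli log-likelihood, numerically safe.
.logistic_ll <- function(eta, y) {
  sum(y * eta - log1p(exp(pmin(eta, 700))))
}

# Newton/IRLS logistic fit of y ~ 1 + len, with step halving so the
# log-likelihood trace is non-decreasing. Returns coefficients, trace and
# convergence diagnostics. Kept lean: it is also the bootstrap inner loop.
.irlsLogistic <- function(len, y, tol = 1e-8, maxit = 50L) {
  X <- matrix(c(rep(1, length(len)), len), ncol = 2L)
  beta <- c(stats::qlogis(mean(y) * 0.98 + 0.01), 0)
  eta <- drop(X %*% beta)
  ll <- .logistic_ll(eta, y)
  trace <- ll
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    g <- drop(crossprod(X, y - mu))
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) g * 1e-4)
    # halve the step until the likelihood does not decrease
    improved <- FALSE
    for (h in 0:20) {
      betaNew <- beta + step / 2^h
      etaNew <- drop(X %*% betaNew)
      llNew <- .logistic_ll(etaNew, y)
      if (llNew >= ll) { improved <- TRUE; break }
    }
    if (!improved) break  # numerical plateau
    beta <- betaNew; eta <- etaNew; ll <- llNew
    trace <- c(trace, ll)
  }
  list(beta = beta, logLik = ll, trace = trace, converged = converged)
}

#' Fit a logistic maturity ogive and estimate L50
#'
#' Maximizes the Bernoulli log-likelihood of
#' `mature ~ logistic(beta0 + beta1 * length)` by Newton/IRLS (gradient norm
#' < 1e-8 or 50 iterations, with step halving so the likelihood never
#' decreases), computes `L50 = -beta0/beta1`, and attaches a nonparametric
#' bootstrap percentile confidence interval for L50 (fish resampled with
#' replacement, `nBoot` resamples from the stated seed). Goodness of fit is
#' reported as the Nagelkerke pseudo-R-squared.
#'
#' Complete (or quasi-complete) separation of the two classes makes the MLE
#' unbounded; the fit is then flagged (`separation`), a warning is issued,
#' and the bootstrap interval is the only meaningful uncertainty statement.
#'
#' @param length fish lengths, cm (or a data.frame with columns
#'   `length_cm` and `mature`).
#' @param mature logical (or 0/1) maturity per fish.
#' @param nBoot number of bootstrap resamples (default 1000; 0 disables).
#' @param seed integer RNG seed for the bootstrap.
#' @return an [OgiveFit-class].
#' @examples
#' set.seed(1)
#' len <- runif(300, 10, 35)
#' mat <- runif(300) < plogis(-10.3 + 0.5 * len)
#' fitOgive(len, mat, nBoot = 50, seed = 1)
#' @export
fitOgive <- function(length, mature, nBoot = 1000L, seed = 1L) {
  if (is.data.frame(length)) {
    mature <- length$mature
    length <- length$length_cm
  }
  y <- as.numeric(mature)
  len <- as.numeric(length)
  if (any(len <= 0)) stop("lengths must be positive", call. = FALSE)
  n <- base::length(len)
  if (n < 10L) stop("at least 10 observations are required", call. = FALSE)
  if (all(y == 1) || all(y == 0))
    stop("no-fit: both maturity classes must be present", call. = FALSE)

  fit <- .irlsLogistic(len, y)
  beta <- fit$beta
  # quasi-complete separation: fitted probabilities pinned at 0/1
  mu <- stats::plogis(drop(cbind(1, len) %*% beta))
  sep <- all(mu[y == 1] > 1 - 1e-6) && all(mu[y == 0] < 1e-6)
  if (sep)
    warning("complete separation detected; coefficients are unbounded and ",
            "only the bootstrap interval is meaningful", call. = FALSE)

  ll0 <- .logistic_ll(rep(stats::qlogis(mean(y)), n), y)
  r2 <- (1 - exp(2 * (ll0 - fit$logLik) / n)) / (1 - exp(2 * ll0 / n))

  bootL50 <- numeric(0)
  ciLow <- ciHigh <- NA_real_
  if (nBoot > 0) {
    set.seed(seed)
    bootL50 <- vapply(seq_len(nBoot), function(b) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (!all(y[idx] == y[idx][1])) break
      }
      bb <- .irlsLogistic(len[idx], y[idx], tol = 1e-6, maxit = 30L)$beta
      -bb[1] / bb[2]
    }, numeric(1))
    qs <- stats::quantile(bootL50, c(0.025, 0.975), names = FALSE, type = 7)
    ciLow <- qs[1]; ciHigh <- qs[2]
  }

  new("OgiveFit", beta0 = beta[1], beta1 = beta[2], L50 = -beta[1] / beta[2],
      ciLow = ciLow, ciHigh = ciHigh, r2 = r2, n = as.integer(n),
      nBoot = as.integer(nBoot), seed = as.integer(seed),
      converged = fit$converged, separation = sep,
      bootL50 = bootL50, logLikTrace = fit$trace)
}

#' Compare two maturity ogives
#'
#' Reports the difference in L50 between two fits (e.g. macroscopic vs
#' stereological maturity data for the same cohort) and whether their
#' bootstrap confidence intervals overlap.
#'
#' @param fitA,fitB [OgiveFit-class] objects.
#' @return list with `deltaL50` (cm, `fitA - fitB`) and `ciOverlap`
#'   (logical; `NA` when either CI is missing).
#' @export
compareOgives <- function(fitA, fitB) {
  overlap <- if (anyNA(c(fitA@ciLow, fitA@ciHigh, fitB@ciLow, fitB@ciHigh)))
    NA
  else fitA@ciLow <= fitB@ciHigh && fitB@ciLow <= fitA@ciHigh
  list(deltaL50 = fitA@L50 - fitB@L50, ciOverlap = overlap)
}

#' Read a per-fish maturity CSV
#'
#' Columns `fish_id, length_cm, mature` (0/1) and optionally `source`
#' (`"macroscopic"` or `"stereology"`).
#'
#' @param path file path.
#' @param source optional filter on the `source` column.
#' @return data.frame.
#' @export
readMaturityCSV <- function(path, source = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("fish_id", "length_cm", "mature")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("maturity CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(source)) df <- df[df$source == source, , drop = FALSE]
  df
}
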