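# E-value calibration: the null distribution of optimal local alignment
# scores is modelled as Gumbel (extreme-value), fitted by maximum
# likelihood on scores of the profile against seeded null samples --
# length-matched i.i.d. background sequences (sequence mode) or
# column-shuffled copies of a target profile (profile mode).

# Maximum-likelihood Gumbel fit (maximum convention): location mu, scale
# beta; lambda = 1/beta.  Newton iterations on the profile likelihood in
# beta, safeguarded to stay positive.
fit_gumbel <- function(x, tol = 1e-9, max_iter = 200L) {
  n <- length(x)
  if (stats::sd(x) < 1e-12) stop("degenerate null score variance")
  xbar <- mean(x)
  f <- function(beta) {
    w <- exp(-(x - xbar) / beta)  # shifted for stability
    beta - xbar + sum(x * w) / sum(w)
  }
  beta <- stats::sd(x) * sqrt(6) / pi  # moment start
  for (it in seq_len(max_iter)) {
    h <- max(1e-8, beta * 1e-7)
    fb <- f(beta)
    dfb <- (f(beta + h) - fb) / h
    step <- fb / dfb
    new_beta <- beta - step
    if (!is.finite(new_beta) || new_beta <= 0) new_beta <- beta / 2
    if (abs(new_beta - beta) < tol) { beta <- new_beta; break }
    beta <- new_beta
  }
  mu <- xbar - beta * log(mean(exp(-(x - xbar) / beta)))
  list(mu = mu, lambda = 1 / beta)
}

#' Calibrate the null score distribution of a profile
#'
#' Scores the profile against `n_null` seeded null samples and fits a
#' Gumbel by maximum likelihood.  In `"sequence"` mode the nulls are
#' i.i.d. background sequences with lengths resampled from `lengths`; in
#' `"profile"` mode they are column-shuffled copies of `target`, aligned
#' with [align_profiles()].
#'
#' @param profile the query [build_profile()] object.
#' @param n_null number of null samples (at least 100).
#' @param database_size number of target records N behind reported
#'   E-values.
#' @param seed RNG seed.
#' @param lengths integer vector of target sequence lengths to resample
#'   (sequence mode).
#' @param mode `"sequence"` or `"profile"`.
#' @param target target `seq_profile` (profile mode).
#' @return Object of class `gumbel_calibration` with fields `mu`,
#'   `lambda`, `n_null`, `database_size` and the null `scores`.
#' @export
calibrate_profile <- function(profile, n_null = 200L, database_size = 1L,
                              seed = 1L, lengths = NULL,
                              mode = c("sequence", "profile"),
                              target = NULL) {
  mode <- match.arg(mode)
  if (n_null < 100L) stop("n_null must be at least 100")
  set.seed(seed)
  scores <- numeric(n_null)
  if (mode == "sequence") {
    if (is.null(lengths)) lengths <- ncol(profile$mat)
    bg <- profile$bg
    lo <- profile_logodds(profile)
    lens <- sample(rep_len(lengths, n_null))
    for (i in seq_len(n_null)) {
      codes <- sample.int(20L, lens[i], replace = TRUE, prob = bg)
      scores[i] <- .sw_affine(lo[, codes, drop = FALSE],
                              profile$gap_open, profile$gap_extend)$score
    }
  } else {
    if (is.null(target)) stop("profile mode needs a target profile")
    for (i in seq_len(n_null)) {
      shuf <- target
      shuf$mat <- target$mat[, sample.int(ncol(target$mat)), drop = FALSE]
      shuf$tm_segments <- NULL
      scores[i] <- align_profiles(profile, shuf)$score
    }
  }
  fit <- fit_gumbel(scores)
  structure(list(mu = fit$mu, lambda = fit$lambda, n_null = n_null,
                 database_size = database_size, scores = scores,
                 mode = mode, seed = seed),
            class = "gumbel_calibration")
}

#' @export
print.gumbel_calibration <- function(x, ...) {
  cat("Gumbel calibration (", x$mode, " null, n = ", x$n_null, "): mu = ",
      signif(x$mu, 4), " bits, lambda = ", signif(x$lambda, 4),
      ", N = ", x$database_size, "\n", sep = "")
  invisible(x)
}

#' E-value of a score under a calibration
#'
#' `E = N exp(-lambda (s - mu))`, clamped to `[0, N]`: at `s = mu` the
#' clamp makes `E = N`, and `E -> 0` as the score grows.
#'
#' @param calibration a [calibrate_profile()] result.
#' @param score score(s) in bits.
#' @return Numeric E-value(s).
#' @export
evalue <- function(calibration, score) {
  N <- calibration$database_size
  pmin(pmax(N * exp(-calibration$lambda * (score - calibration$mu)), 0), N)
}
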