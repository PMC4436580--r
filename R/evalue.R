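# Gumbel calibration of profile scores and E-values.
#
# Maximum local-alignment scores of unrelated sequences follow an extreme
# value (Gumbel) distribution; the calibration scores random background
# sequences, fits (mu, beta) by maximum likelihood and converts a score s
# to an expected hit count E(s) = K * db_size * exp(-lambda * s), with
# lambda = 1/beta and K = exp(lambda * mu).

#' Fit a Gumbel (max) distribution by maximum likelihood
#'
#' @param x Numeric sample (length >= 10, non-degenerate).
#' @return List with `mu` (location), `beta` (scale), `lambda = 1/beta`.
#' @export
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  if (sd(x) < 1e-12) stop("degenerate score distribution (zero variance)")
  nll <- function(par) {
    mu <- par[1]; beta <- exp(par[2])
    z <- (x - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  beta0 <- sd(x) * sqrt(6) / pi
  mu0 <- mean(x) - 0.5772157 * beta0
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- fit$par[1]
  beta <- exp(fit$par[2])
  list(mu = mu, beta = beta, lambda = 1 / beta)
}

#' Calibrate an E-value model for a profile
#'
#' Scores `n_shuffles` random sequences drawn from the profile's background
#' distribution at the mean target length and fits a Gumbel law to the
#' resulting maximum local scores. Scores are calibrated at the mean target
#' length; no per-sequence length correction is applied.
#'
#' @param profile A `pap_profile`.
#' @param n_shuffles Number of null sequences (>= 200).
#' @param target_lengths Lengths of the target database sequences (their
#'   mean sets the null sequence length), or a single length.
#' @param db_size Number of sequences in the target database.
#' @param seed Integer seed for the null sequences.
#' @return The profile with an `evalue_model` attached (class
#'   `pap_evalue`): `lambda`, `K`, `db_size`, plus calibration metadata.
#' @export
calibrate_evalue <- function(profile, n_shuffles = 500, target_lengths,
                             db_size, seed = 1) {
  stopifnot(n_shuffles >= 200, db_size >= 1)
  len <- max(1L, as.integer(round(mean(target_lengths))))
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- paste(sample(AA_ALPHABET, len, replace = TRUE,
                        prob = profile$background), collapse = "")
      score_sequence(profile, s)$score
    }, numeric(1))
  })
  g <- fit_gumbel(scores)
  profile$evalue_model <- structure(
    list(lambda = g$lambda, K = exp(g$lambda * g$mu), db_size = db_size,
         mu = g$mu, beta = g$beta, n_shuffles = n_shuffles,
         calibration_length = len, calibration_seed = seed),
    class = "pap_evalue"
  )
  profile
}

#' Convert scores to E-values
#'
#' @param model A `pap_evalue` model (or a calibrated `pap_profile`).
#' @param score Numeric scores in bits.
#' @return Expected number of hits of equal or better score in the
#'   database; strictly decreasing in `score`.
#' @export
evalue <- function(model, score) {
  if (inherits(model, "pap_profile")) model <- model$evalue_model
  if (is.null(model)) stop("profile has no calibrated E-value model")
  model$K * model$db_size * exp(-model$lambda * score)
}

#' @export
print.pap_evalue <- function(x, ...) {
  cat("<E-value model> lambda = ", signif(x$lambda, 4), ", K = ",
      signif(x$K, 4), ", db size ", x$db_size, " (", x$n_shuffles,
      " null sequences at length ", x$calibration_length, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.pap_evalue <- function(x, ...) {
  tibble(term = c("lambda", "K", "mu", "beta"),
         estimate = c(x$lambda, x$K, x$mu, x$beta))
}

#' @export
glance.pap_evalue <- function(x, ...) {
  tibble(db_size = x$db_size, n_shuffles = x$n_shuffles,
         calibration_length = x$calibration_length,
         calibration_seed = x$calibration_seed)
}
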