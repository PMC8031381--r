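#' Bundle chevron counts from repeated simulations
#'
#' A survey collects the per-run chevron count over an ensemble of seeded
#' re-initialisations at one control level, together with the assumed number
#' of available chevron sites n_s per chain (3, 4 or 6 in practice: reversals
#' come in wedge/anti-wedge pairs, so six disruption points support at most
#' three chevrons).
#'
#' @param counts integer vector of per-run chevron counts.
#' @param n_sites assumed maximum chevrons per chain n_s.
#' @param mechanism control mechanism label.
#' @param control_value numeric control level (d_X, A_X or f_X).
#' @return object of class \code{chevron_survey}.
#' @export
chevron_survey <- function(counts, n_sites, mechanism = "none",
                           control_value = NA_real_) {
  counts <- as.integer(counts)
  n_sites <- as.integer(n_sites)
  stopifnot(length(counts) > 0, n_sites > 0, all(counts >= 0))
  violations <- which(counts > n_sites)
  structure(list(counts = counts, n_sites = n_sites,
                 n_runs = length(counts),
                 mechanism = mechanism, control_value = control_value,
                 violations = violations),
            class = "chevron_survey")
}

#' Estimated per-site chevron probability
#'
#' Total observed chevrons divided by the total number of available sites,
#' n_sites x n_runs (e.g. 150 for 50 runs with 3 sites each).  Counts above
#' n_sites violate the fixed-trials assumption of the binomial model and are
#' reported as an error rather than clipped.
#'
#' @param survey a [chevron_survey()].
#' @return proportion in [0, 1].
#' @export
p_chevron <- function(survey) {
  stopifnot(inherits(survey, "chevron_survey"))
  if (length(survey$violations) > 0)
    stop("counts exceed n_sites in run(s) ",
         paste(survey$violations, collapse = ", "),
         ": the fixed-trials assumption is violated")
  sum(survey$counts) / (survey$n_sites * survey$n_runs)
}

#' Exact two-tailed binomial test
#'
#' Probability, under Binomial(trials, p0), of every outcome no more likely
#' than the observed count (minimum-likelihood two-tailed convention; the
#' standard exact binomial test, symmetric about the median at p0 = 0.5).  A
#' relative tolerance guards against ties lost to floating point.
#'
#' @param successes observed successes.
#' @param trials number of trials.
#' @param p0 null success probability (default 0.5).
#' @return two-tailed p-value.
#' @export
binomial_test <- function(successes, trials, p0 = 0.5) {
  stopifnot(trials >= 1, successes >= 0, successes <= trials,
            p0 >= 0, p0 <= 1)
  dens <- stats::dbinom(0:trials, trials, p0)
  d_obs <- dens[successes + 1]
  min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
}

#' Classify chevron preference at one control level
#'
#' Tests the pooled chevron count against the no-preference null p0 = 0.5
#' with the exact two-tailed binomial test.  Not significant (p > alpha):
#' \code{no_preference}.  Significant with p_ch below 0.5: \code{reduced}
#' (chevrons rarer than chance); above 0.5: \code{enhanced}.  Surveys whose
#' count distribution is bimodal (at least a quarter of the runs at 0 and at
#' n_s each) carry a validity warning: the fixed-trials binomial assumption
#' is then doubtful, as happens for strong frequency detuning.
#'
#' @param survey a [chevron_survey()].
#' @param alpha significance level (default 0.05).
#' @return object of class \code{preference_result}: list with \code{p_ch},
#'   \code{p_value}, \code{class} (one of no_preference/reduced/enhanced),
#'   \code{warning_bimodal}, plus the survey metadata.
#' @export
classify_preference <- function(survey, alpha = 0.05) {
  p_ch <- p_chevron(survey)
  trials <- survey$n_sites * survey$n_runs
  p_value <- binomial_test(sum(survey$counts), trials, 0.5)
  cls <- if (p_value > alpha) "no_preference"
         else if (p_ch < 0.5) "reduced" else "enhanced"
  frac0 <- mean(survey$counts == 0)
  fracs <- mean(survey$counts == survey$n_sites)
  structure(list(p_ch = p_ch, p_value = p_value, class = cls,
                 warning_bimodal = frac0 >= 0.25 && fracs >= 0.25,
                 n_sites = survey$n_sites, n_runs = survey$n_runs,
                 mechanism = survey$mechanism,
                 control_value = survey$control_value),
            class = "preference_result")
}

#' Observed chevron-count distribution with its fair-coin reference
#'
#' Tabulates how many runs produced each count 0..n_s alongside the expected
#' frequencies under no preference, n_runs x Binomial(n_s, 0.5).
#'
#' @param survey a [chevron_survey()].
#' @return data.frame with columns \code{count}, \code{observed},
#'   \code{expected_null}.
#' @export
chevron_histogram <- function(survey) {
  stopifnot(inherits(survey, "chevron_survey"))
  counts <- 0:survey$n_sites
  observed <- vapply(counts, function(k) sum(survey$counts == k), integer(1))
  data.frame(count = counts,
             observed = observed,
             expected_null = survey$n_runs *
               stats::dbinom(counts, survey$n_sites, 0.5))
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("chevron preference [%s, control = %g]: p_ch = %.3f, p = %.4g -> %s%s\n",
              x$mechanism, x$control_value, x$p_ch, x$p_value, x$class,
              if (x$warning_bimodal) " (warning: bimodal counts)" else ""))
  invisible(x)
}
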