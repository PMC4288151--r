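#' Expected Rc under a population mixture model
#'
#' Forward model linking the prevalence of a structural variant among the
#' genomic DNA molecules of a population to the expected origin/terminus
#' coverage ratio Rc. Under a tandem duplication present in a fraction `f` of
#' molecules, each carrier contributes two copies of the origin segment, so
#' Rc = 1 + f. Under a deletion of the complementary (terminus) segment in a
#' fraction `q` of molecules, the terminus coverage drops to `1 - q` of the
#' origin coverage, so Rc = 1 / (1 - q), undefined at q = 1.
#'
#' @param scenario `"duplication"` or `"deletion"`.
#' @param prevalence Fraction of genomic DNA molecules carrying the variant,
#'   in `[0, 1]`.
#' @return The expected Rc (a number >= 1).
#' @examples
#' expected_rc("duplication", 0.8) # 1.8
#' expected_rc("deletion", 1 / 6)  # 1.2
#' @export
expected_rc <- function(scenario = c("duplication", "deletion"), prevalence) {
  scenario <- match.arg(scenario)
  if (any(prevalence < 0 | prevalence > 1)) abort("`prevalence` must be in [0, 1].")
  if (scenario == "duplication") {
    1 + prevalence
  } else {
    if (any(prevalence == 1)) abort("expected Rc is undefined for a deletion at prevalence 1.")
    1 / (1 - prevalence)
  }
}

#' Infer variant prevalence from an observed Rc
#'
#' Exact inverse of [expected_rc()], clipped to `[0, 1]`:
#' `f = Rc - 1` for a duplication, `q = 1 - 1/Rc` for a deletion. An observed
#' Rc below 1 means the complementary segment is the amplified one; this is
#' reported as an error rather than silently swapping orientation.
#'
#' @param rc Observed Rc, must be >= 1.
#' @inheritParams expected_rc
#' @return Estimated prevalence in `[0, 1]`.
#' @examples
#' infer_prevalence(1.25, "duplication") # 0.25
#' @export
infer_prevalence <- function(rc, scenario = c("duplication", "deletion")) {
  scenario <- match.arg(scenario)
  if (any(rc < 1)) {
    abort("Rc < 1: the complementary segment is amplified; swap the segment orientation.")
  }
  p <- if (scenario == "duplication") rc - 1 else 1 - 1 / rc
  pmin(pmax(p, 0), 1)
}

#' Probability of observing k pattern-positive clones among n sampled
#'
#' When clones are sampled from a population in which a coverage pattern
#' (e.g. the duplication) is present at prevalence `p`, the number of
#' pattern-positive clones among `n` is Binomial(n, p). This is the
#' clone-sampling probability used to weigh structural-variant scenarios.
#'
#' @param n Number of sampled clones.
#' @param k Number displaying the pattern, `0 <= k <= n`.
#' @param p Pattern prevalence in the population, in `[0, 1]`.
#' @return The binomial probability mass at `k`.
#' @examples
#' clone_sampling_pmf(16, 3, 0.25)
#' @export
clone_sampling_pmf <- function(n, k, p) {
  if (any(k < 0 | k > n)) abort("`k` must satisfy 0 <= k <= n.")
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1].")
  dbinom(k, n, p)
}

#' Likelihood ratio of duplication versus deletion scenarios
#'
#' Given that `k` of `n` sampled clones display the coverage pattern, and
#' that the observed population Rc implies a prevalence of `p_dup` under the
#' duplication scenario or `p_del` under the deletion scenario, the ratio of
#' the two binomial clone-sampling probabilities measures how much more
#' likely the clone sample is under duplication than deletion. With the
#' calibration n = 16, k = 3, p_dup = 0.25, p_del = 0.07 the ratio is ~2.8
#' (about three): the duplication scenario is about three times more likely.
#'
#' @inheritParams clone_sampling_pmf
#' @param p_dup Pattern prevalence implied by the duplication scenario.
#' @param p_del Pattern prevalence implied by the deletion scenario.
#' @return A `scenario_lr`: list with `pmf_dup`, `pmf_del`, `ratio`.
#' @examples
#' scenario_likelihood_ratio(16, 3, p_dup = 0.25, p_del = 0.07)
#' @export
scenario_likelihood_ratio <- function(n, k, p_dup, p_del) {
  pmf_dup <- clone_sampling_pmf(n, k, p_dup)
  pmf_del <- clone_sampling_pmf(n, k, p_del)
  if (pmf_del == 0) abort("deletion-scenario probability mass is zero; ratio undefined.")
  structure(
    list(n = n, k = k, p_dup = p_dup, p_del = p_del,
         pmf_dup = pmf_dup, pmf_del = pmf_del, ratio = pmf_dup / pmf_del),
    class = "scenario_lr"
  )
}

#' @export
print.scenario_lr <- function(x, ...) {
  cat(sprintf(
    "<scenario_lr> k = %d of n = %d clones; P(dup, p=%.3g) = %.4g; P(del, p=%.3g) = %.4g; ratio = %.3f\n",
    x$k, x$n, x$p_dup, x$pmf_dup, x$p_del, x$pmf_del, x$ratio
  ))
  invisible(x)
}
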