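#' Specify a synthetic staging cohort
#'
#' A cohort is drawn in two stages: the true (pathological) stage of each
#' patient follows `stage_prior`, and the imaging-assigned stage follows the
#' row of `misclassification` for that true stage. The identity matrix gives
#' a perfectly concordant cohort; the empirical joint distribution of a
#' printed contingency table can be emulated by using its column proportions
#' as the prior and its column-normalized counts as the misclassification
#' rows.
#'
#' @param n_patients cohort size.
#' @param stage_labels ordered character vector of stage names.
#' @param stage_prior probability vector over true stages (sums to 1).
#' @param misclassification row-stochastic `K x K` matrix;
#'   `misclassification[t, o]` is the probability that a patient of true
#'   stage `t` is called stage `o` by imaging.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, stage_labels, stage_prior,
                        misclassification, seed = 0) {
  K <- length(stage_labels)
  if (K < 2) stop_invalid("need at least two stages")
  if (length(stage_prior) != K || abs(sum(stage_prior) - 1) > 1e-12 ||
      any(stage_prior < 0))
    stop_invalid("stage_prior must be a probability vector over the stages")
  m <- as.matrix(misclassification)
  if (!all(dim(m) == K) || any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
    stop_invalid("misclassification must be a row-stochastic K x K matrix")
  if (n_patients < 1) stop_invalid("n_patients must be >= 1")
  structure(list(n_patients = as.integer(n_patients),
                 stage_labels = as.character(stage_labels),
                 stage_prior = as.numeric(stage_prior),
                 misclassification = m, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a staging cohort
#'
#' @param spec a [cohort_spec].
#' @return a [staging_table]: `K x K` counts with rows the imaging call and
#'   columns the pathological stage, summing to `n_patients`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  K <- length(spec$stage_labels)
  with_seed(spec$seed, {
    true <- sample.int(K, spec$n_patients, replace = TRUE,
                       prob = spec$stage_prior)
    counts <- matrix(0L, K, K)
    for (t in seq_len(K)) {
      nt <- sum(true == t)
      if (nt == 0) next
      obs <- sample.int(K, nt, replace = TRUE,
                        prob = spec$misclassification[t, ])
      tb <- tabulate(obs, nbins = K)
      counts[, t] <- counts[, t] + tb
    }
    staging_table(counts, spec$stage_labels)
  })
}
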