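#' Calibrated proportion of wild genome left
#'
#' Wild reference populations average P(wild) below one and farm references
#' above zero, so a raw admixed-sample mean is rescaled against the two
#' reference anchors:
#' \deqn{\mathrm{wild\ genome\ left} =
#'   \frac{\bar P_{adm} - Farm_{ref}}{Wild_{ref} - Farm_{ref}}}
#' Values can fall outside \[0, 1\] when sampling noise pushes the admixed
#' mean beyond an anchor; such values are returned as-is with a warning.
#'
#' @param p_adm_mean mean P(wild) of the admixed sample.
#' @param wild_ref mean P(wild) of the wild references (must exceed
#'   `farm_ref`).
#' @param farm_ref mean P(wild) of the farm references.
#' @return the calibrated proportion.
#' @examples
#' wild_genome_proportion(0.48, 0.93, 0.07)  # 0.4767...
#' @export
wild_genome_proportion <- function(p_adm_mean, wild_ref, farm_ref) {
  if (wild_ref <= farm_ref) {
    stop("wild_ref (", wild_ref, ") must exceed farm_ref (", farm_ref, ")")
  }
  out <- (p_adm_mean - farm_ref) / (wild_ref - farm_ref)
  flagged <- out < 0 | out > 1
  if (any(flagged)) {
    warning("calibrated proportion outside [0, 1] (sampling noise beyond ",
            "the calibration anchors)")
  }
  out
}

# Pooled within-population variance of logit P(wild) across a panel of
# reference distributions, and the population mean logits with sizes.
.panel_components <- function(wild_panel) {
  vals <- lapply(wild_panel, function(d) {
    split(d$values$logit_p_wild, d$values$population)
  })
  vals <- unlist(vals, recursive = FALSE)
  ns <- lengths(vals)
  if (any(ns < 1L)) stop("empty population in the wild reference panel")
  ss <- sum(vapply(vals, function(v) sum((v - mean(v))^2), numeric(1)))
  df <- sum(pmax(ns - 1L, 0L))
  if (df == 0) stop("within-population variance needs a population with >= 2 values")
  list(sigma2_within = ss / df,
       pop_means = vapply(vals, mean, numeric(1)),
       pop_ns = ns)
}

#' One-sided test for reduced mean P(wild) in a contemporary sample
#'
#' Tests the null hypothesis that a contemporary sample has the same mean
#' P(wild) as the wild reference against the one-sided alternative that its
#' mean is lower (i.e. the population is admixed). All P(wild) values are
#' logit-transformed first; under the null the samples come from the same
#' population, so a common within-population variance is pooled across all
#' wild reference populations.
#'
#' Two modes:
#' \describe{
#'   \item{with_reference}{a population-specific historical sample exists;
#'     a two-sample z-test of the contemporary versus historical mean with
#'     variance `sigma2_within * (1/n_hist + 1/n_cont)`.}
#'   \item{without_reference}{no historical sample; the null mean is the
#'     grand mean of the wild reference population means, and the variance
#'     of the contemporary mean gains a between-population component:
#'     `sigma2_between + sigma2_within / n_cont`. `sigma2_between` is the
#'     method-of-moments estimate (variance of population mean logits minus
#'     the average within-population contribution), floored at 0.}
#' }
#'
#' @param contemporary a [build_reference_distribution()] of the contemporary
#'   sample.
#' @param historical optional historical distribution for the same
#'   population; supplying it selects with_reference mode.
#' @param wild_panel list of wild reference distributions (one or more, each
#'   possibly multi-population); without_reference mode needs at least two
#'   populations in total.
#' @param level one-sided significance level (default 0.05).
#' @return an `introgression_test` list: `mode`, `reference_mean_logit`,
#'   `contemporary_mean_logit`, `sigma2_within`, `sigma2_between`,
#'   `n_contemporary`, `n_reference`, `critical_value_logit`,
#'   `critical_value` (back-transformed to the P(wild) scale), `p_value`,
#'   `reject`, `level`.
#' @export
test_mean_pwild <- function(contemporary, historical = NULL, wild_panel,
                            level = 0.05) {
  if (inherits(wild_panel, "reference_distribution")) {
    wild_panel <- list(wild_panel)
  }
  comp <- .panel_components(wild_panel)
  s2w <- comp$sigma2_within
  m_cont <- mean(contemporary$values$logit_p_wild)
  n_cont <- contemporary$n

  if (!is.null(historical)) {
    mode <- "with_reference"
    n_ref <- historical$n
    null_mean <- mean(historical$values$logit_p_wild)
    var_diff <- s2w * (1 / n_ref + 1 / n_cont)
    s2b <- 0
  } else {
    mode <- "without_reference"
    if (length(comp$pop_means) < 2L) {
      stop("without a historical reference, the wild panel needs >= 2 populations")
    }
    null_mean <- mean(comp$pop_means)
    s2b <- max(0, stats::var(comp$pop_means) - s2w * mean(1 / comp$pop_ns))
    n_ref <- sum(comp$pop_ns)
    var_diff <- s2b + s2w / n_cont
  }
  z <- (m_cont - null_mean) / sqrt(var_diff)
  p_value <- stats::pnorm(z)
  crit_logit <- null_mean + stats::qnorm(level) * sqrt(var_diff)
  structure(list(
    mode = mode,
    reference_mean_logit = null_mean,
    contemporary_mean_logit = m_cont,
    sigma2_within = s2w,
    sigma2_between = s2b,
    n_contemporary = n_cont,
    n_reference = n_ref,
    critical_value_logit = crit_logit,
    critical_value = inv_logit(crit_logit),
    p_value = p_value,
    reject = m_cont < crit_logit,
    level = level
  ), class = "introgression_test")
}

#' @export
print.introgression_test <- function(x, ...) {
  cat(sprintf("introgression test (%s, one-sided level %.3g)\n", x$mode, x$level))
  cat(sprintf("  contemporary mean logit P(wild) = %.3f (n = %d)\n",
              x$contemporary_mean_logit, x$n_contemporary))
  cat(sprintf("  null mean = %.3f; critical value = %.3f [P(wild) %.3f]\n",
              x$reference_mean_logit, x$critical_value_logit, x$critical_value))
  cat(sprintf("  p = %.4g -> %s\n", x$p_value,
              if (x$reject) "REJECT: evidence of introgression" else "no rejection"))
  invisible(x)
}

#' Critical-value curve versus contemporary sample size
#'
#' For each sample size n, the largest contemporary mean P(wild) that would
#' still be rejected at the given level (the inverse of [test_mean_pwild()]),
#' back-transformed from the logit to the P(wild) scale. The curve rises
#' towards the reference mean as n grows; without a historical reference it
#' plateaus at `inv_logit(grand mean - z_{1-level} * sqrt(sigma2_between))`.
#'
#' @inheritParams test_mean_pwild
#' @param n_range contemporary sample sizes (each >= 2).
#' @return data frame `n`, `critical_value_logit`, `critical_value`.
#' @export
critical_value_curve <- function(wild_panel, historical = NULL,
                                 n_range = c(5, 10, 20, 30, 50, 100),
                                 level = 0.05) {
  if (inherits(wild_panel, "reference_distribution")) {
    wild_panel <- list(wild_panel)
  }
  if (any(n_range < 2)) stop("n_range values must be >= 2")
  comp <- .panel_components(wild_panel)
  s2w <- comp$sigma2_within
  if (!is.null(historical)) {
    null_mean <- mean(historical$values$logit_p_wild)
    var_n <- s2w * (1 / historical$n + 1 / n_range)
  } else {
    if (length(comp$pop_means) < 2L) {
      stop("without a historical reference, the wild panel needs >= 2 populations")
    }
    null_mean <- mean(comp$pop_means)
    s2b <- max(0, stats::var(comp$pop_means) - s2w * mean(1 / comp$pop_ns))
    var_n <- s2b + s2w / n_range
  }
  crit <- null_mean + stats::qnorm(level) * sqrt(var_n)
  data.frame(n = n_range, critical_value_logit = crit,
             critical_value = inv_logit(crit))
}

#' Bootstrap confidence interval for the proportion of wild genome left
#'
#' Resamples the admixed individuals' P(wild) values with replacement,
#' applies the calibration of [wild_genome_proportion()] to each resample
#' mean, and reports the percentile interval.
#'
#' @param values per-individual P(wild) of the admixed sample.
#' @param wild_ref,farm_ref calibration anchors (reference means).
#' @param n_boot bootstrap replicates (default 1000).
#' @param level central coverage of the interval (default 0.95).
#' @param seed integer seed.
#' @return an `introgression_estimate` list: `p_adm_mean`, `wild_ref`,
#'   `farm_ref`, `wild_genome_left`, `ci_low`, `ci_high`, `n`, `n_boot`,
#'   `level`, `seed`.
#' @export
bootstrap_ci <- function(values, wild_ref, farm_ref, n_boot = 1000L,
                         level = 0.95, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no P(wild) values supplied")
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  n <- length(values)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_means <- rowMeans(matrix(values[idx], nrow = n_boot))
  boot_est <- suppressWarnings(
    wild_genome_proportion(boot_means, wild_ref, farm_ref))
  est <- wild_genome_proportion(mean(values), wild_ref, farm_ref)
  qs <- stats::quantile(boot_est, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  structure(list(p_adm_mean = mean(values), wild_ref = wild_ref,
                 farm_ref = farm_ref, wild_genome_left = est,
                 ci_low = qs[1], ci_high = qs[2], n = n,
                 n_boot = as.integer(n_boot), level = level,
                 seed = as.integer(seed)),
            class = "introgression_estimate")
}

#' @export
print.introgression_estimate <- function(x, ...) {
  cat(sprintf("wild genome left: %.1f%% (%.0f%% CI %.1f%% - %.1f%%)\n",
              100 * x$wild_genome_left, 100 * x$level,
              100 * x$ci_low, 100 * x$ci_high))
  cat(sprintf("  mean P(wild) = %.3f over %d individuals; anchors wild %.3f / farm %.3f\n",
              x$p_adm_mean, x$n, x$wild_ref, x$farm_ref))
  invisible(x)
}
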