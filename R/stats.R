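#' Chance level for a k-class decoder
#'
#' @param k Number of classes (>= 2).
#' @return `100 / k`, in percent, rounded to two decimals (14.29 for 7
#'   classes, 12.5 for 8, 50 for 2).
#' @export
chance_level <- function(k) {
  if (!is.numeric(k) || k < 2) stop("k must be >= 2", call. = FALSE)
  round(100 / k, 2)
}

#' Binomial null model for decoder accuracy
#'
#' @param k_classes Number of classes.
#' @param n_predictions Number of predictions per accuracy estimate (the
#'   average number of classifications made per participant).
#' @param alpha Significance level.
#' @return A list of class `chance_model` with `chance_rate = 1/k`.
#' @export
chance_model <- function(k_classes, n_predictions, alpha = 0.05) {
  stopifnot(k_classes >= 2, n_predictions >= 1, alpha > 0, alpha < 1)
  structure(list(k_classes = as.integer(k_classes),
                 n_predictions = as.integer(round(n_predictions)),
                 alpha = alpha, chance_rate = 1 / k_classes),
            class = "chance_model")
}

#' Minimum correct count exceeding chance under the binomial null
#'
#' Smallest integer `m` with `P(X >= m) <= alpha` for
#' `X ~ Binomial(n, 1/k)`, evaluated with the exact binomial CDF (no
#' normal approximation). When no achievable count rejects (e.g. n = 1,
#' k = 2 at alpha = 0.05), the sentinel `n + 1` is returned with
#' `attainable = FALSE`.
#'
#' @param cm A [chance_model()].
#' @return A list: `m` (count), `accuracy_pct` (`100 m / n`),
#'   `attainable`.
#' @export
binomial_chance_threshold <- function(cm) {
  stopifnot(inherits(cm, "chance_model"))
  n <- cm$n_predictions; p <- cm$chance_rate; a <- cm$alpha
  m0 <- stats::qbinom(1 - a, n, p)
  m <- NA_integer_
  for (cand in seq(max(0L, m0 - 2L), n)) {
    if (stats::pbinom(cand - 1, n, p, lower.tail = FALSE) <= a) {
      m <- cand
      break
    }
  }
  if (is.na(m)) {
    return(list(m = n + 1L, accuracy_pct = 100 * (n + 1) / n,
                attainable = FALSE))
  }
  list(m = as.integer(m), accuracy_pct = 100 * m / n, attainable = TRUE)
}

#' Draw accuracies of a chance-level classifier
#'
#' I.i.d. draws `X/n` with `X ~ Binomial(n, 1/k)`.
#'
#' @param cm A [chance_model()].
#' @param size Number of draws.
#' @param seed Seed.
#' @return Numeric vector of accuracies in `[0, 1]`.
#' @export
sample_null_accuracies <- function(cm, size, seed = 1) {
  stopifnot(size >= 1)
  with_seed(derive_seed(seed, "null_acc"),
            stats::rbinom(size, cm$n_predictions, cm$chance_rate) /
              cm$n_predictions)
}

#' Bootstrap comparison of subject accuracies against the binomial null
#'
#' Each iteration draws one binomial-null accuracy per subject and
#' records the difference between the observed mean accuracy and that
#' null sample's mean. The 95% CI is the (2.5, 97.5) percentile interval
#' of the bootstrap difference distribution and the p value is the
#' one-sided proportion of iterations in which the model fails to beat
#' chance (floored at `1/n_iter`).
#'
#' With `resample_subjects = TRUE` the observed mean is additionally
#' recomputed from a with-replacement resample of the subjects in every
#' iteration. That variant folds between-subject variability into the CI
#' but doubles the variance of the difference under the null, making the
#' test markedly conservative; the default keeps the observed mean fixed,
#' which is type-I calibrated.
#'
#' @param subject_accuracies Per-subject accuracies, as proportions in
#'   `[0, 1]` (values above 1 are interpreted as percent).
#' @param cm A [chance_model()].
#' @param n_iter Bootstrap iterations (default 100000).
#' @param seed Seed.
#' @param resample_subjects Also resample subjects with replacement (see
#'   above; default `FALSE`).
#' @return An object of class `chance_test`: mean accuracy and SD (%),
#'   mean difference from chance (%), `ci95`, `p_value`, `n_bootstrap`,
#'   `seed`, and `significant` at the model's alpha.
#' @export
bootstrap_vs_chance <- function(subject_accuracies, cm, n_iter = 100000,
                                seed = 1, resample_subjects = FALSE) {
  stopifnot(length(subject_accuracies) >= 1)
  acc <- subject_accuracies
  if (any(acc > 1)) acc <- acc / 100
  if (n_iter < 100)
    warning("n_iter < 100 gives unstable percentile intervals")
  S <- length(acc)
  diffs <- with_seed(derive_seed(seed, "bootstrap"), {
    obs <- if (resample_subjects) {
      rowMeans(matrix(acc[sample.int(S, S * n_iter, replace = TRUE)],
                      nrow = n_iter))
    } else mean(acc)
    nul <- matrix(stats::rbinom(S * n_iter, cm$n_predictions,
                                cm$chance_rate) / cm$n_predictions,
                  nrow = n_iter)
    100 * (obs - rowMeans(nul))
  })
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975)))
  p <- max(mean(diffs <= 0), 1 / n_iter)
  structure(
    list(mean_accuracy = 100 * mean(acc),
         sd = 100 * stats::sd(acc),
         mean_difference_from_chance = mean(diffs),
         ci95 = ci, p_value = p, n_bootstrap = as.integer(n_iter),
         seed = seed, chance_model = cm,
         significant = p < cm$alpha && ci[1] > 0),
    class = "chance_test")
}

#' @export
print.chance_test <- function(x, ...) {
  cat(sprintf(
    "<chance_test> accuracy %.2f +- %.2f%% vs %.2f%% chance | diff %.2f%% (95%% CI %.2f-%.2f), p %s\n",
    x$mean_accuracy, if (is.na(x$sd)) 0 else x$sd,
    100 * x$chance_model$chance_rate, x$mean_difference_from_chance,
    x$ci95[1], x$ci95[2], format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.chance_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_difference_from_chance,
    conf.low = x$ci95[1], conf.high = x$ci95[2], p.value = x$p_value,
    mean_accuracy = x$mean_accuracy, sd_accuracy = x$sd,
    chance_pct = 100 * x$chance_model$chance_rate,
    n_bootstrap = x$n_bootstrap)
}

#' @export
glance.chance_test <- function(x, ...) tidy(x)

#' Two-sample pooled-variance t-test between model accuracy lists
#'
#' Classic two-sample t-test with pooled variance,
#' `df = n1 + n2 - 2`, two-sided p value and a 95% CI of the mean
#' difference. With zero pooled variance the statistic degenerates to 0
#' (equal means, p = 1) or +-Inf (p = 0).
#'
#' @param acc_a,acc_b Accuracy vectors (any common scale), length >= 2.
#' @return An object of class `model_comparison`.
#' @export
compare_models <- function(acc_a, acc_b) {
  if (length(acc_a) < 2 || length(acc_b) < 2)
    stop("both accuracy lists need at least 2 entries", call. = FALSE)
  n1 <- length(acc_a); n2 <- length(acc_b)
  df <- n1 + n2 - 2
  md <- mean(acc_a) - mean(acc_b)
  sp2 <- ((n1 - 1) * stats::var(acc_a) + (n2 - 1) * stats::var(acc_b)) / df
  if (sp2 == 0) {
    tstat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    ci <- c(md, md)
  } else {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- md / se
    p <- 2 * stats::pt(-abs(tstat), df)
    ci <- md + c(-1, 1) * stats::qt(0.975, df) * se
  }
  structure(list(t_statistic = tstat, degrees_of_freedom = df,
                 p_value = p, ci95 = ci, mean_difference = md),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> t(%d) = %.3f, p = %s, 95%% CI %.2f-%.2f\n",
              x$degrees_of_freedom, x$t_statistic,
              format.pval(x$p_value, digits = 3), x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::tibble(estimate = x$mean_difference, statistic = x$t_statistic,
                 p.value = x$p_value, parameter = x$degrees_of_freedom,
                 conf.low = x$ci95[1], conf.high = x$ci95[2])
}
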