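#' Bootstrap a mean over replicate cores
#'
#' Resamples the replicate values (one per replicate core) with
#' replacement, `n_draws` times, and summarizes the resample means: the
#' bootstrap mean and a percentile confidence interval. With few
#' replicates the plain percentile interval is too narrow (resample
#' variance carries the n-divisor bias), so by default the draw means are
#' expanded about the sample mean by \eqn{\sqrt{n/(n-1)}} before taking
#' percentiles ("expanded percentile"; set `expand = FALSE` for the plain
#' interval). `method = "exhaustive"` enumerates all \eqn{n^n} equally
#' likely resamples instead of drawing them, giving the exact bootstrap
#' distribution for small n.
#'
#' @param values Numeric vector of per-replicate statistics (e.g. WADs);
#'   at least one value (a single value draws a warning and yields a
#'   degenerate interval).
#' @param n_draws Number of bootstrap draws (ignored for `"exhaustive"`).
#' @param seed Optional RNG seed for reproducibility.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"resample"` (Monte Carlo) or `"exhaustive"` (all
#'   \eqn{n^n} resamples, n <= 8).
#' @param expand Apply the small-sample expansion factor
#'   \eqn{\sqrt{n/(n-1)}} to the draw spread (default `TRUE`).
#' @return An object of class `qsip_boot`: list with `mean`, `ci_low`,
#'   `ci_high`, `n`, `n_draws`, `seed`, `conf_level`, `method`.
#' @export
#' @examples
#' bootstrap_mean(c(1.70, 1.72), method = "exhaustive")$mean  # 1.71
bootstrap_mean <- function(values, n_draws = 1000, seed = NULL,
                           conf_level = 0.95,
                           method = c("resample", "exhaustive"),
                           expand = TRUE) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0L) data_error("cannot bootstrap an empty set of values")
  if (n < 2L) warning("bootstrapping a single replicate: degenerate interval")
  draws <- with_seed(seed, boot_draw_means(values, n_draws, method))
  est <- summarize_draws(draws, mean(values), n, conf_level, expand)
  structure(c(est, list(n = n, n_draws = length(draws), seed = seed,
                        conf_level = conf_level, method = method)),
            class = "qsip_boot")
}

#' @export
print.qsip_boot <- function(x, ...) {
  cat(sprintf("bootstrap mean %.6g, %d%% CI [%.6g, %.6g] (n = %d, draws = %d)\n",
              x$mean, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$n_draws))
  invisible(x)
}

# Resample (or enumerate) means of `values`.
boot_draw_means <- function(values, n_draws, method) {
  n <- length(values)
  if (method == "exhaustive") {
    if (n > 8L) config_error("exhaustive enumeration supported for n <= 8")
    idx <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
    rowMeans(matrix(values[idx], nrow(idx)))
  } else {
    idx <- matrix(sample.int(n, n_draws * n, replace = TRUE), n_draws)
    rowMeans(matrix(values[idx], n_draws))
  }
}

# Center/expand draw means and take percentile bounds.
summarize_draws <- function(draws, center, n, conf_level, expand) {
  if (expand) draws <- expand_draws(draws, center, n)
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  list(mean = mean(draws, na.rm = TRUE), ci_low = qs[1L], ci_high = qs[2L])
}

#' Bootstrapped density shift between labeled and unlabeled treatments
#'
#' Estimates \eqn{Z = W_{lab} - W_{light}} for one taxon by resampling
#' replicate cores with replacement independently within each treatment
#' and differencing the paired draw means: in every draw a labeled and an
#' unlabeled resample are taken and their means subtracted, and the
#' resulting draws are summarized as in [bootstrap_mean()]. A taxon with
#' no unlabeled observations cannot be differenced; this raises a
#' `qsip_label_only` error directing the caller to the label-only rule
#' ([call_active_label_only()]).
#'
#' @param labeled Per-core WADs in the labeled treatment (\eqn{^{13}}C).
#' @param unlabeled Per-core WADs in the unlabeled treatment (\eqn{^{12}}C).
#' @inheritParams bootstrap_mean
#' @return An object of class `qsip_boot` for Z.
#' @export
#' @examples
#' wad_difference(c(1.74, 1.76), 1.70, method = "exhaustive")$mean  # 0.05
wad_difference <- function(labeled, unlabeled, n_draws = 1000, seed = NULL,
                           conf_level = 0.95,
                           method = c("resample", "exhaustive"),
                           expand = TRUE) {
  method <- match.arg(method)
  labeled <- labeled[!is.na(labeled)]
  unlabeled <- unlabeled[!is.na(unlabeled)]
  if (length(labeled) == 0L) data_error("taxon absent from the labeled treatment")
  if (length(unlabeled) == 0L) {
    stop(errorCondition(
      "taxon absent from the unlabeled treatment: defer to the label-only rule",
      class = c("qsip_label_only", "error")))
  }
  nl <- length(labeled); nu <- length(unlabeled)
  draws <- with_seed(seed, {
    if (method == "exhaustive") {
      dl <- boot_draw_means(labeled, 0L, "exhaustive")
      du <- boot_draw_means(unlabeled, 0L, "exhaustive")
      if (expand) {
        dl <- expand_draws(dl, mean(labeled), nl)
        du <- expand_draws(du, mean(unlabeled), nu)
      }
      as.vector(outer(dl, du, "-"))  # all equally likely pairs
    } else {
      dl <- boot_draw_means(labeled, n_draws, "resample")
      du <- boot_draw_means(unlabeled, n_draws, "resample")
      if (expand) {
        dl <- expand_draws(dl, mean(labeled), nl)
        du <- expand_draws(du, mean(unlabeled), nu)
      }
      dl - du
    }
  })
  alpha <- (1 - conf_level) / 2
  qs <- stats::quantile(draws, c(alpha, 1 - alpha), names = FALSE)
  structure(list(mean = mean(draws), ci_low = qs[1L], ci_high = qs[2L],
                 n = c(labeled = nl, unlabeled = nu), n_draws = length(draws),
                 seed = seed, conf_level = conf_level, method = method),
            class = "qsip_boot")
}

# Rescale draw means about the sample mean by sqrt(n/(n-1)) to undo the
# n-divisor variance deficit of the resample distribution.
expand_draws <- function(draws, center, n) {
  if (n > 1L) center + sqrt(n / (n - 1)) * (draws - center) else draws
}
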