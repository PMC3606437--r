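#' Welch two-sample comparison of group means
#'
#' Two-tailed t-test not assuming equal variances (Satterthwaite degrees of
#' freedom), via [stats::t.test()]. Degenerate inputs (a group with fewer
#' than two values, or both groups with zero variance) do not raise: the
#' comparison is returned with `computable = FALSE` or flagged `degenerate`.
#'
#' @param x,y numeric vectors for the two groups.
#' @param labels character length-2 group labels.
#' @return An object of class `class_comparison`: list with `group_labels`,
#'   `group_means`, `group_sizes`, `t_statistic`, `df`, `p_value`,
#'   `computable`, `degenerate`.
#' @export
welch_comparison <- function(x, y, labels = c("group1", "group2")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  out <- list(group_labels = labels,
              group_means = c(mean(x), mean(y)),
              group_sizes = c(length(x), length(y)),
              t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
              computable = FALSE, degenerate = FALSE)
  class(out) <- "class_comparison"
  if (length(x) < 2L || length(y) < 2L) return(out)
  out$computable <- TRUE
  if (var(x) == 0 && var(y) == 0) {
    out$degenerate <- TRUE
    if (mean(x) == mean(y)) {
      out$t_statistic <- 0
      out$df <- length(x) + length(y) - 2
      out$p_value <- 1
    } else {
      # variance floor: means differ with no within-group spread
      out$t_statistic <- sign(mean(x) - mean(y)) * Inf
      out$df <- length(x) + length(y) - 2
      out$p_value <- 0
    }
    return(out)
  }
  tt <- t.test(x, y, var.equal = FALSE)
  out$t_statistic <- unname(tt$statistic)
  out$df <- unname(tt$parameter)
  out$p_value <- tt$p.value
  out
}

#' @export
print.class_comparison <- function(x, ...) {
  cat("class_comparison: ", x$group_labels[1], " (n=", x$group_sizes[1],
      ", mean=", signif(x$group_means[1], 4), ") vs ", x$group_labels[2],
      " (n=", x$group_sizes[2], ", mean=", signif(x$group_means[2], 4),
      ")\n", sep = "")
  if (x$computable)
    cat("  Welch t = ", signif(x$t_statistic, 4), ", df = ",
        signif(x$df, 4), ", two-tailed p = ", format.pval(x$p_value),
        if (x$degenerate) "  [degenerate: zero within-group variance]" else "",
        "\n", sep = "")
  else cat("  not computable (a class has fewer than 2 observations)\n")
  invisible(x)
}

#' Mean lower-node rho by pathogenicity-score class
#'
#' Splits nonsynonymous observations at a pathogenicity-score threshold
#' (default 0.7) and compares the mean overall lower-node rho of the
#' low-score class against the high-score class with Welch's t-test. Under
#' purifying selection the high-score (more deleterious) class is expected
#' to sit at lower rho, i.e. on younger branches. Observations exactly at
#' the threshold join the lower class; their count is reported.
#'
#' @param obs observation table from [observations()].
#' @param score_threshold score cut point (default 0.7).
#' @return A `class_comparison` with extra fields `n_at_threshold`,
#'   `threshold`.
#' @export
mean_rho_by_score_class <- function(obs, score_threshold = 0.7) {
  ns <- obs[obs$class == "nonsynonymous" & !is.na(obs$score), , drop = FALSE]
  lo <- ns$rho_total_lower[ns$score <= score_threshold]
  hi <- ns$rho_total_lower[ns$score > score_threshold]
  cmp <- welch_comparison(lo, hi,
                          labels = c(paste0("score<", score_threshold),
                                     paste0("score>", score_threshold)))
  cmp$n_at_threshold <- sum(ns$score == score_threshold)
  cmp$threshold <- score_threshold
  cmp
}

#' Mean pathogenicity score by rho depth class
#'
#' Splits nonsynonymous observations at a lower-node rho threshold (default
#' 4) and compares mean pathogenicity scores of the young (recent, low-rho)
#' class against the old class. Under purifying selection recent variants
#' carry higher mean scores. Observations exactly at the threshold join the
#' lower (young) class.
#'
#' @param obs observation table from [observations()].
#' @param rho_threshold rho cut point (default 4).
#' @return A `class_comparison` with extra fields `n_at_threshold`,
#'   `threshold`.
#' @export
mean_score_by_rho_class <- function(obs, rho_threshold = 4) {
  ns <- obs[obs$class == "nonsynonymous" & !is.na(obs$score), , drop = FALSE]
  young <- ns$score[ns$rho_total_lower <= rho_threshold]
  old <- ns$score[ns$rho_total_lower > rho_threshold]
  cmp <- welch_comparison(young, old,
                          labels = c(paste0("rho<", rho_threshold),
                                     paste0("rho>", rho_threshold)))
  cmp$n_at_threshold <- sum(ns$rho_total_lower == rho_threshold)
  cmp$threshold <- rho_threshold
  cmp
}

#' Binned pathogenicity score distributions
#'
#' Bins scores into ten equal classes over \[0, 1\] (left-closed bins, the
#' last bin closed on both sides so a score of exactly 1 is counted) and
#' normalises counts to probabilities.
#'
#' @param observed_scores,all_possible_scores numeric vectors of scores in
#'   \[0, 1\].
#' @return list with elements `observed` and `possible`, each of class
#'   `score_distribution` (fields `bin_edges`, `counts`, `probabilities`).
#' @export
score_histograms <- function(observed_scores, all_possible_scores) {
  list(observed = score_distribution(observed_scores),
       possible = score_distribution(all_possible_scores))
}

#' @rdname score_histograms
#' @param scores numeric vector of scores in \[0, 1\].
#' @export
score_distribution <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no scores to bin")
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  bin <- pmin(floor(scores * 10 + 1e-9) + 1L, 10L)
  counts <- tabulate(bin, nbins = 10L)
  structure(list(bin_edges = seq(0, 1, 0.1), counts = counts,
                 probabilities = counts / sum(counts)),
            class = "score_distribution")
}

#' Fit the exponential selection function
#'
#' Fits `P_observed / P_allpossible = A * exp(-R * g)` by nonlinear least
#' squares on the per-bin probability ratios, with `g` the bin midpoint.
#' `R` is the pathogenicity selection constant: the rate at which the
#' observed-to-possible frequency ratio decays with predicted pathogenicity,
#' larger values meaning stronger purifying selection. Bins with zero
#' all-possible probability are excluded; at least three usable bins are
#' required. Starting values are `A` = first usable ratio, `R` = 1.
#'
#' @param observed_dist,possible_dist `score_distribution` objects (or the
#'   list returned by [score_histograms()] passed via `observed_dist`).
#' @return An object of class `selection_fit`: list with `A`, `R`,
#'   `stderr_A`, `stderr_R`, `n_bins_used`, `g`, `ratio`, `fitted`,
#'   `residual_ss`.
#' @export
fit_selection_constant <- function(observed_dist, possible_dist) {
  if (is.list(observed_dist) && !inherits(observed_dist,
                                          "score_distribution") &&
      missing(possible_dist)) {
    possible_dist <- observed_dist$possible
    observed_dist <- observed_dist$observed
  }
  g <- seq(0.05, 0.95, by = 0.1)
  keep <- possible_dist$probabilities > 0
  if (sum(keep) < 3L)
    stop("need at least 3 bins with nonzero all-possible probability")
  g <- g[keep]
  ratio <- observed_dist$probabilities[keep] /
    possible_dist$probabilities[keep]
  dat <- data.frame(g = g, ratio = ratio)
  starts <- list(list(A = ratio[1], R = 1),
                 list(A = mean(ratio), R = 0))
  pos <- ratio > 0
  if (sum(pos) >= 2L) {
    # log-linear initialisation from the positive ratios
    ll <- stats::lm(log(ratio[pos]) ~ g[pos])
    starts <- c(list(list(A = exp(unname(coef(ll)[1])),
                          R = -unname(coef(ll)[2]))), starts)
  }
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(ratio ~ A * exp(-R * g), data = dat, start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("exponential selection fit did not converge (last start: A = ",
         signif(st$A, 4), ", R = ", signif(st$R, 4), ")")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(A = unname(est["A"]), R = unname(est["R"]),
                 stderr_A = unname(se["A"]), stderr_R = unname(se["R"]),
                 n_bins_used = sum(keep), g = g, ratio = ratio,
                 fitted = unname(predict(fit)),
                 residual_ss = sum(residuals(fit)^2)),
            class = "selection_fit")
}

#' @export
print.selection_fit <- function(x, ...) {
  cat("selection_fit: A = ", signif(x$A, 4), " (se ", signif(x$stderr_A, 3),
      "), R = ", signif(x$R, 4), " (se ", signif(x$stderr_R, 3), "), ",
      x$n_bins_used, " bins\n", sep = "")
  invisible(x)
}
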