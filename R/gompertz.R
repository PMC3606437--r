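#' Node points for the synonymous-proportion curve
#'
#' Extracts, for every internal node with `rho_total > 0`, the synonymous
#' rho proportion `s = rho_syn / rho_total` together with the mutation-count
#' weights used by the agglomeration: the subtree totals of synonymous and
#' protein-coding tip-path counts (`rho * n_tips`).
#'
#' @param rho rho table from [rho_table()].
#' @return data frame with columns `node_id`, `label`, `rho_total`, `s`,
#'   `syn_count`, `total_count`, sorted by decreasing `rho_total`.
#' @export
node_points <- function(rho) {
  keep <- rho$n_tips > 1L & rho$rho_total > 0
  pts <- data.frame(node_id = rho$node_id[keep], label = rho$label[keep],
                    rho_total = rho$rho_total[keep],
                    s = rho$rho_syn[keep] / rho$rho_total[keep],
                    syn_count = rho$rho_syn[keep] * rho$n_tips[keep],
                    total_count = rho$rho_total[keep] * rho$n_tips[keep],
                    stringsAsFactors = FALSE)
  pts[order(-pts$rho_total), ]
}

#' Agglomerate node points under a variance threshold
#'
#' Because rho values at nested nodes are correlated and the variance of the
#' synonymous proportion shrinks with the amount of variation beneath a
#' node, raw node points are noisy and non-independent. Scanning the points
#' in order of decreasing overall rho, synonymous and total mutation counts
#' are pooled until the binomial variance estimate of the pooled proportion,
#' `s(1-s)/N_total`, drops to `nu` or below; the group is then emitted as a
#' single averaged point (count-weighted mean rho, pooled proportion) and a
#' fresh accumulation starts. The trailing incomplete group is emitted with
#' `complete = FALSE`. Counts are conserved exactly.
#'
#' @param points data frame from [node_points()].
#' @param nu positive variance threshold (default 2.5e-3).
#' @return data frame with columns `rho_total`, `s`, `syn_count`,
#'   `total_count`, `nodes_merged`, `complete`.
#' @export
agglomerate_nodes <- function(points, nu = 2.5e-3) {
  if (!is.numeric(nu) || nu <= 0) stop("nu must be > 0")
  points <- points[order(-points$rho_total), ]
  groups <- list()
  syn <- tot <- wrho <- 0
  n_merged <- 0L
  for (i in seq_len(nrow(points))) {
    syn <- syn + points$syn_count[i]
    tot <- tot + points$total_count[i]
    wrho <- wrho + points$rho_total[i] * points$total_count[i]
    n_merged <- n_merged + 1L
    s_bar <- syn / tot
    if (tot > 0 && s_bar * (1 - s_bar) / tot <= nu) {
      groups[[length(groups) + 1L]] <- data.frame(
        rho_total = wrho / tot, s = s_bar, syn_count = syn,
        total_count = tot, nodes_merged = n_merged, complete = TRUE)
      syn <- tot <- wrho <- 0
      n_merged <- 0L
    }
  }
  if (n_merged > 0L)
    groups[[length(groups) + 1L]] <- data.frame(
      rho_total = wrho / tot, s = syn / tot, syn_count = syn,
      total_count = tot, nodes_merged = n_merged, complete = FALSE)
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out
}

#' Fit the Gompertz curve of synonymous proportion versus rho
#'
#' Models the expected synonymous rho proportion as
#' \deqn{s(\rho) = a\,e^{-b\,e^{-c\rho}}}
#' by nonlinear least squares. The asymptote `a` is the equilibrium
#' synonymous fraction once purifying selection has removed the transient
#' excess of nonsynonymous variants; the y-intercept `a*exp(-b)` is the
#' pre-selection synonymous fraction among fresh mutations; `c` sets how
#' fast (in rho units) the equilibrium is approached.
#'
#' Least squares is weighted by the pooled mutation count of each point
#' when a `total_count` column is present (groups emitted exactly at the
#' variance threshold carry similar information, but deep-node groups stop
#' far below it and are correspondingly more precise).
#'
#' @param agg agglomerated points from [agglomerate_nodes()] (or any data
#'   frame with `rho_total` and `s`; optional `total_count` weights).
#' @return An object of class `gompertz_fit`: list with `a`, `b`, `c`,
#'   `y_intercept`, standard errors, `residual_ss`, `n_points`,
#'   `low_confidence` (fewer than 10 points), `degenerate` (flat input
#'   data fitted as a constant).
#' @export
fit_gompertz <- function(agg) {
  rho <- agg$rho_total
  s <- agg$s
  if (length(rho) < 4L) stop("need at least 4 agglomerated points")
  if (diff(range(rho)) <= 0) stop("degenerate rho range")
  if (sd(s) < 1e-10) {
    # flat data: asymptote at the common value, no time dependence
    fit <- list(a = mean(s), b = 0, c = NA_real_,
                y_intercept = mean(s), stderr_a = 0, stderr_b = NA_real_,
                stderr_c = NA_real_, residual_ss = sum((s - mean(s))^2),
                n_points = length(rho), low_confidence = length(rho) < 10L,
                degenerate = TRUE)
    class(fit) <- "gompertz_fit"
    return(fit)
  }
  a0 <- min(1, max(s) * 1.02)
  s_young <- s[which.min(rho)]
  b0 <- max(-log(max(min(s_young / a0, 0.999), 1e-6)), 1e-3)
  c0 <- 1 / max(median(rho), 1e-6)
  w <- if (!is.null(agg$total_count)) agg$total_count else rep(1, length(s))
  dat <- data.frame(rho = rho, s = s, w = w)
  starts <- c(list(list(a = a0, b = b0, c = c0)),
              lapply(c(0.05, 0.3, 1), function(cc)
                list(a = a0, b = 0.5, c = cc)))
  fit <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        s ~ a * exp(-b * exp(-c * rho)), data = dat, weights = w,
        start = st,
        lower = c(a = 1e-6, b = 0, c = 1e-9),
        upper = c(a = 1, b = Inf, c = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    # no identifiable time dependence: weighted-mean flat curve, flagged
    a_bar <- sum(w * s) / sum(w)
    out <- list(a = a_bar, b = 0, c = NA_real_, y_intercept = a_bar,
                stderr_a = NA_real_, stderr_b = NA_real_,
                stderr_c = NA_real_,
                residual_ss = sum(w * (s - a_bar)^2) / mean(w),
                n_points = length(rho),
                low_confidence = TRUE, degenerate = TRUE)
    class(out) <- "gompertz_fit"
    return(out)
  }
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  out <- list(a = unname(est["a"]), b = unname(est["b"]),
              c = unname(est["c"]),
              y_intercept = unname(est["a"] * exp(-est["b"])),
              stderr_a = unname(se["a"]), stderr_b = unname(se["b"]),
              stderr_c = unname(se["c"]),
              residual_ss = sum(residuals(fit)^2),
              n_points = length(rho),
              low_confidence = length(rho) < 10L,
              degenerate = FALSE)
  class(out) <- "gompertz_fit"
  out
}

#' Predicted synonymous proportion at a given rho
#'
#' @param fit a `gompertz_fit`.
#' @param rho numeric vector of overall rho values.
#' @return numeric vector of predicted synonymous proportions.
#' @export
predict_syn_proportion <- function(fit, rho) {
  if (isTRUE(fit$degenerate)) return(rep(fit$a, length(rho)))
  fit$a * exp(-fit$b * exp(-fit$c * rho))
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("gompertz_fit: s(rho) = ", signif(x$a, 4), " * exp(-",
      signif(x$b, 4), " * exp(-", signif(x$c, 4), " * rho))\n",
      "  asymptote a = ", signif(x$a, 4), ", y-intercept = ",
      signif(x$y_intercept, 4), ", points = ", x$n_points,
      if (x$low_confidence) "  [low confidence: < 10 points]" else "",
      if (isTRUE(x$degenerate)) "  [degenerate: flat data]" else "",
      "\n", sep = "")
  invisible(x)
}
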