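#' Box-and-whisker summary of an intensity distribution
#'
#' Five-number summary matching the strain-comparison box plots: box
#' boundaries at the 25th and 75th percentiles, horizontal line at the
#' median, whiskers at the 10th and 90th percentiles. Percentiles use linear
#' interpolation between order statistics (`stats::quantile` type 7 by
#' default; the `type` argument exposes the other definitions).
#'
#' @param values numeric vector, n >= 1, finite.
#' @param type percentile interpolation type passed to [stats::quantile()].
#' @return A `box_summary` list: `median`, `p25`, `p75`, `p10`, `p90`, `n`.
#' @export
box_summary <- function(values, type = 7) {
  if (length(values) < 1) stop("box_summary needs at least one value")
  if (!all(is.finite(values))) stop("values must be finite")
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = type, names = FALSE)
  structure(list(median = q[3], p25 = q[2], p75 = q[4],
                 p10 = q[1], p90 = q[5], n = length(values)),
            class = "box_summary")
}

# Kruskal-Wallis H computed directly from the rank formula with midranks
# and tie correction; used for the permutation null.
kw_h <- function(values, grp) {
  rk <- rank(values)                 # midranks
  n <- length(values)
  rbar <- tapply(rk, grp, mean)
  ni <- tabulate(grp)
  h <- 12 / (n * (n + 1)) * sum(ni * (rbar - (n + 1) / 2)^2)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) h / corr else 0
}

#' Rank-based one-way ANOVA (Kruskal-Wallis)
#'
#' Omnibus comparison of two or more intensity distributions by ANOVA on
#' ranks: the Kruskal-Wallis H statistic with midrank tie handling and tie
#' correction, and a p value from the chi-square approximation with
#' `groups - 1` degrees of freedom (via [stats::kruskal.test()]). For small
#' samples an exact-style permutation p value (seeded label permutation) can
#' be requested. When all observations are identical the convention
#' `H = 0, p = 1` is returned rather than an error.
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   n >= 1, total n >= 3).
#' @param n_perm number of label permutations for the optional permutation p
#'   value; 0 (default) for the chi-square approximation only.
#' @param seed RNG seed for the permutation p value.
#' @return A list with `H`, `df`, `p_value`, `p_permutation` (NA unless
#'   requested), `n`.
#' @export
rank_anova <- function(groups, n_perm = 0L, seed = 1L) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 1))
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 3) stop("need a total of at least 3 observations")
  grp <- rep(seq_along(groups), lengths(groups))
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p_value = 1,
                p_permutation = NA_real_, n = length(values)))
  kt <- stats::kruskal.test(values, factor(grp))
  p_perm <- NA_real_
  if (n_perm > 0) {
    h_obs <- kw_h(values, grp)
    exceed <- withr::with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i)
        kw_h(values, sample(grp)) >= h_obs - 1e-12, logical(1)))
    })
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value, p_permutation = p_perm, n = length(values))
}

#' Dunn's post-hoc pairwise rank comparisons
#'
#' Pairwise z tests on mean ranks with the tie-corrected pooled variance,
#' following a significant Kruskal-Wallis omnibus test; p values are
#' two-sided and adjusted by Holm's method by default.
#'
#' @param groups named list of numeric vectors.
#' @param p_adjust_method method for [stats::p.adjust()].
#' @return Data frame with columns `group1`, `group2`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_test <- function(groups, p_adjust_method = "holm") {
  stopifnot(length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  grp <- rep(seq_along(groups), lengths(groups))
  n <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, grp, mean)
  ni <- tabulate(grp)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / ni[i] + 1 / ni[j]))
    z[k] <- (rbar[i] - rbar[j]) / se
  }
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = names(groups)[pairs[1, ]],
             group2 = names(groups)[pairs[2, ]],
             z = z, p_value = p,
             p_adjusted = stats::p.adjust(p, method = p_adjust_method),
             stringsAsFactors = FALSE)
}

#' Compare focus-intensity distributions across strains
#'
#' Per-strain box summaries, the omnibus rank ANOVA, and Dunn-Holm pairwise
#' post-hoc comparisons, with significance flagged at `alpha`.
#'
#' @param distributions named list of numeric vectors (>= 2 strains), e.g.
#'   corrected focus mean intensities per strain.
#' @param alpha significance level.
#' @param value_type label recorded in the report saying which intensity
#'   column was compared (e.g. `"corrected"` or `"raw"`).
#' @return A `strain_comparison` list: `summaries` (data frame), `omnibus`,
#'   `pairwise`, `alpha`, `significant`, `value_type`.
#' @export
compare_strains <- function(distributions, alpha = 0.05,
                            value_type = "corrected") {
  stopifnot(length(distributions) >= 2)
  if (is.null(names(distributions)))
    names(distributions) <- paste0("strain", seq_along(distributions))
  summaries <- do.call(rbind, lapply(names(distributions), function(s) {
    b <- box_summary(distributions[[s]])
    data.frame(strain_label = s, n = b$n, median = b$median,
               p25 = b$p25, p75 = b$p75, p10 = b$p10, p90 = b$p90,
               stringsAsFactors = FALSE)
  }))
  omnibus <- rank_anova(distributions)
  pairwise <- dunn_test(distributions)
  pairwise$significant <- pairwise$p_adjusted < alpha
  structure(list(summaries = summaries, omnibus = omnibus,
                 pairwise = pairwise, alpha = alpha,
                 significant = omnibus$p_value < alpha,
                 value_type = value_type),
            class = "strain_comparison")
}

#' @export
print.strain_comparison <- function(x, ...) {
  cat("Strain comparison (", x$value_type, " intensities)\n", sep = "")
  print(x$summaries, row.names = FALSE)
  cat(sprintf("ANOVA on ranks: H = %.4g, df = %d, p = %.3g (%s at alpha = %g)\n",
              x$omnibus$H, x$omnibus$df, x$omnibus$p_value,
              if (x$significant) "significant" else "not significant",
              x$alpha))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' Box plot of per-strain intensity distributions
#'
#' Draws the comparison as box plots with boxes at the 25th/75th
#' percentiles, median line, and whiskers at the 10th/90th percentiles.
#'
#' @param distributions named list of numeric vectors.
#' @param path optional PNG path; when given the plot is written there.
#' @param ylab y-axis label.
#' @return Invisibly, the matrix of box statistics.
#' @export
plot_intensity_boxes <- function(distributions, path = NULL,
                                 ylab = "focus intensity (au)") {
  stats_mat <- vapply(distributions, function(v)
    stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                    names = FALSE), numeric(5))
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 480)
    on.exit(grDevices::dev.off())
  }
  bx <- list(stats = stats_mat, n = lengths(distributions),
             conf = NULL, out = numeric(0),
             names = names(distributions))
  graphics::bxp(bx, ylab = ylab, boxfill = "grey85", whisklty = 1)
  invisible(stats_mat)
}
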