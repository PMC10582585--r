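# Binned group-mean correlations and group comparisons ----------------------
#
# Species are grouped either by fixed thresholds on a parameter (first bin
# closed at its upper edge, interior bins left-open/right-closed, last bin
# open above) or by ranking and chunking into equal-size groups. Group
# means of a repeat metric and a phenotype are then correlated (Pearson),
# and ratio bands are compared by one-way ANOVA with a Student-Newman-Keuls
# stepdown on ordered group means.

#' Define a binning scheme
#'
#' @param name Scheme name (used in reports).
#' @param mode `"threshold"` (fixed edges) or `"rank"` (equal-size groups
#'   of ranked values).
#' @param edges Strictly increasing numeric edges (threshold mode). A
#'   scheme with `k` edges has `k + 1` bins: bin 1 is `<= edges[1]`,
#'   interior bins are left-open/right-closed, the last bin is
#'   `> edges[k]`.
#' @param group_size Species per group (rank mode, `>= 2`).
#' @return An object of class `bin_scheme`.
#' @examples
#' bin_scheme("char_freq", edges = seq(30, 90, by = 10))
#' @export
bin_scheme <- function(name, mode = c("threshold", "rank"), edges = NULL,
                       group_size = NULL) {
  mode <- match.arg(mode)
  if (mode == "threshold") {
    stopifnot(is.numeric(edges), length(edges) >= 1L,
              all(diff(edges) > 0))
    group_size <- NULL
  } else {
    stopifnot(is.numeric(group_size), length(group_size) == 1L,
              group_size >= 2L)
    edges <- NULL
  }
  structure(list(name = name, mode = mode, edges = edges,
                 group_size = group_size),
            class = "bin_scheme")
}

#' Built-in binning schemes
#'
#' The published schemes: characteristic frequency (<=30, 30-90 kHz by 10,
#' >90), minimum frequency (<=20, 20-80 by 10, >80), bandwidth (<=5, 5-40
#' by 5, >40), Q1/Q2 ten-bin (<=1, 1-5 by 0.5, >5), Q1/Q2 six-bin (<=3,
#' 3-5 by 0.5, >5), and CW/BW ranking in groups of 5 species.
#'
#' @return Named list of [bin_scheme()]s.
#' @export
builtin_bin_schemes <- function() {
  list(
    char_freq = bin_scheme("char_freq", edges = seq(30, 90, by = 10)),
    min_freq = bin_scheme("min_freq", edges = seq(20, 80, by = 10)),
    bandwidth = bin_scheme("bandwidth", edges = seq(5, 40, by = 5)),
    ratio_q1q2_10 = bin_scheme("ratio_q1q2_10", edges = seq(1, 5, by = 0.5)),
    ratio_q1q2_6 = bin_scheme("ratio_q1q2_6", edges = seq(3, 5, by = 0.5)),
    cwbw_rank5 = bin_scheme("cwbw_rank5", mode = "rank", group_size = 5L)
  )
}

#' Assign values to bins
#'
#' Threshold mode gives every non-missing value exactly one integer label
#' in `1..(length(edges) + 1)`. Rank mode sorts non-missing values
#' ascending (stable on ties by input order) and chunks them into
#' consecutive groups of `group_size`; the non-missing count must be
#' divisible by `group_size`. Missing values receive `NA`.
#'
#' @param values Numeric vector (`NA` allowed).
#' @param scheme A [bin_scheme()].
#' @return Integer vector of bin labels, `NA` where `values` is `NA`.
#' @examples
#' assign_bins(c(25, 95, 30), builtin_bin_schemes()$char_freq)
#' @export
assign_bins <- function(values, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  if (scheme$mode == "threshold") {
    out[ok] <- findInterval(values[ok], scheme$edges, left.open = TRUE) + 1L
  } else {
    n <- sum(ok)
    if (n %% scheme$group_size != 0L) {
      stop(sprintf(
        "rank binning: %d non-missing values not divisible by group size %d",
        n, scheme$group_size), call. = FALSE)
    }
    ord <- order(values[ok])  # radix sort: stable on ties by input order
    bins <- integer(n)
    bins[ord] <- ceiling(seq_len(n) / scheme$group_size)
    out[ok] <- bins
  }
  out
}

#' Correlate group means of two variables
#'
#' Applies the per-value transforms, averages `x` and `y` within each bin,
#' and computes the Pearson correlation over the group means with a
#' two-sided p-value from the t distribution with `n_groups - 2` degrees
#' of freedom. Pairs with any missing member are dropped; empty bins are
#' dropped before correlation.
#'
#' @param x,y Numeric vectors (`NA` allowed).
#' @param labels Bin labels per value (e.g. from [assign_bins()]).
#' @param transform_x,transform_y `"identity"` or `"log10"` (log10
#'   requires positive values).
#' @return An object of class `correlation_result`: `r`, `n_groups`,
#'   `p_value`, the transforms, and a `summaries` data frame (one row per
#'   group: `bin_label`, `n`, `mean_x`, `mean_y`).
#' @examples
#' correlate_group_means(1:6, 6:1, labels = rep(1:3, each = 2))
#' @export
correlate_group_means <- function(x, y, labels,
                                  transform_x = c("identity", "log10"),
                                  transform_y = c("identity", "log10")) {
  transform_x <- match.arg(transform_x)
  transform_y <- match.arg(transform_y)
  stopifnot(length(x) == length(y), length(x) == length(labels))
  keep <- !is.na(x) & !is.na(y) & !is.na(labels)
  x <- x[keep]; y <- y[keep]; labels <- labels[keep]
  x <- apply_transform(x, transform_x, "x")
  y <- apply_transform(y, transform_y, "y")
  mx <- tapply(x, labels, mean)
  my <- tapply(y, labels, mean)
  ns <- tapply(x, labels, length)
  if (length(mx) < 2L) {
    stop("correlation requires at least 2 non-empty groups", call. = FALSE)
  }
  if (stats::sd(mx) == 0 || stats::sd(my) == 0) {
    stop("degenerate_means: zero variance in group means", call. = FALSE)
  }
  r <- stats::cor(as.numeric(mx), as.numeric(my))
  df <- length(mx) - 2L
  p <- if (df >= 1L) {
    if (abs(r) >= 1) 0 else {
      tt <- r * sqrt(df / (1 - r^2))
      2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    }
  } else NA_real_  # two groups: r is +/-1 by construction, p undefined
  structure(
    list(r = r, n_groups = length(mx),
         p_value = p,
         transform_x = transform_x, transform_y = transform_y,
         summaries = data.frame(bin_label = names(mx),
                                n = as.integer(ns),
                                mean_x = as.numeric(mx),
                                mean_y = as.numeric(my),
                                stringsAsFactors = FALSE)),
    class = "correlation_result"
  )
}

apply_transform <- function(v, transform, axis) {
  if (transform == "log10") {
    if (any(v <= 0)) {
      stop(sprintf("log10 transform on %s requires positive values", axis),
           call. = FALSE)
    }
    log10(v)
  } else v
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.4f over %d groups (p = %.4g)\n",
              x$r, x$n_groups, x$p_value))
  invisible(x)
}

#' One-way ANOVA with Student-Newman-Keuls post hoc comparisons
#'
#' Fixed-effects one-way ANOVA on `values` grouped by `labels`. When the
#' omnibus test is significant at `alpha`, an SNK stepdown is run on the
#' ordered group means: stretches of `p` ordered means are tested with the
#' studentized range distribution ([stats::ptukey()]) at the within-group
#' degrees of freedom, from the full range downwards; stretches inside a
#' non-significant stretch are declared non-significant without testing.
#' Unbalanced groups use the harmonic mean of the two group sizes.
#'
#' @param values Numeric vector (`NA` dropped).
#' @param labels Group labels.
#' @param alpha Significance level for the omnibus gate and the SNK steps.
#' @return An object of class `group_comparison`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `means`, and `posthoc` (a data frame of
#'   pairwise results, or `NULL` when the omnibus test is not
#'   significant).
#' @examples
#' compare_groups(c(rnorm(5), rnorm(5, 4)), rep(c("a", "b"), each = 5))
#' @export
compare_groups <- function(values, labels, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels[keep])
  ns <- tapply(values, labels, length)
  if (length(ns) < 2L || any(ns < 2L)) {
    stop("ANOVA requires at least 2 groups with at least 2 values each",
         call. = FALSE)
  }
  means <- tapply(values, labels, mean)
  grand <- mean(values)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[labels])^2)
  if (ssw == 0 && ssb == 0) {
    stop("degenerate_groups: all values identical", call. = FALSE)
  }
  k <- length(ns)
  df_b <- k - 1L
  df_w <- length(values) - k
  mse <- ssw / df_w
  f_stat <- (ssb / df_b) / mse
  p_value <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  posthoc <- NULL
  if (!is.na(p_value) && p_value <= alpha) {
    posthoc <- snk_stepdown(means, ns, mse, df_w, alpha)
  }
  structure(
    list(f_stat = f_stat, df_between = df_b, df_within = as.integer(df_w),
         p_value = p_value, alpha = alpha,
         means = data.frame(group = names(means), n = as.integer(ns),
                            mean = as.numeric(means),
                            stringsAsFactors = FALSE),
         posthoc = posthoc),
    class = "group_comparison"
  )
}

# SNK stepdown on ordered means. Tests stretches from the widest span
# downwards; a stretch contained in an already-non-significant stretch is
# blocked (declared non-significant untested).
snk_stepdown <- function(means, ns, mse, df_w, alpha) {
  ord <- order(means)
  m <- as.numeric(means)[ord]
  n <- as.numeric(ns)[ord]
  gs <- names(means)[ord]
  k <- length(m)
  sig <- matrix(NA, k, k)
  blocked <- matrix(FALSE, k, k)
  rows <- list()
  for (span in k:2) {
    for (i in seq_len(k - span + 1L)) {
      j <- i + span - 1L
      if (blocked[i, j]) {
        sig[i, j] <- FALSE
        q <- NA_real_; p <- NA_real_
      } else {
        nh <- 2 / (1 / n[i] + 1 / n[j])
        q <- (m[j] - m[i]) / sqrt(mse / nh)
        p <- stats::ptukey(q, nmeans = span, df = df_w, lower.tail = FALSE)
        sig[i, j] <- p <= alpha
        if (!sig[i, j]) {
          # block every stretch nested inside this one
          for (ii in i:j) for (jj in ii:j) {
            if (!(ii == i && jj == j)) blocked[ii, jj] <- TRUE
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        group1 = gs[i], group2 = gs[j], diff = m[j] - m[i],
        span = span, q = q, p = p, significant = sig[i, j],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> F(%d,%d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc[x$posthoc$significant %in% TRUE, c("group1", "group2")]
    if (nrow(sig) > 0L) {
      cat("SNK significant pairs:",
          paste(sprintf("%s-%s", sig$group1, sig$group2), collapse = ", "),
          "\n")
    } else cat("SNK: no significant pairs\n")
  }
  invisible(x)
}

#' Pick one value per species across overlapping datasets
#'
#' When several datasets report the same phenotype for a species, maxima
#' (maximum vocalization frequency, body mass) keep the maximum and
#' minima (minimum/fundamental frequency) keep the minimum.
#'
#' @param values Numeric vector of reported values (`NA` allowed).
#' @param species Species label per value.
#' @param type `"max"` or `"min"`.
#' @return Named numeric vector, one value per species.
#' @export
consolidate_phenotype <- function(values, species, type = c("max", "min")) {
  type <- match.arg(type)
  keep <- !is.na(values)
  fun <- if (type == "max") max else min
  out <- tapply(values[keep], species[keep], fun)
  stats::setNames(as.numeric(out), dimnames(out)[[1L]])
}
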