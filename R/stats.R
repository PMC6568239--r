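#' Quartile categorization of a contraction parameter
#'
#' Contraction parameters (amplitude, distance, duration, velocity) are
#' roughly exponentially distributed, so comparisons of means are dominated
#' by the mass of small values. Values are instead binned into three
#' categories by the sample quartiles: low/short (value <= Q1), medium
#' (Q1 < value < Q3) and high/long (value >= Q3). Quartiles use linear
#' interpolation between order statistics (plotting position
#' `(k - 1) / (n - 1)`, R's type-7 default), recorded in the output because
#' category membership near a cutoff depends on the convention.
#'
#' @param values Numeric vector with at least 4 finite values.
#' @param labels Category labels, low to high.
#' @return A `category_breakdown`: list with per-value `category`,
#'   `breakdown` tibble (`category`, `n`, `proportion`), `q1`, `q3`, and a
#'   `degenerate` flag (all values equal: every value is both <= Q1 and
#'   >= Q3).
#' @export
quartile_categories <- function(values, labels = c("low", "medium", "high")) {
  v <- values[is.finite(values)]
  if (length(v) < 4) abort("Need at least 4 finite values for quartile categories.")
  q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  degenerate <- q[1] == q[2]
  category <- factor(
    ifelse(values <= q[1], labels[1],
           ifelse(values >= q[2], labels[3], labels[2])),
    levels = labels
  )
  category[!is.finite(values)] <- NA
  breakdown <- tibble(category = factor(labels, levels = labels)) |>
    left_join(count(tibble(category = category[!is.na(category)]), .data$category),
              by = "category") |>
    mutate(n = tidyr::replace_na(.data$n, 0L),
           proportion = .data$n / sum(.data$n))
  if (degenerate) {
    warn("All values equal: quartile categories are degenerate (low == high).")
  }
  structure(
    list(category = category, breakdown = breakdown,
         q1 = q[1], q3 = q[2], degenerate = degenerate,
         quartile_type = "type7 (linear interpolation of order statistics)"),
    class = "category_breakdown"
  )
}

#' @export
print.category_breakdown <- function(x, ...) {
  cat(sprintf("<category_breakdown> Q1 = %g, Q3 = %g%s\n", x$q1, x$q3,
              if (x$degenerate) " [degenerate]" else ""))
  print(x$breakdown)
  invisible(x)
}

#' @rdname quartile_categories
#' @param x A `category_breakdown`.
#' @param ... Unused.
#' @method tidy category_breakdown
#' @export
tidy.category_breakdown <- function(x, ...) x$breakdown

#' Log2 after/before ratios of paired metrics
#'
#' The treatment contrast works on `log2(after / before)` per replicate,
#' which symmetrizes the wide between-individual ratio spread. Pairs with a
#' zero or missing value on either side have no defined ratio and are
#' excluded (not zero-filled); the number of exclusions is reported.
#'
#' @param before,after Nonnegative paired metric values (e.g. cpm per
#'   replicate before and after treatment).
#' @return A tibble with `before`, `after`, `log2_ratio` (`NA` where
#'   excluded); the exclusion count is in the `n_excluded` attribute.
#' @export
pre_post_log2 <- function(before, after) {
  if (length(before) != length(after)) abort("`before` and `after` must be paired.")
  if (any(before < 0 | after < 0, na.rm = TRUE)) {
    abort("Metrics must be nonnegative.")
  }
  defined <- !is.na(before) & !is.na(after) & before > 0 & after > 0
  out <- tibble(
    before = before, after = after,
    log2_ratio = ifelse(defined, log2(after / before), NA_real_)
  )
  attr(out, "n_excluded") <- sum(!defined)
  out
}

#' One-sample t-test of log2 ratios against zero
#'
#' Tests whether the mean log2(after/before) ratio differs from `mu` (0 = no
#' treatment effect). Because of the large variation between individual
#' intestines a 90% confidence interval is used, with the two significance
#' tiers of the original figures: `"*"` for 0.05 <= p < 0.1 and `"**"` for
#' p < 0.05.
#'
#' @param ratios Numeric vector of log2 ratios (`NA`s dropped).
#' @param mu Null mean (default 0).
#' @param conf_level Confidence level (default 0.90).
#' @return A `prepost_t` object with `estimate`, `sd`, `n`, `statistic`
#'   (t), `df`, `p_value`, `conf_low`/`conf_high` and `tier`; zero-variance
#'   input is flagged (`degenerate = TRUE`, no fabricated p).
#' @export
one_sample_t <- function(ratios, mu = 0, conf_level = 0.90) {
  x <- ratios[!is.na(ratios)]
  n <- length(x)
  if (n < 2) abort("Need at least 2 finite ratios.")
  m <- mean(x)
  s <- sd(x)
  if (s == 0) {
    out <- list(estimate = m, sd = 0, n = n, statistic = NA_real_, df = n - 1,
                p_value = NA_real_, conf_low = m, conf_high = m,
                conf_level = conf_level, mu = mu, tier = NA_character_,
                degenerate = TRUE)
    return(structure(out, class = "prepost_t"))
  }
  se <- s / sqrt(n)
  t_stat <- (m - mu) / se
  df <- n - 1
  p <- 2 * pt(-abs(t_stat), df)
  half <- qt(1 - (1 - conf_level) / 2, df) * se
  tier <- if (p < 0.05) "**" else if (p < 0.1) "*" else ""
  structure(
    list(estimate = m, sd = s, n = n, statistic = t_stat, df = df, p_value = p,
         conf_low = m - half, conf_high = m + half, conf_level = conf_level,
         mu = mu, tier = tier, degenerate = FALSE),
    class = "prepost_t"
  )
}

#' @export
print.prepost_t <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<prepost_t> zero-variance input (mean %g, n %d): undefined test\n",
                x$estimate, x$n))
  } else {
    cat(sprintf(
      "<prepost_t> mean %0.4g, t(%d) = %0.4g, p = %0.4g %s [%g%% CI %0.4g, %0.4g]\n",
      x$estimate, x$df, x$statistic, x$p_value, x$tier,
      100 * x$conf_level, x$conf_low, x$conf_high
    ))
  }
  invisible(x)
}

#' @rdname one_sample_t
#' @param x A `prepost_t`.
#' @param ... Unused.
#' @method tidy prepost_t
#' @export
tidy.prepost_t <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p_value = x$p_value, conf_low = x$conf_low, conf_high = x$conf_high,
    tier = x$tier
  )
}

#' @rdname one_sample_t
#' @method glance prepost_t
#' @export
glance.prepost_t <- function(x, ...) {
  tibble(n = x$n, sd = x$sd, conf_level = x$conf_level,
         degenerate = x$degenerate)
}

#' Compare a parameter across contraction types (Kruskal-Wallis + Dunn)
#'
#' Nonparametric comparison of a contraction parameter between the three
#' contraction types: Kruskal-Wallis rank test (with tie correction) followed
#' by Dunn's pairwise post-hoc z tests. P-value adjustment defaults to Holm;
#' configurable to `"none"` or `"bonferroni"`. Groups with fewer than two
#' values are excluded with a warning.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) of the parameter and the
#'   grouping factor.
#' @param p_adjust `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return A `type_comparison`: list with `kruskal` (statistic, df,
#'   p_value), `dunn` (pairwise tibble), `medians` tibble.
#' @export
compare_types <- function(data, value, group, p_adjust = c("holm", "bonferroni", "none")) {
  p_adjust <- match.arg(p_adjust)
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]
  g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("Excluding group(s) with < 2 values: %s", paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  if (length(unique(g)) < 2) abort("Need at least 2 groups with >= 2 values.")
  kw <- kruskal.test(v, factor(g))
  med <- tibble(v = v, g = g) |>
    group_by(.data$g) |>
    summarise(n = n(), median = median(.data$v), .groups = "drop") |>
    dplyr::rename(group = "g")
  dunn <- dunn_test(v, g, p_adjust)
  structure(
    list(
      kruskal = tibble(statistic = unname(kw$statistic), df = unname(kw$parameter),
                       p_value = kw$p.value),
      dunn = dunn, medians = med, p_adjust = p_adjust
    ),
    class = "type_comparison"
  )
}

# Dunn's pairwise z tests on joint ranks with tie correction
dunn_test <- function(v, g, p_adjust = "holm") {
  r <- rank(v)
  N <- length(v)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  groups <- sort(unique(g))
  mean_rank <- unname(vapply(groups, function(gr) mean(r[g == gr]), numeric(1)))
  n_g <- unname(vapply(groups, function(gr) sum(g == gr), numeric(1)))
  pairs <- utils::combn(seq_along(groups), 2)
  res <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n_g[i] + 1 / n_g[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    tibble(group1 = groups[i], group2 = groups[j], z = z,
           p_value = 2 * pnorm(-abs(z)))
  }) |> bind_rows()
  res$p_adj <- p.adjust(res$p_value, method = p_adjust)
  res
}

#' @export
print.type_comparison <- function(x, ...) {
  cat(sprintf("<type_comparison> Kruskal-Wallis chi2 = %0.4g (df %d), p = %0.4g\n",
              x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  print(x$dunn)
  invisible(x)
}

#' @rdname compare_types
#' @param x A `type_comparison`.
#' @param ... Unused.
#' @method tidy type_comparison
#' @export
tidy.type_comparison <- function(x, ...) x$dunn

#' @rdname compare_types
#' @method glance type_comparison
#' @export
glance.type_comparison <- function(x, ...) x$kruskal

#' Compare frequencies across segments (one-way ANOVA + Tukey)
#'
#' One-way ANOVA across segments followed by Tukey's HSD; segments sharing no
#' significant pairwise difference share a compact-display letter, as in
#' per-segment frequency plots.
#'
#' @inheritParams compare_types
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `segment_comparison`: list with `anova` (`statistic` F,
#'   `df_between`, `df_within`, `p_value`), `tukey` pairwise tibble and
#'   `letters` tibble.
#' @export
compare_segments <- function(data, value, group, alpha = 0.05) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  ok <- !is.na(v) & !is.na(g)
  v <- v[ok]
  g <- g[ok]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("Excluding group(s) with < 2 values: %s", paste(small, collapse = ", ")))
    keep <- !g %in% small
    v <- v[keep]
    g <- g[keep]
  }
  if (length(unique(g)) < 2) abort("Need at least 2 groups with >= 2 values.")
  gf <- factor(g)
  fit <- aov(v ~ gf)
  sm <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$gf
  comps <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey <- tibble(
    group1 = vapply(comps, `[`, "", 1),
    group2 = vapply(comps, `[`, "", 2),
    diff = unname(tk[, "diff"]), conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]), p_adj = unname(tk[, "p adj"])
  )
  letters <- cld_letters(levels(gf), tukey, alpha)
  structure(
    list(
      anova = tibble(statistic = sm[["F value"]][1], df_between = sm[["Df"]][1],
                     df_within = sm[["Df"]][2], p_value = sm[["Pr(>F)"]][1]),
      tukey = tukey, letters = letters, alpha = alpha
    ),
    class = "segment_comparison"
  )
}

# compact letter display by insert-and-absorb over the significant pairs
cld_letters <- function(groups, tukey, alpha) {
  sets <- list(groups)
  sig <- tukey[!is.na(tukey$p_adj) & tukey$p_adj < alpha, , drop = FALSE]
  for (k in seq_len(nrow(sig))) {
    a <- sig$group1[k]
    b <- sig$group2[k]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (i in seq_along(new_sets)) {
      for (j in seq_along(new_sets)) {
        if (i != j && keep[j] && all(new_sets[[i]] %in% new_sets[[j]]) &&
            !(j < i && identical(new_sets[[i]], new_sets[[j]]))) {
          if (length(new_sets[[i]]) < length(new_sets[[j]]) ||
              (length(new_sets[[i]]) == length(new_sets[[j]]) && i > j)) {
            keep[i] <- FALSE
          }
        }
      }
    }
    sets <- new_sets[keep]
  }
  labels <- vapply(groups, function(gr) {
    paste0(letters[which(vapply(sets, function(s) gr %in% s, logical(1)))],
           collapse = "")
  }, character(1))
  tibble(group = groups, letters = unname(labels))
}

#' @export
print.segment_comparison <- function(x, ...) {
  cat(sprintf("<segment_comparison> F(%d, %d) = %0.4g, p = %0.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$statistic,
              x$anova$p_value))
  print(x$letters)
  invisible(x)
}

#' @rdname compare_segments
#' @param x A `segment_comparison`.
#' @param ... Unused.
#' @method tidy segment_comparison
#' @export
tidy.segment_comparison <- function(x, ...) x$tukey

#' @rdname compare_segments
#' @method glance segment_comparison
#' @export
glance.segment_comparison <- function(x, ...) x$anova

#' Length reduction and shortening-event frequency around a treatment
#'
#' Quantifies the longitudinal response to a treatment from a length trace:
#' percent length reduction is the drop from the mean pre-treatment length to
#' the minimum post-treatment length, as percent of the pre-treatment mean.
#' Discrete shortening events are local minima of the length trace with
#' prominence at least `prominence_frac` of the window's mean length, counted
#' per minute separately in the before and after windows.
#'
#' @param trace A length trace tibble (from [measure_length()] or
#'   [simulate_length_trace()]): columns `time_s`, `length_mm`.
#' @param event_time_s Treatment time (s).
#' @param before_s,after_s Window lengths in seconds (default 600 = 10 min).
#' @param prominence_frac Event prominence floor as a fraction of the mean
#'   window length (default 0.01).
#' @return A `length_reduction` object: `percent_reduction` and an `events`
#'   tibble (`window`, `n_events`, `minutes`, `per_min`).
#' @export
length_reduction <- function(trace, event_time_s, before_s = 600, after_s = 600,
                             prominence_frac = 0.01) {
  before <- filter(trace, .data$time_s >= event_time_s - before_s,
                   .data$time_s < event_time_s)
  after <- filter(trace, .data$time_s >= event_time_s,
                  .data$time_s <= event_time_s + after_s)
  if (!nrow(before) || !nrow(after) || all(is.na(before$length_mm)) ||
      all(is.na(after$length_mm))) {
    abort("Trace does not cover both the before and after windows.")
  }
  base <- mean(before$length_mm, na.rm = TRUE)
  post_min <- min(after$length_mm, na.rm = TRUE)
  pct <- 100 * (base - post_min) / base
  count_events <- function(win) {
    x <- win$length_mm[!is.na(win$length_mm)]
    if (length(x) < 3) return(0L)
    prom <- prominence_frac * mean(x)
    runs <- candidate_min_runs(x)
    sum(vapply(runs, function(r) min_depth(x, r[1], r[2]) >= prom, logical(1)))
  }
  events <- tibble(
    window = c("before", "after"),
    n_events = c(count_events(before), count_events(after)),
    minutes = c(before_s, after_s) / 60
  ) |>
    mutate(per_min = .data$n_events / .data$minutes)
  structure(
    list(percent_reduction = pct, events = events,
         prominence_frac = prominence_frac, event_time_s = event_time_s),
    class = "length_reduction"
  )
}

#' @export
print.length_reduction <- function(x, ...) {
  cat(sprintf("<length_reduction> %0.3g%% reduction after t = %g s\n",
              x$percent_reduction, x$event_time_s))
  print(x$events)
  invisible(x)
}

#' @rdname length_reduction
#' @param x A `length_reduction`.
#' @param ... Unused.
#' @method tidy length_reduction
#' @export
tidy.length_reduction <- function(x, ...) {
  mutate(x$events, percent_reduction = x$percent_reduction)
}
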