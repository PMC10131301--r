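#' Welch's unequal-variances t statistic
#'
#' Implemented from the formula:
#' \deqn{t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}}
#' with Welch-Satterthwaite degrees of freedom. The two-sided p-value uses
#' the t distribution at those df.
#'
#' @param a,b numeric samples, each with n >= 2 and nonzero variance.
#' @return List with `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each sample needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("both samples have zero variance")
  se2a <- va / na; se2b <- vb / nb
  t_stat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  list(statistic = t_stat, df = df,
       p_value = 2 * stats::pt(-abs(t_stat), df),
       mean_a = mean(a), mean_b = mean(b))
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D = sup over x of |ECDF_a(x) - ECDF_b(x)|, evaluated by enumeration at
#' the pooled sample points. The approximate two-sided p-value uses the
#' asymptotic Kolmogorov distribution.
#'
#' @param a,b numeric samples, each non-empty.
#' @return List with `statistic` (D, in [0, 1]) and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- sort(as.numeric(a)); b <- sort(as.numeric(b))
  na <- length(a); nb <- length(b)
  if (na < 1L || nb < 1L) stop("each sample needs at least 1 value")
  pooled <- sort(unique(c(a, b)))
  fa <- findInterval(pooled, a) / na
  fb <- findInterval(pooled, b) / nb
  d <- max(abs(fa - fb))
  ne <- na * nb / (na + nb)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  j <- 1:100
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  list(statistic = d, p_value = max(0, min(1, p)))
}

#' Compare distance distributions between corridors (or guilds)
#'
#' Per labelled group: sample size, mean and median distance to the
#' vegetation and to the lamppost. Between every pair of groups, Welch t
#' and Kolmogorov-Smirnov comparisons of each distance metric; within each
#' group, the same comparisons between the two metrics (distance to
#' lamppost vs distance to vegetation), mirroring how corridor case studies
#' are reported. No multiple-testing correction is applied. Groups with
#' fewer than 2 positions are summarised but excluded from tests with a
#' warning.
#'
#' @param distances data frame with columns `dist_vegetation`,
#'   `dist_lamppost` (metres) and optionally `label`; or the output of
#'   [run_end_to_end()]'s distance stage.
#' @param labels group label per row (used if `distances` lacks `label`).
#' @return A list of class `corridor_comparison` with `summary` (one row
#'   per group) and `tests` (one row per comparison: `kind`
#'   between-group/within-group, `metric`, `group_a`, `group_b`,
#'   `welch_t`, `welch_df`, `welch_p`, `ks_d`, `ks_p`).
#' @export
corridor_comparison <- function(distances, labels = NULL) {
  df <- as.data.frame(distances)
  if (!is.null(labels)) df$label <- labels
  if (is.null(df$label)) df$label <- "all"
  need <- c("dist_vegetation", "dist_lamppost")
  if (!all(need %in% names(df)))
    stop("distances need columns ", paste(need, collapse = ", "))
  groups <- split(df, df$label)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(label = g, n = nrow(x),
               mean_dist_vegetation = mean(x$dist_vegetation),
               median_dist_vegetation = stats::median(x$dist_vegetation),
               mean_dist_lamppost = mean(x$dist_lamppost),
               median_dist_lamppost = stats::median(x$dist_lamppost),
               stringsAsFactors = FALSE)
  }))
  testable <- names(groups)[vapply(groups, nrow, 1L) >= 2L]
  if (length(testable) < length(groups))
    warning("groups with fewer than 2 positions excluded from tests: ",
            paste(setdiff(names(groups), testable), collapse = ", "))
  tests <- list()
  add <- function(kind, metric, ga, gb, a, b) {
    wt <- welch_t(a, b); ks <- ks_two_sample(a, b)
    tests[[length(tests) + 1L]] <<- data.frame(
      kind = kind, metric = metric, group_a = ga, group_b = gb,
      welch_t = wt$statistic, welch_df = wt$df, welch_p = wt$p_value,
      ks_d = ks$statistic, ks_p = ks$p_value, stringsAsFactors = FALSE)
  }
  for (g in testable) {
    x <- groups[[g]]
    if (stats::var(x$dist_lamppost) > 0 || stats::var(x$dist_vegetation) > 0)
      add("within-group", "lamppost_vs_vegetation", g, g,
          x$dist_lamppost, x$dist_vegetation)
  }
  if (length(testable) >= 2L) {
    pairs <- utils::combn(testable, 2)
    for (k in seq_len(ncol(pairs))) {
      ga <- pairs[1, k]; gb <- pairs[2, k]
      for (metric in need)
        add("between-group", metric, ga, gb,
            groups[[ga]][[metric]], groups[[gb]][[metric]])
    }
  }
  structure(list(summary = summ,
                 tests = if (length(tests)) do.call(rbind, tests) else NULL),
            class = "corridor_comparison")
}

#' @export
print.corridor_comparison <- function(x, ...) {
  cat("Distance-to-structure comparison\n\nGroup summaries:\n")
  print(x$summary, digits = 3, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("\nTests (Welch t / Kolmogorov-Smirnov):\n")
    print(x$tests, digits = 3, row.names = FALSE)
  } else cat("\n(single group: summary only, no tests)\n")
  invisible(x)
}

#' Point-in-polygon test (XY plane)
#'
#' Ray-casting test used to assign positions to corridor polygons.
#'
#' @param x,y point coordinates (vectors).
#' @param poly_x,poly_y polygon vertex coordinates (closed implicitly).
#' @return Logical vector.
#' @export
point_in_polygon <- function(x, y, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((poly_y[i] > y) != (poly_y[j] > y)) &
      (x < (poly_x[j] - poly_x[i]) * (y - poly_y[i]) /
         (poly_y[j] - poly_y[i]) + poly_x[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
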