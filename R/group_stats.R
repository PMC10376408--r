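# Group-level statistics: mean +/- SEM summaries, distributional assumption
# checks, one-way ANOVA with Dunnett comparisons against control, unpaired
# t-tests, and the figure-caption significance-mark conventions.

#' Group summary: n, mean, SEM
#'
#' SEM uses the sample SD (n - 1 denominator) over sqrt(n); a single-value
#' group gets SEM 0 with a warning.
#'
#' @param values numeric vector, non-empty.
#' @param group_label label to attach.
#' @return An object of class `"group_summary"`: list `(group, n, mean, sem)`.
#' @export
summarize_group <- function(values, group_label = "group") {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) stop("values must be non-empty and free of NA")
  n <- length(values)
  sem <- if (n == 1L) {
    warning("single observation: SEM set to 0")
    0
  } else stats::sd(values) / sqrt(n)
  structure(list(group = group_label, n = n, mean = mean(values), sem = sem),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: %.4g +/- %.4g (n = %d)\n", x$group, x$mean, x$sem, x$n))
  invisible(x)
}

comparison_row <- function(test, groups, statistic, p, context = "vs_control") {
  data.frame(test = test, groups = groups, statistic = statistic,
             p_value = p,
             marks = if (is.na(p)) "" else significance_marks(p, context),
             stringsAsFactors = FALSE)
}

# Lilliefors-corrected Kolmogorov-Smirnov test for normality with estimated
# mean and SD (Dallal-Wilkinson / Stephens p-value approximation)
lilliefors_test <- function(x) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 4) stop("Lilliefors test needs n >= 4")
  p_i <- stats::pnorm(x, mean(x), stats::sd(x))
  D <- max(seq_len(n) / n - p_i, p_i - (seq_len(n) - 1) / n)
  if (n <= 100) { Kd <- D; nd <- n } else { Kd <- D * (n / 100)^0.49; nd <- 100 }
  pvalue <- exp(-7.01256 * Kd^2 * (nd + 2.78019) +
                2.99587 * Kd * sqrt(nd + 2.78019) - 0.122119 +
                0.974598 / sqrt(nd) + 1.67997 / nd)
  if (pvalue > 0.1) {
    KK <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * D
    pvalue <-
      if (KK <= 0.302) 1
      else if (KK <= 0.5) 2.76773 - 19.828315 * KK + 80.709644 * KK^2 -
        138.55152 * KK^3 + 81.218052 * KK^4
      else if (KK <= 0.9) -4.901232 + 40.662806 * KK - 97.490286 * KK^2 +
        94.029866 * KK^3 - 32.355711 * KK^4
      else if (KK <= 1.31) 6.198765 - 19.558097 * KK + 23.186922 * KK^2 -
        12.234627 * KK^3 + 2.423045 * KK^4
      else 0
  }
  list(statistic = D, p_value = min(max(pvalue, 0), 1))
}

# Levene's test, center = mean (Brown-Forsythe uses the median; the classic
# mean-centred variant is implemented here)
levene_test <- function(groups) {
  z <- lapply(groups, function(g) abs(g - mean(g)))
  k <- length(z)
  ns <- lengths(z)
  N <- sum(ns)
  zbar_g <- vapply(z, mean, 0)
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(ns * (zbar_g - zbar)^2)
  ss_within <- sum(vapply(z, function(v) sum((v - mean(v))^2), 0))
  if (ss_within == 0) {
    W <- if (ss_between == 0) 0 else Inf
    p <- if (ss_between == 0) 1 else 0
    return(list(statistic = W, p_value = p, df = c(k - 1, N - k)))
  }
  W <- (N - k) / (k - 1) * ss_between / ss_within
  list(statistic = W, p_value = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}

#' Distributional assumption checks
#'
#' Per-group Kolmogorov-Smirnov normality tests against a normal fitted to
#' the sample mean and SD (Lilliefors-corrected p-values, since the
#' parameters are estimated) plus one Levene homogeneity-of-variance test
#' (centred at the group means). Groups with fewer than 3 observations have
#' their normality check skipped with a flag.
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return data frame of comparison rows (`test`, `groups`, `statistic`,
#'   `p_value`, `marks`), one `ks_normality` row per group (NA where
#'   skipped) and one `levene` row.
#' @export
check_assumptions <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a named list of at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (length(x) < 4L)
      return(cbind(comparison_row("ks_normality", g, NA_real_, NA_real_),
                   flag = "skipped: n < 4"))
    r <- lilliefors_test(x)
    cbind(comparison_row("ks_normality", g, r$statistic, r$p_value),
          flag = "lilliefors-corrected")
  })
  lv_groups <- groups[lengths(groups) >= 3L]
  lv <- if (length(lv_groups) >= 2L) levene_test(lv_groups) else
    list(statistic = NA_real_, p_value = NA_real_)
  rows <- c(rows, list(cbind(
    comparison_row("levene", paste(names(lv_groups), collapse = "|"),
                   lv$statistic, lv$p_value),
    flag = if (length(lv_groups) >= 2L) "center = mean" else "skipped: n < 3")))
  do.call(rbind, rows)
}

# restore-on-exit wrapper: mvtnorm's quadrature consumes the R RNG stream;
# keep caller RNG state untouched and the adjusted p deterministic
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' One-way ANOVA with Dunnett comparisons against control
#'
#' The omnibus F test plus two-sided Dunnett-adjusted p-values for each
#' treatment group versus the control, computed from the multivariate t
#' distribution with the pooled-variance correlation structure
#' (`rho_ij = lambda_i lambda_j`, `lambda_i = sqrt(n_i / (n_i + n_0))`).
#' With a single treatment group the adjusted p reduces exactly to the
#' pooled two-sided t-test.
#'
#' @param groups named list of numeric vectors, each n >= 2.
#' @param control_label name of the control group (must be present).
#' @param abseps absolute tolerance on the multivariate-t probability.
#' @return list with `anova` (one `anova_F` comparison row) and `dunnett`
#'   (one row per treatment, with unadjusted p in column `p_unadjusted`).
#' @export
anova_dunnett <- function(groups, control_label = "CTL", abseps = 1e-5) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (is.null(names(groups)) || !control_label %in% names(groups))
    stop("control group '", control_label, "' not found; have: ",
         paste(names(groups), collapse = ", "))
  if (any(lengths(groups) < 2L)) stop("every group needs n >= 2")
  k <- length(groups)
  ns <- lengths(groups)
  N <- sum(ns)
  means <- vapply(groups, mean, 0)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  grand <- sum(unlist(groups)) / N
  ss_between <- sum(ns * (means - grand)^2)
  df1 <- k - 1; df2 <- N - k
  if (ss_within == 0) {
    Fstat <- if (ss_between == 0) NA_real_ else Inf
    p_F <- if (ss_between == 0) 1 else 0
    flag <- "degenerate: zero within-group variance"
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
    p_F <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    flag <- NA_character_
  }
  anova_row <- cbind(comparison_row("anova_F", paste(names(groups),
                                                     collapse = "|"),
                                    Fstat, p_F), flag = flag)
  s2 <- if (ss_within == 0) 0 else ss_within / df2
  trt <- setdiff(names(groups), control_label)
  n0 <- ns[control_label]
  lambda <- sqrt(ns[trt] / (ns[trt] + n0))
  corr <- outer(lambda, lambda)
  diag(corr) <- 1
  rows <- lapply(seq_along(trt), function(i) {
    g <- trt[i]
    se <- sqrt(s2 * (1 / ns[g] + 1 / n0))
    tstat <- if (se == 0) {
      if (means[g] == means[control_label]) 0 else Inf * sign(means[g] - means[control_label])
    } else (means[g] - means[control_label]) / se
    p_un <- 2 * stats::pt(-abs(tstat), df2)
    p_adj <- if (!is.finite(tstat)) 0 else if (length(trt) == 1L) p_un else
      with_local_seed(2903, 1 - as.numeric(mvtnorm::pmvt(
        lower = rep(-abs(tstat), length(trt)),
        upper = rep(abs(tstat), length(trt)),
        df = as.integer(df2), corr = corr,
        algorithm = mvtnorm::GenzBretz(abseps = abseps, maxpts = 100000))))
    out <- comparison_row("dunnett", paste(g, "vs", control_label),
                          tstat, min(max(p_adj, 0), 1))
    out$p_unadjusted <- p_un
    out
  })
  list(anova = anova_row, dunnett = do.call(rbind, rows))
}

#' Unpaired two-sample t-test
#'
#' Welch (unequal variance) by default; set `welch = FALSE` for the pooled
#' variant. Two groups that are both constant with equal means give p = 1
#' by convention.
#'
#' @param group_a,group_b numeric vectors, each n >= 2.
#' @param welch logical.
#' @param context marking convention for [significance_marks()] (intergroup
#'   comparisons use `"#"` marks).
#' @return one comparison row (data frame).
#' @export
unpaired_t <- function(group_a, group_b, welch = TRUE,
                       context = "intergroup") {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(comparison_row("t_unpaired", "a vs b",
                          if (equal) 0 else Inf * sign(mean(a) - mean(b)),
                          if (equal) 1 else 0, context))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  comparison_row(if (welch) "t_unpaired" else "t_unpaired_pooled", "a vs b",
                 unname(tt$statistic), tt$p.value, context)
}

#' Significance marks per the figure-caption convention
#'
#' Comparisons against control use asterisks, intergroup comparisons use
#' hashes: one symbol for p < 0.05, two for p < 0.01, three for p < 0.001,
#' four for p < 0.0001; empty string otherwise.
#'
#' @param p p-value in \[0, 1\].
#' @param context `"vs_control"` or `"intergroup"`.
#' @return character mark string.
#' @export
significance_marks <- function(p, context = c("vs_control", "intergroup")) {
  context <- match.arg(context)
  if (!is.finite(p) || p < 0 || p > 1) stop("p must lie in [0, 1]")
  sym <- if (context == "vs_control") "*" else "#"
  n <- sum(p < c(0.05, 0.01, 0.001, 0.0001))
  strrep(sym, n)
}
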