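# Cohort-level statistics. The Mann-Whitney U test is computed by exact
# enumeration of group assignments whenever feasible (it always is at the
# study's 8-vs-10 group sizes); the normal approximation with tie and
# continuity corrections covers larger cohorts.

.combn_cache <- new.env(parent = emptyenv())

combn_cached <- function(n, k) {
  key <- paste0(n, "_", k)
  if (!exists(key, envir = .combn_cache))
    assign(key, utils::combn(n, k), envir = .combn_cache)
  get(key, envir = .combn_cache)
}

#' Mann-Whitney U test (exact or approximate)
#'
#' `U` is the smaller of the two directed statistics
#' `U_a = #\{(x, y): x < y\} + 0.5 #\{ties\}` and `U_b = n_a n_b - U_a`.
#' The two-sided p-value is `P(U <= U_obs)` by exact enumeration of all
#' `choose(n_a + n_b, n_a)` group assignments of the pooled values when that
#' count does not exceed `max_enumeration`; otherwise the normal
#' approximation with mid-ranks, tie-corrected variance and continuity
#' correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @param max_enumeration assignment-count threshold for the exact path.
#' @return list with `u` (the reported U), `p` (two-sided), `method`
#'   (`"exact_enumeration"` or `"normal_approximation"`), `u_a`, `u_b`.
#' @export
mann_whitney_u <- function(a, b, max_enumeration = 200000) {
  if (!length(a) || !length(b)) stop("input error: both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)  # mid-ranks
  ua <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ub <- na * nb - ua
  u <- min(ua, ub)
  if (choose(n, na) <= max_enumeration) {
    cmb <- combn_cached(n, na)
    ra <- matrix(r[cmb], nrow = na)
    ua_all <- colSums(ra) - na * (na + 1) / 2
    u_all <- pmin(ua_all, na * nb - ua_all)
    p <- mean(u_all <= u + 1e-9)
    method <- "exact_enumeration"
  } else {
    mu <- na * nb / 2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu + 0.5) / sqrt(sigma2)  # u <= mu, continuity toward the mean
      p <- min(1, 2 * stats::pnorm(z))
    }
    method <- "normal_approximation"
  }
  list(u = u, p = p, method = method, u_a = ua, u_b = ub)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard Royston implementation with explicit
#' domain errors for unusable samples.
#'
#' @param x numeric vector, 3 <= n <= 5000.
#' @return list with `w` and `p`.
#' @export
shapiro_wilk <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3 || length(x) > 5000)
    stop("input error: Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    stop("degenerate sample: all values identical")
  res <- stats::shapiro.test(x)
  list(w = unname(res$statistic), p = res$p.value)
}

#' Welch two-sample t test
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided.
#'
#' @param a,b numeric vectors with n >= 2 each.
#' @return list with `t`, `p`, `df`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("input error: n >= 2 per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = NA_real_))
    stop("input error: both groups have zero variance")
  }
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Compare two cohorts of normalized strain ratios
#'
#' Shapiro-Wilk normality per group, Mann-Whitney U on the ratios, group
#' medians and five-number summaries.
#'
#' @param summaries_a,summaries_b lists of [subject_strain_summary()]
#'   objects, or plain numeric ratio vectors.
#' @param alpha significance level (default 0.05).
#' @return Object of class `group_comparison`.
#' @export
compare_cohorts <- function(summaries_a, summaries_b, alpha = 0.05) {
  get_ratios <- function(s) {
    if (is.numeric(s)) return(s)
    vapply(s, function(x) {
      if (!inherits(x, "subject_strain_summary"))
        stop("input error: expected subject_strain_summary objects")
      x$ratio
    }, numeric(1))
  }
  ra <- get_ratios(summaries_a)
  rb <- get_ratios(summaries_b)
  if (length(ra) < 2 || length(rb) < 2)
    stop("input error: at least 2 subjects per group")
  sw_a <- tryCatch(shapiro_wilk(ra)$p, error = function(e) NA_real_)
  sw_b <- tryCatch(shapiro_wilk(rb)$p, error = function(e) NA_real_)
  mw <- mann_whitney_u(ra, rb)
  structure(list(ratios_a = ra, ratios_b = rb,
                 medians = c(stats::median(ra), stats::median(rb)),
                 u_statistic = mw$u, p_value = mw$p, method = mw$method,
                 normality_p = c(sw_a, sw_b), alpha = alpha,
                 significant = mw$p < alpha,
                 fivenum_a = stats::fivenum(ra), fivenum_b = stats::fivenum(rb)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(paste0("group comparison of normalized strain ratios\n",
                     "  n = %d vs %d, medians %.3f vs %.3f\n",
                     "  Mann-Whitney U = %.1f, p = %.4g (%s)\n",
                     "  Shapiro-Wilk p: %.3g / %.3g; significant at alpha ",
                     "%.2g: %s\n"),
              length(x$ratios_a), length(x$ratios_b), x$medians[1],
              x$medians[2], x$u_statistic, x$p_value, x$method,
              x$normality_p[1], x$normality_p[2], x$alpha,
              if (x$significant) "yes" else "no"))
  invisible(x)
}
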