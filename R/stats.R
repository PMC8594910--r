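## The statistical battery: Spearman rank correlation (one- or two-tailed,
## exact permutation null for small n), Pearson regression, Friedman
## two-factorial ANOVA for dependent samples, Wilcoxon signed-rank with
## Bonferroni correction, and the Mann-Whitney U test. Exact small-sample
## null distributions are computed with tie-aware enumeration /
## convolution, which base R's tests decline when ties are present; base R
## remains the cross-check on tie-free inputs.

new_stats_result <- function(method, n, statistic, estimate = NULL, p,
                             sided = "two", correction = "none", m = 1L,
                             extra = list()) {
  structure(c(list(method = method, n = n, statistic = statistic,
                   estimate = estimate, p = p, sided = sided,
                   correction = correction, m = m), extra),
            class = "stats_result")
}

#' @export
print.stats_result <- function(x, ...) {
  cat(x$method, ": n = ", x$n, sep = "")
  if (!is.null(x$estimate))
    cat(",", paste(names(x$estimate), "=", signif(x$estimate, 4), collapse = ", "))
  cat(sprintf(", statistic = %.4g, p = %.4g (%s-sided", x$statistic, x$p, x$sided))
  if (x$correction != "none") cat(sprintf(", %s m = %d", x$correction, x$m))
  cat(")\n")
  invisible(x)
}

## all permutations of 1..n as a matrix (n! rows); n <= 8
perm_matrix <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- r + seq_len(nrow(sub))
    out[rows, 1] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1] <- matrix(rest[sub], nrow(sub))
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' Average ranks for ties; `r_s` is the Pearson correlation of the rank
#' vectors. The p-value is exact (full permutation enumeration of the rank
#' pairing) for `n <= exact_max`, otherwise the t approximation on
#' `r_s * sqrt((n-2)/(1-r_s^2))`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param sided `"two"`, `"greater"` (positive association) or `"less"`.
#' @param exact_max enumeration cutoff (default 8).
#' @return a `stats_result` with estimate `r_s`.
#' @export
spearman_cor <- function(x, y, sided = c("two", "greater", "less"),
                         exact_max = 8L) {
  sided <- match.arg(sided)
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  rx <- rank(x); ry <- rank(y)
  rs <- stats::cor(rx, ry)
  if (n <= exact_max) {
    P <- perm_matrix(n)
    ryc <- ry - mean(ry)
    rxc <- rx - mean(rx)
    num <- matrix(ryc[P], nrow(P)) %*% rxc
    allr <- as.vector(num) / (sqrt(sum(rxc^2)) * sqrt(sum(ryc^2)))
    eps <- 1e-12
    p <- switch(sided,
                greater = mean(allr >= rs - eps),
                less = mean(allr <= rs + eps),
                two = mean(abs(allr) >= abs(rs) - eps))
    exact <- TRUE
  } else {
    tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
    p <- switch(sided,
                greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
                less = stats::pt(tstat, n - 2),
                two = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
    p <- min(1, p)
    exact <- FALSE
  }
  new_stats_result("Spearman rank correlation", n, rs,
                   c(r_s = rs), p, sided, extra = list(exact = exact))
}

#' Pearson correlation and least-squares regression
#'
#' @param x,y numeric vectors (n >= 3) with nonzero variance.
#' @param sided sidedness of the correlation test.
#' @return `stats_result` with estimates `r`, `r2`, `slope`, `intercept`.
#' @export
pearson_regression <- function(x, y, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors, n >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance: regression undefined")
  r <- stats::cor(x, y)
  slope <- r * stats::sd(y) / stats::sd(x)
  intercept <- mean(y) - slope * mean(x)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- switch(sided,
              greater = stats::pt(tstat, n - 2, lower.tail = FALSE),
              less = stats::pt(tstat, n - 2),
              two = 2 * stats::pt(abs(tstat), n - 2, lower.tail = FALSE))
  new_stats_result("Pearson correlation / least squares", n, r,
                   c(r = r, r2 = r^2, slope = slope, intercept = intercept),
                   min(1, p), sided)
}

friedman_statistic <- function(R, tie_correct = TRUE) {
  n <- nrow(R); k <- ncol(R)
  Rj <- colSums(R)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  denom <- n * k * (k + 1) / 12
  if (tie_correct) {
    C <- 0
    for (i in seq_len(n)) {
      tt <- table(R[i, ])
      C <- C + sum(tt^3 - tt)
    }
    denom <- denom - C / (12 * (k - 1))
  }
  if (denom <= 0) return(0)
  S / denom
}

#' Friedman two-factorial analysis of variance for dependent samples
#'
#' Within-subject average ranks; tie-corrected chi-square statistic on
#' `k - 1` degrees of freedom. For small tables
#' (`k!^n <= exact_limit`) the p-value is computed exactly by enumerating
#' all within-row rank permutations.
#'
#' @param pt_matrix complete numeric matrix, subjects x conditions.
#' @param exact enumerate the within-row permutation null (default: when
#'   feasible).
#' @param exact_limit cap on `k!^n` for enumeration.
#' @return `stats_result`.
#' @export
friedman_anova <- function(pt_matrix, exact = NULL, exact_limit = 5e5) {
  X <- as.matrix(pt_matrix)
  if (anyNA(X)) stop("missing cells in the threshold matrix")
  n <- nrow(X); k <- ncol(X)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 conditions")
  R <- t(apply(X, 1, rank))
  stat <- friedman_statistic(R)
  nperm <- factorial(k)^n
  if (is.null(exact)) exact <- nperm <= exact_limit
  if (exact && nperm > exact_limit) exact <- FALSE
  if (exact) {
    P <- perm_matrix(k)
    ## enumerate row-permutation indices via mixed-radix counting
    idx <- rep(1L, n)
    count <- 0L; ge <- 0L
    repeat {
      Rp <- R
      for (i in seq_len(n)) Rp[i, ] <- R[i, P[idx[i], ]]
      s <- friedman_statistic(Rp)
      count <- count + 1L
      if (s >= stat - 1e-12) ge <- ge + 1L
      j <- 1L
      repeat {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nrow(P)) break
        idx[j] <- 1L; j <- j + 1L
        if (j > n) break
      }
      if (j > n) break
    }
    p <- ge / count
  } else {
    p <- stats::pchisq(stat, k - 1, lower.tail = FALSE)
  }
  new_stats_result("Friedman rank ANOVA", n, stat, NULL, p, "two",
                   extra = list(df = k - 1, exact = exact))
}

## exact signed-rank null via convolution over 2*ranks (tie-aware)
signed_rank_exact_cdf <- function(ranks2) {
  maxs <- sum(ranks2)
  dist <- numeric(maxs + 1L); dist[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(maxs + 1L - r)])
    dist <- (dist + shifted) / 2
  }
  dist            # P(2V = 0..maxs)
}

#' Wilcoxon signed-rank test
#'
#' Zero differences are dropped; |differences| get average ranks. The
#' statistic is `V`, the rank sum of the positive differences. For
#' `n <= 20` retained pairs the null distribution is computed exactly by
#' tie-aware convolution over all sign assignments; otherwise the normal
#' approximation with tie correction is used.
#'
#' @param x,y paired vectors (or `y = NULL` for signed values in `x`).
#' @param sided `"two"`, `"greater"` (x > y) or `"less"`.
#' @return `stats_result`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate test: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 20) {
    cdf <- signed_rank_exact_cdf(round(2 * r))
    v2 <- round(2 * V)
    pge <- sum(cdf[(v2 + 1L):length(cdf)])
    ple <- sum(cdf[1:(v2 + 1L)])
    p <- switch(sided, greater = pge, less = ple,
                two = min(1, 2 * min(pge, ple)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie <- sum(table(r)^3 - table(r))
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie / 48)
    z <- (V - mu) / sig
    p <- switch(sided,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    exact <- FALSE
  }
  new_stats_result("Wilcoxon signed-rank", n, V, NULL, p, sided,
                   extra = list(exact = exact))
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' @param pt_matrix subjects x montages matrix.
#' @param pairs list of length-2 character vectors (column names); default
#'   all pairs.
#' @param m Bonferroni multiplier; defaults to the number of comparisons
#'   performed.
#' @param sided test sidedness.
#' @return data.frame: pair, n, statistic, p, p_bonferroni.
#' @export
wilcoxon_pairwise <- function(pt_matrix, pairs = NULL, m = NULL,
                              sided = "two") {
  X <- as.matrix(pt_matrix)
  if (is.null(pairs)) {
    cn <- colnames(X)
    pairs <- utils::combn(cn, 2, simplify = FALSE)
  }
  if (is.null(m)) m <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    res <- wilcoxon_signed_rank(X[, pr[1]], X[, pr[2]], sided = sided)
    data.frame(a = pr[1], b = pr[2], n = res$n, statistic = res$statistic,
               p = res$p, p_bonferroni = min(1, m * res$p))
  })
  out <- do.call(rbind, rows)
  attr(out, "m") <- m
  out
}

#' Mann-Whitney U test for independent samples
#'
#' `U` counts pairs where a group-A value exceeds a group-B value (ties
#' count one half). Exact enumeration of all group labelings for small
#' samples (`choose(n1+n2, n1) <= exact_limit`), tie-corrected normal
#' approximation otherwise.
#'
#' @param a,b numeric vectors.
#' @param sided `"two"`, `"greater"` (A tends larger) or `"less"`.
#' @param exact_limit enumeration cutoff.
#' @return `stats_result`.
#' @export
mann_whitney <- function(a, b, sided = c("two", "greater", "less"),
                         exact_limit = 20000) {
  sided <- match.arg(sided)
  n1 <- length(a); n2 <- length(b)
  if (!n1 || !n2) stop("both groups must be nonempty")
  pool <- c(a, b)
  r <- rank(pool)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= exact_limit) {
    combs <- utils::combn(n1 + n2, n1)
    Us <- apply(combs, 2, function(id) sum(r[id])) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    pge <- mean(Us >= U - eps)
    ple <- mean(Us <= U + eps)
    p <- switch(sided, greater = pge, less = ple,
                two = min(1, 2 * min(pge, ple)))
    exact <- TRUE
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    tie <- sum(table(r)^3 - table(r))
    sig <- sqrt(n1 * n2 / 12 * (nt + 1 - tie / (nt * (nt - 1))))
    z <- (U - mu) / sig
    p <- switch(sided,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    p <- min(1, p)
    exact <- FALSE
  }
  new_stats_result("Mann-Whitney U", c(n1 = n1, n2 = n2), U, NULL, p, sided,
                   extra = list(exact = exact))
}

#' Electrode-distance analysis
#'
#' Pearson correlation of per-montage phosphene thresholds with the average
#' electrode distance to the eye and to the occipital cortex. The So-rS
#' montage is excluded (its low current levels in both targets make the
#' distance surrogate meaningless for it, following the study's analysis
#' rule).
#'
#' @param distances data.frame with columns `montage`, `eye_cm`, `oc_cm`
#'   (e.g. assembled from [electrode_eye_distances()]).
#' @param pt named vector of per-montage thresholds (uA), names matching
#'   `distances$montage`.
#' @param exclude montages dropped before correlating.
#' @return list of two `stats_result`s: `eye` and `oc`.
#' @export
distance_analysis <- function(distances, pt, exclude = "So-rS") {
  keep <- !(distances$montage %in% exclude)
  d <- distances[keep, , drop = FALSE]
  if (nrow(d) < 3) stop("fewer than 3 montages after exclusion")
  y <- pt[d$montage]
  if (anyNA(y)) stop("missing thresholds for: ",
                     paste(d$montage[is.na(y)], collapse = ", "))
  list(eye = pearson_regression(d$eye_cm, y),
       oc = pearson_regression(d$oc_cm, y))
}
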