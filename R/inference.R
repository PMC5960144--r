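# Permutation and rank-based hypothesis tests and the serum-metabolite
# regression. PERMANOVA is implemented directly (Anderson's among/within
# sum-of-squares on squared distances) because the analysis contract pins the
# plus-one permutation p-value, within-stratum shuffling and an exhaustive
# enumeration mode; vegan::adonis2 serves as an independent cross-check in
# the test suite.

# Within-group sum of squares for one labeling, from the squared-distance
# matrix: sum_g (sum of squared distances within g) / n_g.
.ss_within <- function(D2, groups) {
  s <- 0
  for (g in levels(groups)) {
    idx <- which(groups == g)
    s <- s + sum(D2[idx, idx]) / (2 * length(idx))
  }
  s
}

#' Permutational multivariate ANOVA on a distance matrix
#'
#' One-way PERMANOVA: pseudo-F from among/within sums of squares computed on
#' squared distances, with a permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`. Permutations can be restricted
#' to shuffles within strata (e.g. subject), or replaced by exhaustive
#' enumeration of all distinct two-group label assignments.
#'
#' @param d Distance matrix ([stats::dist] or square matrix).
#' @param groups Group labels, one per sample (>= 2 non-empty groups).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation draw.
#' @param strata Optional labels restricting permutations to within-stratum
#'   shuffles.
#' @param exact If `TRUE` (two groups only), enumerate every distinct
#'   assignment of the labels instead of sampling permutations; the p-value
#'   is the fraction of assignments (including the observed one) with
#'   `F >= F_obs`.
#' @return List with `pseudo_F`, `p_value`, `n_permutations`, `partial_R2`,
#'   `df_among`, `df_within`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1, strata = NULL,
                      exact = FALSE) {
  D2 <- as.matrix(d)^2
  n <- nrow(D2)
  groups <- factor(groups)
  if (length(groups) != n) stop("length(groups) must equal the matrix size")
  if (any(table(groups) == 0) || nlevels(groups) < 2)
    stop("need at least 2 non-empty groups")
  k <- nlevels(groups)
  sst <- sum(D2) / (2 * n)
  if (sst <= 0) stop("all distances are zero; pseudo-F undefined")
  ssw <- .ss_within(D2, groups)
  f_stat <- function(ssw) ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  F_obs <- f_stat(ssw)
  eps <- 1e-12
  if (exact) {
    if (k != 2) stop("exact enumeration implemented for 2 groups only")
    if (!is.null(strata)) stop("exact enumeration does not support strata")
    n1 <- sum(groups == levels(groups)[1])
    sets <- combn(n, n1)
    F_all <- apply(sets, 2, function(idx) {
      lab <- factor(ifelse(seq_len(n) %in% idx, "a", "b"))
      f_stat(.ss_within(D2, lab))
    })
    p <- mean(F_all >= F_obs - eps)
    return(list(pseudo_F = F_obs, p_value = p, n_permutations = ncol(sets),
                partial_R2 = (sst - ssw) / sst, df_among = k - 1,
                df_within = n - k))
  }
  set.seed(seed)
  if (is.null(strata)) {
    perms <- replicate(n_perm, sample.int(n))
  } else {
    strata <- as.factor(strata)
    if (length(strata) != n) stop("length(strata) must equal the matrix size")
    perms <- replicate(n_perm, {
      idx <- seq_len(n)
      for (s in levels(strata)) {
        w <- which(strata == s)
        idx[w] <- w[sample.int(length(w))]
      }
      idx
    })
  }
  # vectorized: one indicator matrix per group level, one matmul each
  ssw_perm <- numeric(n_perm)
  for (g in levels(groups)) {
    V <- matrix(groups[perms] == g, n, n_perm) + 0
    ssw_perm <- ssw_perm + colSums((D2 %*% V) * V) / (2 * sum(groups == g))
  }
  F_perm <- vapply(ssw_perm, f_stat, 0)
  p <- (1 + sum(F_perm >= F_obs - eps)) / (1 + n_perm)
  list(pseudo_F = F_obs, p_value = p, n_permutations = n_perm,
       partial_R2 = (sst - ssw) / sst, df_among = k - 1, df_within = n - k)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Tests every pair of groups with [permanova()] and multiplies each p-value
#' by the number of pairs (capped at 1).
#'
#' @inheritParams permanova
#' @return Data frame with one row per pair: `group_a`, `group_b`,
#'   `pseudo_F`, `p_value`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 3)
    stop("pairwise testing needs at least 3 groups; use permanova() for 2")
  pairs <- combn(levels(groups), 2)
  n_pairs <- ncol(pairs)
  out <- lapply(seq_len(n_pairs), function(i) {
    keep <- groups %in% pairs[, i]
    res <- permanova(m[keep, keep], droplevels(groups[keep]),
                     n_perm = n_perm, seed = seed + i)
    data.frame(group_a = pairs[1, i], group_b = pairs[2, i],
               pseudo_F = res$pseudo_F, p_value = res$p_value,
               p_adjusted = min(1, res$p_value * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Kruskal-Wallis rank sum test
#'
#' Midrank-based H with tie correction, p from chi-square with k-1 degrees of
#' freedom (via [stats::kruskal.test()]). Used for the donor-vs-other
#' beta-diversity comparison, where group sizes differ greatly.
#'
#' @param values Numeric values, or a list of per-group value vectors (in
#'   which case `groups` is ignored).
#' @param groups Group labels matching `values`.
#' @return List with `H` and `p_value`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (length(values) < 3) stop("need at least 3 values in total")
  if (length(unique(values)) == 1)
    return(list(H = 0, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), p_value = kt$p.value)
}

#' Ordinary least-squares regression of y on x
#'
#' @param x Predictor values (not constant).
#' @param y Response values.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (F-test on
#'   the slope), `n`.
#' @export
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (sd(x) == 0) stop("x is constant; slope undefined")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(pf(sm$fstatistic[1], sm$fstatistic[2],
                           sm$fstatistic[3], lower.tail = FALSE)),
       n = length(x))
}
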