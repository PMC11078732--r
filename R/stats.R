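#' Permutation t-test
#'
#' Paired tests use sign flips of the pairwise differences (equivalent to
#' testing the differences against zero); unpaired tests permute group labels.
#' P-values use the (b+1)/(m+1) estimator, so `p >= 1/(nPerm+1)` always.
#'
#' @param x,y numeric samples (`y` omitted for a one-sample test on `x`).
#' @param paired logical.
#' @param nPerm number of permutations (default 10000).
#' @param sided `"two"`, `"greater"` (x > y) or `"less"`.
#' @return A list with `t`, `p`, `nPerm`.
#' @export
permTTest <- function(x, y = NULL, paired = FALSE, nPerm = 10000L,
                      sided = c("two", "greater", "less")) {
  sided <- match.arg(sided)
  if (paired && !is.null(y)) { x <- x - y; y <- NULL }
  if (is.null(y)) {
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 2L) stop("need at least 2 observations")
    tObs <- .tOne(x)
    if (all(x == 0)) {
      warning("constant zero differences; p = 1")
      return(list(t = 0, p = 1, nPerm = nPerm))
    }
    tNull <- vapply(seq_len(nPerm), function(i)
      .tOne(x * sample(c(-1, 1), n, replace = TRUE)), numeric(1))
  } else {
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 observations per group")
    pool <- c(x, y); nx <- length(x)
    tObs <- .tTwo(x, y)
    tNull <- vapply(seq_len(nPerm), function(i) {
      p <- sample(pool)
      .tTwo(p[seq_len(nx)], p[-seq_len(nx)])
    }, numeric(1))
  }
  p <- switch(sided,
    two = (sum(abs(tNull) >= abs(tObs)) + 1) / (nPerm + 1),
    greater = (sum(tNull >= tObs) + 1) / (nPerm + 1),
    less = (sum(tNull <= tObs) + 1) / (nPerm + 1))
  list(t = tObs, p = p, nPerm = nPerm)
}

.tOne <- function(d) {
  s <- sd(d)
  if (s == 0) return(0)
  mean(d) / (s / sqrt(length(d)))
}

.tTwo <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
             (length(x) + length(y) - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
}

#' Permutation one-way ANOVA
#'
#' F-statistic with a group-label permutation null; p uses the (b+1)/(m+1)
#' estimator.
#'
#' @param values numeric observations.
#' @param groups group labels, at least 2 groups with 2 observations each.
#' @param nPerm number of permutations.
#' @return A list with `F`, `p`, `nPerm`.
#' @export
permAnova <- function(values, groups, nPerm = 2000L) {
  groups <- as.factor(groups)
  ok <- is.finite(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2L || any(table(groups) < 2L))
    stop("need at least 2 groups with 2 observations each")
  fObs <- .fStat(values, groups)
  fNull <- vapply(seq_len(nPerm), function(i)
    .fStat(values, sample(groups)), numeric(1))
  list(F = fObs, p = (sum(fNull >= fObs) + 1) / (nPerm + 1), nPerm = nPerm)
}

.fStat <- function(v, g) {
  gi <- as.integer(g)
  n <- tabulate(gi)
  sums <- as.vector(rowsum(v, gi))
  gm <- mean(v)
  ssb <- sum(n * (sums / n - gm)^2)
  ssw <- sum(v^2) - sum(sums^2 / n)
  k <- length(n)
  if (ssw <= 0) return(Inf)
  (ssb / (k - 1)) / (ssw / (length(v) - k))
}

#' Cluster-based permutation test over frequencies
#'
#' For a pairs x frequencies matrix of condition differences, forms clusters
#' of contiguous frequencies whose per-frequency one-sample t exceeds the
#' cluster-forming threshold (separately per sign), scores each cluster by the
#' sum of its t-values, and compares against the maximal cluster mass under
#' sign-flip permutations. One-sided clusters at `alphaCluster` (default
#' 0.025) per direction, matching a two-sided test at 0.05 overall; invariant
#' to a global sign flip of the input.
#'
#' @param diffs numeric matrix, pairs x frequencies (at least 5 pairs).
#' @param nPerm permutations.
#' @param alphaCluster per-direction cluster alpha.
#' @param clusterThresh cluster-forming t threshold; default the two-sided
#'   5% t quantile for `nrow(diffs) - 1` df.
#' @return A list with `clusters` (data frame: start, end, mass, p,
#'   significant, sign) and `tValues`.
#' @export
clusterPermFreq <- function(diffs, nPerm = 10000L, alphaCluster = 0.025,
                            clusterThresh = NULL) {
  diffs <- as.matrix(diffs)
  n <- nrow(diffs)
  if (n < 5L) stop("need at least 5 pairs")
  if (is.null(clusterThresh)) clusterThresh <- qt(0.975, n - 1)
  tv <- .colT(diffs)
  pos <- .clusters(tv, clusterThresh)
  neg <- .clusters(-tv, clusterThresh)
  pos$sign0 <- rep(1L, nrow(pos))
  neg$sign0 <- rep(-1L, nrow(neg))
  obs <- rbind(pos, neg)
  obs$sign <- obs$sign0
  nullMax <- vapply(seq_len(nPerm), function(i) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tvp <- .colT(diffs * s)
    m1 <- .clusters(tvp, clusterThresh)$mass
    m2 <- .clusters(-tvp, clusterThresh)$mass
    max(c(m1, m2, 0))
  }, numeric(1))
  obs$p <- vapply(obs$mass, function(m)
    (sum(nullMax >= m) + 1) / (nPerm + 1), numeric(1))
  obs$significant <- obs$p < alphaCluster
  obs$sign0 <- NULL
  list(clusters = obs, tValues = tv)
}

.colT <- function(m) {
  mu <- colMeans(m)
  se <- apply(m, 2L, sd) / sqrt(nrow(m))
  ifelse(se > 0, mu / se, 0)
}

.clusters <- function(tv, thr) {
  above <- tv > thr
  if (!any(above))
    return(data.frame(start = integer(), end = integer(), mass = numeric(),
                      sign0 = integer()))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             mass = vapply(keep, function(k)
               sum(abs(tv[starts[k]:ends[k]])), numeric(1)),
             sign0 = 1L)
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up FDR control; returns which p-values survive at level `q`.
#'
#' @param pvals numeric vector of p-values.
#' @param q FDR level.
#' @return A list with `mask` (logical) and `pAdjusted`.
#' @export
fdrMask <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(mask = logical(0), pAdjusted = numeric(0)))
  pa <- p.adjust(pvals, method = "BH")
  list(mask = pa < q, pAdjusted = pa)
}

#' Bonferroni-adjusted alpha for a test family
#'
#' @param alpha family-wise alpha.
#' @param nTests number of tests in the family (e.g. 2 MTL areas x 3 frontal
#'   areas x 2 cell populations = 12 for the cross-regional coherence
#'   contrasts).
#' @return `alpha / nTests`.
#' @export
bonferroniAlpha <- function(alpha = 0.05, nTests) alpha / nTests

#' Mixed-effects GLM contract for trial-level models
#'
#' Thin wrapper around `lme4` for the trial-by-trial models (e.g. reaction
#' time or firing rate against single-trial PAC with load as a confounder and
#' random intercepts for channel nested in patient). Gaussian responses use
#' `lmer`, counts use Poisson `glmer`; fixed effects are reported with Wald
#' z-tests. A Poisson fit with overdispersion (Pearson ratio > 2) is flagged.
#'
#' @param formula an `lme4`-style formula with random-intercept terms, e.g.
#'   `rt ~ pac + load + (1 | patient/channel)`.
#' @param data data frame of trial-level observations (correct trials).
#' @param family `"gaussian"` or `"poisson"`.
#' @return A list with `coefficients` (term, estimate, se, z, p), `fit`,
#'   `singular`, `overdispersed`.
#' @export
fitMixedGlm <- function(formula, data, family = c("gaussian", "poisson")) {
  family <- match.arg(family)
  fit <- if (family == "gaussian")
    lme4::lmer(formula, data = data, REML = FALSE)
  else
    lme4::glmer(formula, data = data, family = poisson())
  b <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  z <- b / se
  co <- data.frame(term = names(b), estimate = unname(b), se = unname(se),
                   z = unname(z), p = 2 * pnorm(-abs(unname(z))))
  od <- FALSE
  if (family == "poisson") {
    pr <- residuals(fit, type = "pearson")
    od <- sum(pr^2) / stats::df.residual(fit) > 2
  }
  list(coefficients = co, fit = fit, singular = lme4::isSingular(fit),
       overdispersed = od)
}
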