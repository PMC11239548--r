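#' Shapiro-Wilk normality test
#'
#' Thin wrapper over the standard implementation in [stats::shapiro.test()],
#' exposed so comparison reports carry a uniform `(W, p)` shape.
#'
#' @param sample numeric vector, 3 <= n <= 5000, non-constant.
#' @return list with `W` and `p`.
#' @export
shapiro_wilk <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) < 3 || length(x) > 5000)
    stop_numeric("shapiro_wilk: sample size must be in [3, 5000]")
  if (stats::sd(x) == 0) stop_numeric("shapiro_wilk: constant sample")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Drops zero differences and ranks absolute differences with mid-ranks.
#' P-values are exact for small samples — full sign enumeration up to 14
#' non-zero differences (valid with ties), the standard exact distribution
#' ([stats::wilcox.test()]) up to 25 without ties — and use the normal
#' approximation (no continuity correction) otherwise.
#'
#' @param sample_a,sample_b paired numeric vectors of equal length.
#' @param alternative `"two.sided"`, `"greater"` (a tends above b) or
#'   `"less"`.
#' @return list with `statistic` (V, the positive-rank sum), `p`, and
#'   `n_used` (pairs remaining after zero-drop).
#' @export
wilcoxon_signed_rank <- function(sample_a, sample_b,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) != length(b)) stop_numeric("wilcoxon: unequal lengths")
  d <- a - b
  keep <- d != 0
  if (!any(keep)) stop_numeric("wilcoxon: all differences are zero")
  if (sum(keep) < 6)
    stop_numeric("wilcoxon: need at least 6 non-zero differences")
  a <- a[keep]; b <- b[keep]
  d <- a - b
  n <- length(d)
  ties <- any(duplicated(abs(d)))
  if (n <= 14) {
    # exact enumeration of all 2^n sign assignments on the mid-ranks
    rk <- rank(abs(d))
    v_obs <- sum(rk[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    v_all <- as.vector(signs %*% rk)
    p <- switch(alternative,
                greater = mean(v_all >= v_obs),
                less = mean(v_all <= v_obs),
                two.sided = min(1, 2 * min(mean(v_all >= v_obs),
                                           mean(v_all <= v_obs))))
    return(list(statistic = v_obs, p = p, n_used = n))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = alternative,
                                            exact = n <= 25 && !ties,
                                            correct = FALSE))
  list(statistic = unname(ht$statistic), p = ht$p.value, n_used = n)
}

#' Paired comparison of optimizer variants
#'
#' Runs each variant on the same objective under an identical list of seeds
#' (paired design), collects the final best fitness and full convergence
#' traces, tests each variant's final-fitness sample for normality
#' (Shapiro-Wilk) and compares variant pairs with the Wilcoxon signed-rank
#' test. With minimization, `alternative = "less"` asks whether the first
#' variant's final fitness tends below (is better than) the second's.
#'
#' @param objective fitness callable (minimized).
#' @param bounds an [hho_bounds()].
#' @param variants character vector of variant names (>= 2).
#' @param n_seeds number of paired seeds (>= 6).
#' @param base_config an [hho_config()] supplying the shared budget.
#' @param seed master seed from which the paired run seeds derive.
#' @param alternative passed to [wilcoxon_signed_rank()] for each ordered
#'   pair.
#' @return object of class `optimizer_comparison`: `samples` (n_seeds x
#'   variants matrix of final best fitness), `traces` (list of matrices),
#'   `shapiro` (per variant), `wilcoxon` (per ordered pair), `medians`.
#' @export
compare_optimizers <- function(objective, bounds,
                               variants = c("hho", "lc_hhoa"),
                               n_seeds = 20L, base_config = hho_config(),
                               seed = 1L, alternative = "less") {
  if (length(variants) < 2) stop_config("need at least 2 variants")
  if (n_seeds < 6) stop_config("need at least 6 paired seeds")
  seeds <- vapply(seq_len(n_seeds),
                  function(i) derive_seed(seed, paste0("cmp", i)), integer(1))
  samples <- matrix(NA_real_, n_seeds, length(variants),
                    dimnames = list(NULL, variants))
  traces <- vector("list", length(variants)); names(traces) <- variants
  for (v in variants) {
    tr <- matrix(NA_real_, n_seeds, base_config$max_iterations)
    for (i in seq_len(n_seeds)) {
      cfg <- base_config
      cfg$variant <- v
      cfg$seed <- seeds[i]
      res <- hho_optimize(objective, bounds, cfg)
      samples[i, v] <- res$best_fitness
      tr[i, seq_along(res$trace)] <- res$trace
    }
    traces[[v]] <- tr
  }
  shapiro <- lapply(variants, function(v) {
    if (stats::sd(samples[, v]) == 0) list(W = NA_real_, p = NA_real_)
    else shapiro_wilk(samples[, v])
  })
  names(shapiro) <- variants
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  wilcoxon <- lapply(pairs, function(pr) {
    d <- samples[, pr[1]] - samples[, pr[2]]
    if (all(d == 0))
      return(list(pair = pr, statistic = NA_real_, p = 1, n_used = 0L))
    c(list(pair = pr),
      wilcoxon_signed_rank(samples[, pr[1]], samples[, pr[2]],
                           alternative = alternative))
  })
  structure(list(samples = samples, traces = traces, shapiro = shapiro,
                 wilcoxon = wilcoxon, seeds = seeds,
                 medians = apply(samples, 2, stats::median),
                 alternative = alternative),
            class = "optimizer_comparison")
}

#' @export
print.optimizer_comparison <- function(x, ...) {
  cat("Paired optimizer comparison over", nrow(x$samples), "seeds\n")
  cat("median final fitness:\n")
  print(round(x$medians, 6))
  for (w in x$wilcoxon)
    cat(sprintf("  %s vs %s: Wilcoxon p = %.4g (%s)\n",
                w$pair[1], w$pair[2], w$p, x$alternative))
  invisible(x)
}

#' Convergence traces as a long data.frame
#'
#' Plot-ready export of a comparison's best-so-far traces.
#'
#' @param comparison an [compare_optimizers()] result.
#' @return data.frame with columns `variant`, `seed_index`, `iteration`,
#'   `best_fitness`.
#' @export
comparison_traces <- function(comparison) {
  out <- lapply(names(comparison$traces), function(v) {
    tr <- comparison$traces[[v]]
    data.frame(variant = v,
               seed_index = rep(seq_len(nrow(tr)), each = ncol(tr)),
               iteration = rep(seq_len(ncol(tr)), times = nrow(tr)),
               best_fitness = as.vector(t(tr)))
  })
  out <- do.call(rbind, out)
  out[!is.na(out$best_fitness), ]
}
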