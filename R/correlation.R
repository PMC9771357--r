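# Trial-wise neural-behavioral correlation and the two-Gaussian
# classification of the resulting per-unit coefficients.

#' Trial-wise correlation between firing rate and the conditioned response
#'
#' For every CR trial, the zero-lag Pearson correlation between the unit's
#' instantaneous firing-rate profile and the eyelid-position profile over the
#' window from 150 ms before CS onset through US onset (exclusive); means of
#' both arguments are subtracted by the correlation itself. Trials whose
#' rate or eyelid segment has zero variance yield an undefined r and are
#' excluded (the count is reported).
#'
#' Correlation is invariant to the affine rate normalizations, so raw or
#' normalized traces give identical r.
#'
#' @param rates List of per-trial rate traces (`pcmli_rate` or numeric),
#'   sample i = t = i - 1 ms on the trial clock.
#' @param eyelids List of per-trial eyelid traces on the same clock.
#' @param cr_flags Logical vector: which trials are CRs.
#' @param cs_onset,us_onset CS/US onset (ms from trace start).
#' @param pre_window Window extension before CS onset (ms).
#' @return A `pcmli_correlation`: list with `per_trial` (tibble `trial`,
#'   `r`, `used`), `mean_r` (mean over usable CR trials), `n_cr`,
#'   `n_excluded`.
#' @export
cr_correlation <- function(rates, eyelids, cr_flags, cs_onset, us_onset,
                           pre_window = 150) {
  stopifnot(length(rates) == length(eyelids),
            length(cr_flags) == length(rates))
  idx <- (cs_onset - pre_window + 1):us_onset # t in [cs-150, us)
  rows <- purrr::map_dfr(seq_along(rates), function(i) {
    if (!cr_flags[i]) {
      return(tibble::tibble(trial = i, r = NA_real_, used = FALSE))
    }
    r <- if (inherits(rates[[i]], "pcmli_rate")) rates[[i]]$rate else
      as.numeric(rates[[i]])
    e <- as.numeric(eyelids[[i]])
    a <- r[idx]; b <- e[idx]
    if (sd(a) == 0 || sd(b) == 0) {
      return(tibble::tibble(trial = i, r = NA_real_, used = FALSE))
    }
    tibble::tibble(trial = i, r = cor(a, b), used = TRUE)
  })
  structure(list(per_trial = rows,
                 mean_r = mean(rows$r[rows$used]),
                 n_cr = sum(cr_flags),
                 n_excluded = sum(cr_flags) - sum(rows$used)),
            class = "pcmli_correlation")
}

#' @export
print.pcmli_correlation <- function(x, ...) {
  cat("<pcmli_correlation> mean r =", round(x$mean_r, 3), "over",
      sum(x$per_trial$used), "CR trials",
      if (x$n_excluded) sprintf("(%d excluded: zero variance)", x$n_excluded),
      "\n")
  invisible(x)
}

# plain two-component 1-D Gaussian EM from a caller-supplied split,
# returning an object shaped like an Mclust fit (mean/variance/pro + bic)
.em_two_gaussian <- function(x, hi_init, equal_variance = FALSE,
                             max_iter = 200, tol = 1e-8) {
  n <- length(x)
  if (sum(hi_init) < 2 || sum(!hi_init) < 2) return(NULL)
  mu <- c(mean(x[!hi_init]), mean(x[hi_init]))
  s2 <- c(var(x[!hi_init]), var(x[hi_init]))
  if (equal_variance) s2 <- rep(var(x), 2)
  w <- c(mean(!hi_init), mean(hi_init))
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * dnorm(x, mu[1], sqrt(s2[1]))
    d2 <- w[2] * dnorm(x, mu[2], sqrt(s2[2]))
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    z <- d2 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    w <- c(mean(1 - z), mean(z))
    if (min(w) < 1e-6) return(NULL)
    mu <- c(sum((1 - z) * x) / sum(1 - z), sum(z * x) / sum(z))
    if (equal_variance) {
      s2 <- rep((sum((1 - z) * (x - mu[1])^2) + sum(z * (x - mu[2])^2)) / n,
                2)
    } else {
      s2 <- c(sum((1 - z) * (x - mu[1])^2) / sum(1 - z),
              sum(z * (x - mu[2])^2) / sum(z))
    }
    if (any(s2 < 1e-10)) return(NULL)
  }
  k <- if (equal_variance) 4 else 5
  list(parameters = list(mean = mu,
                         variance = list(sigmasq = if (equal_variance)
                           s2[1] else s2),
                         pro = w),
       bic = 2 * ll_old - k * log(n))
}

.skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

#' Fit a two-Gaussian mixture to per-unit correlation coefficients
#'
#' Maximum-likelihood (EM) fit of a two-component Gaussian mixture, with the
#' one-component fit for comparison by BIC, the sample skewness, and the
#' classification cutoff: the smallest r at which the posterior probability
#' of membership in the higher-mean component reaches `level` (0.95). Units
#' at or above the cutoff are classified putative PC-MLIs.
#'
#' The cutoff interpretation is posterior membership; `cutoff_method =
#' "density_ratio"` instead returns the smallest r where the higher
#' component's density exceeds the lower's by `level/(1-level)`.
#'
#' @param r_values Numeric vector of per-unit mean correlations (n >= 20).
#' @param level Membership probability defining the cutoff.
#' @param cutoff_method `"posterior"` (default) or `"density_ratio"`.
#' @param equal_variance Constrain the two components to a common variance
#'   (stabilizes the fit when one component holds few units).
#' @return A `pcmli_mixture`: list with `means`, `sds`, `weights` (low
#'   component first), `skewness`, `cutoff`, `level`, `bic_1`, `bic_2`,
#'   `bimodal` (two components beat one by BIC), `degenerate`,
#'   `classification` (tibble `r`, `posterior_high`, `putative_pcmli`).
#' @export
fit_two_gaussian_mixture <- function(r_values, level = 0.95,
                                     cutoff_method = c("posterior",
                                                       "density_ratio"),
                                     equal_variance = FALSE) {
  cutoff_method <- match.arg(cutoff_method)
  r_values <- r_values[is.finite(r_values)]
  if (length(r_values) < 20) {
    stop("input error: at least 20 correlation values required",
         call. = FALSE)
  }
  mclustBIC <- mclust::mclustBIC # Mclust() resolves this in the caller frame
  f1 <- mclust::Mclust(r_values, G = 1, modelNames = "E", verbose = FALSE)
  f2e <- suppressWarnings(
    mclust::Mclust(r_values, G = 2, modelNames = "E", verbose = FALSE))
  f2v <- if (equal_variance) NULL else suppressWarnings(
    mclust::Mclust(r_values, G = 2, modelNames = "V", verbose = FALSE))
  bic_of <- function(f) if (is.null(f) || !is.finite(f$bic)) -Inf else f$bic
  # additional EM start seeded from the upper tail: the hierarchical
  # initialization can miss a small, well-separated high component
  f2q <- .em_two_gaussian(r_values,
                          hi_init = r_values >= quantile(r_values, 0.95),
                          equal_variance = equal_variance)
  cand <- list(f2e, f2v, f2q)
  bics <- vapply(cand, bic_of, 1)
  f2 <- if (all(!is.finite(bics))) NULL else cand[[which.max(bics)]]
  if (is.null(f2)) {
    return(structure(list(means = NA_real_, sds = NA_real_,
                          weights = NA_real_, skewness = .skewness(r_values),
                          cutoff = NA_real_, level = level, bic_1 = f1$bic,
                          bic_2 = NA_real_, bimodal = FALSE,
                          degenerate = TRUE, classification = NULL),
                     class = "pcmli_mixture"))
  }
  mu <- as.numeric(f2$parameters$mean)
  sig <- sqrt(as.numeric(f2$parameters$variance$sigmasq))
  if (length(sig) == 1) sig <- rep(sig, 2)
  w <- as.numeric(f2$parameters$pro)
  ord <- order(mu)
  mu <- mu[ord]; sig <- sig[ord]; w <- w[ord]
  degenerate <- min(w) < 0.005 || abs(diff(mu)) < 1e-3 ||
    abs(diff(mu)) < 0.25 * mean(sig)

  post_high <- function(r) {
    d_lo <- w[1] * dnorm(r, mu[1], sig[1])
    d_hi <- w[2] * dnorm(r, mu[2], sig[2])
    d_hi / (d_lo + d_hi)
  }
  cutoff <- NA_real_
  if (!degenerate) {
    grid <- seq(mu[1], 1, by = 1e-4)
    target <- switch(cutoff_method,
      posterior = post_high(grid) >= level,
      density_ratio = (w[2] * dnorm(grid, mu[2], sig[2])) >=
        level / (1 - level) * (w[1] * dnorm(grid, mu[1], sig[1])))
    hit <- which(target)
    if (length(hit)) cutoff <- grid[hit[1]]
  }
  classification <- tibble::tibble(
    r = r_values, posterior_high = post_high(r_values),
    putative_pcmli = if (is.na(cutoff)) NA else r_values >= cutoff)
  structure(list(means = mu, sds = sig, weights = w,
                 skewness = .skewness(r_values), cutoff = cutoff,
                 level = level, bic_1 = as.numeric(f1$bic),
                 bic_2 = as.numeric(f2$bic),
                 bimodal = is.finite(f2$bic) && f2$bic > f1$bic,
                 degenerate = degenerate, classification = classification),
            class = "pcmli_mixture")
}

#' @export
print.pcmli_mixture <- function(x, ...) {
  if (x$degenerate) {
    cat("<pcmli_mixture> degenerate fit (components collapse); cutoff undefined\n")
  } else {
    cat(sprintf(
      "<pcmli_mixture> means %.3f / %.3f (sd %.3f / %.3f, weights %.2f / %.2f)\n",
      x$means[1], x$means[2], x$sds[1], x$sds[2], x$weights[1], x$weights[2]))
    cat(sprintf("  skewness %.2f; cutoff r* = %.3f at %.2f membership; %s by BIC\n",
                x$skewness, x$cutoff, x$level,
                if (x$bimodal) "bimodal" else "unimodal"))
  }
  invisible(x)
}

#' Compare simulated and recorded correlation distributions by repeated draws
#'
#' Draws `n_draws` random subsets of simulated pairs, each of the same size
#' as the recorded sample, and applies a two-sample test to each draw.
#'
#' @param sim_r Simulated per-pair correlations.
#' @param real_r Recorded per-pair correlations (sets the draw size).
#' @param n_draws Number of random draws.
#' @param test `"t"` (paired Student's t on sorted values) or `"ks"`
#'   (two-sample Kolmogorov-Smirnov).
#' @return Tibble with one row per draw: `draw`, `statistic`, `p_value`.
#' @export
compare_correlation_distributions <- function(sim_r, real_r, n_draws = 1000,
                                              test = c("ks", "t")) {
  test <- match.arg(test)
  n <- length(real_r)
  stopifnot(length(sim_r) >= n)
  purrr::map_dfr(seq_len(n_draws), function(d) {
    x <- sample(sim_r, n)
    h <- if (test == "ks") {
      suppressWarnings(stats::ks.test(x, real_r))
    } else {
      stats::t.test(sort(x), sort(real_r), paired = TRUE)
    }
    tibble::tibble(draw = d, statistic = unname(h$statistic),
                   p_value = h$p.value)
  })
}
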