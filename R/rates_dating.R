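# Branch-length equality tests with simulated p-values, pedigree
# generation intervals, mutation-rate estimation and closed-form
# Poisson molecular-clock dating.

.branch_test_result <- function(statistic, p_value, n_sims, seed) {
  structure(list(statistic = statistic, p_value = p_value,
                 n_sims = as.integer(n_sims), seed = as.integer(seed),
                 se = sqrt(p_value * (1 - p_value) / n_sims)),
            class = "branch_test")
}

#' @export
print.branch_test <- function(x, ...) {
  cat(sprintf("X-squared = %.4f, simulated p-value = %.4g (%d sims, MC SE %.2g)\n",
              x$statistic, x$p_value, x$n_sims, x$se))
  invisible(x)
}

#' Test branch mutation counts for a common Poisson expectation
#'
#' Branches descending from the same split should accumulate mutations
#' at the same rate under a molecular clock. The statistic is the
#' chi-square form `X2 = sum((n_i - nbar)^2 / nbar)` with `nbar` the
#' mean count. The p-value is Monte-Carlo: replicate count vectors are
#' drawn under the null, each replicate's statistic is computed about
#' its own mean, and p is the fraction of replicates with a statistic at
#' least as large as observed. Two resampling schemes are available:
#' `"poisson"` draws every entry i.i.d. Poisson(`nbar`) (unconditional);
#' `"multinomial"` conditions on the observed total and splits it
#' uniformly over branches, which for two branches matches the exact
#' conditional binomial test ([binomial_branch_test_exact()]). The two
#' differ slightly for mid-range p-values.
#'
#' @param counts integer vector (>= 2 branches) of mutation counts, not
#'   all zero.
#' @param n_sims number of Monte-Carlo replicates.
#' @param seed RNG seed for the replicate stream.
#' @param resample null resampling scheme, `"poisson"` or
#'   `"multinomial"`.
#' @return a `branch_test` object: `statistic`, `p_value`, `n_sims`,
#'   `seed`, and the binomial Monte-Carlo standard error `se`.
#' @examples
#' poisson_equal_branch_test(c(5, 26), n_sims = 2000, seed = 1)
#' @export
poisson_equal_branch_test <- function(counts, n_sims = 10000L, seed = 1L,
                                      resample = c("poisson",
                                                   "multinomial")) {
  resample <- match.arg(resample)
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least two branch counts")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (all(counts == 0)) stop("all counts zero; common expectation undefined")
  k <- length(counts)
  nbar <- mean(counts)
  stat <- sum((counts - nbar)^2 / nbar)
  p <- with_seed(seed, {
    M <- if (resample == "poisson")
      matrix(rpois(n_sims * k, nbar), nrow = k)
    else rmultinom(n_sims, sum(counts), rep(1 / k, k))
    mbar <- colMeans(M)
    s2 <- colSums(sweep(M, 2, mbar)^2)
    x2 <- ifelse(mbar > 0, s2 / mbar, 0)
    mean(x2 >= stat - 1e-12)
  })
  .branch_test_result(stat, p, n_sims, seed)
}

#' Exact conditional test of equality for two branch counts
#'
#' Conditional on the total, either count is Binomial(n1 + n2, 1/2)
#' under equality; the two-sided p-value sums the probabilities of all
#' outcomes at least as far from the expected half-split as observed.
#' Serves as an exact oracle for [poisson_equal_branch_test()] with two
#' branches.
#'
#' @param counts integer vector of length 2.
#' @return the exact two-sided p-value.
#' @export
binomial_branch_test_exact <- function(counts) {
  stopifnot(length(counts) == 2, all(counts >= 0), sum(counts) > 0)
  N <- sum(counts)
  dev <- abs(0:N - N / 2)
  obs <- abs(counts[1] - N / 2)
  sum(stats::dbinom((0:N)[dev >= obs - 1e-12], N, 0.5))
}

#' Chi-square test of counts against given weights, simulated p-value
#'
#' Tests branch mutation counts against expectations proportional to
#' supplied weights (typically expected generations, i.e. elapsed years
#' divided by each branch's mean generation interval). Expected counts
#' are `e_i = N * w_i / sum(w)` with `N = sum(counts)`; the p-value is
#' estimated by multinomial resampling of `N` trials with probabilities
#' `w / sum(w)`.
#'
#' @param counts integer vector of branch mutation counts.
#' @param weights positive expectation weights, same length.
#' @param n_sims number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return a `branch_test` object.
#' @examples
#' generation_weighted_test(c(40, 10), c(30, 20), n_sims = 2000, seed = 1)
#' @export
generation_weighted_test <- function(counts, weights, n_sims = 10000L,
                                     seed = 1L) {
  counts <- as.numeric(counts)
  if (length(counts) != length(weights))
    stop("counts and weights must have the same length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (sum(counts) == 0) stop("all counts zero")
  N <- sum(counts)
  prob <- weights / sum(weights)
  e <- N * prob
  stat <- sum((counts - e)^2 / e)
  p <- with_seed(seed, {
    M <- rmultinom(n_sims, N, prob)
    x2 <- colSums((M - e)^2 / e)
    mean(x2 >= stat - 1e-12)
  })
  .branch_test_result(stat, p, n_sims, seed)
}

#' Mean generation interval along patrilines
#'
#' Walks each descendant up its unique patriline to the common ancestor.
#' Per descendant, the generation count is the number of father-son
#' links traversed and the span is the birth-year difference; the mean
#' interval is the mean over descendants of span/generations. The
#' pooled ratio (total span over total generations) is also reported
#' since the two disagree slightly on unbalanced pedigrees.
#'
#' @param links data.frame of father-son pairs: `father_id`, `son_id`,
#'   `father_birth`, `son_birth` (integer years; sons born after
#'   fathers).
#' @param ancestor_id the common patrilineal ancestor.
#' @param descendant_ids descendants to trace (default: all childless
#'   males in `links`).
#' @return list: `mean_interval_years`, `mean_generations`, `n_pairs`
#'   (distinct links traversed), `pooled_interval_years`, and per-
#'   descendant `paths` (data.frame `descendant`, `generations`,
#'   `span_years`, `interval_years`).
#' @export
mean_generation_interval <- function(links, ancestor_id,
                                     descendant_ids = NULL) {
  stopifnot(all(c("father_id", "son_id", "father_birth", "son_birth")
                %in% names(links)))
  if (any(links$son_birth <= links$father_birth))
    stop("every son must be born after his father")
  dup <- unique(links$son_id[duplicated(links$son_id)])
  conflicted <- dup[vapply(dup, function(s)
    length(unique(links$father_id[links$son_id == s])) > 1, logical(1))]
  if (length(conflicted))
    stop("multiple fathers recorded for: ",
         paste(conflicted, collapse = ", "))
  links <- links[!duplicated(links$son_id), , drop = FALSE]
  father_of <- setNames(links$father_id, links$son_id)
  birth <- c(setNames(links$son_birth, links$son_id),
             setNames(links$father_birth, links$father_id))
  birth <- birth[!duplicated(names(birth))]
  if (is.null(descendant_ids))
    descendant_ids <- setdiff(links$son_id, links$father_id)

  used_links <- character(0)
  paths <- lapply(descendant_ids, function(d) {
    node <- d; g <- 0L
    while (node != ancestor_id) {
      if (!node %in% names(father_of))
        stop("descendant not connected to ", ancestor_id, ": ", d)
      used_links <<- c(used_links, node)
      node <- father_of[[node]]
      g <- g + 1L
      if (g > length(father_of)) stop("pedigree cycle detected at ", d)
    }
    if (g == 0L) stop("descendant equals the ancestor: ", d)
    span <- birth[[d]] - birth[[ancestor_id]]
    data.frame(descendant = d, generations = g, span_years = span,
               interval_years = span / g, stringsAsFactors = FALSE)
  })
  paths <- do.call(rbind, paths)
  list(mean_interval_years = mean(paths$interval_years),
       mean_generations = mean(paths$generations),
       n_pairs = length(unique(used_links)),
       pooled_interval_years = sum(paths$span_years) / sum(paths$generations),
       paths = paths)
}

#' De novo mutation rate per site per generation
#'
#' Mean observed de novo mutations per lineage, divided by the number of
#' generations and by the interrogated sequence length.
#'
#' @param mean_denovo mean de novo mutations observed per lineage.
#' @param generations generations over which they accumulated.
#' @param length_bp interrogated single-copy sequence length in bp.
#' @return mutation rate per site per generation.
#' @examples
#' estimate_mutation_rate(2.75, 28.3, 5.83e6)
#' @export
estimate_mutation_rate <- function(mean_denovo, generations, length_bp) {
  if (any(c(mean_denovo, generations, length_bp) <= 0))
    stop("all inputs must be positive")
  mean_denovo / generations / length_bp
}

#' Convert a per-generation rate to a per-year rate
#'
#' @param rate_per_gen mutation rate per site per generation.
#' @param interval_years mean generation interval in years.
#' @return mutation rate per site per year.
#' @examples
#' rate_per_year(1.69e-8, 10)
#' @export
rate_per_year <- function(rate_per_gen, interval_years) {
  if (interval_years <= 0) stop("interval_years must be positive")
  rate_per_gen / interval_years
}

#' Closed-form Poisson molecular-clock TMRCA
#'
#' Under a strict clock the mutations `k` accumulated on a lineage over
#' `t` years are Poisson with mean `L * mu_year * t`, so the point
#' estimate is `t = k / (L * rate_per_gen / interval_mid)` with
#' `interval_mid` the midpoint of the generation-interval range. The
#' confidence bounds combine the exact Poisson 95% interval on `k` with
#' the interval range, taking the envelope: the lower bound uses the
#' Poisson lower limit at the shortest interval, the upper bound the
#' Poisson upper limit at the longest.
#'
#' @param mutations observed mutation count since the coalescence point.
#' @param length_bp interrogated sequence length in bp.
#' @param rate_per_gen mutation rate per site per generation.
#' @param interval_low,interval_high generation-interval range in years.
#' @return list of class `tmrca_estimate`: `mutations`, `years`,
#'   `ci_low`, `ci_high`.
#' @examples
#' clock_tmrca(10, 5.83e6, 1.69e-8, 10, 10)
#' @export
clock_tmrca <- function(mutations, length_bp, rate_per_gen,
                        interval_low = 8, interval_high = 12) {
  stopifnot(mutations >= 0, mutations == round(mutations),
            length_bp > 0, rate_per_gen > 0,
            interval_low > 0, interval_high >= interval_low)
  mid <- (interval_low + interval_high) / 2
  lam <- length_bp * rate_per_gen    # mutations per generation
  years <- mutations / lam * mid
  k_lo <- if (mutations == 0) 0 else qgamma(0.025, mutations)
  k_hi <- qgamma(0.975, mutations + 1)
  structure(list(mutations = as.integer(mutations), years = years,
                 ci_low = k_lo / lam * interval_low,
                 ci_high = k_hi / lam * interval_high),
            class = "tmrca_estimate")
}

#' @export
print.tmrca_estimate <- function(x, ...) {
  cat(sprintf("TMRCA: %.0f years (95%% CI %.0f - %.0f; %d mutations)\n",
              x$years, x$ci_low, x$ci_high, x$mutations))
  invisible(x)
}
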