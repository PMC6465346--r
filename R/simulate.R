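# Synthetic-data generators: coverage tables with the three window
# classes, infinite-sites genealogies, and patriline pedigrees. All
# generators are pure functions of their parameters and seed.

#' Simulate a male/female window-coverage dataset
#'
#' Emulates the coverage signature of the three window classes: in a
#' nonMSY (diploid) window every sample's mean coverage is Poisson with
#' mean `c`; in an scY window males are haploid (mean `c/2`) and females
#' see only background; in an mcY window males carry `mcY_copies`
#' haploid copies (mean `copies * c/2`, so the expected relative
#' coverage `copies/2` clears the single-copy cutoff for `copies >= 3`)
#' and females again see background. Each class occupies its own contig
#' of consecutive windows.
#'
#' @param n_males,n_females sample counts (>= 1 each).
#' @param c_range range of the uniform draw for each sample's diploid
#'   calibration coverage.
#' @param background female background coverage in raw units; must be
#'   below `c_range[1] / 2`.
#' @param window_size window width in bp.
#' @param n_windows_per_class windows simulated for each class.
#' @param mcY_copies haploid copy number of mcY windows (>= 3).
#' @param overdispersion optional negative-binomial overdispersion
#'   (variance = mean * (1 + overdispersion)); 0 keeps the Poisson model.
#' @param seed RNG seed.
#' @return list: `windows` (data.frame `contig`, `start`, `end`, one
#'   coverage column per sample), `profiles` (from [sample_profiles()],
#'   carrying the true `c` and `b`), `truth` (factor of true labels).
#' @export
simulate_coverage <- function(n_males = 10L, n_females = 5L,
                              c_range = c(20, 40), background = 0.3,
                              window_size = 50L,
                              n_windows_per_class = 2000L,
                              mcY_copies = 3L, overdispersion = 0,
                              seed = 1L) {
  stopifnot(n_males >= 1, n_females >= 1, n_windows_per_class >= 1,
            mcY_copies >= 3, window_size >= 1, background >= 0,
            c_range[1] > 0, c_range[2] >= c_range[1], overdispersion >= 0)
  if (background >= c_range[1] / 2)
    stop("background must be < c_range[1] / 2")
  with_seed(seed, {
    ids <- c(paste0("M", seq_len(n_males)), paste0("F", seq_len(n_females)))
    sex <- rep(c("male", "female"), c(n_males, n_females))
    cc <- runif(length(ids), c_range[1], c_range[2])
    profiles <- sample_profiles(ids, sex, cc,
                                ifelse(sex == "female", background, NA_real_))
    classes <- c("scY", "mcY", "nonMSY")
    nw <- n_windows_per_class
    draw <- function(mean_vec) {
      m <- matrix(rep(mean_vec, each = nw), nrow = nw)
      if (overdispersion > 0)
        matrix(stats::rnbinom(length(m), mu = m, size = m / overdispersion),
               nrow = nw)
      else matrix(rpois(length(m), m), nrow = nw)
    }
    male <- sex == "male"
    mean_for <- function(class) {
      mv <- numeric(length(ids))
      mv[male] <- switch(class, nonMSY = cc[male], scY = cc[male] / 2,
                         mcY = mcY_copies * cc[male] / 2)
      mv[!male] <- if (class == "nonMSY") cc[!male] else background
      mv
    }
    blocks <- lapply(classes, function(cl) {
      Y <- draw(mean_for(cl))
      colnames(Y) <- ids
      data.frame(contig = paste0("sim_", cl),
                 start = (seq_len(nw) - 1L) * window_size,
                 end = seq_len(nw) * window_size, Y,
                 check.names = FALSE, stringsAsFactors = FALSE)
    })
    windows <- do.call(rbind, blocks)
    truth <- factor(rep(classes, each = nw), levels = classes)
    # consumers require (contig, start) order
    ord <- order(windows$contig, windows$start)
    windows <- windows[ord, , drop = FALSE]
    rownames(windows) <- NULL
    list(windows = windows, profiles = profiles, truth = truth[ord])
  })
}

#' Simulate an infinite-sites genealogy and haplotype matrix
#'
#' Drops mutations on a known rooted tree: each branch receives a
#' Poisson number of mutations, and every mutation creates a new site
#' derived in exactly the leaves below that branch — so the matrix
#' passes the four-gamete test by construction. An outgroup row
#' (all-ancestral) is appended; `outgroup_mutations` additional sites
#' are derived in every ingroup leaf, representing mutations on the stem
#' separating the outgroup.
#'
#' @param n_leaves number of ingroup leaves (ignored when `tree` is
#'   given).
#' @param expected_per_branch expected mutations per branch; a scalar or
#'   a vector over the tree's edges.
#' @param outgroup_mutations expected count of stem sites separating the
#'   outgroup from all ingroup leaves.
#' @param tree optional rooted `phylo` topology (e.g. `ape::stree`); by
#'   default a random rooted topology on `n_leaves` leaves.
#' @param samples_per_leaf number of identical sample rows emitted per
#'   leaf haplotype (several sequenced males typically share one MSY
#'   haplotype; nearest-neighbour imputation relies on this).
#' @param mask_fraction fraction of ingroup entries set missing.
#' @param scramble_polarity fraction of sites emitted with flipped
#'   ref/alt coding (the outgroup then reads 1), to exercise
#'   [polarize()].
#' @param outgroup_id name for the outgroup row.
#' @param seed RNG seed.
#' @return list: `matrix` (a [haplo_matrix()]; polarized when
#'   `scramble_polarity == 0`), `tree` (the simulating `phylo`, edge
#'   lengths = realised mutation counts), `site_edges` (edge index per
#'   site), `flipped_sites`, `masked` (index matrix of masked entries),
#'   `truth` (the unmasked, unscrambled state matrix).
#' @export
simulate_infinite_sites <- function(n_leaves = 10L, expected_per_branch = 5,
                                    outgroup_mutations = 0L, tree = NULL,
                                    samples_per_leaf = 1L,
                                    mask_fraction = 0,
                                    scramble_polarity = 0,
                                    outgroup_id = "OUT", seed = 1L) {
  stopifnot(mask_fraction >= 0, mask_fraction < 1,
            scramble_polarity >= 0, scramble_polarity <= 1,
            samples_per_leaf >= 1)
  with_seed(seed, {
    if (is.null(tree)) {
      tree <- ape::rtree(n_leaves, rooted = TRUE, br = NULL)
      tree$tip.label <- paste0("S", seq_len(n_leaves))
    }
    n_tip <- length(tree$tip.label)
    n_edge <- nrow(tree$edge)
    exp_mut <- rep_len(expected_per_branch, n_edge)
    counts <- rpois(n_edge, exp_mut)
    # leaves below each edge's child node
    tips_below <- function(node) {
      if (node <= n_tip) return(node)
      kids <- tree$edge[tree$edge[, 1] == node, 2]
      unlist(lapply(kids, tips_below))
    }
    below <- lapply(tree$edge[, 2], tips_below)

    n_stem <- if (outgroup_mutations > 0) rpois(1, outgroup_mutations) else 0L
    total <- sum(counts) + n_stem
    S <- matrix(0L, n_tip + 1L, total,
                dimnames = list(c(tree$tip.label, outgroup_id),
                                if (total > 0) sprintf("v%04d", seq_len(total))
                                else NULL))
    site_edges <- integer(0)
    col <- 0L
    for (e in seq_len(n_edge)) {
      if (counts[e] == 0) next
      for (j in seq_len(counts[e])) {
        col <- col + 1L
        S[below[[e]], col] <- 1L
        site_edges[col] <- e
      }
    }
    if (n_stem > 0) for (j in seq_len(n_stem)) {
      col <- col + 1L
      S[seq_len(n_tip), col] <- 1L
      site_edges[col] <- 0L   # stem
    }
    if (samples_per_leaf > 1) {
      rep_rows <- rep(seq_len(n_tip), each = samples_per_leaf)
      nm <- paste0(tree$tip.label[rep_rows], "_",
                   rep(seq_len(samples_per_leaf), n_tip))
      S <- rbind(S[rep_rows, , drop = FALSE], S[n_tip + 1L, , drop = FALSE])
      rownames(S) <- c(nm, outgroup_id)
      n_tip <- n_tip * samples_per_leaf
    }
    truth <- S
    flipped <- integer(0)
    if (scramble_polarity > 0 && total > 0) {
      flipped <- which(runif(total) < scramble_polarity)
      S[, flipped] <- 1L - S[, flipped]
    }
    masked <- matrix(integer(0), 0, 2)
    if (mask_fraction > 0 && total > 0) {
      idx <- which(runif(n_tip * total) < mask_fraction)
      masked <- cbind(((idx - 1) %% n_tip) + 1L,
                      ((idx - 1) %/% n_tip) + 1L)
      S[masked] <- NA_integer_
      keep <- colSums(!is.na(S)) > 0
      S <- S[, keep, drop = FALSE]
      truth <- truth[, keep, drop = FALSE]
      site_edges <- site_edges[keep]
      masked <- masked[keep[masked[, 2]], , drop = FALSE]
      masked[, 2] <- cumsum(keep)[masked[, 2]]
    }
    tree$edge.length <- as.numeric(counts)
    list(matrix = haplo_matrix(S, outgroup_id,
                               polarized = length(flipped) == 0),
         tree = tree, site_edges = site_edges, flipped_sites = flipped,
         masked = masked, truth = truth)
  })
}

#' Simulate a patriline pedigree
#'
#' Grows a single-founder patriline: each new male's father is drawn
#' uniformly from the `father_pool` most recently born individuals (a
#' stallion sires sons only during his lifetime, which is what makes
#' real studbook pedigrees tens of generations deep over a few
#' centuries) and his birth year is his father's plus a
#' truncated-normal generation interval (minimum 2 years). Acyclic by
#' construction; descendants for interval estimation are the childless
#' tips.
#'
#' @param n_tips number of descendants generated (pedigree size minus
#'   the founder).
#' @param interval_mean,interval_sd generation-interval distribution in
#'   years (`interval_mean > interval_sd >= 0`).
#' @param founder_birth founder's birth year.
#' @param founder_id founder's id.
#' @param father_pool fathers are drawn from this many most recently
#'   born individuals.
#' @param seed RNG seed.
#' @return data.frame of links: `father_id`, `son_id`, `father_birth`,
#'   `son_birth`.
#' @export
simulate_pedigree <- function(n_tips = 500L, interval_mean = 11,
                              interval_sd = 2, founder_birth = 1680L,
                              founder_id = "P1", father_pool = 25L,
                              seed = 1L) {
  stopifnot(n_tips >= 1, interval_mean > interval_sd, interval_sd >= 0,
            father_pool >= 1)
  with_seed(seed, {
    ids <- c(founder_id, paste0("P", seq_len(n_tips) + 1L))
    birth <- c(founder_birth, rep(NA_real_, n_tips))
    father <- rep(NA_integer_, n_tips + 1L)
    for (i in seq_len(n_tips) + 1L) {
      lo <- max(1L, i - 1L - father_pool + 1L)
      f <- if (lo == i - 1L) lo else sample(seq(lo, i - 1L), 1L)
      repeat {
        iv <- rnorm(1, interval_mean, interval_sd)
        if (iv >= 2) break
      }
      father[i] <- f
      birth[i] <- birth[f] + iv
    }
    kids <- seq_len(n_tips) + 1L
    data.frame(father_id = ids[father[kids]], son_id = ids[kids],
               father_birth = round(birth[father[kids]]),
               son_birth = round(birth[kids]), stringsAsFactors = FALSE)
  })
}
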