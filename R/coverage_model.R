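# Poisson likelihood-ratio classification of assembly windows into
# scY / mcY / nonMSY from male vs. female mapping coverage.
#
# All model arithmetic is done in RAW reads-depth units: y (window mean
# coverage), c (diploid calibration coverage, the mode of PAR window
# coverages) and b (female background) share the same unit. Relative
# coverage y/c is computed only for the scY/mcY cutoff and for reporting.

# Log-probability floor standing in for -Inf when a Poisson rate is zero
# but a positive count was observed (near log(.Machine$double.xmin)).
.LOG_FLOOR <- -745

#' Build a table of sample profiles
#'
#' A sample profile records, per sequenced individual, its sex, its diploid
#' calibration coverage `c` (raw reads-depth units; the mode of its mean
#' coverages over pseudoautosomal-region windows, where both sexes are
#' diploid) and, for females only, the background coverage `b` — the low
#' level of spurious female mapping onto true single-copy Y sequence.
#'
#' @param sample_id character vector of unique sample names.
#' @param sex character vector, `"male"` or `"female"`.
#' @param c positive numeric vector, diploid calibration coverage per
#'   sample.
#' @param b numeric vector of female background coverages (raw units);
#'   must be `NA` for males and finite for females. Background must sit
#'   far below the diploid signal: `b < c/2` is enforced.
#' @return a `data.frame` with columns `sample_id`, `sex`, `c`, `b`.
#' @examples
#' sample_profiles(c("M1", "F1"), c("male", "female"), c(30, 25), c(NA, 0.3))
#' @export
sample_profiles <- function(sample_id, sex, c, b = NA_real_) {
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  b <- rep_len(as.numeric(b), length(sample_id))
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id in profiles")
  if (length(sex) != length(sample_id) || length(c) != length(sample_id))
    stop("sample_id, sex and c must have equal length")
  if (any(!is.finite(c)) || any(c <= 0))
    stop("calibration coverage c must be finite and > 0 for every sample")
  fem <- sex == "female"
  if (any(!is.na(b[!fem])))
    stop("background b must be absent (NA) for males")
  if (any(is.na(b[fem])) || any(b[fem] < 0))
    stop("background b must be defined and >= 0 for every female")
  if (any(b[fem] >= 0.5 * c[fem]))
    stop("female background b must be < 0.5 * c (background far below diploid signal)")
  data.frame(sample_id = as.character(sample_id), sex = sex, c = c, b = b,
             stringsAsFactors = FALSE)
}

.check_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles),
            all(c("sample_id", "sex", "c", "b") %in% names(profiles)))
  if (!any(profiles$sex == "male") || !any(profiles$sex == "female"))
    stop("need at least one male and one female profile; ",
         "the coverage model is undefined without both sexes")
  invisible(profiles)
}

#' Classifier configuration
#'
#' @param window_size window width in bp used when tiling contigs.
#' @param posterior_threshold minimum posterior probability of the MSY
#'   class for a window to be called Y-specific; 0.5 corresponds to equal
#'   prior probabilities for the MSY and nonMSY classes.
#' @param scY_cutoff relative male coverage (diploid = 1) at or below
#'   which an MSY window is called single-copy; above it, multi-copy.
#' @param min_contig_len minimum contig length in bp retained by
#'   [filter_contigs()].
#' @param min_y_content minimum fraction of a contig's windows labelled
#'   scY or mcY for the contig to be retained.
#' @param min_window_sites windows narrower than this many sites are
#'   excluded from classification (a Poisson mean over very few sites is
#'   unstable).
#' @return a list of class `classifier_config`.
#' @export
classifier_config <- function(window_size = 50L,
                              posterior_threshold = 0.5,
                              scY_cutoff = 1.0,
                              min_contig_len = 300L,
                              min_y_content = 0.45,
                              min_window_sites = 10L) {
  stopifnot(window_size >= 1, posterior_threshold > 0, scY_cutoff > 0,
            min_contig_len > 0, min_y_content > 0, min_y_content < 1,
            min_window_sites >= 1)
  structure(list(window_size = as.integer(window_size),
                 posterior_threshold = posterior_threshold,
                 scY_cutoff = scY_cutoff,
                 min_contig_len = as.integer(min_contig_len),
                 min_y_content = min_y_content,
                 min_window_sites = as.integer(min_window_sites)),
            class = "classifier_config")
}

#' Estimate diploid calibration coverage from PAR windows
#'
#' The mode of the empirical distribution of mean coverages over
#' pseudoautosomal-region (PAR) windows. Both sexes carry two PAR copies,
#' so this mode measures the sample's diploid sequencing depth. The mode
#' is taken over a histogram with unit-width bins anchored at integers
#' (`[k, k+1)`); ties break toward the smaller bin and the bin's left
#' edge is returned.
#'
#' @param par_window_coverages numeric vector of mean window coverages.
#' @return the calibration coverage `c` (positive scalar).
#' @examples
#' estimate_diploid_calibration(c(30, 30, 30, 30))
#' @export
estimate_diploid_calibration <- function(par_window_coverages) {
  x <- par_window_coverages
  if (length(x) == 0) stop("no PAR window coverages supplied")
  if (any(!is.finite(x)) || any(x < 0))
    stop("PAR window coverages must be finite and >= 0")
  if (all(x == 0))
    stop("all PAR window coverages are zero; sample unusable for calibration")
  bins <- table(floor(x))
  mode_bin <- min(as.numeric(names(bins)[bins == max(bins)]))
  if (mode_bin <= 0)
    stop("modal PAR coverage bin is [0, 1); sample unusable for calibration")
  mode_bin
}

#' Estimate a female's background coverage over trusted scY windows
#'
#' Reads from females map spuriously at a low rate onto true single-copy
#' Y sequence. The background `b` for a female is her mean raw coverage
#' over a seed set of trusted scY windows.
#'
#' @param window_coverages the female's raw mean coverages over the seed
#'   scY windows.
#' @return `b`, a non-negative scalar in raw reads-depth units.
#' @examples
#' estimate_female_background(c(0, 0, 1, 0, 0, 0, 0, 0, 0, 1))
#' @export
estimate_female_background <- function(window_coverages) {
  x <- window_coverages
  if (length(x) == 0)
    stop("no seed scY windows supplied; cannot estimate female background ",
         "(provide a trusted scY BED or use classify_windows(two_pass = TRUE))")
  if (any(!is.finite(x)) || any(x < 0))
    stop("seed window coverages must be finite and >= 0")
  mean(x)
}

.split_profiles <- function(profiles) {
  list(males = profiles[profiles$sex == "male", , drop = FALSE],
       females = profiles[profiles$sex == "female", , drop = FALSE])
}

#' Per-window maximum-likelihood coverage estimates
#'
#' Under the MSY model a window is present in one copy on the Y: a male's
#' coverage is Poisson with mean `v * c/2` (haploid scale) and a female
#' sees only background `b`. Under the nonMSY model both sexes carry the
#' window in the diploid state: coverage is Poisson with mean `mu * c`.
#' The closed-form MLEs are `v_hat = sum(male y) / sum(male c/2)` and
#' `mu_hat = sum(all y) / sum(all c)`.
#'
#' @param y named numeric vector of raw mean window coverages, names are
#'   sample ids matching `profiles$sample_id`.
#' @param profiles profile table from [sample_profiles()].
#' @return list with elements `v_hat` and `mu_hat`.
#' @examples
#' p <- sample_profiles(c("M1", "F1"), c("male", "female"), c(20, 20), c(NA, 0.2))
#' fit_window_models(c(M1 = 10, F1 = 0), p)
#' @export
fit_window_models <- function(y, profiles) {
  .check_profiles(profiles)
  miss <- setdiff(profiles$sample_id, names(y))
  if (length(miss))
    stop("window has no coverage entry for sample(s): ",
         paste(miss, collapse = ", "))
  y <- y[profiles$sample_id]
  if (any(!is.finite(y)) || any(y < 0))
    stop("window coverages must be finite and >= 0")
  male <- profiles$sex == "male"
  list(v_hat = sum(y[male]) / sum(profiles$c[male] / 2),
       mu_hat = sum(y) / sum(profiles$c))
}

# Poisson log-kernel y*log(lambda) - lambda with 0*log(0) := 0 and the
# zero-rate guard (lambda == 0, y > 0) mapped to a finite floor.
.pois_kernel <- function(y, lambda) {
  out <- ifelse(lambda > 0, y * log(lambda) - lambda,
                ifelse(y > 0, .LOG_FLOOR, 0))
  out
}

#' Window log likelihood ratio and posterior MSY probability
#'
#' Evaluates the log of the ratio of the MSY-model likelihood (males at
#' haploid rate `v_hat * c/2`, females at background `b`) to the
#' nonMSY-model likelihood (everyone at diploid rate `mu_hat * c`).
#' Factorial terms cancel in the ratio and are omitted, so fractional
#' mean coverages need no rounding. Under equal priors the posterior MSY
#' probability is `plogis(log_lr)`.
#'
#' @inheritParams fit_window_models
#' @return list of class `window_fit`: `v_hat`, `mu_hat`, `log_lr`,
#'   `posterior_msy`, `male_rel_cov` (mean male `y/c`; diploid = 1).
#' @examples
#' p <- sample_profiles(c("M1", "F1"), c("male", "female"), c(20, 20), c(NA, 0.2))
#' window_log_lr(c(M1 = 10, F1 = 0), p)
#' @export
window_log_lr <- function(y, profiles) {
  fit <- fit_window_models(y, profiles)
  y <- y[profiles$sample_id]
  male <- profiles$sex == "male"
  cm <- profiles$c[male]; cf <- profiles$c[!male]
  ym <- y[male]; yf <- y[!male]
  b <- profiles$b[!male]
  ll_msy <- sum(.pois_kernel(ym, fit$v_hat * cm / 2)) +
    sum(.pois_kernel(yf, b))
  ll_non <- sum(.pois_kernel(ym, fit$mu_hat * cm)) +
    sum(.pois_kernel(yf, fit$mu_hat * cf))
  log_lr <- ll_msy - ll_non
  structure(list(v_hat = fit$v_hat, mu_hat = fit$mu_hat, log_lr = log_lr,
                 posterior_msy = plogis(log_lr),
                 male_rel_cov = mean(ym / cm)),
            class = "window_fit")
}

#' Classify windows into scY, mcY and nonMSY
#'
#' Applies the likelihood-ratio model to every window. A window is
#' nonMSY when its posterior MSY probability falls below
#' `config$posterior_threshold`; otherwise it is scY when the mean male
#' relative coverage (`y/c`, diploid = 1) is at or below
#' `config$scY_cutoff`, else mcY. Windows narrower than
#' `config$min_window_sites` bp are dropped with a warning.
#'
#' @param windows data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) plus one raw-coverage column per sample id.
#' @param profiles profile table from [sample_profiles()]; every
#'   profiled sample must have a coverage column.
#' @param config a [classifier_config()].
#' @param two_pass if `TRUE` and some female has `b = NA`, run a first
#'   pass with `b` initialised to `0.1 * c`, re-estimate each female's
#'   background from first-pass scY windows, and reclassify once.
#' @return data.frame with one row per classified window: coordinates,
#'   `v_hat`, `mu_hat`, `log_lr`, `posterior_msy`, `male_rel_cov`,
#'   `label` (factor scY/mcY/nonMSY).
#' @export
classify_windows <- function(windows, profiles, config = classifier_config(),
                             two_pass = FALSE) {
  .check_profiles(profiles)
  stopifnot(all(c("contig", "start", "end") %in% names(windows)))
  miss <- setdiff(profiles$sample_id, names(windows))
  if (length(miss))
    stop("coverage table has no column for sample(s): ",
         paste(miss, collapse = ", "))

  if (any(is.na(profiles$b[profiles$sex == "female"]))) {
    if (!two_pass)
      stop("female background b missing; supply it or set two_pass = TRUE")
    prof1 <- profiles
    fem <- prof1$sex == "female"
    prof1$b[fem] <- 0.1 * prof1$c[fem]
    pass1 <- classify_windows(windows, prof1, config, two_pass = FALSE)
    scy <- pass1$label == "scY"
    if (!any(scy))
      stop("two-pass background estimation found no scY windows in pass one")
    key <- paste(windows$contig, windows$start)
    seed <- key %in% paste(pass1$contig[scy], pass1$start[scy])
    for (i in which(fem))
      profiles$b[i] <- estimate_female_background(windows[[prof1$sample_id[i]]][seed])
    return(classify_windows(windows, profiles, config, two_pass = FALSE))
  }

  wide <- windows[, c("contig", "start", "end"), drop = FALSE]
  short <- (wide$end - wide$start) < config$min_window_sites
  if (any(short)) {
    warning(sum(short), " window(s) narrower than ", config$min_window_sites,
            " sites dropped from classification")
    windows <- windows[!short, , drop = FALSE]
    wide <- wide[!short, , drop = FALSE]
  }
  Y <- as.matrix(windows[, profiles$sample_id, drop = FALSE])
  if (any(!is.finite(Y)) || any(Y < 0))
    stop("window coverages must be finite and >= 0")

  male <- profiles$sex == "male"
  cm <- profiles$c[male]; cf <- profiles$c[!male]; b <- profiles$b[!male]
  Ym <- Y[, male, drop = FALSE]; Yf <- Y[, !male, drop = FALSE]

  v_hat <- rowSums(Ym) / sum(cm / 2)
  mu_hat <- rowSums(Y) / sum(profiles$c)

  lam_msy_m <- outer(v_hat, cm / 2)
  lam_non_m <- outer(mu_hat, cm)
  lam_non_f <- outer(mu_hat, cf)
  lam_msy_f <- matrix(b, nrow(Y), length(b), byrow = TRUE)

  ll_msy <- rowSums(.pois_kernel(Ym, lam_msy_m)) +
    rowSums(.pois_kernel(Yf, lam_msy_f))
  ll_non <- rowSums(.pois_kernel(Ym, lam_non_m)) +
    rowSums(.pois_kernel(Yf, lam_non_f))
  log_lr <- ll_msy - ll_non
  posterior <- plogis(log_lr)
  mrc <- rowMeans(sweep(Ym, 2, cm, `/`))

  label <- ifelse(posterior < config$posterior_threshold, "nonMSY",
                  ifelse(mrc <= config$scY_cutoff, "scY", "mcY"))
  data.frame(wide, v_hat = v_hat, mu_hat = mu_hat, log_lr = log_lr,
             posterior_msy = posterior, male_rel_cov = mrc,
             label = factor(label, levels = c("scY", "mcY", "nonMSY")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter contigs by Y-specific content and length
#'
#' A contig is retained when at least `min_y_content` of its classified
#' windows are Y-specific (scY or mcY) and its length is at least
#' `min_contig_len`. Contigs present in `contig_lengths` but carrying no
#' classified window are discarded with a warning.
#'
#' @param classes output of [classify_windows()].
#' @param contig_lengths named numeric vector of contig lengths in bp.
#' @param config a [classifier_config()].
#' @return list with `kept` (character vector of contig names) and
#'   `summary` (per-contig data.frame: length, window counts, Y-content
#'   fraction, scY/mcY/nonMSY bp totals, kept flag).
#' @export
filter_contigs <- function(classes, contig_lengths,
                           config = classifier_config()) {
  stopifnot(!is.null(names(contig_lengths)))
  empty <- setdiff(names(contig_lengths), unique(classes$contig))
  if (length(empty))
    warning("contig(s) with zero classified windows discarded: ",
            paste(empty, collapse = ", "))
  unknown <- setdiff(unique(classes$contig), names(contig_lengths))
  if (length(unknown))
    stop("classified windows on contig(s) without a length: ",
         paste(unknown, collapse = ", "))

  bp <- classes$end - classes$start
  agg <- function(lab) {
    v <- tapply(bp * (classes$label == lab), classes$contig, sum)
    v[is.na(v)] <- 0
    v
  }
  n_win <- tapply(rep(1, nrow(classes)), classes$contig, sum)
  n_msy <- tapply(classes$label %in% c("scY", "mcY"), classes$contig, sum)
  contigs <- names(n_win)
  y_frac <- as.numeric(n_msy[contigs] / n_win[contigs])
  len <- contig_lengths[contigs]
  kept <- y_frac >= config$min_y_content & len >= config$min_contig_len
  summary <- data.frame(
    contig = contigs, length = as.numeric(len),
    n_windows = as.integer(n_win[contigs]), y_content = y_frac,
    scY_bp = as.numeric(agg("scY")[contigs]),
    mcY_bp = as.numeric(agg("mcY")[contigs]),
    nonMSY_bp = as.numeric(agg("nonMSY")[contigs]),
    kept = kept, row.names = NULL, stringsAsFactors = FALSE)
  list(kept = contigs[kept], summary = summary)
}
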