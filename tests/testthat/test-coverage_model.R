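# Coverage-model unit and property tests.

test_that("diploid calibration is the unit-bin histogram mode", {
  expect_equal(estimate_diploid_calibration(rep(30, 4)), 30)
  expect_equal(estimate_diploid_calibration(c(rep(30, 10), rep(60, 5))), 30)
  # tie breaks toward the smaller bin
  expect_equal(estimate_diploid_calibration(c(rep(30, 5), rep(60, 5))), 30)
  expect_error(estimate_diploid_calibration(numeric(0)), "no PAR")
  expect_error(estimate_diploid_calibration(c(0, 0, 0)), "zero")

  # oracle: histogram argmax with unit bins on the same draws
  set.seed(1)
  draws <- rpois(1000, 30)
  oracle <- as.numeric(names(which.max(table(floor(draws)))))
  got <- estimate_diploid_calibration(draws)
  expect_equal(got, oracle)
  expect_gte(got, 28); expect_lte(got, 32)
})

test_that("female background is the seed-window mean", {
  expect_equal(estimate_female_background(c(0, 0, 1, 0, 0, 0, 0, 0, 0, 1)), 0.2)
  expect_equal(estimate_female_background(rep(0, 8)), 0)
  expect_error(estimate_female_background(numeric(0)), "seed")
  set.seed(5)
  x <- rpois(5000, 0.3)
  b <- estimate_female_background(x)
  expect_gte(b, 0.27); expect_lte(b, 0.33)
  expect_equal(b, mean(x))  # direct-mean oracle
})

test_that("profile invariants are enforced", {
  expect_error(sample_profiles("M1", "male", 0), "c must be")
  expect_error(sample_profiles("F1", "female", 20, NA), "defined")
  expect_error(sample_profiles("F1", "female", 20, 15), "b must be <")
  expect_error(sample_profiles("M1", "male", 20, 0.2), "absent")
})

two_sample_profiles <- function(b = 0.2)
  sample_profiles(c("M1", "F1"), c("male", "female"), c(20, 20), c(NA, b))

test_that("per-window MLEs take their closed forms", {
  p <- two_sample_profiles()
  fit <- fit_window_models(c(M1 = 10, F1 = 0), p)
  expect_equal(fit$v_hat, 1.0)
  expect_equal(fit$mu_hat, 0.25)
  expect_equal(fit_window_models(c(M1 = 0, F1 = 0), p),
               list(v_hat = 0, mu_hat = 0))
  p4 <- sample_profiles(c("M1", "M2", "F1", "F2"),
                        c("male", "male", "female", "female"),
                        rep(20, 4), c(NA, NA, 0.2, 0.2))
  fit4 <- fit_window_models(c(M1 = 10, M2 = 10, F1 = 10, F2 = 10), p4)
  expect_equal(fit4$v_hat, 1.0)
  expect_equal(fit4$mu_hat, 0.5)
  expect_error(fit_window_models(c(M1 = 1), p), "coverage entry")
  p_m <- data.frame(sample_id = "M1", sex = "male", c = 20, b = NA)
  expect_error(fit_window_models(c(M1 = 1), p_m), "male and")
})

test_that("log likelihood ratio matches hand-derived values", {
  p <- two_sample_profiles()
  f <- window_log_lr(c(M1 = 10, F1 = 0), p)
  expect_equal(f$log_lr, 10 * log(2) - 0.2, tolerance = 1e-12)
  expect_equal(f$posterior_msy, plogis(10 * log(2) - 0.2))
  f2 <- window_log_lr(c(M1 = 20, F1 = 20), p)
  expect_equal(f2$log_lr, 20 * log(0.01) + 19.8, tolerance = 1e-12)
  expect_lt(f2$posterior_msy, 1e-20)
  # equal likelihoods: v_hat = 2 * mu_hat makes the male rates agree and
  # b = mu_hat * c_f makes the female rates agree -> log_lr exactly 0
  p_eq <- sample_profiles(c("M1", "F1"), c("male", "female"), c(20, 30),
                          c(NA, 9))
  f3 <- window_log_lr(c(M1 = 6, F1 = 9), p_eq)
  expect_equal(f3$log_lr, 0, tolerance = 1e-12)
  expect_equal(f3$posterior_msy, 0.5)
})

test_that("log_lr equals the literally transcribed ratio with factorials", {
  set.seed(99)
  for (i in 1:100) {
    nm <- sample(1:4, 1); nf <- sample(1:4, 1)
    p <- sample_profiles(
      c(paste0("M", seq_len(nm)), paste0("F", seq_len(nf))),
      rep(c("male", "female"), c(nm, nf)),
      sample(10:40, nm + nf, replace = TRUE),
      c(rep(NA, nm), runif(nf, 0.05, 2)))
    y <- setNames(c(rpois(nm, 12), rpois(nf, 1)) + 0, p$sample_id)
    if (sum(y) == 0) next
    expect_equal(window_log_lr(y, p)$log_lr, log_lr_literal(y, p),
                 tolerance = 1e-9)
  }
})

test_that("posterior is a probability and responds monotonically", {
  set.seed(7)
  p <- sample_profiles(c("M1", "M2", "F1"), c("male", "male", "female"),
                       c(22, 30, 26), c(NA, NA, 0.4))
  for (i in 1:50) {
    y <- setNames(rpois(3, c(12, 16, 2)), p$sample_id)
    f <- window_log_lr(y, p)
    expect_gte(f$posterior_msy, 0); expect_lte(f$posterior_msy, 1)
    # raising a female's coverage lowers log_lr whenever b < mu_hat * c
    y2 <- y; y2["F1"] <- y["F1"] + 1
    f2 <- window_log_lr(y2, p)
    if (p$b[3] < f2$mu_hat * p$c[3]) expect_lt(f2$log_lr, f$log_lr)
  }
})

test_that("high-confidence labels are scale invariant", {
  sim <- simulate_coverage(n_windows_per_class = 150, seed = 11)
  cl1 <- classify_windows(sim$windows, sim$profiles)
  k <- 3
  w2 <- sim$windows
  w2[sim$profiles$sample_id] <- w2[sim$profiles$sample_id] * k
  p2 <- sim$profiles; p2$c <- p2$c * k; p2$b <- p2$b * k
  cl2 <- classify_windows(w2, p2)
  high <- abs(cl1$log_lr) > 5
  expect_true(all(cl1$label[high] == cl2$label[high]))
})

test_that("classification rules route posteriors and relative coverage", {
  # one male, one female, c = 20; craft windows hitting each rule
  p <- two_sample_profiles(b = 0.2)
  win <- data.frame(contig = "c", start = c(0, 50, 100) * 1L,
                    end = c(50, 100, 150) * 1L,
                    M1 = c(10, 36, 20), F1 = c(0, 0, 20))
  cl <- classify_windows(win, p)
  expect_equal(as.character(cl$label), c("scY", "mcY", "nonMSY"))
  expect_gt(cl$posterior_msy[1], 0.99)
  expect_lte(cl$male_rel_cov[1], 1)
  expect_gt(cl$male_rel_cov[2], 1)
  expect_lt(cl$posterior_msy[3], 0.5)
})

test_that("classify_windows validates input and drops tiny windows", {
  p <- two_sample_profiles()
  win <- data.frame(contig = "c", start = 0L, end = 50L, M1 = 10)
  expect_error(classify_windows(win, p), "F1")
  win2 <- data.frame(contig = "c", start = c(0L, 50L), end = c(50L, 55L),
                     M1 = c(10, 1), F1 = c(0, 0))
  expect_warning(cl <- classify_windows(win2, p), "narrower")
  expect_equal(nrow(cl), 1L)
})

test_that("two-pass background estimation recovers b and labels", {
  sim <- simulate_coverage(n_windows_per_class = 400, seed = 23)
  p0 <- sim$profiles
  p0$b[p0$sex == "female"] <- NA
  expect_error(classify_windows(sim$windows, p0), "two_pass")
  cl <- classify_windows(sim$windows, p0, two_pass = TRUE)
  expect_gt(mean(as.character(cl$label) == as.character(sim$truth)), 0.97)
})

test_that("contig filtering applies Y-content and length thresholds", {
  mk <- function(contig, n, n_msy, wsize = 50L) {
    data.frame(contig = contig, start = (seq_len(n) - 1L) * wsize,
               end = seq_len(n) * wsize,
               label = factor(rep(c("scY", "nonMSY"), c(n_msy, n - n_msy)),
                              levels = c("scY", "mcY", "nonMSY")),
               posterior_msy = 0.9)
  }
  classes <- rbind(mk("keep60", 20, 12),   # 60% MSY, 1000 bp
                   mk("short", 5, 5),      # 100% MSY but 250 bp
                   mk("low40", 20, 8),     # 40% MSY
                   mk("edge45", 20, 9),    # exactly 45% -> kept
                   mk("edge300", 6, 6))    # exactly 300 bp -> kept
  lens <- c(keep60 = 1000, short = 250, low40 = 1000, edge45 = 1000,
            edge300 = 300, empty = 5000)
  expect_warning(fc <- filter_contigs(classes, lens), "zero classified")
  expect_setequal(fc$kept, c("keep60", "edge45", "edge300"))
  s <- fc$summary[fc$summary$contig == "keep60", ]
  expect_equal(s$scY_bp, 12 * 50)
  expect_equal(s$nonMSY_bp, 8 * 50)
})
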