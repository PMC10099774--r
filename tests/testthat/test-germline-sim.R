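test_that("parameter validation enforces the model's invariants", {
  expect_error(sim_params(65, mu = 1e-10, selection_s = 0.5), "selection_s")
  expect_error(sim_params(65, mu = -1), "mu")
  p <- sim_params(65, mu = 1e-10)
  expect_equal(p$n_ssc, 2^30)
  expect_equal(p$n_pieces, 192L)
  expect_equal(adult_cycles(p), floor((65 - 13) * 365.25 / 16))
  expect_equal(adult_cycles(sim_params(10, mu = 0)), 0L)  # pre-puberty
})

test_that("neutral lineage survival follows the extinction recursion", {
  # q_{t+1} = 0.5 + 0.5 q_t^2, survival = 1 - q_t; Monte Carlo within 3 SE
  surv_mc <- function(s, t, n, seed) {
    set.seed(seed)
    cnt <- rep(1, n)
    for (j in seq_len(t)) {
      idx <- which(cnt > 0)
      if (!length(idx)) break
      cnt[idx] <- 2 * rbinom(length(idx), cnt[idx], 0.5 + s)
    }
    mean(cnt > 0)
  }
  for (t in c(10L, 100L)) {
    q <- 0
    for (i in seq_len(t)) q <- 0.5 + 0.5 * q^2
    n <- 20000L
    est <- surv_mc(0, t, n, seed = t)
    se <- sqrt((1 - q) * q / n)
    expect_lt(abs(est - (1 - q)), 3 * se)
  }
  # supercritical: ultimate survival 1 - (0.5 - s)/(0.5 + s) = 1/3 at s = 0.1
  est <- surv_mc(0.1, 300L, 20000L, seed = 42)
  expect_lt(abs(est - 1 / 3), 3 * sqrt(est * (1 - est) / 20000))
})

test_that("zero mutation rate produces an empty mutant pool", {
  p <- sim_params(65, mu = 0, seed = 1L)
  tst <- simulate_testis(p)
  expect_true(all(tst$piece_fraction == 0))
  expect_equal(tst$sperm_fraction, 0)
  expect_equal(sperm_variant_fraction(p, n_reps = 3L), rep(0, 3))
  expect_equal(expected_sperm_fraction(p), 0)
})

test_that("neutral mutant frequency is a martingale matching closed form", {
  # E[freq] = mu (T + G/2) under neutrality; check at two ages
  mu <- 2e-9
  for (age in c(30, 65)) {
    p <- sim_params(age, mu = mu, seed = age)
    n <- 4000L
    st <- simulate_variant_stats(p, n, background = 0)
    expct <- mu * (adult_cycles(p) + p$growth_generations / 2)
    se <- sd(st$avg) / sqrt(n)
    expect_lt(abs(mean(st$avg) - expct), 4 * se)
  }
})

test_that("selection inflates the sperm fraction relative to neutral", {
  mu <- 5e-10
  n <- 600L
  set.seed(7)
  sel <- sperm_variant_fraction(sim_params(65, mu = mu, selection_s = 0.01),
                                n_reps = n)
  set.seed(7)
  neu <- sperm_variant_fraction(sim_params(65, mu = mu), n_reps = n)
  expect_gt(mean(sel), mean(neu))
})

test_that("selection-model mean frequency matches the closed form", {
  # moderate age keeps the jackpot skew mild enough for Monte-Carlo checks
  p <- sim_params(26, mu = 2e-9, selection_s = 0.01, seed = 8L)
  n <- 10000L
  st <- simulate_variant_stats(p, n, background = 0)
  expct <- expected_sperm_fraction(p, 26) / (1 - 2 * p$selection_s)
  se <- sd(st$avg) / sqrt(n)
  expect_lt(abs(mean(st$avg) - expct), 4 * se)
})

test_that("expected sperm fraction grows linearly in divisions when neutral", {
  p <- sim_params(65, mu = 3e-10)
  ages <- c(20, 30, 40, 50, 60)
  ef <- vapply(ages, function(a) expected_sperm_fraction(p, a), numeric(1))
  cyc <- vapply(ages, function(a) adult_cycles(p, a), numeric(1))
  fit <- lm(ef ~ cyc)
  expect_equal(unname(coef(fit)[2]), 3e-10, tolerance = 1e-3)
})

test_that("piece placement conserves cells and keeps clones contiguous", {
  n_ssc <- 2^20
  # single clone smaller than one piece: exactly one nonzero piece
  one <- map_to_pieces(data.frame(count = 1000, anchor = 0.37),
                       n_pieces = 192L, n_ssc = n_ssc)
  expect_equal(sum(one > 0), 1L)
  expect_equal(sum(one) * n_ssc / 192, 1000)
  # clone of 2.5 piece-widths: 3 or 4 adjacent pieces, cells conserved
  w <- 2.5 * n_ssc / 192
  multi <- map_to_pieces(data.frame(count = w, anchor = 0.5),
                         n_pieces = 192L, n_ssc = n_ssc)
  nz <- which(multi > 0)
  expect_true(length(nz) %in% c(3L, 4L))
  expect_true(all(diff(nz) == 1L))
  expect_equal(sum(multi) * n_ssc / 192, w)
  # anchors near 1 wrap around the circular axis without losing cells
  wrap <- map_to_pieces(data.frame(count = w, anchor = 0.999),
                        n_pieces = 192L, n_ssc = n_ssc)
  expect_equal(sum(wrap) * n_ssc / 192, w, tolerance = 1e-9)
  # empty pool
  expect_equal(map_to_pieces(data.frame(count = numeric(), anchor = numeric()),
                             192L, n_ssc), numeric(192))
})

test_that("sequencing sampling has binomial mean and respects bounds", {
  p <- sim_params(65, mu = 0)
  # fraction 0, background 0: all zero
  z <- sample_sequencing(numeric(192), p, background = 0)
  expect_true(all(z$mutant_families == 0L))
  # fraction 1: every family mutant
  o <- sample_sequencing(rep(1, 4), p, background = 0)
  expect_true(all(o$mutant_families == o$total_families))
  # background 3.3e-6 at 64,000 families: mean count 0.211 per piece
  set.seed(30)
  cnt <- replicate(60, sum(sample_sequencing(numeric(192), p,
                                             background = 3.3e-6)$mutant_families))
  expct <- 3.3e-6 * 64000 * 192
  expect_lt(abs(mean(cnt) - expct) / expct, 0.2)
  expect_error(sample_sequencing(numeric(4), p, mutation_type = "X>Y"),
               "unknown mutation type")
})

test_that("fixed seeds give bit-identical simulated testes", {
  p <- sim_params(65, mu = 1e-9, selection_s = 0.002, seed = 77L)
  a <- simulate_testis(p)
  b <- simulate_testis(p)
  expect_identical(a$counts, b$counts)
  expect_identical(a$piece_fraction, b$piece_fraction)
})

test_that("birth-rate prediction is linear in sites and needs calibration", {
  p <- sim_params(65, mu = 1e-10, selection_s = 0.0025)
  expect_error(predict_birth_rate(p), "not calibrated")
  r1 <- predict_birth_rate(p, n_sites = 1, allow_uncalibrated = TRUE)
  r110 <- predict_birth_rate(p, n_sites = 110, allow_uncalibrated = TRUE)
  expect_equal(r110, 110 * r1)
  p0 <- sim_params(65, mu = 0)
  expect_equal(predict_birth_rate(p0, allow_uncalibrated = TRUE), 0)
  # donor-age default weights 65 and 68 equally
  expect_equal(predict_birth_rate(p, allow_uncalibrated = TRUE),
               110 * mean(c(expected_sperm_fraction(p, 65),
                            expected_sperm_fraction(p, 68))))
})
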