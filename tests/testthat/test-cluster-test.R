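test_that("pooled average frequency reproduces the worked examples", {
  # 175 mutant families among 10 million
  tab <- table_from_counts(c(175, rep(0, 191)), totals = 10e6 / 192)
  expect_equal(pooled_average_frequency(tab, 45L, "G"), 1.75e-5)
  tab1 <- table_from_counts(c(1, rep(0, 191)), totals = 10e6 / 192)
  expect_equal(pooled_average_frequency(tab1, 45L, "G"), 1.0e-7)
  tab0 <- table_from_counts(rep(0, 192), totals = 64000)
  expect_equal(pooled_average_frequency(tab0, 45L, "G"), 0)
})

test_that("pooled average equals the count-weighted mean of piece rates", {
  set.seed(31)
  tot <- sample(1000:64000, 192, replace = TRUE)
  mut <- rbinom(192, tot, 1e-4)
  tab <- table_from_counts(mut, tot)
  avg <- pooled_average_frequency(tab, 45L, "G")
  w <- tot / sum(tot)
  expect_equal(avg, sum(w * (mut / tot)))
})

test_that("MaxPF equals an exhaustive scan with deterministic tie-break", {
  set.seed(32)
  mut <- rbinom(192, 64000, 2e-5)
  tab <- table_from_counts(mut, 64000)
  res <- max_piece_frequency(tab, 45L, "G")
  expect_equal(res$maxpf, max(mut) / 64000)
  first <- which(mut == max(mut))[1]
  expect_equal(res$piece$slice, ((first - 1) %/% 32) + 1)
  expect_equal(res$piece$piece, ((first - 1) %% 32) + 1)
  # all-zero table ties break to the first piece
  tz <- table_from_counts(rep(0, 192), 64000)
  rz <- max_piece_frequency(tz, 45L, "G")
  expect_equal(rz$maxpf, 0)
  expect_equal(unlist(rz$piece[, c("slice", "piece")], use.names = FALSE),
               c(1L, 1L))
})

test_that("missing pieces are excluded; fully missing variants warn", {
  mut <- c(500, rep(0, 191))                       # large count in piece 1
  miss <- c(TRUE, rep(FALSE, 191))                 # but piece 1 is missing
  tab <- table_from_counts(mut, 64000, missing = miss)
  expect_equal(pooled_average_frequency(tab, 45L, "G"), 0)
  expect_equal(max_piece_frequency(tab, 45L, "G")$maxpf, 0)
  allmiss <- table_from_counts(mut, 64000, missing = rep(TRUE, 192))
  expect_warning(v <- pooled_average_frequency(allmiss, 45L, "G"), "missing")
  expect_true(is.na(v))
  # MaxPF >= pooled average when every piece shares one total
  set.seed(33)
  m2 <- rbinom(192, 64000, 5e-5)
  t2 <- table_from_counts(m2, 64000)
  expect_gte(max_piece_frequency(t2, 45L, "G")$maxpf,
             pooled_average_frequency(t2, 45L, "G"))
})

test_that("cluster_statistics agrees with the per-variant operations", {
  set.seed(34)
  tabs <- do.call(rbind, lapply(c("d1", "d2"), function(d)
    table_from_counts(rbinom(192, 64000, 1e-5), 64000, donor = d)))
  cs <- cluster_statistics(tabs)
  expect_equal(nrow(cs), 2L)
  for (d in unique(tabs$donor)) {
    expect_equal(cs$avg[cs$donor == d],
                 pooled_average_frequency(tabs[tabs$donor == d, ], 45L, "G"))
    expect_equal(cs$maxpf[cs$donor == d],
                 max_piece_frequency(tabs[tabs$donor == d, ], 45L, "G")$maxpf)
  }
})

test_that("envelope quantiles, monotonicity and tail follow the design", {
  # one bin: threshold equals the direct empirical quantile
  st <- data.frame(avg = rep(2e-6, 10),
                   maxpf = c(1, 2, 2, 3, 3, 3, 4, 4, 5, 9) * 1e-4)
  env <- build_envelope(st, K = 1L, alpha = 0.01, bins = 2L,
                        bin_range = c(1e-6, 4e-6), min_bin = 5L)
  expect_equal(unname(env$thresholds),
               unname(quantile(st$maxpf, 0.99, type = 1)))
  expect_equal(envelope_threshold(env, env$centers),
               unname(env$thresholds))
  # constant MaxPF: threshold equals that constant
  stc <- data.frame(avg = rep(2e-6, 200), maxpf = rep(3e-4, 200))
  envc <- build_envelope(stc, K = 1L, alpha = 0.01, bins = 2L,
                         bin_range = c(1e-6, 4e-6))
  expect_equal(envelope_threshold(envc, envc$centers), 3e-4)
  # monotone thresholds across bins, slope-one tail above the top center
  st2 <- data.frame(avg = c(rep(2e-6, 500), rep(2e-5, 500)),
                    maxpf = c(runif(500, 0, 1e-4), runif(500, 0, 1e-3)))
  env2 <- build_envelope(st2, K = 10L, alpha = 0.01, bins = 10L,
                         bin_range = c(1e-6, 1e-4))
  grid_avg <- 10^seq(-6, -3.5, by = 0.1)
  thr <- envelope_threshold(env2, grid_avg)
  expect_true(all(diff(thr) >= -1e-15))
  top <- max(env2$centers)
  expect_equal(envelope_threshold(env2, 100 * top),
               100 * envelope_threshold(env2, top))
  # sparse-only input fails
  expect_error(build_envelope(data.frame(avg = 1e-6, maxpf = 1e-4), K = 1L),
               "supply more simulations")
})

test_that("classification flags only MaxPF above the envelope", {
  st <- data.frame(avg = rep(2e-6, 1000), maxpf = runif(1000, 0, 1e-4))
  env <- build_envelope(st, K = 1L, alpha = 0.01, bins = 2L,
                        bin_range = c(1e-6, 4e-6))
  thr <- envelope_threshold(env, 2e-6)
  cl <- classify_variant(c(2e-6, 2e-6, 2e-6), c(0, thr, 2 * thr), env)
  expect_equal(cl$significant, c(FALSE, FALSE, TRUE))  # strict exceedance
})

test_that("enrichment test reproduces the study's contingency structure", {
  reg <- tiny_registry()
  sites <- as.data.frame(reg$sites)
  ann <- sites$cds_label[sites$category != "none"]          # 50 variants
  oth <- sites$cds_label[sites$category == "none"]          # 331 variants
  # two testes: 25/100 annotated significant, 2/662 others significant
  calls <- data.frame(
    cds_label = c(rep(ann, 2), rep(oth, 2)),
    significant = c(rep(c(TRUE, FALSE), c(25, 75)),
                    rep(c(TRUE, FALSE), c(2, 660))))
  res <- enrichment_test(calls, reg)
  expect_equal(unname(res$table["annotated", ]), c(25, 75))
  expect_equal(unname(res$table["other", ]), c(2, 660))
  expect_lt(res$p, 2.2e-16)
  # empty stratum: table reported, p undefined
  res0 <- enrichment_test(data.frame(cds_label = ann,
                                     significant = rep(FALSE, 50)), reg)
  expect_true(is.na(res0$p))
})

test_that("envelope files round-trip through the TSV format", {
  st <- data.frame(avg = runif(500, 1.1e-6, 3.9e-6),
                   maxpf = runif(500, 0, 1e-4))
  env <- build_envelope(st, K = 762L, alpha = 0.01, bins = 4L,
                        bin_range = c(1e-6, 1e-5))
  f <- tempfile(fileext = ".tsv")
  write_envelope(env, f)
  env2 <- read_envelope(f)
  expect_equal(env2$centers, env$centers)
  expect_equal(env2$thresholds, env$thresholds)
  expect_equal(env2$K, env$K)
  q <- c(1.5e-6, 3e-6, 1e-5, 1e-4)
  expect_equal(envelope_threshold(env2, q), envelope_threshold(env, q))
})

test_that("a stricter envelope can only reduce false positives", {
  st <- data.frame(avg = rep(2e-6, 1000), maxpf = runif(1000, 0, 1e-4))
  env <- build_envelope(st, K = 1L, alpha = 0.01, bins = 2L,
                        bin_range = c(1e-6, 4e-6))
  env_inf <- env
  env_inf$thresholds[] <- Inf
  gen <- function(reps) data.frame(rep_id = rep(seq_len(reps), each = 5),
                                   avg = 2e-6,
                                   maxpf = runif(5 * reps, 0, 1e-4))
  set.seed(35)
  base_rate <- measure_type_one_error(env, gen, 200L)$fwer
  set.seed(35)
  zero_rate <- measure_type_one_error(env_inf, gen, 200L)$fwer
  expect_equal(zero_rate, 0)
  expect_lte(zero_rate, base_rate)
  expect_error(measure_type_one_error(env, gen, 50L), ">= 100")
})
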