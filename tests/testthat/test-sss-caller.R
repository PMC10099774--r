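test_that("barcode correction assigns at distance <= 1 and discards beyond", {
  bcs <- make_barcodes(6L, seed = 4L)
  map <- barcode_map(data.frame(barcode = bcs, donor = "d1",
                                slice = 1L, piece = seq_along(bcs)))
  # exact match
  expect_equal(correct_barcode(bcs, map), seq_along(bcs))
  # one error: corrected to the unique whitelist entry
  mut1 <- bcs
  substr(mut1, 3, 3) <- ifelse(substr(bcs, 3, 3) == "A", "C", "A")
  expect_equal(correct_barcode(mut1, map), seq_along(bcs))
  # two errors: discarded (never misassigned, guaranteed by distance >= 3)
  mut2 <- mut1
  substr(mut2, 7, 7) <- ifelse(substr(mut1, 7, 7) == "G", "T", "G")
  expect_true(all(is.na(correct_barcode(mut2, map))))
  # N counts as a mismatch but a single N is still correctable
  mutN <- bcs
  substr(mutN, 1, 1) <- "N"
  expect_equal(correct_barcode(mutN, map), seq_along(bcs))
})

test_that("whitelists violating the distance floor are rejected", {
  expect_error(barcode_map(data.frame(
    barcode = c("AAAAAAAA", "AAAAAAAT"), donor = "d1", slice = 1,
    piece = 1:2)), "Hamming")
  expect_error(barcode_map(data.frame(
    barcode = c("AAAAAAAA", "AAAAAAAA"), donor = "d1", slice = 1,
    piece = 1:2)), "duplicate")
})

test_that("UID-family grouping matches a brute-force sort-based oracle", {
  set.seed(8)
  n <- 1000L
  uids <- sprintf("UID%03d", sample(120L, n, replace = TRUE))
  uids <- vapply(uids, function(u)
    paste0(u, strrep("A", 20 - nchar(u))), character(1), USE.NAMES = FALSE)
  reads <- data.frame(donor = "d1", slice = sample(1:2, n, TRUE),
                      piece = sample(1:4, n, TRUE), uid = uids,
                      insert = strrep("A", 127))
  fams <- group_uid_families(reads)
  oracle <- aggregate(rep(1L, n),
                      by = list(donor = reads$donor, slice = reads$slice,
                                piece = reads$piece, uid = reads$uid), FUN = sum)
  oracle <- oracle[order(oracle$donor, oracle$slice, oracle$piece, oracle$uid), ]
  expect_equal(nrow(fams), nrow(oracle))
  expect_equal(fams$size, oracle$x)
  expect_equal(sum(fams$size), n)                  # conservation
  # n distinct UIDs in one piece -> n singleton families
  solo <- group_uid_families(data.frame(
    donor = "d1", slice = 1L, piece = 1L,
    uid = replicate(15, paste(sample(c("A","C","G","T"), 20, TRUE),
                              collapse = "")),
    insert = strrep("A", 127)))
  expect_equal(nrow(solo), 15L)
  expect_true(all(solo$size == 1L))
})

test_that("family consensus requires a dominant allele and minimum size", {
  ref <- strrep("A", 127)
  mut <- paste0(strrep("A", 46), "G", strrep("A", 80))   # alt at site 47
  # unanimity: mutant call at site 47
  calls <- call_family_consensus(rep(mut, 5), ref)
  expect_equal(calls$local_index, 47L)
  expect_equal(calls$alt, "G")
  # 50/50 split: no call at any min_fraction > 0.5
  calls <- call_family_consensus(c(rep(mut, 3), rep(ref, 3)), ref)
  expect_equal(nrow(calls), 0L)
  # below min_size: family rejected outright
  expect_null(call_family_consensus(rep(mut, 2), ref, min_size = 3))
  # N never produces an alternate call
  mutN <- paste0(strrep("A", 46), "N", strrep("A", 80))
  calls <- call_family_consensus(rep(mutN, 4), ref)
  expect_equal(nrow(calls), 0L)
  expect_error(call_family_consensus(rep(mut, 5), ref, min_fraction = 0.5),
               "exceed 0.5")
})

test_that("consensus miscall rate matches exhaustive error enumeration", {
  # wild-type families of size 3, per-read error e: a site is miscalled when
  # all 3 reads independently acquire the same one of the 3 alternate bases
  # (min_fraction 0.9 forces unanimity at size 3)
  e <- 0.01
  p_same_alt <- 3 * (e / 3)^3
  # enumeration over all 4^3 per-read allele combinations via the caller
  ref <- strrep("A", 127)
  bases <- c("A", "C", "G", "T")
  p_err <- c(1 - e, e / 3, e / 3, e / 3)
  p_miscall <- 0
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    reads <- vapply(bases[c(i, j, k)], function(b)
      paste0(b, strrep("A", 126)), character(1), USE.NAMES = FALSE)
    calls <- call_family_consensus(reads, ref, min_size = 3, min_fraction = 0.9)
    if (nrow(calls) > 0 && 1L %in% calls$local_index)
      p_miscall <- p_miscall + p_err[i] * p_err[j] * p_err[k]
  }
  expect_equal(p_miscall, p_same_alt)
})

test_that("zero-error reads round-trip to the generator's exact counts", {
  reg <- tiny_registry()
  cfg <- tiny_config(seed = 13L, families = 30L)
  sp <- list(spike_spec("c.182A>G", "d1", 1L, 1L, 0.4),
             spike_spec("c.188A>G", "d1", 2L, 3L, c(0.5, 0.2)))
  out <- gen_piece_counts(cfg, reg, spikes = sp)
  fq <- tempfile(fileext = ".fastq"); bmp <- tempfile(fileext = ".tsv")
  gen_reads(out$table, cfg, reg, fq, bmp)
  tab <- call_sss(fq, bmp, reg, min_size = 1L, missing_threshold = 10L)
  key <- c("donor", "slice", "piece", "local_index", "alt")
  m <- merge(as.data.frame(out$table), as.data.frame(tab), by = key,
             suffixes = c("_true", "_called"))
  expect_equal(nrow(m), nrow(out$table))
  expect_equal(m$mutant_families_called, m$mutant_families_true)
  expect_equal(m$total_families_called, m$total_families_true)
  expect_equal(m$missing_called, m$missing_true)
})

test_that("reads with one barcode error are still assigned to their piece", {
  reg <- tiny_registry()
  cfg <- tiny_config(seed = 17L, families = 25L,
                     family_size_dist = "constant", family_size_mean = 3)
  out <- gen_piece_counts(cfg, reg, variants = "c.182A>G")
  fq <- tempfile(fileext = ".fastq"); bmp <- tempfile(fileext = ".tsv")
  gen_reads(out$table, cfg, reg, fq, bmp)
  seqs <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  n <- length(seqs)
  set.seed(18)
  hit <- sample(n, round(0.2 * n))
  for (i in hit) {                                  # one barcode error each
    pos <- sample(8L, 1L)
    cur <- substr(seqs[i], pos, pos)
    substr(seqs[i], pos, pos) <- setdiff(c("A","C","G","T"), cur)[1]
  }
  fq2 <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@r", seq_len(n)), seqs, "+",
                             strrep("I", nchar(seqs)))), fq2)
  map <- barcode_map(bmp)
  reads <- read_sss_fastq(fq2, map)
  expect_equal(attr(reads, "n_discarded"), 0L)      # all corrected
  # per-piece read counts identical to the uncorrupted stream
  r0 <- read_sss_fastq(fq, map)
  expect_equal(table(paste(reads$slice, reads$piece)),
               table(paste(r0$slice, r0$piece)))
})

test_that("missing-piece flag and totals follow the threshold rule", {
  reg <- tiny_registry()
  fams <- data.frame(family = 1:6, donor = "d1",
                     slice = c(1, 1, 1, 1, 1, 2),
                     piece = c(1, 1, 1, 1, 1, 1),
                     uid = paste0("u", 1:6), size = 3L)
  pieces <- data.frame(donor = "d1", slice = c(1, 2), piece = 1L)
  calls <- data.frame(family = 1L, local_index = 45L, alt = "G")
  tab <- tabulate_piece_counts(fams, calls, reg, pieces, missing_threshold = 5L)
  t1 <- tab[tab$slice == 1 & tab$piece == 1, ]
  expect_true(all(t1$total_families == 5L))
  expect_false(any(t1$missing))
  expect_equal(t1$mutant_families[t1$local_index == 45 & t1$alt == "G"], 1L)
  t2 <- tab[tab$slice == 2, ]
  expect_true(all(t2$total_families == 1L))
  expect_true(all(t2$missing))                     # 1 < 5 -> missing
  # conservation: totals sum to number of retained families
  per_piece <- unique(tab[, c("donor", "slice", "piece", "total_families")])
  expect_equal(sum(per_piece$total_families), nrow(fams))
  # unknown piece key rejected
  badfams <- transform(fams, slice = 3)
  expect_error(tabulate_piece_counts(badfams, calls, reg, pieces), "unknown piece")
})
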