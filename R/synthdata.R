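#' Configuration for the synthetic sequencing-structure generator
#'
#' Describes the study layout being emulated: testes cut into slices x pieces
#' (default 6 x 32 = 192 pieces per testis), a target number of UID families
#' per piece, per-substitution-type assay background rates, and the read-level
#' error process used when emitting raw reads.
#'
#' @param n_donors Number of donor testes (default 3, as in the study).
#' @param donor_ids Donor labels; defaults to `d1..dN`.
#' @param n_slices,pieces_per_slice Spatial grid (defaults 6 and 32).
#' @param families_per_piece Either a single count (default 64,000, the
#'   study's average), a vector recycled over pieces, or a function
#'   `f(n)` sampling `n` per-piece totals (stand-in for an empirical
#'   distribution of per-piece family counts).
#' @param background_rates Named per-type background rates; see
#'   [default_background_rates()].
#' @param read_error Per-base sequencing error rate applied when emitting
#'   reads (default 0).
#' @param family_size_dist `"shifted_poisson"` (size = 1 + Poisson(mean-1))
#'   or `"constant"`.
#' @param family_size_mean Mean family size (default 6).
#' @param missing_threshold Pieces with fewer UID families than this are
#'   flagged missing (default 1000).
#' @param seed Mandatory RNG seed: fixed seed gives byte-identical output.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_donors = 3L, donor_ids = NULL, n_slices = 6L,
                             pieces_per_slice = 32L,
                             families_per_piece = 64000L,
                             background_rates = default_background_rates(),
                             read_error = 0,
                             family_size_dist = c("shifted_poisson", "constant"),
                             family_size_mean = 6,
                             missing_threshold = 1000L,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory for reproducibility")
  family_size_dist <- match.arg(family_size_dist)
  stopifnot(n_donors >= 1L, n_slices >= 1L, pieces_per_slice >= 1L,
            read_error >= 0, read_error < 1, family_size_mean >= 1,
            all(background_rates >= 0), all(background_rates <= 1))
  if (is.null(names(background_rates)) ||
      !all(names(default_background_rates()) %in% names(background_rates)))
    stop("background_rates must be named by the six substitution types")
  if (is.null(donor_ids)) donor_ids <- paste0("d", seq_len(n_donors))
  stopifnot(length(donor_ids) == n_donors)
  structure(list(
    n_donors = as.integer(n_donors), donor_ids = donor_ids,
    n_slices = as.integer(n_slices),
    pieces_per_slice = as.integer(pieces_per_slice),
    families_per_piece = families_per_piece,
    background_rates = background_rates, read_error = read_error,
    family_size_dist = family_size_dist, family_size_mean = family_size_mean,
    missing_threshold = as.integer(missing_threshold), seed = as.integer(seed)),
    class = "generator_config")
}

#' Specify a clonal spike: a contiguous run of elevated-frequency pieces
#'
#' Emulates a spatially confined mutant clone: the variant's true mutant
#' fraction is raised over `length(fractions)` adjacent pieces of one slice,
#' starting at the anchor piece.
#'
#' @param cds_label Variant label, e.g. `"c.182A>G"` (must be on the amplicon).
#' @param donor Donor id the spike belongs to.
#' @param slice,piece Anchor piece (1-based within the grid).
#' @param fractions Numeric vector in `[0,1]`: per-piece mutant fraction
#'   profile over the contiguous run.
#' @return Object of class `spike_spec`.
#' @export
spike_spec <- function(cds_label, donor, slice, piece, fractions) {
  stopifnot(length(cds_label) == 1L, length(slice) == 1L, length(piece) == 1L,
            is.numeric(fractions), length(fractions) >= 1L,
            all(fractions >= 0), all(fractions <= 1))
  structure(list(cds_label = cds_label, donor = donor, slice = as.integer(slice),
                 piece = as.integer(piece), fractions = fractions),
            class = "spike_spec")
}

# piece grid for a config: one row per (donor, slice, piece)
piece_grid <- function(config) {
  g <- data.table(
    donor = rep(config$donor_ids, each = config$n_slices * config$pieces_per_slice),
    slice = rep(rep(seq_len(config$n_slices), each = config$pieces_per_slice),
                config$n_donors),
    piece = rep(seq_len(config$pieces_per_slice),
                config$n_donors * config$n_slices))
  g
}

piece_totals <- function(config, n) {
  fp <- config$families_per_piece
  if (is.function(fp)) as.integer(fp(n)) else as.integer(rep_len(fp, n))
}

#' Generate per-piece UID-family count tables with known ground truth
#'
#' For every candidate variant and piece, the mutant UID-family count is
#' drawn as Binomial(total families, spike fraction + type background), the
#' sampling model of the error-corrected assay. A ledger records the true
#' spiked fraction of every cell, enabling exact round-trip tests.
#'
#' @param config A [generator_config()].
#' @param registry A [load_registry()] object.
#' @param spikes List of [spike_spec()] objects (may be empty).
#' @param variants Optional subset of variant `cds_label`s to generate
#'   (default: all 381 candidates).
#' @return List with `table` (long-format piece-call table: donor, slice,
#'   piece, local_index, ref, alt, mutant_families, total_families, missing)
#'   and `ledger` (same rows plus `true_frac`).
#' @export
gen_piece_counts <- function(config, registry, spikes = list(), variants = NULL) {
  stopifnot(inherits(config, "generator_config"),
            inherits(registry, "site_registry"))
  if (inherits(spikes, "spike_spec")) spikes <- list(spikes)
  set.seed(config$seed)
  sites <- registry$sites
  if (!is.null(variants)) {
    if (!all(variants %in% sites$cds_label))
      stop("unknown variant(s): ",
           paste(setdiff(variants, sites$cds_label), collapse = ", "))
    sites <- sites[sites$cds_label %in% variants]
  }
  grid <- piece_grid(config)
  grid[, total_families := piece_totals(config, .N)]
  grid[, piece_id := .I]

  nv <- nrow(sites); np <- nrow(grid)
  # true fraction matrix is sparse: only spiked cells are nonzero
  true_frac <- numeric(nv * np)  # column-major: piece within variant
  for (sp in spikes) {
    if (!inherits(sp, "spike_spec")) stop("spikes must be spike_spec objects")
    vi <- match(sp$cds_label, sites$cds_label)
    if (is.na(vi)) stop("spike references unknown variant: ", sp$cds_label)
    if (!(sp$donor %in% config$donor_ids)) stop("spike references unknown donor")
    if (sp$slice < 1L || sp$slice > config$n_slices) stop("spike slice out of range")
    run <- sp$piece + seq_along(sp$fractions) - 1L
    if (sp$piece < 1L || max(run) > config$pieces_per_slice)
      stop("spike pieces out of grid bounds (must stay inside one slice)")
    pid <- grid[donor == sp$donor & slice == sp$slice & piece %in% run,
                piece_id]
    true_frac[(vi - 1L) * np + pid] <- true_frac[(vi - 1L) * np + pid] +
      sp$fractions
  }
  if (any(true_frac > 1)) stop("overlapping spikes exceed fraction 1")

  bg <- config$background_rates[sites$mutation_type]
  p <- pmin(1, rep(bg, each = np) + true_frac)
  tot <- rep(grid$total_families, nv)
  mut <- rbinom(nv * np, tot, p)

  tab <- data.table(
    donor = rep(grid$donor, nv), slice = rep(grid$slice, nv),
    piece = rep(grid$piece, nv),
    local_index = rep(sites$local_index, each = np),
    ref = rep(sites$ref, each = np), alt = rep(sites$alt, each = np),
    mutant_families = mut, total_families = tot)
  tab[, missing := total_families < config$missing_threshold]
  tf <- true_frac                      # row order still matches construction
  ledger <- data.table::copy(tab)
  ledger[, true_frac := tf]
  setorder(tab, donor, slice, piece, local_index, alt)
  setorder(ledger, donor, slice, piece, local_index, alt)
  list(table = tab[], ledger = ledger[])
}

#' Generate a piece-barcode whitelist with pairwise Hamming distance >= 3
#'
#' Greedy rejection sampling over a shuffled enumeration of all 8-mers:
#' candidates are kept only if they sit at Hamming distance >= 3 from every
#' barcode already kept, so a single sequencing error in a barcode is always
#' uniquely correctable and a double error is always detectable.
#'
#' @param n Number of barcodes required.
#' @param seed RNG seed.
#' @param width Barcode length (default 8).
#' @return Character vector of `n` barcodes.
#' @export
make_barcodes <- function(n, seed, width = 8L) {
  set.seed(seed)
  g <- as.matrix(expand.grid(rep(list(1:4), width)))
  ord <- sample.int(nrow(g))
  kept <- matrix(0L, 0L, width)
  for (i in ord) {
    cand <- g[i, ]
    if (nrow(kept)) {
      d <- rowSums(kept != matrix(cand, nrow(kept), width, byrow = TRUE))
      if (min(d) < 3L) next
    }
    kept <- rbind(kept, cand)
    if (nrow(kept) == n) break
  }
  if (nrow(kept) < n)
    stop("could not satisfy the Hamming >= 3 constraint for ", n, " barcodes")
  apply(kept, 1L, function(r) paste(DNA_BASES[r], collapse = ""))
}

# reference insert sequence (127-mer) from an amplicon lookup
amplicon_ref_seq <- function(amplicon) paste(amplicon$ref, collapse = "")

#' Emit UID-tagged reads for a piece-call table
#'
#' Writes single-end FASTQ reads with the assay layout (bases 1-8 piece
#' barcode, 9-28 UID, 29-155 target amplicon) plus the barcode-map TSV.
#' Every UID family in the table is emitted: mutant families carry their
#' variant allele in all reads (before read error), wild-type families carry
#' the reference. Per-base read errors are applied independently across the
#' whole read. Fixed seed gives byte-identical FASTQ.
#'
#' @param table Piece-call table (typically a [gen_piece_counts()] ledger or
#'   table at small scale).
#' @param config A [generator_config()].
#' @param registry A [load_registry()] object (for the reference sequence).
#' @param fastq,barcode_map Output paths.
#' @return Invisibly, a list with the barcode map `data.frame` and the number
#'   of reads written.
#' @export
gen_reads <- function(table, config, registry, fastq, barcode_map) {
  stopifnot(inherits(config, "generator_config"))
  if (config$family_size_mean < 1) stop("family sizes must have mean >= 1")
  set.seed(config$seed + 1L)
  amp <- e3_amplicon()
  refseq <- strsplit(amplicon_ref_seq(amp), "")[[1]]
  tab <- as.data.table(table)

  pieces <- unique(tab[, .(donor, slice, piece, total_families)])
  if (anyDuplicated(pieces[, .(donor, slice, piece)]))
    stop("inconsistent total_families within a piece")
  bcs <- make_barcodes(nrow(pieces), seed = config$seed, width = 8L)
  pieces[, barcode := bcs]

  reads <- vector("list", nrow(pieces))
  for (i in seq_len(nrow(pieces))) {
    pc <- pieces[i]
    tt <- as.integer(pc$total_families)
    muts <- tab[donor == pc$donor & slice == pc$slice & piece == pc$piece &
                  mutant_families > 0L]
    if (sum(muts$mutant_families) > tt)
      stop("mutant families exceed total families in a piece")
    # assign mutant families to disjoint family slots
    fam_site <- rep(NA_integer_, tt); fam_alt <- rep(NA_character_, tt)
    slot <- 1L
    if (nrow(muts)) for (j in seq_len(nrow(muts))) {
      k <- muts$mutant_families[j]
      fam_site[slot:(slot + k - 1L)] <- muts$local_index[j]
      fam_alt[slot:(slot + k - 1L)] <- muts$alt[j]
      slot <- slot + k
    }
    sizes <- switch(config$family_size_dist,
      constant = rep(as.integer(round(config$family_size_mean)), tt),
      shifted_poisson = 1L + rpois(tt, config$family_size_mean - 1))
    uids <- random_uids(tt)
    # family inserts
    ins <- character(tt)
    wt <- paste(refseq, collapse = "")
    ins[] <- wt
    mi <- which(!is.na(fam_site))
    for (j in mi) {
      s <- refseq; s[fam_site[j]] <- fam_alt[j]
      ins[j] <- paste(s, collapse = "")
    }
    rd <- data.table(uid = rep(uids, sizes), insert = rep(ins, sizes))
    rd[, barcode := pc$barcode]
    reads[[i]] <- rd
  }
  reads <- data.table::rbindlist(reads)
  seqs <- paste0(reads$barcode, reads$uid, reads$insert)
  if (config$read_error > 0) seqs <- apply_read_errors(seqs, config$read_error)

  write_fastq(seqs, fastq)
  bm <- pieces[, .(barcode, donor, slice, piece)]
  write.table(bm, barcode_map, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(barcode_map = as.data.frame(bm), n_reads = length(seqs)))
}

random_uids <- function(n, width = 20L) {
  repeat {
    u <- vapply(seq_len(n), function(i)
      paste(sample(DNA_BASES, width, replace = TRUE), collapse = ""),
      character(1))
    if (!anyDuplicated(u)) return(u)
  }
}

# substitute errors uniformly at random positions; the error base is drawn
# from the three non-reference bases
apply_read_errors <- function(seqs, rate) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n_err <- rbinom(1L, length(m), rate)
  if (n_err > 0L) {
    idx <- sample.int(length(m), n_err)
    shift <- sample.int(3L, n_err, replace = TRUE)
    cur <- match(m[idx], DNA_BASES)
    m[idx] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
  }
  apply(m, 1L, paste, collapse = "")
}

write_fastq <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- sprintf("read%07d", seq_along(seqs))
  q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Write / read a piece-call table as TSV
#'
#' Long-format TSV (donor, slice, piece, local_index, ref, alt,
#' mutant_families, total_families, missing); bit-exact across runs.
#'
#' @param table A piece-call table.
#' @param path File path.
#' @return `write_piece_table` returns the path invisibly;
#'   `read_piece_table` returns a `data.table`.
#' @export
write_piece_table <- function(table, path) {
  data.table::fwrite(as.data.table(table), path, sep = "\t")
  invisible(path)
}

#' @rdname write_piece_table
#' @export
read_piece_table <- function(path) {
  data.table::fread(path, sep = "\t")
}
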