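#' Load and validate a piece-barcode map
#'
#' The whitelist must have pairwise Hamming distance >= 3 so that any single
#' sequencing error in a barcode is uniquely correctable and any double error
#' is detectable (the read is then discarded rather than misassigned).
#'
#' @param x Path to a TSV with columns `barcode`, `donor`, `slice`, `piece`,
#'   or an equivalent `data.frame`.
#' @return Object of class `barcode_map`: the map `data.frame` with the
#'   barcode character matrix attached.
#' @export
barcode_map <- function(x) {
  bm <- if (is.character(x)) read.delim(x, stringsAsFactors = FALSE) else
    as.data.frame(x)
  need <- c("barcode", "donor", "slice", "piece")
  if (!all(need %in% names(bm)))
    stop("barcode map needs columns: ", paste(need, collapse = ", "))
  w <- unique(nchar(bm$barcode))
  if (length(w) != 1L) stop("barcodes must share one width")
  if (anyDuplicated(bm$barcode)) stop("duplicate barcodes in map")
  M <- do.call(rbind, strsplit(bm$barcode, ""))
  if (!all(M %in% DNA_BASES)) stop("barcodes must contain only A/C/G/T")
  # pairwise Hamming distance >= 3 (vectorized per column over all pairs)
  n <- nrow(M)
  if (n > 1L) {
    agree <- matrix(0L, n, n)
    for (j in seq_len(ncol(M))) agree <- agree + outer(M[, j], M[, j], "==")
    d <- ncol(M) - agree
    diag(d) <- ncol(M)
    if (min(d) < 3L)
      stop("barcode whitelist violates pairwise Hamming distance >= 3")
  }
  structure(bm, barcode_matrix = M, class = c("barcode_map", "data.frame"))
}

#' Correct observed piece barcodes against the whitelist
#'
#' Each observed barcode is assigned to the unique whitelist entry at Hamming
#' distance <= 1 (exact match or one sequencing error); anything else is
#' discarded (`NA`). `N` bases count as mismatches. Because the whitelist has
#' pairwise distance >= 3, a match at distance <= 1 is always unique and a
#' read is never assigned to a barcode two or more errors away.
#'
#' @param observed Character vector of observed barcodes.
#' @param map A [barcode_map()].
#' @return Integer vector of row indices into `map` (NA = discard).
#' @export
correct_barcode <- function(observed, map) {
  stopifnot(inherits(map, "barcode_map"))
  M <- attr(map, "barcode_matrix")
  w <- ncol(M)
  if (any(nchar(observed) != w))
    stop("observed barcodes must have width ", w)
  idx <- match(observed, map$barcode)          # exact matches first
  todo <- which(is.na(idx))
  if (length(todo)) {
    O <- do.call(rbind, strsplit(observed[todo], ""))
    for (k in seq_along(todo)) {
      d <- rowSums(M != matrix(O[k, ], nrow(M), w, byrow = TRUE))
      hit <- which(d <= 1L)
      if (length(hit) == 1L) idx[todo[k]] <- hit
    }
  }
  idx
}

#' Read UID-tagged amplicon reads from FASTQ
#'
#' Expects the assay layout: bases 1-8 piece barcode, 9-28 UID, 29-155 the
#' 127-nt target amplicon. Reads are barcode-corrected against the map;
#' reads with uncorrectable barcodes or with any `N` in barcode or UID are
#' discarded (an `N` inside the insert is kept and treated as a
#' non-matching allele downstream).
#'
#' @param fastq Path to the FASTQ file.
#' @param map A [barcode_map()] (or path to one).
#' @return `data.table` with columns `donor`, `slice`, `piece`, `uid`,
#'   `insert`; attribute `n_discarded` counts dropped reads.
#' @export
read_sss_fastq <- function(fastq, map) {
  if (!inherits(map, "barcode_map")) map <- barcode_map(map)
  seqs <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  if (length(seqs) && any(nchar(seqs) != 155L))
    stop("reads must be 155 nt (8 barcode + 20 UID + 127 insert)")
  bc <- substr(seqs, 1L, 8L)
  uid <- substr(seqs, 9L, 28L)
  insert <- substr(seqs, 29L, 155L)
  keep <- !grepl("N", bc, fixed = TRUE) & !grepl("N", uid, fixed = TRUE)
  idx <- rep(NA_integer_, length(seqs))
  idx[keep] <- correct_barcode(bc[keep], map)
  ok <- !is.na(idx)
  out <- data.table(donor = map$donor[idx[ok]], slice = map$slice[idx[ok]],
                    piece = map$piece[idx[ok]], uid = uid[ok],
                    insert = insert[ok])
  setattr(out, "n_discarded", sum(!ok))
  out
}

#' Group barcode-assigned reads into UID families
#'
#' Reads sharing a UID within one piece derive from the same original DNA
#' strand and form a UID family, the unit of error-corrected counting.
#'
#' @param reads `data.table` from [read_sss_fastq()] (columns `donor`,
#'   `slice`, `piece`, `uid`, at least).
#' @return `data.table` of families (`family` id, piece key, `uid`, `size`),
#'   deterministically ordered by piece key and UID.
#' @export
group_uid_families <- function(reads) {
  reads <- as.data.table(reads)
  if (!nrow(reads))
    return(data.table(family = integer(), donor = character(),
                      slice = integer(), piece = integer(),
                      uid = character(), size = integer()))
  fams <- reads[, .(size = .N), by = .(donor, slice, piece, uid)]
  setorder(fams, donor, slice, piece, uid)
  fams[, family := .I]
  fams[, .(family, donor, slice, piece, uid, size)]
}

#' Call the consensus allele profile of one UID family
#'
#' A family is counted only if it has at least `min_size` reads. At each
#' site the majority allele is called when its read fraction reaches
#' `min_fraction` (> 0.5 required, so at most one allele can qualify); an
#' alternate call is emitted only where that allele differs from the
#' reference. Sites without a qualifying majority contribute the family to
#' the total but no alternate allele ("almost all reads must agree").
#'
#' @param inserts Character vector of the family's read inserts (equal
#'   length).
#' @param ref Reference insert sequence (single string, same width).
#' @param min_size Minimum family size (default 3).
#' @param min_fraction Minimum consensus read fraction (default 0.9).
#' @return `NULL` if the family is rejected (too small); otherwise a
#'   `data.frame` with `local_index`, `alt` of alternate calls (possibly
#'   0-row).
#' @export
call_family_consensus <- function(inserts, ref, min_size = 3L,
                                  min_fraction = 0.9) {
  if (min_fraction <= 0.5) stop("min_fraction must exceed 0.5")
  n <- length(inserts)
  if (n < min_size) return(NULL)
  refv <- strsplit(ref, "")[[1]]
  M <- do.call(rbind, strsplit(inserts, ""))
  if (ncol(M) != length(refv)) stop("insert width disagrees with reference")
  calls <- list()
  mism <- which(M != matrix(refv, n, length(refv), byrow = TRUE))
  if (length(mism)) {
    sitecol <- ((mism - 1L) %/% n) + 1L
    base <- M[mism]
    tab <- data.table(site = sitecol, base = base)[, .N, by = .(site, base)]
    tab <- tab[base %in% DNA_BASES & N / n >= min_fraction]
    if (nrow(tab)) calls <- tab[, .(local_index = site, alt = base)]
  }
  if (!length(calls)) data.frame(local_index = integer(), alt = character())
  else as.data.frame(calls)
}

# batch consensus over all families: returns list(families_kept, calls)
consensus_calls <- function(reads, fams, ref, min_size = 3L,
                            min_fraction = 0.9) {
  if (min_fraction <= 0.5) stop("min_fraction must exceed 0.5")
  kept <- fams[size >= min_size]
  if (!nrow(kept))
    return(list(families = kept,
                calls = data.table(family = integer(),
                                   local_index = integer(),
                                   alt = character())))
  rk <- merge(as.data.table(reads),
              kept[, .(family, donor, slice, piece, uid, size)],
              by = c("donor", "slice", "piece", "uid"))
  refv <- strsplit(ref, "")[[1]]
  L <- length(refv)
  M <- do.call(rbind, strsplit(rk$insert, ""))
  if (ncol(M) != L) stop("insert width disagrees with reference")
  mism <- which(M != matrix(refv, nrow(M), L, byrow = TRUE))
  calls <- data.table(family = integer(), local_index = integer(),
                      alt = character())
  if (length(mism)) {
    row <- ((mism - 1L) %% nrow(M)) + 1L
    site <- ((mism - 1L) %/% nrow(M)) + 1L
    mm <- data.table(family = rk$family[row], local_index = site,
                     base = M[mism])
    cnt <- mm[, .(n_alt = .N), by = .(family, local_index, base)]
    cnt <- merge(cnt, kept[, .(family, size)], by = "family")
    cnt <- cnt[base %in% DNA_BASES & n_alt / size >= min_fraction]
    if (nrow(cnt))
      calls <- cnt[, .(family, local_index, alt = base)]
  }
  list(families = kept, calls = calls)
}

#' Tabulate per-piece mutant and total UID-family counts
#'
#' Builds the central count matrix of the analysis: for every piece and
#' candidate substitution, the number of consensus-called mutant UID families
#' and the piece's total retained UID families. Pieces with fewer than
#' `missing_threshold` families are flagged missing (the per-piece frequency
#' precision, 1/total, is then too coarse to use).
#'
#' @param families Kept families (from [consensus_calls()] internals or
#'   [group_uid_families()] filtered by size).
#' @param calls Alternate-allele calls per family (`family`, `local_index`,
#'   `alt`).
#' @param registry A [load_registry()] object.
#' @param pieces `data.frame` of all expected piece keys (`donor`, `slice`,
#'   `piece`), e.g. from the barcode map; pieces without any retained family
#'   get total 0 and are flagged missing.
#' @param missing_threshold Default 1000.
#' @return Long-format piece-call `data.table` (donor, slice, piece,
#'   local_index, ref, alt, mutant_families, total_families, missing).
#' @export
tabulate_piece_counts <- function(families, calls, registry, pieces,
                                  missing_threshold = 1000L) {
  stopifnot(inherits(registry, "site_registry"))
  pieces <- unique(as.data.table(pieces)[, .(donor, slice, piece)])
  fams <- as.data.table(families)
  if (nrow(fams)) {
    unknown <- fams[!pieces, on = c("donor", "slice", "piece")]
    if (nrow(unknown))
      stop("family references unknown piece key: ",
           paste(unique(paste(unknown$donor, unknown$slice, unknown$piece)),
                 collapse = "; "))
  }
  totals <- fams[, .(total_families = .N), by = .(donor, slice, piece)]
  totals <- merge(pieces, totals, by = c("donor", "slice", "piece"),
                  all.x = TRUE)
  totals[is.na(total_families), total_families := 0L]

  sites <- registry$sites[, .(local_index, ref, alt)]
  np <- nrow(totals); nv <- nrow(sites)
  tab <- data.table(
    donor = rep(totals$donor, each = nv), slice = rep(totals$slice, each = nv),
    piece = rep(totals$piece, each = nv),
    local_index = rep(sites$local_index, np), ref = rep(sites$ref, np),
    alt = rep(sites$alt, np),
    total_families = rep(totals$total_families, each = nv))

  cl <- as.data.table(calls)
  if (nrow(cl)) {
    cl <- merge(cl, fams[, .(family, donor, slice, piece)], by = "family")
    mut <- cl[, .(mutant_families = .N),
              by = .(donor, slice, piece, local_index, alt)]
    tab <- merge(tab, mut, by = c("donor", "slice", "piece", "local_index", "alt"),
                 all.x = TRUE)
    tab[is.na(mutant_families), mutant_families := 0L]
  } else tab[, mutant_families := 0L]
  tab[, missing := total_families < missing_threshold]
  setorder(tab, donor, slice, piece, local_index, alt)
  tab[, .(donor, slice, piece, local_index, ref, alt, mutant_families,
          total_families, missing)]
}

#' End-to-end UID-family variant calling from FASTQ
#'
#' Barcode correction, UID-family grouping, consensus calling and
#' tabulation in one call.
#'
#' @param fastq FASTQ path (assay read layout).
#' @param barcodes Barcode map path or `data.frame`.
#' @param registry A [load_registry()] object.
#' @param min_size,min_fraction Consensus thresholds (defaults 3 and 0.9).
#' @param missing_threshold Missing-piece threshold (default 1000).
#' @return Piece-call `data.table` (see [tabulate_piece_counts()]).
#' @export
call_sss <- function(fastq, barcodes, registry, min_size = 3L,
                     min_fraction = 0.9, missing_threshold = 1000L) {
  map <- if (inherits(barcodes, "barcode_map")) barcodes else barcode_map(barcodes)
  reads <- read_sss_fastq(fastq, map)
  fams <- group_uid_families(reads)
  ref <- amplicon_ref_seq(e3_amplicon())
  cc <- consensus_calls(reads, fams, ref, min_size, min_fraction)
  tabulate_piece_counts(cc$families, cc$calls, registry,
                        pieces = unique(map[, c("donor", "slice", "piece")]),
                        missing_threshold = missing_threshold)
}
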