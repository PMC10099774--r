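# shared helpers for building tiny in-memory fixtures

tiny_registry <- function() load_registry()

# minimal generator layout: one donor, 2 slices x 4 pieces
tiny_config <- function(seed = 1L, families = 200L, ...) {
  generator_config(n_donors = 1L, n_slices = 2L, pieces_per_slice = 4L,
                   families_per_piece = families, missing_threshold = 10L,
                   seed = seed, ...)
}

# write an annotation data.frame to a temp TSV in the registry file format
write_annotation <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

# piece-call table for one testis built directly from a matrix of mutant
# counts (pieces x 1 variant), constant totals
table_from_counts <- function(mutant, totals, local_index = 45L, alt = "G",
                              donor = "d1", missing = NULL) {
  np <- length(mutant)
  slice <- rep(seq_len(ceiling(np / 32)), each = 32)[seq_len(np)]
  piece <- ((seq_len(np) - 1L) %% 32L) + 1L
  data.frame(donor = donor, slice = slice, piece = piece,
             local_index = local_index, ref = "A", alt = alt,
             mutant_families = mutant,
             total_families = rep_len(totals, np),
             missing = if (is.null(missing)) rep(FALSE, np) else missing)
}
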