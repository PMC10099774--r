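#' Load the packaged exon-3 amplicon site lookup
#'
#' The amplicon covers 127 consecutive nucleotide sites of *PTPN11* exon 3:
#' 108 coding sites (c.138..c.245, amino acids 46-82 of SHP-2) and 19 flanking
#' intronic sites. The lookup maps the 1-based `local_index` along the
#' amplicon to the c.-notation site label, reference base and codon
#' bookkeeping. Reference bases at positions constrained by the variant table
#' are as reported; the remaining bases are fixed synthetic filler (see the
#' `ref_source` column), sufficient for simulation and consequence
#' classification but deliberately not the RefSeq transcript sequence.
#'
#' @param path Path to the lookup TSV; defaults to the packaged file.
#' @return A `data.frame` with columns `local_index`, `site_label`, `ref`,
#'   `region`, `codon`, `codon_pos`, `ref_source`, and attribute `context`
#'   (named vector of the three exonic context bases flanking the amplicon's
#'   partial codons).
#' @export
e3_amplicon <- function(path = system.file("extdata", "e3_amplicon_sites.tsv",
                                           package = "germselect")) {
  stopifnot(file.exists(path))
  lines <- readLines(path, n = 10L)
  ctxline <- grep("^# context_", lines, value = TRUE)
  amp <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (length(ctxline) == 1L) {
    kv <- regmatches(ctxline, gregexpr("context_(c\\d+)=([ACGT])", ctxline))[[1]]
    ctx <- sub(".*=", "", kv)
    names(ctx) <- sub("context_(c\\d+)=.*", "\\1", kv)
    attr(amp, "context") <- ctx
  }
  stopifnot(nrow(amp) == 127L, all(amp$ref %in% DNA_BASES))
  amp
}

# consequence of substituting `alt` at amplicon row `i` (single site)
site_consequences <- function(amp, ctx) {
  gc <- codon_table()
  out <- vector("list", nrow(amp))
  base_at <- function(cds_pos) {
    hit <- match(paste0("c.", cds_pos), amp$site_label)
    if (!is.na(hit)) return(amp$ref[hit])
    b <- ctx[paste0("c", cds_pos)]      # flanking exonic context
    if (is.na(b)) stop("no context base for c.", cds_pos)
    unname(b)
  }
  for (i in seq_len(nrow(amp))) {
    if (amp$region[i] != "coding") { out[[i]] <- rep("noncoding", 3L); next }
    cds_pos <- as.integer(sub("^c\\.", "", amp$site_label[i]))
    cod <- amp$codon[i]; cp <- amp$codon_pos[i]
    cod_pos <- (3L * (cod - 1L) + 1L):(3L * cod)
    ref_codon <- vapply(cod_pos, base_at, character(1))
    alts <- setdiff(DNA_BASES, amp$ref[i])
    cons <- vapply(alts, function(a) {
      alt_codon <- ref_codon
      alt_codon[cp] <- a
      if (gc[paste(alt_codon, collapse = "")] ==
          gc[paste(ref_codon, collapse = "")]) "synonymous" else "missense"
    }, character(1))
    out[[i]] <- cons
  }
  out
}

#' Load a variant-site registry for the 127-site amplicon
#'
#' Reads an annotation table of known disease/cancer substitutions (the
#' packaged fixture transcribes the study's curated table: 30 Noonan-syndrome
#' NS1 variant sites and 20 sporadic-only cancer sites) and expands it over
#' the full candidate space: every one of the 127 amplicon positions times 3
#' alternate bases, i.e. 381 candidate substitutions per testis. Substitutions
#' absent from the annotation get category `"none"` and zero case counts.
#'
#' A "variant site" here is a specific base substitution (e.g. `c.174C>A` and
#' `c.174C>G` are two sites at one nucleotide position), the convention under
#' which all of the study's summary counts reproduce.
#'
#' @param path Annotation TSV with columns `cds_label`, `category`,
#'   `ns_cases`, `cosmic_cases`, `clusters` (donor ages, `;`-separated, may be
#'   empty). Defaults to the packaged fixture.
#' @param amplicon Amplicon lookup, as returned by [e3_amplicon()].
#' @param donors Integer vector of donor ages that may legally appear in the
#'   `clusters` column.
#' @return An object of class `site_registry`: a list with `sites` (a
#'   `data.table`, 381 rows), `amplicon_length`, `n_coding`, `n_intron`,
#'   `donors`.
#' @examples
#' reg <- load_registry()
#' table(reg$sites$category)
#' @export
load_registry <- function(path = system.file("extdata", "table1_registry.tsv",
                                             package = "germselect"),
                          amplicon = e3_amplicon(),
                          donors = c(65L, 68L)) {
  stopifnot(file.exists(path))
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(clusters = "character"))
  if (nrow(ann) && !all(c("cds_label", "category", "clusters") %in% names(ann)))
    stop("annotation must have columns cds_label, category, clusters")
  if (!"ns_cases" %in% names(ann)) ann$ns_cases <- integer(0)
  if (!"cosmic_cases" %in% names(ann)) ann$cosmic_cases <- integer(0)
  if (anyDuplicated(ann$cds_label))
    stop("duplicate cds_label in annotation: ",
         paste(unique(ann$cds_label[duplicated(ann$cds_label)]), collapse = ", "))

  # full candidate space: 127 positions x 3 alternates
  cons <- site_consequences(amplicon, attr(amplicon, "context"))
  sites <- data.table(
    local_index = rep(amplicon$local_index, each = 3L),
    site_label  = rep(amplicon$site_label, each = 3L),
    ref         = rep(amplicon$ref, each = 3L),
    alt         = unlist(lapply(amplicon$ref, function(r) setdiff(DNA_BASES, r))),
    region      = rep(amplicon$region, each = 3L),
    consequence = unlist(cons),
    category    = "none",
    ns_cases    = 0L,
    cosmic_cases = 0L,
    clusters    = ""
  )
  sites[, cds_label := paste0(site_label, ref, ">", alt)]

  if (nrow(ann)) {
    m <- regmatches(ann$cds_label,
                    regexec("^(c\\.[-+0-9]+)([ACGTN])>([ACGTN])$", ann$cds_label))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad))
      stop("malformed cds_label: ", paste(ann$cds_label[bad], collapse = ", "))
    ann$site_label <- vapply(m, `[`, "", 2L)
    ann$ref <- vapply(m, `[`, "", 3L)
    ann$alt <- vapply(m, `[`, "", 4L)
    if (!all(ann$ref %in% DNA_BASES) || !all(ann$alt %in% DNA_BASES) ||
        any(ann$ref == ann$alt))
      stop("annotation ref/alt bases must be distinct bases in A/C/G/T")
    # cluster annotation: ';'-separated donor ages from the known donor set
    cl <- strsplit(ann$clusters, ";", fixed = TRUE)
    okcl <- vapply(cl, function(x) {
      x <- x[nzchar(x)]
      all(!is.na(suppressWarnings(as.integer(x)))) &&
        all(as.integer(x) %in% donors) && !anyDuplicated(x)
    }, logical(1))
    if (!all(okcl))
      stop("malformed cluster annotation: ",
           paste(ann$cds_label[!okcl], collapse = ", "))
    if (any(ann$ns_cases < 0) || any(ann$cosmic_cases < 0))
      stop("case counts must be non-negative")
    ok_cat <- c("recurrent_NS1", "rare_NS1", "SO_cancer")
    if (!all(ann$category %in% ok_cat))
      stop("unknown category: ", paste(setdiff(ann$category, ok_cat), collapse = ", "))
    hit <- match(paste(ann$site_label, ann$alt), paste(sites$site_label, sites$alt))
    if (anyNA(hit))
      stop("annotated substitution not on the amplicon: ",
           paste(ann$cds_label[is.na(hit)], collapse = ", "))
    if (!all(sites$ref[hit] == ann$ref))
      stop("annotation ref base disagrees with the amplicon reference")
    sites[hit, `:=`(category = ann$category,
                    ns_cases = as.integer(ann$ns_cases),
                    cosmic_cases = as.integer(ann$cosmic_cases),
                    clusters = ann$clusters,
                    consequence = "missense")]
    # NS1 categories require at least one patient report; S-O sites have none
    if (sites[category %in% c("recurrent_NS1", "rare_NS1") & ns_cases < 1L, .N])
      stop("NS1 sites must have ns_cases >= 1")
    if (sites[category == "SO_cancer" & (ns_cases != 0L | cosmic_cases < 1L), .N])
      stop("SO_cancer sites must have ns_cases = 0 and cosmic_cases >= 1")
  }
  sites[, mutation_type := substitution_type(ref, alt)]
  setorder(sites, local_index, alt)

  out <- list(sites = sites[],
              amplicon_length = nrow(amplicon),
              n_coding = sum(amplicon$region == "coding"),
              n_intron = sum(amplicon$region == "intron"),
              donors = as.integer(donors))
  class(out) <- "site_registry"
  out
}

#' @export
print.site_registry <- function(x, ...) {
  cat(sprintf("site_registry: %d candidate substitutions at %d sites (%d coding, %d intron)\n",
              nrow(x$sites), x$amplicon_length, x$n_coding, x$n_intron))
  print(table(x$sites$category))
  invisible(x)
}

#' Enumerate candidate variants across testes
#'
#' Every amplicon position admits 3 alternate bases, so one testis carries
#' `127 x 3 = 381` candidate variants and two testes carry 762.
#'
#' @param registry A [load_registry()] object.
#' @param n_testes Number of testes scanned (>= 1).
#' @return `data.table` of (candidate variant, testis) pairs ordered by
#'   `local_index`, `alt`, `testis`; `nrow()` gives the candidate count.
#' @export
enumerate_candidates <- function(registry, n_testes) {
  stopifnot(inherits(registry, "site_registry"))
  if (!is.numeric(n_testes) || length(n_testes) != 1L || n_testes < 1)
    stop("n_testes must be a single integer >= 1")
  n_testes <- as.integer(n_testes)
  out <- registry$sites[rep(seq_len(.N), each = n_testes),
                        .(local_index, site_label, cds_label, ref, alt)]
  out[, testis := rep_len(seq_len(n_testes), .N)]
  setorder(out, local_index, alt, testis)
  out[]
}

#' Summarize patient/case counts for a registry category
#'
#' For NS1 categories the case count is the number of NS1 patient reports;
#' for sporadic-only cancer sites it is the number of reported sporadic
#' cancers. The packaged fixture reproduces the study's summaries: rare NS1
#' mean 2.9 cases (range 1-9, 19 sites), recurrent NS1 mean ~43.0 (range
#' 16-110, 11 sites).
#'
#' @param registry A [load_registry()] object.
#' @param category One or more of `"recurrent_NS1"`, `"rare_NS1"`,
#'   `"SO_cancer"`, `"none"`; a vector summarizes the union.
#' @return List with `mean`, `min`, `max`, `n_sites`.
#' @export
summarize_cases <- function(registry, category) {
  stopifnot(inherits(registry, "site_registry"))
  keep_cat <- registry$sites[["category"]] %in% category
  s <- registry$sites[keep_cat]
  if (!nrow(s)) stop("no sites in category: ", paste(category, collapse = ", "))
  cases <- ifelse(s$category == "SO_cancer", s$cosmic_cases, s$ns_cases)
  list(mean = mean(cases), min = min(cases), max = max(cases),
       n_sites = nrow(s))
}

#' Count variant sites with significant testis clusters
#'
#' @param registry A [load_registry()] object.
#' @param categories Character vector of categories to include.
#' @param donor `"any"` to count sites clustered in at least one donor, or a
#'   single donor age to count sites clustered in that donor's testis.
#' @return Integer count.
#' @examples
#' reg <- load_registry()
#' count_clustered_sites(reg, c("recurrent_NS1", "rare_NS1"))        # 14
#' count_clustered_sites(reg, "SO_cancer")                           # 6
#' @export
count_clustered_sites <- function(registry, categories, donor = "any") {
  stopifnot(inherits(registry, "site_registry"))
  ok_cat <- c("recurrent_NS1", "rare_NS1", "SO_cancer", "none")
  if (!all(categories %in% ok_cat))
    stop("unknown category: ", paste(setdiff(categories, ok_cat), collapse = ", "))
  keep_cat <- registry$sites[["category"]] %in% categories
  s <- registry$sites[keep_cat]
  cl <- strsplit(s$clusters, ";", fixed = TRUE)
  if (identical(donor, "any")) {
    return(sum(lengths(cl) > 0L))
  }
  donor <- suppressWarnings(as.integer(donor))
  if (is.na(donor) || !(donor %in% registry$donors))
    stop("unknown donor age; known donors: ",
         paste(registry$donors, collapse = ", "))
  sum(vapply(cl, function(x) as.character(donor) %in% x, logical(1)))
}
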