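#' Parameters of the spermatogonial stem-cell (SSC) proliferation models
#'
#' The germline is modelled in two phases. A growth phase (zygote to puberty)
#' of `growth_generations` synchronous symmetric doublings builds the adult
#' SSC pool. In the adult phase every stem cell divides once per
#' `cycle_days`; a wild-type division is symmetric self-renewal (two stem
#' daughters) with probability `p_sym_wt` = 0.5 and differentiation (two
#' sperm-bound daughters, zero stem daughters) otherwise, keeping the pool
#' size constant in expectation. Mutant stem cells self-renew with
#' probability `0.5 + selection_s`: the neutral model has `selection_s = 0`,
#' the selection model a small positive bias that drives clonal expansion.
#' New mutant lineages arise at `mu` per site per cell division throughout
#' both phases.
#'
#' The adult pool size defaults to `2^growth_generations` (2^30), the size
#' implied by the growth phase itself. Cluster statistics are sensitive to
#' this absolute size: a neutral adult clone surviving t cycles has absolute
#' size of order t/2 cells regardless of pool size, so its piece *frequency*
#' scales inversely with the pool.
#'
#' @param donor_age_years Age at testis sampling.
#' @param mu Mutation rate per site per cell division.
#' @param selection_s Self-renewal bias of mutant cells (0 <= s < 0.5).
#' @param growth_generations Pre-puberty doublings (default 30).
#' @param cycle_days Days per adult stem-cell cycle (default 16).
#' @param p_sym_wt Wild-type symmetric-renewal probability (default 0.5).
#' @param puberty_age_years Start of the adult phase (default 13).
#' @param n_slices,pieces_per_slice Dissection grid (6 x 32 = 192 pieces).
#' @param families_per_piece Sequencing depth per piece (default 64,000 UID
#'   families).
#' @param n_ssc Adult SSC pool size (default `2^growth_generations`).
#' @param background_rates Per-type assay background rates.
#' @param missing_threshold Missing-piece threshold (default 1000).
#' @param seed Optional RNG seed: fixed seed gives bit-identical simulations.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(donor_age_years, mu, selection_s = 0,
                       growth_generations = 30L, cycle_days = 16,
                       p_sym_wt = 0.5, puberty_age_years = 13,
                       n_slices = 6L, pieces_per_slice = 32L,
                       families_per_piece = 64000L,
                       n_ssc = 2^growth_generations,
                       background_rates = default_background_rates(),
                       missing_threshold = 1000L, seed = NULL) {
  stopifnot(is.numeric(donor_age_years), donor_age_years >= 0,
            is.numeric(mu), mu >= 0,
            growth_generations >= 1L,
            cycle_days > 0, p_sym_wt >= 0, p_sym_wt <= 1,
            puberty_age_years >= 0, n_slices >= 1L, pieces_per_slice >= 1L,
            families_per_piece >= 1L, n_ssc >= 1,
            all(background_rates >= 0), all(background_rates <= 1))
  if (selection_s < 0 || selection_s >= 0.5)
    stop("selection_s must satisfy 0 <= s < 0.5")
  structure(list(
    donor_age_years = donor_age_years, mu = mu, selection_s = selection_s,
    growth_generations = as.integer(growth_generations),
    cycle_days = cycle_days, p_sym_wt = p_sym_wt,
    puberty_age_years = puberty_age_years,
    n_slices = as.integer(n_slices),
    pieces_per_slice = as.integer(pieces_per_slice),
    n_pieces = as.integer(n_slices * pieces_per_slice),
    families_per_piece = as.integer(families_per_piece),
    n_ssc = n_ssc, background_rates = background_rates,
    missing_threshold = as.integer(missing_threshold), seed = seed),
    class = "sim_params")
}

#' Number of adult stem-cell cycles reached by a given age
#'
#' @param params A [sim_params()].
#' @param age Age in years (default the donor age).
#' @return Integer cycle count (0 if the age precedes puberty).
#' @export
adult_cycles <- function(params, age = params$donor_age_years) {
  max(0L, floor((age - params$puberty_age_years) * 365.25 / params$cycle_days))
}

# Vectorized lineage-pool engine. Simulates n_reps independent variant-testis
# replicates jointly: the wild-type pool is tracked in expectation (constant
# n_ssc), mutant lineages individually as Galton-Watson branching processes
# (offspring 2 with probability 0.5+s, else 0). Growth-phase lineages double
# deterministically until puberty. Returns surviving lineages (rep_id, count,
# anchor) and, if requested, the mutant share of differentiation output in
# the final cycle.
simulate_lineage_pool <- function(params, n_reps, record_sperm = FALSE,
                                  n_cycles = adult_cycles(params)) {
  G <- params$growth_generations
  N <- params$n_ssc
  mu <- params$mu
  p <- 0.5 + params$selection_s
  rep_id <- integer(0); cnt <- numeric(0); anchor <- numeric(0)

  if (mu > 0) {
    # growth phase: arrivals at generation g (cells halve going back in time)
    lam_g <- N * 2^((0:(G - 1L)) - G) * mu
    k <- rpois(n_reps * G, rep(lam_g, n_reps))
    if (sum(k) > 0) {
      gi <- rep(rep(0:(G - 1L), n_reps), k)
      rep_id <- rep(rep(seq_len(n_reps), each = G), k)
      cnt <- pmin(2^(G - gi - 1L), N)
      anchor <- runif(length(cnt))
    }
  }

  sperm_frac <- if (record_sperm) numeric(n_reps) else NULL
  if (n_cycles > 0L && (mu > 0 || length(cnt))) {
    lam_adult <- N * mu
    for (j in seq_len(n_cycles)) {
      last <- record_sperm && j == n_cycles
      if (last) {
        prev_rep <- rep_id; prev_cnt <- cnt
      }
      if (length(cnt)) {
        cnt <- 2 * rbinom(length(cnt), pmin(cnt, .Machine$integer.max), p)
        cnt <- pmin(cnt, N)
        alive <- cnt > 0
        if (last) {
          # differentiation output this cycle: 2*(n - renewals) = 2n - n'
          diff_m <- rowsum(2 * prev_cnt - cnt, prev_rep)
          m_prev <- rowsum(prev_cnt, prev_rep)
          ridx <- as.integer(rownames(diff_m))
          wt_diff <- pmax(N - m_prev[, 1L], 0)  # wt pool * 2 * (1 - 0.5)
          tot <- diff_m[, 1L] + wt_diff
          sperm_frac[ridx] <- ifelse(tot > 0, diff_m[, 1L] / tot, 0)
        }
        if (!all(alive)) {
          rep_id <- rep_id[alive]; cnt <- cnt[alive]; anchor <- anchor[alive]
        }
      }
      if (mu > 0) {
        k <- rpois(n_reps, lam_adult)
        tot_k <- sum(k)
        if (tot_k > 0) {
          rep_id <- c(rep_id, rep(seq_len(n_reps), k))
          cnt <- c(cnt, rep(1, tot_k))
          anchor <- c(anchor, runif(tot_k))
        }
      }
    }
  }
  list(lineages = data.table(rep_id = rep_id, count = cnt, anchor = anchor),
       sperm_frac = sperm_frac, n_reps = n_reps)
}

#' Place mutant lineages on the 1-D piece layout
#'
#' Cells are arranged on a circular 1-D axis with each clone occupying a
#' contiguous arc anchored at its (uniformly drawn) seeding position; the
#' axis is cut into `n_pieces` equal segments, slices being consecutive
#' blocks of pieces. A clone therefore spans contiguous pieces and total
#' cell counts are conserved.
#'
#' @param lineages `data.frame` with `count` (cells) and `anchor` in `[0,1)`,
#'   optionally `rep_id` (default one replicate).
#' @param n_pieces Number of pieces (default 192).
#' @param n_ssc Total pool size.
#' @return If a single replicate: numeric vector of per-piece mutant cell
#'   fractions (length `n_pieces`). Otherwise a `data.table`
#'   (`rep_id`, `piece`, `frac`) of nonzero entries.
#' @export
map_to_pieces <- function(lineages, n_pieces = 192L, n_ssc) {
  ln <- as.data.table(lineages)
  single <- !("rep_id" %in% names(ln))
  if (single) ln[, rep_id := 1L]
  ln <- ln[count > 0]
  if (!nrow(ln)) {
    if (single) return(numeric(n_pieces))
    return(data.table(rep_id = integer(), piece = integer(), frac = numeric()))
  }
  piece_cells <- n_ssc / n_pieces
  s <- ln$anchor * n_pieces                      # in piece units
  len <- pmin(ln$count / piece_cells, n_pieces)
  e <- s + len
  span <- floor(e) - floor(s) + 1L
  cl <- rep(seq_len(nrow(ln)), span)
  j <- floor(s)[cl] + sequence(span) - 1L
  ov <- pmin(e[cl], j + 1) - pmax(s[cl], j)      # overlap in piece units
  ov <- pmax(ov, 0)
  out <- data.table(rep_id = ln$rep_id[cl],
                    piece = (j %% n_pieces) + 1L,
                    frac = ov)                    # fraction of a piece's cells
  out <- out[, .(frac = min(1, sum(frac))), by = .(rep_id, piece)]
  if (single) {
    v <- numeric(n_pieces)
    v[out$piece] <- out$frac
    return(v)
  }
  out[]
}

#' Apply binomial sequencing sampling to per-piece mutant fractions
#'
#' Mutant UID-family counts are Binomial(total families, piece fraction +
#' assay background for the variant's substitution type), independently per
#' piece — the sampling model of the error-corrected assay, whose per-piece
#' precision is 1/total families.
#'
#' @param fractions Numeric vector of per-piece mutant cell fractions.
#' @param params A [sim_params()].
#' @param mutation_type Substitution-type label (see [substitution_type()]),
#'   used to look up the background rate; alternatively give `background`
#'   directly.
#' @param background Optional explicit background rate (overrides type).
#' @param totals Optional per-piece total family counts (default constant
#'   `families_per_piece`).
#' @return `data.table` (piece, mutant_families, total_families).
#' @export
sample_sequencing <- function(fractions, params, mutation_type = NULL,
                              background = NULL, totals = NULL) {
  if (is.null(background)) {
    if (is.null(mutation_type)) stop("give mutation_type or background")
    if (!mutation_type %in% names(params$background_rates))
      stop("unknown mutation type: ", mutation_type)
    background <- unname(params$background_rates[mutation_type])
  }
  np <- length(fractions)
  if (is.null(totals)) totals <- rep(params$families_per_piece, np)
  stopifnot(length(totals) == np, all(totals >= 1))
  p <- pmin(1, fractions + background)
  data.table(piece = seq_len(np),
             mutant_families = rbinom(np, totals, p),
             total_families = as.integer(totals))
}

#' Simulate one variant site in one testis
#'
#' Runs the branching-process engine for a single candidate substitution,
#' places surviving clones on the piece grid and applies sequencing
#' sampling.
#'
#' @param params A [sim_params()] (use `selection_s = 0` for the neutral
#'   model).
#' @param mutation_type Substitution-type label for the background rate
#'   (default an ordinary-transition background).
#' @return Object of class `simulated_testis`: list with `piece_fraction`
#'   (true per-piece mutant cell fractions), `counts` (sampled per-piece
#'   family counts), `sperm_fraction` (mutant share of differentiation
#'   output in the final cycle) and `params`.
#' @export
simulate_testis <- function(params, mutation_type = "A>G/T>C") {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  pool <- simulate_lineage_pool(params, n_reps = 1L, record_sperm = TRUE)
  frac <- map_to_pieces(pool$lineages[, c("count", "anchor")],
                        params$n_pieces, params$n_ssc)
  counts <- sample_sequencing(frac, params, mutation_type = mutation_type)
  out <- list(piece_fraction = frac, counts = counts,
              sperm_fraction = if (adult_cycles(params) > 0L)
                (pool$sperm_frac %||% 0) else 0,
              params = params)
  class(out) <- "simulated_testis"
  out
}

#' @export
print.simulated_testis <- function(x, ...) {
  cat(sprintf(
    "simulated_testis: age %.0f, mu %.3g, s %.3g | %d/%d pieces with mutants, MaxPF %.3g\n",
    x$params$donor_age_years, x$params$mu, x$params$selection_s,
    sum(x$counts$mutant_families > 0), nrow(x$counts),
    max(x$counts$mutant_families / x$counts$total_families)))
  invisible(x)
}

#' Mutant sperm fraction at a given age
#'
#' The probability a newly conceived child inherits the variant is proxied
#' by the mutant share of the differentiation (sperm-producing) output of
#' the stem-cell pool during the cycle at the requested age.
#'
#' @param params A [sim_params()].
#' @param age Age in years (default donor age). Ages before puberty return 0
#'   with a warning.
#' @param n_reps Number of Monte-Carlo replicates.
#' @return Numeric vector of per-replicate mutant sperm fractions.
#' @export
sperm_variant_fraction <- function(params, age = params$donor_age_years,
                                   n_reps = 1L) {
  stopifnot(inherits(params, "sim_params"))
  if (age < params$puberty_age_years) {
    warning("age precedes puberty; sperm variant fraction is 0")
    return(rep(0, n_reps))
  }
  if (params$mu == 0) return(rep(0, n_reps))
  if (!is.null(params$seed)) set.seed(params$seed)
  pool <- simulate_lineage_pool(params, n_reps = n_reps, record_sperm = TRUE,
                                n_cycles = adult_cycles(params, age))
  pool$sperm_frac %||% rep(0, n_reps)
}

#' Expected mutant sperm fraction (closed form)
#'
#' By linearity of expectation over lineage arrivals, the expected mutant
#' frequency after T adult cycles is
#' `mu * ((1+2s)^T - 1) / (2s)` for adult-origin lineages (T*mu when s = 0)
#' plus `(G/2) * mu * (1+2s)^T` for growth-phase lineages; the
#' differentiation output weights mutants by `(1 - 2s)` relative to wild
#' type. Used for the birth-rate integral, where Monte-Carlo estimates of a
#' jackpot-dominated expectation would be prohibitively noisy.
#'
#' @param params A [sim_params()].
#' @param age Age in years.
#' @return Expected mutant sperm fraction (0 before puberty).
#' @export
expected_sperm_fraction <- function(params, age = params$donor_age_years) {
  if (age < params$puberty_age_years) return(0)
  tt <- adult_cycles(params, age)
  s <- params$selection_s; mu <- params$mu; G <- params$growth_generations
  adult <- if (s > 0) ((1 + 2 * s)^tt - 1) / (2 * s) else tt
  growth <- (G / 2) * (1 + 2 * s)^tt
  mu * (adult + growth) * (1 - 2 * s)
}

#' Paternal-age distributions for the birth-rate prediction
#'
#' `study_donor_ages()` puts equal weight on the two older donor ages (65
#' and 68) — the ages at which the selection model is constrained by the
#' testis data and at which the measured average testis frequency proxies
#' the transmission probability. This is the default for
#' [predict_birth_rate()] and reproduces the study's procedure.
#' `population_paternal_ages()` is a discretized bell-shaped population
#' distribution of fathers' ages at conception (default mean 31, SD 6.5,
#' support 18-55), provided for sensitivity analyses: because clonal
#' expansion is exponential in age, rates integrated over young fatherhood
#' ages are one to two orders of magnitude lower.
#'
#' @param mean,sd Location and spread of the population distribution.
#' @return `data.frame` with `age` and normalized `weight`.
#' @export
study_donor_ages <- function() {
  data.frame(age = c(65, 68), weight = c(0.5, 0.5))
}

#' @rdname study_donor_ages
#' @export
population_paternal_ages <- function(mean = 31, sd = 6.5) {
  age <- 18:55
  w <- dnorm(age, mean = mean, sd = sd)
  data.frame(age = age, weight = w / sum(w))
}

#' Predict the Noonan-syndrome birth rate from the selection model
#'
#' Under the equal-contribution assumption, the predicted birth rate is
#' `n_sites` times the expected mutant sperm fraction averaged over the
#' paternal-age distribution, each site behaving like the calibrated exon-3
#' variant. The default age distribution evaluates the model at the study's
#' donor ages (see [study_donor_ages()]).
#'
#' @param params A calibrated [sim_params()] (see [calibrate_selection()]);
#'   uncalibrated parameters are rejected unless `allow_uncalibrated`.
#' @param n_sites Number of contributing variant sites (default 110, the
#'   filtered count of NS1 missense sites in the gene).
#' @param age_dist `data.frame` with `age`, `weight` (defaults to
#'   [study_donor_ages()]).
#' @param allow_uncalibrated Set `TRUE` to bypass the calibration check.
#' @return Predicted birth rate (births per birth).
#' @export
predict_birth_rate <- function(params, n_sites = 110L,
                               age_dist = study_donor_ages(),
                               allow_uncalibrated = FALSE) {
  stopifnot(inherits(params, "sim_params"), n_sites >= 1L)
  if (!isTRUE(attr(params, "calibrated")) && !allow_uncalibrated)
    stop("params are not calibrated; run calibrate_selection() or set ",
         "allow_uncalibrated = TRUE")
  stopifnot(all(c("age", "weight") %in% names(age_dist)),
            all(age_dist$weight >= 0))
  w <- age_dist$weight / sum(age_dist$weight)
  per_site <- sum(w * vapply(age_dist$age, function(a)
    expected_sperm_fraction(params, a), numeric(1)))
  n_sites * per_site
}
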