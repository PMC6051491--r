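#' Sequence simulation parameters
#'
#' Generator of protein sequences with a planted charge composition, a
#' disorder layout, and preferential placement of acidic residues inside
#' disordered segments — the structure probed by the halophilicity
#' profiler.
#'
#' @param length Sequence length in residues.
#' @param target_acidic_fraction,target_basic_fraction Target fractions of
#'   acidic (D+E) and basic (R+K) residues; must sum to <= 1.
#' @param disorder_segments List of `c(start, end)` 1-based inclusive
#'   intervals marking disordered regions.
#' @param acidic_enrichment_in_disorder Fraction of each acidic residue
#'   class (Asp, Glu separately) placed inside disorder segments; applied
#'   deterministically (counts are rounded), so the realized per-tag
#'   in-disorder fraction matches the parameter to rounding accuracy.
#' @param asp_fraction_of_acidic Fraction of acidic residues that are Asp
#'   (default 0.5).
#' @param domain_layout Optional data frame (`name`, `start`, `end`) of
#'   non-overlapping, ordered domain annotations.
#' @param seed Integer seed.
#' @return An object of class `sequence_sim_params`.
#' @export
sequence_sim_params <- function(length, target_acidic_fraction = 0.15,
                                target_basic_fraction = 0.10,
                                disorder_segments = list(),
                                acidic_enrichment_in_disorder = 0.5,
                                asp_fraction_of_acidic = 0.5,
                                domain_layout = NULL, seed = 1L) {
  check_that(length >= 1, "length", "must be >= 1")
  check_that(target_acidic_fraction >= 0 && target_acidic_fraction <= 1,
             "target_acidic_fraction", "must lie in [0, 1]")
  check_that(target_basic_fraction >= 0 && target_basic_fraction <= 1,
             "target_basic_fraction", "must lie in [0, 1]")
  if (target_acidic_fraction + target_basic_fraction > 1)
    halopol_error("target acidic and basic fractions sum to more than 1: composition infeasible",
                  "halopol_validation_error")
  check_that(acidic_enrichment_in_disorder >= 0 &&
               acidic_enrichment_in_disorder <= 1,
             "acidic_enrichment_in_disorder", "must lie in [0, 1]")
  check_that(asp_fraction_of_acidic >= 0 && asp_fraction_of_acidic <= 1,
             "asp_fraction_of_acidic", "must lie in [0, 1]")
  for (seg in disorder_segments) {
    check_that(base::length(seg) == 2 && seg[1] >= 1 && seg[2] <= length &&
                 seg[1] <= seg[2],
               "disorder_segments", "intervals must lie within [1, length]")
  }
  if (!is.null(domain_layout)) validate_domains(domain_layout, length)
  structure(list(length = as.integer(length),
                 target_acidic_fraction = target_acidic_fraction,
                 target_basic_fraction = target_basic_fraction,
                 disorder_segments = disorder_segments,
                 acidic_enrichment_in_disorder = acidic_enrichment_in_disorder,
                 asp_fraction_of_acidic = asp_fraction_of_acidic,
                 domain_layout = domain_layout, seed = as.integer(seed)),
            class = "sequence_sim_params")
}

#' Simulate a protein sequence with planted composition and disorder layout
#'
#' Places `round(length * target)` acidic and basic residues so realized
#' fractions match the targets to 1/length; acidic residues (split into Asp
#' and Glu) go preferentially into disorder segments per the enrichment
#' parameter; remaining positions draw uniformly from the 16 non-charged
#' residues. The disorder track is >= 0.5 inside the planted segments and
#' < 0.5 outside.
#'
#' @param params A [sequence_sim_params()] object.
#' @return List of class `sequence_simulation`: `record` (list with `id`,
#'   `residues`), `disorder` (numeric track), `domains` (or `NULL`) and
#'   `truth` (planted counts and per-tag in-disorder fractions).
#' @export
simulate_sequence <- function(params) {
  stopifnot(inherits(params, "sequence_sim_params"))
  p <- params
  n <- p$length
  dis_pos <- sort(unique(unlist(lapply(p$disorder_segments, function(s)
    seq.int(s[1], s[2])))))
  ord_pos <- setdiff(seq_len(n), dis_pos)
  n_acid <- round(n * p$target_acidic_fraction)
  n_basic <- round(n * p$target_basic_fraction)
  n_asp <- round(n_acid * p$asp_fraction_of_acidic)
  n_glu <- n_acid - n_asp
  enrich <- if (length(dis_pos) == 0) 0 else p$acidic_enrichment_in_disorder
  n_asp_dis <- round(n_asp * enrich)
  n_glu_dis <- round(n_glu * enrich)
  if (n_asp_dis + n_glu_dis > length(dis_pos))
    halopol_error("disorder segments too small for the requested acidic enrichment",
                  "halopol_validation_error")
  if ((n_asp - n_asp_dis) + (n_glu - n_glu_dis) > length(ord_pos))
    halopol_error("ordered region too small for the acidic residues outside disorder",
                  "halopol_validation_error")
  with_private_seed(p$seed, {
    res <- character(n)
    pick <- function(pool, k) if (k == 0) integer(0) else
      pool[sample.int(length(pool), k)]
    asp_dis <- pick(dis_pos, n_asp_dis)
    glu_dis <- pick(setdiff(dis_pos, asp_dis), n_glu_dis)
    asp_ord <- pick(ord_pos, n_asp - n_asp_dis)
    glu_ord <- pick(setdiff(ord_pos, asp_ord), n_glu - n_glu_dis)
    res[c(asp_dis, asp_ord)] <- "D"
    res[c(glu_dis, glu_ord)] <- "E"
    free <- which(res == "")
    basic_pos <- pick(free, n_basic)
    res[basic_pos] <- sample(BASIC, n_basic, replace = TRUE)
    free <- which(res == "")
    other <- setdiff(AA20, c(ACIDIC, BASIC))
    res[free] <- sample(other, length(free), replace = TRUE)
    track <- stats::runif(n, 0.05, 0.45)
    track[dis_pos] <- stats::runif(length(dis_pos), 0.55, 0.95)
    truth <- list(
      n_acidic = n_acid, n_basic = n_basic,
      n_asp = n_asp, n_glu = n_glu,
      asp_in_disorder_frac = if (n_asp > 0) n_asp_dis / n_asp else NA_real_,
      glu_in_disorder_frac = if (n_glu > 0) n_glu_dis / n_glu else NA_real_,
      asp_positions = sort(c(asp_dis, asp_ord)),
      glu_positions = sort(c(glu_dis, glu_ord)))
    structure(list(
      record = list(id = sprintf("synthetic_%d", p$seed),
                    residues = paste(res, collapse = "")),
      disorder = track,
      domains = p$domain_layout,
      truth = truth, params = p),
      class = "sequence_simulation")
  })
}
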