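# Residue classes used throughout: halophilic adaptation statistics count
# acidic = {D, E} and basic = {R, K} only (His excluded; no pKa modelling).
ACIDIC <- c("D", "E")
BASIC <- c("R", "K")
BULKY <- c("F", "I", "L")
SMALL <- c("G", "A", "S", "T")
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

seq_chars <- function(seq) {
  if (is.list(seq) && !is.null(seq$residues)) seq <- seq$residues
  if (length(seq) == 1 && is.character(seq)) seq <- strsplit(seq, "")[[1]]
  toupper(as.character(seq))
}

#' Charge composition of a protein sequence
#'
#' Counts and percentages of acidic (Asp+Glu) and basic (Arg+Lys) residues
#' and their ratio, the primary sequence signature of halophilic
#' adaptation (excess surface carboxylates). `X` and other non-standard
#' letters are excluded from numerators and denominators.
#'
#' @param seq A sequence: character string, character vector of residues,
#'   or a list with a `residues` field.
#' @return List of class `charge_profile`: `n_acidic`, `n_basic`,
#'   `n_total`, `pct_acidic`, `pct_basic`, `ratio_neg_pos` (`NA` with a
#'   message when there are no basic residues).
#' @export
charge_composition <- function(seq) {
  ch <- seq_chars(seq)
  ch <- ch[ch %in% AA20]
  n <- length(ch)
  if (n == 0) halopol_error("sequence contains no standard residues",
                            "halopol_validation_error")
  na <- sum(ch %in% ACIDIC)
  nb <- sum(ch %in% BASIC)
  ratio <- if (nb > 0) na / nb else NA_real_
  if (nb == 0) message("no basic residues: negative/positive ratio is undefined")
  structure(list(n_acidic = na, n_basic = nb, n_total = n,
                 pct_acidic = 100 * na / n, pct_basic = 100 * nb / n,
                 ratio_neg_pos = ratio),
            class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat(sprintf("Charge: %.1f%% acidic (D+E, n=%d), %.1f%% basic (R+K, n=%d), -/+ ratio %s\n",
              x$pct_acidic, x$n_acidic, x$pct_basic, x$n_basic,
              if (is.na(x$ratio_neg_pos)) "undefined" else
                sprintf("%.2f", x$ratio_neg_pos)))
  invisible(x)
}

validate_domains <- function(domains, seq_len) {
  stopifnot(is.data.frame(domains),
            all(c("name", "start", "end") %in% names(domains)))
  if (any(domains$start < 1 | domains$end > seq_len | domains$start > domains$end))
    halopol_error("domain boundaries outside the sequence",
                  "halopol_validation_error")
  d <- domains[order(domains$start), , drop = FALSE]
  if (nrow(d) > 1 && any(d$start[-1] <= d$end[-nrow(d)]))
    halopol_error("domains overlap", "halopol_validation_error")
  d
}

#' Per-domain charge profiles
#'
#' [charge_composition()] restricted to each annotated domain (1-based
#' inclusive residue ranges, e.g. N-terminal / exonuclease / palm / fingers
#' / thumb).
#'
#' @param seq A sequence (see [charge_composition()]).
#' @param domains Data frame with columns `name`, `start`, `end` (1-based
#'   inclusive, non-overlapping).
#' @return Named list of `charge_profile` objects, one per domain.
#' @export
domain_charge_profiles <- function(seq, domains) {
  ch <- seq_chars(seq)
  domains <- validate_domains(domains, length(ch))
  out <- lapply(seq_len(nrow(domains)), function(i)
    charge_composition(ch[domains$start[i]:domains$end[i]]))
  names(out) <- domains$name
  out
}

#' Hydrophobic side-chain classes
#'
#' Counts and percentages of hydrophobic residues with bulky side chains
#' (Phe, Ile, Leu) versus small side chains (Gly, Ala, Ser, Thr); halophilic
#' proteins shift toward the small class.
#'
#' @param seq A sequence (see [charge_composition()]).
#' @return List of class `hydrophobic_classes`: `n_bulky`, `n_small`,
#'   `n_total`, `pct_bulky`, `pct_small`.
#' @export
hydrophobic_classes <- function(seq) {
  ch <- seq_chars(seq)
  ch <- ch[ch %in% AA20]
  n <- length(ch)
  if (n == 0) halopol_error("sequence contains no standard residues",
                            "halopol_validation_error")
  nb <- sum(ch %in% BULKY)
  ns <- sum(ch %in% SMALL)
  structure(list(n_bulky = nb, n_small = ns, n_total = n,
                 pct_bulky = 100 * nb / n, pct_small = 100 * ns / n),
            class = "hydrophobic_classes")
}

#' Build an aligned pair from two gapped sequences
#'
#' Accepts the output of any standard pairwise global aligner as two
#' equal-length gapped strings (`-` for gaps) and converts it to an
#' explicit column map.
#'
#' @param query_aln,subject_aln Gapped aligned sequences (equal length).
#' @param query_id,subject_id Identifiers.
#' @return List of class `aligned_pair` with `columns` (data frame
#'   `query_pos`, `subject_pos`, `query_res`, `subject_res`; `NA` position
#'   marks a gap) and the degapped sequences.
#' @export
aligned_pair <- function(query_aln, subject_aln,
                         query_id = "query", subject_id = "subject") {
  q <- seq_chars(query_aln)
  s <- seq_chars(subject_aln)
  if (length(q) != length(s))
    halopol_error("aligned sequences must have equal length",
                  "halopol_validation_error")
  qgap <- q == "-"; sgap <- s == "-"
  if (any(qgap & sgap))
    halopol_error("alignment has a gap-gap column", "halopol_validation_error")
  columns <- data.frame(
    query_pos = ifelse(qgap, NA_integer_, cumsum(!qgap)),
    subject_pos = ifelse(sgap, NA_integer_, cumsum(!sgap)),
    query_res = ifelse(qgap, NA_character_, q),
    subject_res = ifelse(sgap, NA_character_, s))
  structure(list(query_id = query_id, subject_id = subject_id,
                 columns = columns,
                 query_seq = paste(q[!qgap], collapse = ""),
                 subject_seq = paste(s[!sgap], collapse = "")),
            class = "aligned_pair")
}

#' Unique acidic residues relative to a homolog
#'
#' Query positions carrying Asp or Glu where the aligned subject residue is
#' not acidic. By default a query residue aligned to a gap also counts as
#' unique (insertions have no homologous counterpart); disable with
#' `gap_is_unique = FALSE`.
#'
#' @param pair An [aligned_pair()].
#' @param query,subject Optional ungapped sequences to validate the
#'   alignment against.
#' @param gap_is_unique Count query-to-gap columns as unique (default TRUE).
#' @return Data frame with `position` (1-based query coordinate), `residue`
#'   (`"D"` or `"E"`) and `subject_residue` (`NA` for gap).
#' @export
unique_acidic_positions <- function(pair, query = NULL, subject = NULL,
                                    gap_is_unique = TRUE) {
  stopifnot(inherits(pair, "aligned_pair"))
  if (!is.null(query) &&
      paste(seq_chars(query), collapse = "") != pair$query_seq)
    halopol_error("alignment is inconsistent with the query sequence",
                  "halopol_alignment_error")
  if (!is.null(subject) &&
      paste(seq_chars(subject), collapse = "") != pair$subject_seq)
    halopol_error("alignment is inconsistent with the subject sequence",
                  "halopol_alignment_error")
  cols <- pair$columns
  is_q_acidic <- !is.na(cols$query_res) & cols$query_res %in% ACIDIC
  s_acidic <- !is.na(cols$subject_res) & cols$subject_res %in% ACIDIC
  keep <- is_q_acidic & !s_acidic &
    (gap_is_unique | !is.na(cols$subject_res))
  data.frame(position = cols$query_pos[keep],
             residue = cols$query_res[keep],
             subject_residue = cols$subject_res[keep])
}

#' Overlap of tagged positions with a disorder track
#'
#' Fraction of positions falling in predicted disordered regions
#' (per-residue disorder probability at or above `threshold`), overall and
#' split by residue tag (Asp vs Glu for unique-acidic positions).
#'
#' @param positions Data frame with `position` and `residue` columns (as
#'   returned by [unique_acidic_positions()]), or an integer vector.
#' @param track Numeric vector of per-residue disorder probabilities in
#'   `[0, 1]`, or a data frame with a `probability` column.
#' @param threshold Disorder call threshold (default 0.5).
#' @return List of class `disorder_overlap` with `overall_pct`, `by_tag`
#'   (named percentages), `n_positions`, `n_in_disorder`. Empty position
#'   sets give `NA` percentages (not applicable), not 0.
#' @export
disorder_overlap <- function(positions, track, threshold = 0.5) {
  if (is.data.frame(track)) track <- track$probability
  track <- as.numeric(track)
  if (any(track < 0 | track > 1))
    halopol_error("disorder probabilities must lie in [0, 1]",
                  "halopol_validation_error")
  if (is.data.frame(positions)) {
    pos <- positions$position
    tag <- as.character(positions$residue)
  } else {
    pos <- as.integer(positions)
    tag <- rep(NA_character_, length(pos))
  }
  if (length(pos) && (min(pos) < 1 || max(pos) > length(track)))
    halopol_error("position beyond the disorder track", "halopol_validation_error")
  in_dis <- track[pos] >= threshold
  pct <- function(x) if (length(x) == 0) NA_real_ else 100 * mean(x)
  by_tag <- if (all(is.na(tag))) NULL else
    vapply(split(in_dis, tag), pct, 0)
  structure(list(overall_pct = pct(in_dis), by_tag = by_tag,
                 n_positions = length(pos), n_in_disorder = sum(in_dis),
                 threshold = threshold),
            class = "disorder_overlap")
}

#' @export
print.disorder_overlap <- function(x, ...) {
  if (x$n_positions == 0) {
    cat("Disorder overlap: not applicable (no positions)\n")
  } else {
    cat(sprintf("Disorder overlap: %.1f%% of %d positions (threshold %.2f)\n",
                x$overall_pct, x$n_positions, x$threshold))
    if (!is.null(x$by_tag))
      for (tg in names(x$by_tag))
        cat(sprintf("  %s: %.1f%%\n", tg, x$by_tag[[tg]]))
  }
  invisible(x)
}
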