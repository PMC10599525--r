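#' Count sense codons in a set of codon sequences
#'
#' Tallies occurrences of each of the 61 sense codons over a list of
#' codon-level sequences (e.g. 5' windows or gene cores). Stop codons
#' must have been removed upstream: windows are stop-free by
#' construction, so meeting one here is treated as a data error.
#' Codons containing characters outside ACGT are silently excluded
#' from the tally (they are pre-flagged at ingest).
#'
#' @param sequences list of character vectors, each element a codon
#' @param code a [genetic_code_partition()]
#' @return object of class `codon_counts`: named integer vector over the
#'   sense codons with attribute `total`
#' @export
count_codons <- function(sequences, code = genetic_code_partition()) {
  all_codons <- unlist(sequences, use.names = FALSE)
  if (length(all_codons) && any(all_codons %in% STOP_CODONS))
    stop("stop codon encountered inside a counting window")
  clean <- all_codons[grepl("^[ACGT]{3}$", all_codons)]
  bad <- clean[!clean %in% code$sense_codons]
  if (length(bad))
    stop("non-sense codon encountered: ", paste(unique(bad), collapse = ", "))
  counts <- table(factor(clean, levels = code$sense_codons))
  out <- as.integer(counts)
  names(out) <- code$sense_codons
  structure(out, total = sum(out), class = "codon_counts")
}

#' Log odds ratio and standard error from one 2x2 count cell
#'
#' The enrichment of a focal codon against its synonyms in a target set
#' relative to a comparator set:
#' `log_odds = ln((n1/s1) / (n2/s2))` with
#' `se = sqrt(1/n1 + 1/s1 + 1/n2 + 1/s2)`,
#' where `n` counts the focal codon and `s` its synonyms. With a zero
#' cell the uncorrected ratio is undefined; `correction = "half-unit"`
#' applies the Haldane-Anscombe correction (add 0.5 to all four cells,
#' flagged `corrected`), `correction = "drop"` returns an NA entry.
#'
#' @param n1,s1 focal-codon and synonym counts in the target set
#' @param n2,s2 focal-codon and synonym counts in the comparator set
#' @param correction `"half-unit"` (default) or `"drop"`
#' @return list with `log_odds`, `se`, `corrected`
#' @examples
#' log_odds_cell(8, 2, 2, 8)  # ln(16), se = sqrt(1.25)
#' @export
log_odds_cell <- function(n1, s1, n2, s2, correction = c("half-unit", "drop")) {
  correction <- match.arg(correction)
  if ((n1 + s1) == 0 || (n2 + s2) == 0)
    return(list(log_odds = NA_real_, se = NA_real_, corrected = NA))
  if (all(c(n1, s1, n2, s2) > 0)) {
    list(
      log_odds = log((n1 / s1) / (n2 / s2)),
      se = sqrt(1 / n1 + 1 / s1 + 1 / n2 + 1 / s2),
      corrected = FALSE
    )
  } else if (correction == "half-unit") {
    a <- n1 + 0.5; b <- s1 + 0.5; c <- n2 + 0.5; d <- s2 + 0.5
    list(
      log_odds = log((a / b) / (c / d)),
      se = sqrt(1 / a + 1 / b + 1 / c + 1 / d),
      corrected = TRUE
    )
  } else {
    list(log_odds = NA_real_, se = NA_real_, corrected = NA)
  }
}

#' Per-codon log-odds enrichment vector between two codon count sets
#'
#' For each scored codon `c` in synonymous block `B`, forms the 2x2 table
#' (count of `c`, count of other members of `B`) in the target and the
#' comparator sets and evaluates [log_odds_cell()]. The standard
#' partition yields a 59-entry vector; a partition with redefined blocks
#' (see [genetic_code_partition()]) adjusts the scored-codon set
#' accordingly.
#'
#' @param target,comparator `codon_counts` objects
#' @param code a [genetic_code_partition()]
#' @param label optional character label (e.g. `"V_edIO"`)
#' @param correction zero-cell policy, see [log_odds_cell()]
#' @return object of class `log_odds_vector`: a data.frame with columns
#'   `codon`, `block`, `log_odds`, `se`, `n_codon_target`,
#'   `n_syn_target`, `n_codon_comp`, `n_syn_comp`, `corrected`; rows in
#'   alphabetical codon order; attribute `label`.
#' @export
log_odds_vector <- function(target, comparator,
                            code = genetic_code_partition(),
                            label = NULL,
                            correction = c("half-unit", "drop")) {
  correction <- match.arg(correction)
  stopifnot(inherits(target, "codon_counts"), inherits(comparator, "codon_counts"))
  scored <- code$scored_codons
  n <- length(scored)
  res <- data.frame(
    codon = scored,
    block = unname(code$block_of[scored]),
    log_odds = NA_real_, se = NA_real_,
    n_codon_target = NA_integer_, n_syn_target = NA_integer_,
    n_codon_comp = NA_integer_, n_syn_comp = NA_integer_,
    corrected = NA,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    cdn <- scored[i]
    blk <- code$blocks[[code$block_of[cdn]]]
    syn <- setdiff(blk, cdn)
    n1 <- as.integer(target[cdn]); s1 <- as.integer(sum(target[syn]))
    n2 <- as.integer(comparator[cdn]); s2 <- as.integer(sum(comparator[syn]))
    cell <- log_odds_cell(n1, s1, n2, s2, correction)
    res$n_codon_target[i] <- n1; res$n_syn_target[i] <- s1
    res$n_codon_comp[i] <- n2; res$n_syn_comp[i] <- s2
    res$log_odds[i] <- cell$log_odds
    res$se[i] <- cell$se
    res$corrected[i] <- cell$corrected
  }
  structure(res, label = label, class = c("log_odds_vector", "data.frame"))
}

#' @export
print.log_odds_vector <- function(x, ...) {
  lbl <- attr(x, "label")
  cat("Log-odds enrichment vector", if (!is.null(lbl)) paste0("(", lbl, ")"),
      "-", nrow(x), "codons\n")
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Per-position log-odds vectors
#'
#' Computes one log-odds vector per requested codon position from
#' position-aligned target and comparator sequence sets (e.g. the
#' transgene 5' windows at positions 2-11). Each position contributes a
#' single codon per sequence.
#'
#' @param target_seqs,comparator_seqs lists of codon character vectors,
#'   aligned so that element `p` of each vector is the codon at position
#'   `positions[p]`... sequences must cover all requested indices.
#' @param positions integer vector of 1-based indices into each sequence
#' @param code a [genetic_code_partition()]
#' @param position_labels optional labels (defaults to `positions`)
#' @param correction zero-cell policy
#' @return object of class `positional_matrix`: named list of
#'   `log_odds_vector`s, one per position, sharing codon order
#' @export
positional_log_odds <- function(target_seqs, comparator_seqs, positions,
                                code = genetic_code_partition(),
                                position_labels = positions,
                                correction = "half-unit") {
  check_cover <- function(seqs, who) {
    short <- which(lengths(seqs) < max(positions))
    if (length(short))
      stop(who, " sequence(s) too short for requested positions: ",
           paste(utils::head(short, 5), collapse = ", "))
  }
  check_cover(target_seqs, "target")
  check_cover(comparator_seqs, "comparator")
  out <- lapply(seq_along(positions), function(i) {
    p <- positions[i]
    tc <- count_codons(lapply(target_seqs, `[`, p), code)
    cc <- count_codons(lapply(comparator_seqs, `[`, p), code)
    log_odds_vector(tc, cc, code, label = paste0("pos", position_labels[i]),
                    correction = correction)
  })
  names(out) <- as.character(position_labels)
  structure(out, class = "positional_matrix")
}

#' Assemble a positional matrix into a subjects-by-items numeric matrix
#'
#' Rows are scored codons, columns positions; suitable input for
#' [cronbach_alpha()] or a correlation matrix across positions.
#' @param pm a `positional_matrix`
#' @return numeric matrix (codons x positions)
#' @export
positional_matrix_values <- function(pm) {
  stopifnot(inherits(pm, "positional_matrix"))
  m <- vapply(pm, function(v) v$log_odds, numeric(nrow(pm[[1]])))
  rownames(m) <- pm[[1]]$codon
  m
}
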