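## Transgene construct pipeline: within-group normalisation, expression
## stratification, and the experimentally derived initiation-optimality
## vector (V_edIO).

#' Read a transgene construct table
#'
#' Header-mapped TSV/CSV with columns `group_id`, `variant_id`,
#' `sequence` (nucleotides of the variable region, first 11 codons
#' including the start), and `protein_ratio` and/or `prot_fcc`, plus an
#' optional `censor` column (`none`, `above-range`, `below-range`).
#' Unknown columns are ignored.
#'
#' @param path file path
#' @param sep field separator (`"\t"` default; `","` for CSV)
#' @return data.frame of class `construct_table`
#' @export
read_construct_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  as_construct_table(df)
}

#' Validate/coerce a data.frame into a construct table
#' @param df data.frame with construct columns
#' @return data.frame of class `construct_table`
#' @export
as_construct_table <- function(df) {
  need <- c("group_id", "variant_id", "sequence")
  if (!all(need %in% names(df)))
    stop("construct table must have columns: ", paste(need, collapse = ", "))
  if (!"censor" %in% names(df)) df$censor <- "none"
  df$censor[is.na(df$censor) | df$censor == ""] <- "none"
  bad <- setdiff(unique(df$censor), c("none", "above-range", "below-range"))
  if (length(bad)) stop("unknown censor values: ", paste(bad, collapse = ", "))
  if (!"protein_ratio" %in% names(df) && !"prot_fcc" %in% names(df))
    stop("need protein_ratio or prot_fcc")
  class(df) <- c("construct_table", "data.frame")
  df
}

construct_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3L != 0L) stop("construct sequence length not a multiple of 3")
  substring(sequence, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Normalise protein levels within synonymous construct groups
#'
#' Fills `prot_fcc` as each construct's reporter ratio divided by the
#' mean ratio of the uncensored members of its group (nominally 13
#' synonymous variants sharing promoter, RBS and N-terminal amino acid
#' sequence). Censored members keep their flag and get `NA`. Groups with
#' fewer than two uncensored members are dropped.
#'
#' @param tbl a `construct_table` with `protein_ratio`
#' @param min_uncensored minimum uncensored members per group (default 2)
#' @return the table with `prot_fcc` filled; dropped group ids in
#'   attribute `"dropped_groups"`
#' @export
compute_prot_fcc <- function(tbl, min_uncensored = 2L) {
  stopifnot("protein_ratio" %in% names(tbl))
  usable <- tbl$censor == "none" & !is.na(tbl$protein_ratio) & tbl$protein_ratio > 0
  bad_ratio <- tbl$censor == "none" & (!is.na(tbl$protein_ratio) & tbl$protein_ratio <= 0)
  if (any(bad_ratio)) tbl$censor[bad_ratio] <- "non-positive-ratio"
  means <- tapply(tbl$protein_ratio[usable], tbl$group_id[usable], mean)
  counts <- table(tbl$group_id[usable])
  ok_groups <- names(counts)[counts >= min_uncensored]
  dropped <- setdiff(unique(tbl$group_id), ok_groups)
  tbl <- tbl[tbl$group_id %in% ok_groups, , drop = FALSE]
  tbl$prot_fcc <- ifelse(tbl$censor == "none" & !is.na(tbl$protein_ratio),
                         tbl$protein_ratio / means[tbl$group_id], NA_real_)
  attr(tbl, "dropped_groups") <- dropped
  tbl
}

#' Stratify constructs by normalised protein level
#'
#' Ranks constructs by `prot_fcc` with `above-range` censored records
#' above all numeric values and `below-range` below all, then takes the
#' highest `ceil(upper_frac * N)` and lowest `ceil(lower_frac * N)`
#' records (nearest-rank quantiles). Ties are broken by a stable sort on
#' `variant_id`.
#'
#' @param tbl a `construct_table` with `prot_fcc` and `censor`
#' @param upper_frac,lower_frac quantile fractions (default 0.25 each)
#' @return list with `top` and `bottom` (row subsets of `tbl`)
#' @export
stratify_constructs <- function(tbl, upper_frac = 0.25, lower_frac = 0.25) {
  if (upper_frac + lower_frac > 1) stop("upper_frac + lower_frac > 1")
  usable <- tbl[tbl$censor %in% c("none", "above-range", "below-range"), , drop = FALSE]
  if (nrow(usable) < 4) stop("need at least 4 usable records")
  key <- usable$prot_fcc
  key[usable$censor == "above-range"] <- Inf
  key[usable$censor == "below-range"] <- -Inf
  keep <- !is.na(key)
  usable <- usable[keep, , drop = FALSE]
  key <- key[keep]
  ord <- order(key, usable$variant_id, decreasing = FALSE, method = "radix")
  usable <- usable[ord, , drop = FALSE]
  n <- nrow(usable)
  n_top <- ceiling(upper_frac * n)
  n_bot <- ceiling(lower_frac * n)
  list(top = usable[(n - n_top + 1L):n, , drop = FALSE],
       bottom = usable[seq_len(n_bot), , drop = FALSE])
}

#' Derive the experimental initiation-optimality vector (V_edIO)
#'
#' Pools the codons at `position_range` of the variable region (start
#' codon at position 1 is never scored) over the top expression stratum
#' (target) and the bottom stratum (comparator), and computes the
#' per-codon log-odds vector.
#'
#' @param tbl a `construct_table` with `prot_fcc` (see
#'   [compute_prot_fcc()])
#' @param code a [genetic_code_partition()]
#' @param position_range codon positions scored (default `2:11`; the
#'   constructs' variable region is their first 11 codons)
#' @param upper_frac,lower_frac stratification fractions (default 0.25)
#' @param correction zero-cell policy, see [log_odds_cell()]
#' @return a `log_odds_vector` labelled `"V_edIO"`
#' @export
derive_edio <- function(tbl, code = genetic_code_partition(),
                        position_range = 2:11,
                        upper_frac = 0.25, lower_frac = 0.25,
                        correction = "half-unit") {
  strata <- stratify_constructs(tbl, upper_frac, lower_frac)
  slice <- function(rows) {
    lapply(rows$sequence, function(s) construct_codons(s)[position_range])
  }
  tc <- count_codons(slice(strata$top), code)
  bc <- count_codons(slice(strata$bottom), code)
  log_odds_vector(tc, bc, code, label = "V_edIO", correction = correction)
}
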