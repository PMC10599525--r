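## CSV round-trip for log-odds vectors, header-name mapped so tables
## with extra columns (or only codon + log_odds columns) load too.

#' Write a log-odds vector to CSV
#'
#' Columns: `codon`, `log_odds`, `se`, `n_codon_target`, `n_syn_target`,
#' `n_codon_comp`, `n_syn_comp`, `corrected`.
#'
#' @param vec a `log_odds_vector`
#' @param path output file
#' @export
write_logodds_vector <- function(vec, path) {
  stopifnot(inherits(vec, "log_odds_vector"))
  cols <- c("codon", "log_odds", "se", "n_codon_target", "n_syn_target",
            "n_codon_comp", "n_syn_comp", "corrected")
  utils::write.csv(as.data.frame(vec)[, cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a log-odds vector from CSV
#'
#' Maps columns by header name: requires `codon` and a log-odds column
#' (`log_odds`, or any single column besides `codon` when
#' `value_col` is given). Count/SE columns are picked up when present;
#' extra columns are ignored.
#'
#' @param path input file
#' @param value_col name of the log-odds column (default `"log_odds"`)
#' @param label optional label for the vector
#' @return a `log_odds_vector` (count columns NA when absent)
#' @export
read_logodds_vector <- function(path, value_col = "log_odds", label = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"codon" %in% names(df)) stop("no codon column in ", path)
  if (!value_col %in% names(df)) stop("no '", value_col, "' column in ", path)
  pick <- function(col, default) if (col %in% names(df)) df[[col]] else default
  n <- nrow(df)
  out <- data.frame(
    codon = toupper(gsub("U", "T", df$codon)),
    block = NA_character_,
    log_odds = as.numeric(df[[value_col]]),
    se = as.numeric(pick("se", rep(NA_real_, n))),
    n_codon_target = pick("n_codon_target", rep(NA_integer_, n)),
    n_syn_target = pick("n_syn_target", rep(NA_integer_, n)),
    n_codon_comp = pick("n_codon_comp", rep(NA_integer_, n)),
    n_syn_comp = pick("n_syn_comp", rep(NA_integer_, n)),
    corrected = pick("corrected", rep(NA, n)),
    stringsAsFactors = FALSE
  )
  code <- genetic_code_partition()
  known <- out$codon %in% names(code$block_of)
  out$block[known] <- unname(code$block_of[out$codon[known]])
  out <- out[order(out$codon), ]
  rownames(out) <- NULL
  structure(out, label = label, class = c("log_odds_vector", "data.frame"))
}

#' Write a genome-survey table as TSV
#' @param survey a `genome_survey` or its table
#' @param path output file
#' @export
write_survey_table <- function(survey, path) {
  utils::write.table(survey_table(survey), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
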