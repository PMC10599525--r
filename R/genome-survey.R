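## Multi-genome 5'-versus-core survey and the GC3 / growth-temperature
## models for the cross-genome correlation with a reference vector.

#' Survey genomes for 5'-versus-core enrichment against a reference
#'
#' For each genome, derives its V_5-core log-odds vector, correlates it
#' (Pearson, two-sided) against a reference vector (typically V_edIO),
#' and records mean per-gene GC3. Input genomes may be given as file
#' paths (parsed and filtered via [parse_cds_collection()] and
#' [filter_cds()]) or as pre-built lists of filtered `cds_record`s.
#' Bonferroni-adjusted p-values use the number of surveyed genomes as
#' the correction factor. Rows with fewer than 50 retained genes are
#' flagged unstable; genomes with no retained CDS are skipped.
#'
#' @param genomes named list; each element a file path or a list of
#'   `cds_record`s. Names are the accessions.
#' @param reference a `log_odds_vector` or named numeric vector
#' @param code a [genetic_code_partition()]
#' @param format file format when elements are paths
#' @param region_len,five_prime_start window parameters
#' @param covariates optional data.frame with `accession` and any of
#'   `pogt`, `dg5`, `dgcore` (merged onto the output)
#' @return list of class `genome_survey`: `table` (one row per genome:
#'   `accession`, `n_genes`, `r`, `p_value`, `p_bonferroni`, `gc3`,
#'   `unstable`, plus covariates) and `vectors` (named list of the
#'   per-genome `log_odds_vector`s), rows ordered by accession
#' @export
survey_genomes <- function(genomes, reference,
                           code = genetic_code_partition(),
                           format = "fasta",
                           region_len = 11L, five_prime_start = 2L,
                           covariates = NULL) {
  stopifnot(length(genomes) >= 1, !is.null(names(genomes)))
  accs <- sort(names(genomes))
  rows <- list(); vectors <- list()
  for (acc in accs) {
    g <- genomes[[acc]]
    recs <- if (is.character(g) && length(g) == 1L)
      filter_cds(parse_cds_collection(g, format, genome_id = acc))$retained
    else g
    if (!length(recs)) {
      message("skipping ", acc, ": no retained CDS")
      next
    }
    regions <- slice_all_regions(recs, region_len, five_prime_start)
    if (!length(regions)) {
      message("skipping ", acc, ": no gene long enough for the 5' window")
      next
    }
    v <- derive_five_core(regions, code)
    ct <- correlate_vectors(v, reference, "pearson")
    rows[[acc]] <- data.frame(
      accession = acc, n_genes = length(regions),
      r = ct$estimate, p_value = ct$p_value,
      gc3 = compute_gc3(recs), unstable = length(regions) < 50,
      stringsAsFactors = FALSE
    )
    vectors[[acc]] <- v
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$p_bonferroni <- pmin(1, tab$p_value * nrow(tab))
  if (!is.null(covariates)) {
    stopifnot("accession" %in% names(covariates))
    tab <- merge(tab, covariates, by = "accession", all.x = TRUE, sort = TRUE)
  }
  structure(list(table = tab, vectors = vectors), class = "genome_survey")
}

#' @export
print.genome_survey <- function(x, ...) {
  cat("Genome survey:", nrow(x$table), "genomes, median r =",
      round(stats::median(x$table$r), 3), "\n")
  invisible(x)
}

survey_table <- function(x) {
  if (inherits(x, "genome_survey")) x$table else x
}

#' Bonferroni significance summary of a genome survey
#'
#' Fraction of genomes whose 5'-core vector correlates significantly
#' positively with the reference: Bonferroni-adjusted two-sided
#' p < `alpha` and r > 0.
#'
#' @param survey a `genome_survey` or its table
#' @param alpha significance threshold (default 0.05)
#' @return list: `fraction_significant_positive`, `n_significant_positive`,
#'   `n_significant_negative`, `n_genomes`
#' @export
bonferroni_summary <- function(survey, alpha = 0.05) {
  tab <- survey_table(survey)
  stopifnot(nrow(tab) >= 1)
  sig_pos <- tab$p_bonferroni < alpha & tab$r > 0
  sig_neg <- tab$p_bonferroni < alpha & tab$r < 0
  list(
    fraction_significant_positive = mean(sig_pos),
    n_significant_positive = sum(sig_pos),
    n_significant_negative = sum(sig_neg),
    n_genomes = nrow(tab)
  )
}

#' GC3 and growth-temperature models of the survey correlations
#'
#' Three OLS fits of the per-genome correlation r: a quadratic GC3 model
#' (`r ~ gc3 + gc3^2`), a temperature-only model (`r ~ pogt`), and the
#' joint model (`r ~ gc3 + gc3^2 + pogt`; no interactions).
#'
#' @param survey a `genome_survey` or its table (needs `r`, `gc3`;
#'   `pogt` for the temperature and joint fits)
#' @return named list of `fit_result`s: `quadratic_gc3`, `ogt`, `joint`
#'   (the latter two `NULL` without `pogt`)
#' @export
fit_gc3_temperature_model <- function(survey) {
  tab <- survey_table(survey)
  if (nrow(tab) < 10) stop("need at least 10 genomes for the GC3 models")
  quad <- multivariate_fit(stats::setNames(tab$r, tab$accession),
                           list(gc3 = stats::setNames(tab$gc3, tab$accession)),
                           include_quadratic = "gc3")
  ogt <- joint <- NULL
  if ("pogt" %in% names(tab) && any(!is.na(tab$pogt))) {
    nm <- tab$accession
    ogt <- multivariate_fit(stats::setNames(tab$r, nm),
                            list(pogt = stats::setNames(tab$pogt, nm)))
    joint <- multivariate_fit(stats::setNames(tab$r, nm),
                              list(gc3 = stats::setNames(tab$gc3, nm),
                                   pogt = stats::setNames(tab$pogt, nm)),
                              include_quadratic = "gc3")
  }
  list(quadratic_gc3 = quad, ogt = ogt, joint = joint)
}

#' Regression of the 5'-core folding-stability differential on GC3
#'
#' With externally supplied mean folding free energies of the 5' and
#' core windows (kcal/mol), fits `(dg5 - dgcore) ~ gc3` and reports the
#' fraction of genomes whose 5' windows are less stable (less negative
#' free energy) than their cores.
#'
#' @param survey a `genome_survey` or its table with `gc3`, `dg5`,
#'   `dgcore`
#' @return list: `fit` (a `fit_result`), `fraction_5prime_less_stable`
#' @export
stability_differential <- function(survey) {
  tab <- survey_table(survey)
  if (!all(c("dg5", "dgcore") %in% names(tab)) ||
      all(is.na(tab$dg5)) || all(is.na(tab$dgcore)))
    stop("requires external folding energies (dg5, dgcore columns)")
  diff <- tab$dg5 - tab$dgcore
  nm <- tab$accession
  fit <- multivariate_fit(stats::setNames(diff, nm),
                          list(gc3 = stats::setNames(tab$gc3, nm)))
  list(fit = fit,
       fraction_5prime_less_stable = mean(tab$dg5 > tab$dgcore, na.rm = TRUE))
}
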