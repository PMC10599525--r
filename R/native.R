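## Native-gene pipeline: abundance / noise / essentiality contrasts and
## the 5'-versus-core vector, plus the expression-binned scan.

#' Read a gene-level annotation table
#'
#' Header-mapped TSV with a `gene_id` column and any of `abundance`,
#' `noise`, `essential`, `delta_g_5prime`, `delta_g_core`. Unknown
#' columns are kept but ignored.
#'
#' @param path file path
#' @param sep field separator
#' @return data.frame
#' @export
read_annotation_table <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(df)) stop("annotation table needs a gene_id column")
  if ("essential" %in% names(df)) df$essential <- as.logical(df$essential)
  df
}

#' Stratify genes by a quantitative metric or a categorical flag
#'
#' Quantitative: nearest-rank quantile sets, the top
#' `ceil(upper_frac * N)` genes as target and bottom
#' `ceil(lower_frac * N)` as comparator (ties broken by a stable sort on
#' gene id; genes missing the metric are excluded). Categorical
#' (logical metric): `TRUE` genes are the target, `FALSE` the
#' comparator. The noise contrast conventionally uses the LOW-noise
#' genes as target (pass `invert = TRUE`), so positive entries read
#' "low-noise-associated".
#'
#' @param annot annotation data.frame with `gene_id`
#' @param metric column name
#' @param upper_frac,lower_frac quantile fractions (ignored for logical
#'   metrics)
#' @param invert swap target and comparator (e.g. bottom-X% as target)
#' @return list with `target` and `comparator` character vectors of gene
#'   ids (always disjoint)
#' @export
stratify_genes <- function(annot, metric, upper_frac = 0.25,
                           lower_frac = 0.25, invert = FALSE) {
  if (!metric %in% names(annot)) stop("metric column not found: ", metric)
  v <- annot[[metric]]
  ids <- annot$gene_id
  keep <- !is.na(v)
  v <- v[keep]; ids <- ids[keep]
  if (is.logical(v)) {
    target <- ids[v]; comparator <- ids[!v]
    if (!length(target) || !length(comparator))
      stop("categorical stratification needs both categories non-empty")
  } else {
    if (length(v) < 4) stop("need the metric for at least 4 genes")
    if (upper_frac + lower_frac > 1) stop("upper_frac + lower_frac > 1")
    ord <- order(v, ids, method = "radix")
    ids <- ids[ord]
    n <- length(ids)
    n_top <- ceiling(upper_frac * n)
    n_bot <- ceiling(lower_frac * n)
    target <- ids[(n - n_top + 1L):n]
    comparator <- ids[seq_len(n_bot)]
  }
  if (invert) { tmp <- target; target <- comparator; comparator <- tmp }
  stopifnot(length(intersect(target, comparator)) == 0L)
  list(target = target, comparator = comparator)
}

pool_region <- function(regions, ids, region = c("five_prime", "core")) {
  region <- match.arg(region)
  present <- intersect(ids, names(regions))
  if (!length(present)) stop("no genes with the requested region")
  lapply(regions[present], `[[`, region)
}

#' Log-odds vector for a gene-set contrast on one window
#'
#' Pools the requested window (`five_prime` or `core`) over the target
#' genes and over the comparator genes and computes the per-codon
#' log-odds vector. This covers the abundance contrasts (5' windows:
#' "V_5-prot"; cores: "V_TO"), the noise contrast ("V_noise") and the
#' essentiality contrast ("V_ess").
#'
#' @param regions named list of `region_pair` (see [slice_all_regions()])
#' @param target,comparator character vectors of gene ids (disjoint)
#' @param region `"five_prime"` or `"core"`
#' @param code a [genetic_code_partition()]
#' @param label vector label
#' @param correction zero-cell policy
#' @return a `log_odds_vector`
#' @export
derive_contrast_vector <- function(regions, target, comparator,
                                   region = c("five_prime", "core"),
                                   code = genetic_code_partition(),
                                   label = NULL, correction = "half-unit") {
  region <- match.arg(region)
  if (length(intersect(target, comparator)))
    stop("target and comparator gene sets overlap")
  tc <- count_codons(pool_region(regions, target, region), code)
  cc <- count_codons(pool_region(regions, comparator, region), code)
  log_odds_vector(tc, cc, code, label = label, correction = correction)
}

#' 5'-window versus core-window enrichment vector (V_5-core)
#'
#' All genes' 5' windows (target) against all genes' core windows
#' (comparator).
#'
#' @param regions named list of `region_pair`
#' @param code a [genetic_code_partition()]
#' @param gene_ids optional subset of genes (default all)
#' @param correction zero-cell policy
#' @return a `log_odds_vector` labelled `"V_5-core"`
#' @export
derive_five_core <- function(regions, code = genetic_code_partition(),
                             gene_ids = names(regions),
                             correction = "half-unit") {
  fp <- count_codons(pool_region(regions, gene_ids, "five_prime"), code)
  co <- count_codons(pool_region(regions, gene_ids, "core"), code)
  log_odds_vector(fp, co, code, label = "V_5-core", correction = correction)
}

#' Expression-binned 5'-versus-core scan
#'
#' Rank-orders genes by abundance, slides a window of
#' `ceil(bin_frac * N)` genes from the lowest to the highest expressed
#' in steps of `step_percentile` percentiles, computes each bin's
#' V_5-core, and correlates it (Pearson) against a reference vector
#' (typically V_edIO).
#'
#' @param regions named list of `region_pair`
#' @param annot annotation data.frame with `gene_id` and `abundance`
#' @param reference a `log_odds_vector` or named numeric vector
#' @param bin_frac fraction of genes per bin (default 0.2)
#' @param step_percentile slide step in percentiles of the gene ranking
#'   (default 1)
#' @param code a [genetic_code_partition()]
#' @return data.frame with `lower_percentile` (rank percentile of the
#'   lowest-expressed gene in the bin), `n_genes`, `r`, `p_value`;
#'   ordered lowest to highest expression
#' @export
expression_binned_scan <- function(regions, annot, reference, bin_frac = 0.2,
                                   step_percentile = 1,
                                   code = genetic_code_partition()) {
  ab <- annot[!is.na(annot$abundance) & annot$gene_id %in% names(regions), ]
  ord <- order(ab$abundance, ab$gene_id, method = "radix")
  ids <- ab$gene_id[ord]
  n <- length(ids)
  bin_size <- ceiling(bin_frac * n)
  if (bin_size < 50) warning("bin size < 50 genes: vectors will be unstable")
  step <- max(1L, floor(n * step_percentile / 100))
  starts <- unique(c(seq(1L, n - bin_size + 1L, by = step), n - bin_size + 1L))
  rows <- lapply(starts, function(s) {
    bin_ids <- ids[s:(s + bin_size - 1L)]
    v <- derive_five_core(regions, code, gene_ids = bin_ids)
    ct <- correlate_vectors(v, reference, "pearson")
    data.frame(lower_percentile = 100 * (s - 1) / n, n_genes = bin_size,
               r = ct$estimate, p_value = ct$p_value)
  })
  do.call(rbind, rows)
}

#' Join two gene-level columns and correlate them
#'
#' Generic utility, e.g. Spearman correlation of protein abundance with
#' externally supplied 5'-window folding free energy.
#'
#' @param annot annotation data.frame with `gene_id`
#' @param x_col,y_col column names
#' @param method `"spearman"` (default) or `"pearson"`
#' @return a `correlation_result`
#' @export
correlate_gene_metrics <- function(annot, x_col, y_col,
                                   method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- annot[[x_col]]; y <- annot[[y_col]]
  ok <- !is.na(x) & !is.na(y)
  correlate_vectors(x[ok], y[ok], method)
}
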