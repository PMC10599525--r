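## Synthetic-data generators with planted per-codon effects and known
## ground truth. All randomness flows from a mandatory seed evaluated in
## a local RNG scope (the caller's .Random.seed is untouched), so
## identical parameters give byte-identical output.

with_local_seed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

## uniform amino-acid alphabet = the synonymous families with >= 2
## codons, so every sampled position is informative for block-level
## contrasts and carries no amino-acid confound
scoring_blocks <- function(code) code$blocks[lengths(code$blocks) >= 2L]

## Per-codon effects enter the generators only through within-block
## softmax weights (genome) or group-normalised sums (transgene), so an
## additive constant per synonymous block is unidentifiable. Planted
## effect vectors are therefore centred within blocks on input; the
## centred vector is the stored ground truth.
center_within_blocks <- function(v, code) {
  for (blk in code$blocks) {
    blk <- intersect(blk, names(v))
    if (length(blk) > 1) v[blk] <- v[blk] - mean(v[blk])
  }
  v
}

## vectorised within-block codon sampling: positions are grouped by
## (amino acid, weight regime) and drawn with one sample() call each
sample_codons <- function(aa, regime, blocks, log_weights_by_regime) {
  out <- character(length(aa))
  for (bname in names(blocks)) {
    blk <- blocks[[bname]]
    for (rg in unique(regime)) {
      idx <- which(aa == bname & regime == rg)
      if (!length(idx)) next
      w <- exp(log_weights_by_regime[[rg]][blk])
      out[idx] <- blk[sample.int(length(blk), length(idx), replace = TRUE,
                                 prob = w)]
    }
  }
  out
}

#' Simulate a bacterial genome fixture with planted 5'-window codon bias
#'
#' Generates `n_genes` coding sequences: start codon ATG, a body of
#' codons whose amino acids are drawn uniformly over the 18 multi-codon
#' families, terminal stop TAA. Within a family the codon is drawn with
#' probability proportional to
#' `exp(log(core_weight) + delta[codon] * in_5prime_window +
#' coupling[codon] * top_abundance_quartile)`, so `delta` is an additive
#' log-weight planted only in the 5' window (codon positions
#' `five_prime_start .. five_prime_start + region_len - 1`) and
#' `coupling` an extra 5'-window log-weight restricted to
#' top-abundance-quartile genes. Protein abundance is lognormal; noise
#' is negatively rank-coupled to abundance via a Gaussian copula;
#' essentiality follows a logistic link on log-abundance. Every
#' generated CDS passes [filter_cds()] by construction.
#'
#' @param seed integer seed (mandatory)
#' @param n_genes number of genes (default 2000)
#' @param length_meanlog,length_sdlog lognormal codon-count distribution
#'   of the CDS (start included, stop excluded); lengths are clamped to
#'   `min_length`
#' @param min_length minimum codon count (default 24)
#' @param delta named per-codon additive log-weight for the 5' window
#'   (default all zero). Names must be sense codons.
#' @param coupling named per-codon extra 5' log-weight for
#'   top-quartile-abundance genes (default all zero)
#' @param core_weights optional named list of per-block probability
#'   weights (default uniform within each block)
#' @param region_len,five_prime_start 5'-window geometry (defaults 11, 2)
#' @param abundance_meanlog,abundance_sdlog lognormal abundance model
#' @param noise_spearman target Spearman correlation between abundance
#'   and noise (default -0.5)
#' @param essential_fraction baseline essentiality probability at median
#'   abundance (default 0.2); 0 gives no essential genes
#' @param code a [genetic_code_partition()]
#' @return list of class `genome_fixture`: `records` (list of
#'   `cds_record`), `annotations` (data.frame `gene_id`, `abundance`,
#'   `noise`, `essential`), `truth` (list: `delta`, `coupling`,
#'   `abundance`, `top_quartile`)
#' @export
simulate_genome_fixture <- function(seed,
                                    n_genes = 2000L,
                                    length_meanlog = log(200),
                                    length_sdlog = 0.35,
                                    min_length = 24L,
                                    delta = NULL,
                                    coupling = NULL,
                                    core_weights = NULL,
                                    region_len = 11L,
                                    five_prime_start = 2L,
                                    abundance_meanlog = 0,
                                    abundance_sdlog = 1,
                                    noise_spearman = -0.5,
                                    essential_fraction = 0.2,
                                    code = genetic_code_partition()) {
  blocks <- scoring_blocks(code)
  all_sense <- code$sense_codons
  full <- function(x) {
    v <- stats::setNames(numeric(length(all_sense)), all_sense)
    if (!is.null(x)) {
      stopifnot(!is.null(names(x)), all(names(x) %in% all_sense))
      v[names(x)] <- x
    }
    v
  }
  delta <- center_within_blocks(full(delta), code)
  coupling <- center_within_blocks(full(coupling), code)
  log_core <- stats::setNames(numeric(length(all_sense)), all_sense)
  if (!is.null(core_weights)) {
    for (bname in names(core_weights)) {
      w <- core_weights[[bname]]
      stopifnot(!is.null(names(w)), all(w > 0))
      log_core[names(w)] <- log(w)
    }
  }

  with_local_seed(seed, {
    lens <- pmax(min_length, round(stats::rlnorm(n_genes, length_meanlog,
                                                 length_sdlog)))
    z_ab <- stats::rnorm(n_genes)
    abundance <- exp(abundance_meanlog + abundance_sdlog * z_ab)
    top_q <- rank(-abundance, ties.method = "first") <= ceiling(n_genes / 4)

    gene_of <- rep.int(seq_len(n_genes), lens - 1L)      # body positions 2..L
    pos <- unlist(lapply(lens - 1L, seq_len), use.names = FALSE) + 1L
    in5 <- pos >= five_prime_start & pos <= five_prime_start + region_len - 1L
    aa <- names(blocks)[sample.int(length(blocks), length(gene_of),
                                   replace = TRUE)]
    regime <- ifelse(in5, ifelse(top_q[gene_of], "five_top", "five"), "core")
    lw <- list(
      core = log_core,
      five = log_core + delta,
      five_top = log_core + delta + coupling
    )
    codons <- sample_codons(aa, regime, blocks, lw)

    bodies <- split(codons, gene_of)
    ids <- sprintf("gene%04d", seq_len(n_genes))
    records <- lapply(seq_len(n_genes), function(i) {
      new_cds_record(ids[i], "synthetic",
                     paste(c("ATG", bodies[[i]], "TAA"), collapse = ""))
    })

    ann <- annotation_from_abundance(ids, abundance, z_ab, noise_spearman,
                                     essential_fraction)

    structure(
      list(
        records = records,
        annotations = ann,
        truth = list(delta = delta, coupling = coupling,
                     abundance = stats::setNames(abundance, ids),
                     top_quartile = stats::setNames(top_q, ids))
      ),
      class = "genome_fixture"
    )
  })
}

## shared generator: noise by Gaussian copula against the abundance
## latent, essentiality by a logistic link on it
annotation_from_abundance <- function(ids, abundance, z_ab, noise_spearman,
                                      essential_fraction,
                                      noise_meanlog = log(0.3),
                                      noise_sdlog = 0.5) {
  # Pearson rho on the latent normals giving the target Spearman
  rho <- 2 * sin(noise_spearman * pi / 6)
  z_noise <- rho * z_ab + sqrt(1 - rho^2) * stats::rnorm(length(z_ab))
  noise <- exp(noise_meanlog + noise_sdlog * z_noise)
  p_ess <- stats::plogis(stats::qlogis(essential_fraction) + z_ab)
  essential <- stats::runif(length(z_ab)) < p_ess
  data.frame(gene_id = ids, abundance = abundance, noise = noise,
             essential = essential, stringsAsFactors = FALSE)
}

#' Simulate a gene annotation table for existing genes
#'
#' Standalone annotation generator (abundance, noise, essentiality) for
#' an arbitrary gene id list, in the same dialect [read_annotation_table()]
#' reads. Noise is negatively rank-coupled to abundance; essentiality is
#' logistic in log-abundance.
#'
#' @param seed integer seed (mandatory)
#' @param gene_ids character vector of gene ids
#' @param abundance_meanlog,abundance_sdlog lognormal abundance model
#' @param noise_spearman target Spearman(abundance, noise) (default -0.5)
#' @param essential_fraction baseline essentiality probability (default 0.2)
#' @return data.frame `gene_id`, `abundance`, `noise`, `essential`
#' @export
simulate_annotations <- function(seed, gene_ids,
                                 abundance_meanlog = 0, abundance_sdlog = 1,
                                 noise_spearman = -0.5,
                                 essential_fraction = 0.2) {
  with_local_seed(seed, {
    z <- stats::rnorm(length(gene_ids))
    abundance <- exp(abundance_meanlog + abundance_sdlog * z)
    annotation_from_abundance(gene_ids, abundance, z, noise_spearman,
                              essential_fraction)
  })
}

#' Simulate a synonymous-recoding transgene construct table
#'
#' Emulates a promoter x RBS x N-terminus randomization experiment: each
#' group has one random 10-residue N-terminal amino-acid sequence
#' (positions 2-11, uniform over the 18 multi-codon families, behind a
#' fixed ATG), recoded into `variants_per_group` synonymous variants
#' with codons drawn uniformly within blocks. The latent expression of a
#' variant is
#' `baseline_group * exp(sum(beta[codon] over positions 2..11)) *
#' exp(N(0, noise_sd))`, emitted as `protein_ratio`. A fraction of
#' measurements at each extreme is censored at the range limits
#' (protein_ratio absent, censor flag set), exercising the extreme-rank
#' handling in [stratify_constructs()].
#'
#' @param seed integer seed (mandatory)
#' @param n_groups number of synonymous groups (default 200)
#' @param variants_per_group synonymous variants per group (default 13)
#' @param beta named per-codon additive log-effect on expression; `NULL`
#'   (default) draws one from `N(0, beta_sd)` over the scored codons
#'   (returned in the ground truth)
#' @param beta_sd sd of the default beta draw (default 0.15)
#' @param noise_sd sd of the multiplicative lognormal measurement noise
#'   (default 0.2)
#' @param baseline_sdlog sd of the lognormal group baselines (default 1)
#' @param censor_frac total fraction of constructs censored, split
#'   evenly between above-range and below-range (default 0.02)
#' @param code a [genetic_code_partition()]
#' @return list of class `transgene_fixture`: `table` (a
#'   `construct_table`) and `truth` (list with `beta`)
#' @export
simulate_transgene_table <- function(seed,
                                     n_groups = 200L,
                                     variants_per_group = 13L,
                                     beta = NULL,
                                     beta_sd = 0.15,
                                     noise_sd = 0.2,
                                     baseline_sdlog = 1,
                                     censor_frac = 0.02,
                                     code = genetic_code_partition()) {
  if (variants_per_group < 2L) stop("variants_per_group must be >= 2")
  blocks <- scoring_blocks(code)
  n_pos <- 10L  # scored positions 2..11 of the 11-codon variable region

  with_local_seed(seed, {
    if (is.null(beta)) {
      beta <- stats::setNames(stats::rnorm(length(code$scored_codons), 0,
                                           beta_sd),
                              code$scored_codons)
    } else {
      stopifnot(!is.null(names(beta)))
    }
    beta_all <- stats::setNames(numeric(length(code$sense_codons)),
                                code$sense_codons)
    beta_all[names(beta)] <- beta
    beta_all <- center_within_blocks(beta_all, code)
    beta <- beta_all[intersect(names(beta_all), code$scored_codons)]

    group_aa <- matrix(
      names(blocks)[sample.int(length(blocks), n_groups * n_pos,
                               replace = TRUE)],
      nrow = n_groups
    )
    baseline <- stats::rlnorm(n_groups, 0, baseline_sdlog)

    total <- n_groups * variants_per_group * n_pos
    # expand: for each group, each variant repeats the group's aa row;
    # ordering is group 1 (variant 1 pos 1..10, variant 2 ...), group 2 ...
    aa_long <- as.vector(apply(group_aa, 1, function(row)
      rep(row, times = variants_per_group)))
    regime <- rep("u", total)
    codons <- sample_codons(aa_long, regime, blocks,
                            list(u = stats::setNames(
                              numeric(length(code$sense_codons)),
                              code$sense_codons)))
    m <- matrix(codons, ncol = n_pos, byrow = TRUE)  # one row per variant

    group_id <- rep(sprintf("grp%04d", seq_len(n_groups)),
                    each = variants_per_group)
    variant_id <- paste0(group_id, "_v",
                         rep(seq_len(variants_per_group), times = n_groups))
    effect <- rowSums(matrix(beta_all[as.vector(m)], ncol = n_pos))
    ratio <- rep(baseline, each = variants_per_group) * exp(effect) *
      exp(stats::rnorm(total / n_pos, 0, noise_sd))

    sequence <- paste0("ATG", apply(m, 1, paste, collapse = ""))

    censor <- rep("none", length(ratio))
    if (censor_frac > 0) {
      hi <- stats::quantile(ratio, 1 - censor_frac / 2)
      lo <- stats::quantile(ratio, censor_frac / 2)
      censor[ratio > hi] <- "above-range"
      censor[ratio < lo] <- "below-range"
    }
    ratio_out <- ifelse(censor == "none", ratio, NA_real_)

    tbl <- as_construct_table(data.frame(
      group_id = group_id, variant_id = variant_id, sequence = sequence,
      protein_ratio = ratio_out, censor = censor, stringsAsFactors = FALSE
    ))
    structure(list(table = tbl, truth = list(beta = beta)),
              class = "transgene_fixture")
  })
}
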