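## CDS ingest: flat-file parsing, quality filtering, window slicing, GC3.

new_cds_record <- function(id, genome_id, seq, flags = character()) {
  seq <- toupper(seq)
  codons <- NULL
  if (nchar(seq) %% 3L == 0L && nchar(seq) >= 3L)
    codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  if (grepl("[^ACGT]", seq)) flags <- union(flags, "contains-ambiguity")
  structure(
    list(id = id, genome_id = genome_id, seq = seq,
         codons = codons, flags = flags),
    class = "cds_record"
  )
}

#' @export
print.cds_record <- function(x, ...) {
  cat("CDS", x$id, "-", nchar(x$seq), "nt",
      if (length(x$flags)) paste0("[", paste(x$flags, collapse = ","), "]"), "\n")
  invisible(x)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

## -- minimal GenBank / EMBL flat-file CDS feature parsing ---------------
## Only what CDS extraction needs: the feature table (CDS locations with
## complement()/join(), locus_tag or gene qualifiers) and the ORIGIN/SQ
## sequence. Nothing on PATH parses these dialects in R, hence in-house.

parse_location <- function(loc) {
  loc <- gsub("[<>]", "", gsub("[[:space:]]", "", loc))
  strand <- 1L
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- lapply(parts, function(p) {
    if (grepl("complement", p)) stop("unsupported mixed-strand location: ", p)
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) == 3) as.integer(m[2:3])
    else if (grepl("^\\d+$", p)) rep(as.integer(p), 2L)
    else stop("unparseable location segment: ", p)
  })
  list(strand = strand, segments = segs)
}

extract_feature_seq <- function(genome_seq, loc) {
  pieces <- vapply(loc$segments, function(s) substr(genome_seq, s[1], s[2]), "")
  s <- paste(pieces, collapse = "")
  if (loc$strand < 0L) s <- reverse_complement(s)
  s
}

parse_flatfile_cds <- function(path, dialect = c("genbank", "embl")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty or unreadable file: ", path)

  if (dialect == "genbank") {
    acc_line <- grep("^(ACCESSION|LOCUS)", lines, value = TRUE)[1]
    genome_id <- if (!is.na(acc_line)) strsplit(trimws(acc_line), "\\s+")[[1]][2] else basename(path)
    fstart <- grep("^FEATURES", lines)[1]
    ostart <- grep("^ORIGIN", lines)[1]
    if (is.na(fstart) || is.na(ostart)) stop("not a GenBank flat file: ", path)
    feat <- lines[(fstart + 1L):(ostart - 1L)]
    seq_lines <- lines[(ostart + 1L):length(lines)]
  } else {
    acc_line <- grep("^(AC|ID)", lines, value = TRUE)[1]
    genome_id <- if (!is.na(acc_line))
      gsub("[;,]", "", strsplit(trimws(sub("^..", "", acc_line)), "\\s+")[[1]][1])
    else basename(path)
    feat <- grep("^FT", lines, value = TRUE)
    feat <- substring(feat, 6L)  # strip "FT   "
    sstart <- grep("^SQ", lines)[1]
    if (is.na(sstart)) stop("not an EMBL flat file: ", path)
    seq_lines <- lines[(sstart + 1L):length(lines)]
  }
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  genome_seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  # fold feature-table continuation lines into one string per feature
  if (dialect == "genbank") {
    is_key <- grepl("^ {5}\\S", feat)
  } else {
    is_key <- grepl("^\\S", feat)
  }
  idx <- cumsum(is_key)
  feats <- split(feat, idx)

  records <- list()
  skipped <- 0L
  for (f in feats) {
    first <- trimws(f[1])
    key <- sub("\\s.*$", "", first)
    if (key != "CDS") next
    rest <- trimws(c(sub("^CDS\\s*", "", first), trimws(f[-1])))
    # location = leading lines up to the first qualifier
    qual_start <- grep("^/", rest)[1]
    loc_str <- paste(rest[seq_len(if (is.na(qual_start)) length(rest) else qual_start - 1L)],
                     collapse = "")
    quals <- if (is.na(qual_start)) character() else rest[qual_start:length(rest)]
    tag <- sub('^/locus_tag="?([^"]*)"?$', "\\1",
               grep("^/locus_tag=", quals, value = TRUE)[1])
    if (is.na(tag))
      tag <- sub('^/gene="?([^"]*)"?$', "\\1",
                 grep("^/gene=", quals, value = TRUE)[1])
    if (is.na(tag)) tag <- paste0("CDS_", length(records) + 1L)
    rec <- tryCatch({
      loc <- parse_location(loc_str)
      s <- extract_feature_seq(genome_seq, loc)
      if (!nzchar(s)) stop("empty extraction")
      new_cds_record(tag, genome_id, s)
    }, error = function(e) {
      message("skipping CDS ", tag, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) skipped <- skipped + 1L else records[[length(records) + 1L]] <- rec
  }
  records
}

#' Read a collection of coding sequences
#'
#' Parses an annotated genome (GenBank or EMBL flat file) or a
#' CDS-per-entry FASTA into unfiltered CDS records. For annotated
#' genomes, every CDS feature is extracted in its annotated reading
#' frame with minus-strand features reverse-complemented; record ids are
#' locus tags (falling back to `/gene`). FASTA ids are headers up to the
#' first whitespace.
#'
#' @param path input file
#' @param format `"genbank"`, `"embl"` or `"fasta"`
#' @param genome_id identifier recorded on FASTA-derived records
#'   (defaults to the file name)
#' @return list of `cds_record` objects
#' @export
parse_cds_collection <- function(path, format = c("fasta", "genbank", "embl"),
                                 genome_id = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read input file: ", path)
  if (format == "fasta") {
    dna <- Biostrings::readDNAStringSet(path)
    ids <- sub("\\s.*$", "", names(dna))
    lapply(seq_along(dna), function(i)
      new_cds_record(ids[i], genome_id, as.character(dna[[i]])))
  } else {
    parse_flatfile_cds(path, format)
  }
}

#' Apply CDS quality filters
#'
#' Retains only sequences that (in this fixed rule order) have length
#' divisible by 3, end with a stop codon, contain no internal stop
#' codon, and begin with an NTG start codon. A rejected record carries
#' the first failing reason only.
#'
#' @param records list of `cds_record`
#' @return list with `retained` (list of records) and `rejected`
#'   (data.frame of `id`, `reason`)
#' @export
filter_cds <- function(records) {
  reasons <- character(0)
  ids <- character(0)
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    reason <- NA_character_
    if (nchar(r$seq) %% 3L != 0L || nchar(r$seq) == 0L) {
      reason <- "length-not-multiple-of-3"
    } else {
      cds <- r$codons
      nc <- length(cds)
      if (!cds[nc] %in% STOP_CODONS) {
        reason <- "no-terminal-stop"
      } else if (any(cds[-nc] %in% STOP_CODONS)) {
        reason <- "internal-stop"
      } else if (!grepl("^.TG$", cds[1])) {
        reason <- "no-start-codon"
      }
    }
    if (is.na(reason)) {
      keep[i] <- TRUE
    } else {
      ids <- c(ids, r$id)
      reasons <- c(reasons, reason)
    }
  }
  list(
    retained = records[keep],
    rejected = data.frame(id = ids, reason = reasons, stringsAsFactors = FALSE)
  )
}

#' Slice a CDS into its 5' window and core window
#'
#' Codon positions are 1-based with position 1 the start codon. The 5'
#' window spans positions `five_prime_start ..
#' five_prime_start + region_len - 1` (default 2..12, the first 11
#' codons of the ORF excluding the start). The core window of the same
#' length is centred in the CDS: start `floor((L - region_len)/2) + 1`
#' where `L` is the codon count excluding the terminal stop. Windows of
#' short genes may overlap; they are retained and flagged.
#'
#' @param record a filtered `cds_record`
#' @param region_len window length in codons (default 11)
#' @param five_prime_start first codon position of the 5' window (default 2)
#' @return object of class `region_pair`: list with `id`, `five_prime`,
#'   `core` (codon vectors) and `overlap_flag`; or `NULL` with a
#'   `"short"` attribute if the gene cannot host the 5' window
#' @export
slice_regions <- function(record, region_len = 11L, five_prime_start = 2L) {
  cds <- record$codons
  stopifnot(!is.null(cds))
  L <- length(cds) - 1L  # exclude terminal stop
  if (L < five_prime_start - 1L + region_len || L < region_len)
    return(NULL)  # too short to host the 5' window
  fp_idx <- five_prime_start:(five_prime_start + region_len - 1L)
  core_start <- (L - region_len) %/% 2L + 1L
  core_idx <- core_start:(core_start + region_len - 1L)
  structure(
    list(
      id = record$id,
      five_prime = cds[fp_idx],
      core = cds[core_idx],
      overlap_flag = length(intersect(fp_idx, core_idx)) > 0L
    ),
    class = "region_pair"
  )
}

#' Slice windows for a whole record list
#'
#' @param records list of filtered `cds_record`
#' @inheritParams slice_regions
#' @return named list of `region_pair` (genes too short for the 5'
#'   window are dropped; their ids are kept in attribute `"dropped"`)
#' @export
slice_all_regions <- function(records, region_len = 11L, five_prime_start = 2L) {
  out <- lapply(records, slice_regions, region_len = region_len,
                five_prime_start = five_prime_start)
  ok <- !vapply(out, is.null, logical(1))
  dropped <- vapply(records[!ok], function(r) r$id, "")
  out <- out[ok]
  names(out) <- vapply(out, function(rp) rp$id, "")
  structure(out, dropped = unname(dropped))
}

#' GC content at third codon positions
#'
#' Fraction of third positions that are G or C over the sense codons of
#' each CDS (terminal stop excluded, start codon included). The default
#' mode averages per-gene fractions with equal gene weight; `pooled`
#' concatenates all third positions first.
#'
#' @param records list of filtered `cds_record`
#' @param mode `"per-gene-mean"` (default) or `"pooled"`
#' @return numeric fraction in `[0, 1]`
#' @export
compute_gc3 <- function(records, mode = c("per-gene-mean", "pooled")) {
  mode <- match.arg(mode)
  per_gene <- vapply(records, function(r) {
    cds <- r$codons
    body <- cds[-length(cds)]                       # drop terminal stop
    body <- body[grepl("^[ACGT]{3}$", body)]        # drop ambiguous codons
    body <- body[!body %in% STOP_CODONS]
    if (!length(body)) return(NA_real_)
    tb <- third_base(body)
    c(sum(tb %in% c("G", "C")), length(body))
  }, numeric(2))
  if (all(is.na(per_gene[2, ])) || sum(per_gene[2, ], na.rm = TRUE) == 0)
    stop("no sense codons available for GC3")
  if (mode == "per-gene-mean") {
    mean(per_gene[1, ] / per_gene[2, ], na.rm = TRUE)
  } else {
    sum(per_gene[1, ], na.rm = TRUE) / sum(per_gene[2, ], na.rm = TRUE)
  }
}

#' Write retained CDS records as FASTA
#' @param records list of `cds_record`
#' @param path output file
#' @export
write_cds_fasta <- function(records, path) {
  dna <- Biostrings::DNAStringSet(vapply(records, function(r) r$seq, ""))
  names(dna) <- vapply(records, function(r) r$id, "")
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Filter a genome manifest by length and genus
#'
#' Collection-level gating for multi-genome surveys: keep genomes of at
#' least `min_length` bp and at most one genome per genus (the first in
#' manifest order).
#'
#' @param manifest data.frame with at least `accession`,
#'   `genome_length`, `genus` columns
#' @param min_length minimum genome length in bp (default 500000)
#' @param one_per_genus keep only the first genome of each genus
#' @return the filtered manifest
#' @export
filter_genome_manifest <- function(manifest, min_length = 5e5,
                                   one_per_genus = TRUE) {
  stopifnot(all(c("accession", "genome_length", "genus") %in% names(manifest)))
  m <- manifest[manifest$genome_length >= min_length, , drop = FALSE]
  if (one_per_genus) m <- m[!duplicated(m$genus), , drop = FALSE]
  m
}
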