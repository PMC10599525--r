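#' Standard bacterial genetic code partitioned into synonymous blocks
#'
#' Builds the codon-to-amino-acid map for the standard genetic code and
#' groups the sense codons into synonymous families ("blocks"). The
#' six-fold families (Leu, Ser, Arg) are kept whole by default. The 59
#' scored codons are the sense codons with at least one synonym, i.e.
#' all 61 sense codons except ATG (Met) and TGG (Trp).
#'
#' @param repartition optional named list overriding one or more blocks.
#'   Each element is a character vector of codons forming a new block;
#'   names label the new blocks. Every codon mentioned is first removed
#'   from its standard block, the remainder of that block stays together.
#'   Example: `list(ArgAG = c("AGA","AGG"), ArgCG = c("CGT","CGC","CGA","CGG"))`
#'   splits arginine into two sub-families.
#' @return an object of class `genetic_code_partition` with elements
#'   `codon_to_aa` (named character over all 64 codons, stops as `"*"`),
#'   `blocks` (named list of codon character vectors),
#'   `scored_codons` (sorted character vector of codons with >= 1 synonym),
#'   `sense_codons` (all 61 sense codons) and
#'   `block_of` (named character mapping each scored codon to its block).
#' @examples
#' code <- genetic_code_partition()
#' length(code$scored_codons)  # 59
#' @export
genetic_code_partition <- function(repartition = NULL) {
  std <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  sense <- names(std)[std != "*"]
  blocks <- split(sense, std[sense])
  blocks <- lapply(blocks, sort)

  if (!is.null(repartition)) {
    stopifnot(is.list(repartition), !is.null(names(repartition)))
    moved <- unlist(repartition, use.names = FALSE)
    if (anyDuplicated(moved))
      stop("repartition assigns a codon to more than one block")
    if (!all(moved %in% sense))
      stop("repartition mentions non-sense codons: ",
           paste(setdiff(moved, sense), collapse = ", "))
    blocks <- lapply(blocks, setdiff, y = moved)
    blocks <- blocks[lengths(blocks) > 0L]
    blocks <- c(blocks, lapply(repartition, sort))
  }

  scored <- sort(unlist(blocks[lengths(blocks) >= 2L], use.names = FALSE))
  block_of <- rep(names(blocks), lengths(blocks))
  names(block_of) <- unlist(blocks, use.names = FALSE)
  block_of <- block_of[scored]

  structure(
    list(
      codon_to_aa = std,
      blocks = blocks,
      scored_codons = scored,
      sense_codons = sort(sense),
      block_of = block_of
    ),
    class = "genetic_code_partition"
  )
}

#' @export
print.genetic_code_partition <- function(x, ...) {
  cat("Genetic code partition:", length(x$blocks), "synonymous blocks,",
      length(x$scored_codons), "scored codons\n")
  invisible(x)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Third base of each codon
#' @param codons character vector of trinucleotides
#' @return character vector of single bases
#' @export
third_base <- function(codons) substr(codons, 3L, 3L)
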