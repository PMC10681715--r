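#' Construct a genome object
#'
#' A genome is a named character vector of uppercase DNA strings
#' (alphabet A/C/G/T/N), one element per chromosome. Coordinates are
#' 1-based and closed throughout the package; BED output converts to the
#' 0-based half-open convention.
#'
#' @param sequences named character vector or named list of DNA strings.
#' @return named character vector of validated, uppercased sequences.
#' @export
as_genome <- function(sequences) {
  if (is.list(sequences)) sequences <- unlist(sequences)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("genome sequences must have unique names")
  nm <- names(sequences)
  sequences <- stats::setNames(toupper(as.character(sequences)), nm)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(names(sequences)[bad], collapse = ", "))
  sequences
}

#' Chromosome lengths of a genome
#' @param genome named character vector as returned by [as_genome()].
#' @return named integer vector of lengths in bp.
#' @export
genome_lengths <- function(genome) {
  stats::setNames(nchar(genome), names(genome))
}

#' Simulate a random genome
#'
#' Draws i.i.d. bases with a given GC content. Used to build desk-scale
#' reference sequences whose MspI fragment universe and CpG density are
#' realistic enough to exercise the pipeline.
#'
#' @param lengths named integer vector: chromosome name -> length in bp.
#' @param gc overall GC fraction (CpG dinucleotides arise at rate (gc/2)^2).
#' @param seed integer seed; the genome is deterministic given it.
#' @return genome (named character vector).
#' @export
random_genome <- function(lengths, gc = 0.5, seed = 1L) {
  stopifnot(!is.null(names(lengths)), all(lengths > 0), gc >= 0, gc <= 1)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  out <- local_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    }, character(1))
  })
  as_genome(out)
}

#' Read a genome from a (possibly gzipped) FASTA file
#' @param path FASTA file path.
#' @return genome (named character vector).
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  as_genome(stats::setNames(as.character(x), nm))
}

#' Write a genome to FASTA
#' @param genome genome object.
#' @param path output path (".gz" suffix enables compression).
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(x, path, compress = endsWith(path, ".gz"))
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Scalar reverse complement without Biostrings overhead, for hot loops.
revcomp_chr <- function(s) {
  paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[
    rev(strsplit(s, "", fixed = TRUE)[[1]])], collapse = "")
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-stage seed derived from a global seed and a stage name.
# Kept below 2^31 so it is a valid R integer seed.
#' Derive a reproducible per-stage seed
#' @param seed global integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed specific to (seed, stage).
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
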