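# Genomes: one promoter string per gene plus cached binding-site lists.

#' Construct a genome from promoter sequences
#'
#' @param promoters named character vector of promoter strings (names
#'   `g1..gG` matching the condition roster).
#' @param pwms optional list of `grn_pwm` (one per TF); when supplied the
#'   site cache is built immediately.
#' @return an object of class `grn_genome` with elements `promoters`,
#'   `sites` (one data.frame of binding sites per gene, or `NULL` before
#'   scanning) and `pwms`.
#' @export
new_genome <- function(promoters, pwms = NULL) {
  stopifnot(is.character(promoters), length(promoters) > 0)
  if (length(unique(nchar(promoters))) != 1L)
    stop("all promoters must have the same length")
  if (any(grepl("[^ACGTacgt]", promoters)))
    stop("promoter alphabet is A,C,G,T")
  if (is.null(names(promoters)))
    names(promoters) <- paste0("g", seq_along(promoters))
  g <- structure(list(promoters = toupper(promoters), sites = NULL,
                      pwms = pwms),
                 class = "grn_genome")
  if (!is.null(pwms)) g <- scan_genome(g, pwms)
  g
}

#' Generate a random genome for a condition
#'
#' Promoters are uniform random strings over A,C,G,T of the condition's
#' promoter length, the state in which every individual of generation 0
#' starts.
#'
#' @param condition a `grn_condition`.
#' @param pwms optional PWM list; if supplied, sites are scanned.
#' @return a `grn_genome`.
#' @export
random_genome <- function(condition, pwms = NULL) {
  G <- n_genes(condition)
  P <- condition$promoter_length
  proms <- vapply(seq_len(G), function(i)
    paste(sample(DNA_BASES, P, replace = TRUE), collapse = ""), "")
  names(proms) <- condition$genes$name
  new_genome(proms, pwms)
}

#' Scan all promoters of a genome against a PWM set
#'
#' @param genome a `grn_genome`.
#' @param pwms list of `grn_pwm`, one per TF; TF identities are taken from
#'   position in the list.
#' @return the genome with its per-gene site cache rebuilt.
#' @export
scan_genome <- function(genome, pwms = genome$pwms) {
  if (is.null(pwms)) stop("no PWMs supplied and none attached to the genome")
  genome$pwms <- pwms
  genome$sites <- lapply(seq_along(genome$promoters), function(g) {
    hits <- lapply(seq_along(pwms), function(h)
      scan_promoter(genome$promoters[[g]], pwms[[h]], tf_id = h, gene_id = g))
    do.call(rbind, hits)
  })
  names(genome$sites) <- names(genome$promoters)
  genome
}

# All cached sites of a genome as one data.frame.
genome_sites <- function(genome) {
  if (is.null(genome$sites))
    stop("genome has no site cache; run scan_genome() first")
  do.call(rbind, genome$sites)
}

#' @export
print.grn_genome <- function(x, ...) {
  cat("grn_genome:", length(x$promoters), "promoters of",
      nchar(x$promoters[[1]]), "bp")
  if (!is.null(x$sites))
    cat(";", sum(vapply(x$sites, nrow, 0L)), "cached binding sites")
  cat("\n")
  invisible(x)
}

#' Write promoters to / read promoters from FASTA
#'
#' One record per gene, ids `g<idx>`.
#'
#' @param genome a `grn_genome`.
#' @param path FASTA file path.
#' @return `write_promoters_fasta()`: the path, invisibly;
#'   `read_promoters_fasta()`: a `grn_genome` (without site cache).
#' @export
write_promoters_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  proms <- as.character(ss)
  names(proms) <- names(ss)
  new_genome(proms)
}
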