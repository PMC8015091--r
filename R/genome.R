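#' Genome sequence container
#'
#' Bundles the records (contigs/scaffolds) of one assembly with a species
#' label. Records are normalized to uppercase; any letter outside
#' \code{A,C,G,T,N} is kept verbatim and simply never contributes a k-mer
#' window. K-mer windows never span record boundaries.
#'
#' @param records character vector of DNA strings (case-insensitive).
#' @param species_label short unique label for the species/assembly.
#' @return An object of class \code{genome_sequence}: a list with elements
#'   \code{species_label} and \code{records}.
#' @examples
#' g <- genome_sequence(c("ACGTACGT", "GGGTTT"), "toy")
#' total_length(g)
#' @export
genome_sequence <- function(records, species_label) {
  if (!is.character(records) || length(records) == 0)
    stop("invalid-input: a genome needs at least one record", call. = FALSE)
  records <- toupper(records)
  if (any(!nzchar(records)))
    stop("invalid-input: empty record in genome '", species_label, "'", call. = FALSE)
  if (!is.character(species_label) || length(species_label) != 1 || !nzchar(species_label))
    stop("invalid-input: species_label must be a non-empty string", call. = FALSE)
  structure(list(species_label = species_label, records = unname(records)),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", x$species_label, ": ", length(x$records),
      " record(s), ", total_length(x), " bp\n", sep = "")
  invisible(x)
}

#' Total length of a genome in bases
#' @param genome a [genome_sequence()].
#' @return integer total number of bases over all records.
#' @export
total_length <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  sum(nchar(genome$records))
}
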