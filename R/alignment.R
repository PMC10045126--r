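#' Aligned sequence set with population labels
#'
#' Container for an aligned set of mtDNA sequences. Sequences are equal-length
#' uppercase strings over `A`, `C`, `G`, `T`, `N`, `-`; sample ids are unique
#' and every sample carries a non-empty population label.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param sequences character vector of aligned sequences (same length as
#'   `sample_ids`).
#' @param pop_labels population label per sample; recycled if length 1.
#' @return An object of class `sequence_alignment` with elements
#'   `sample_ids`, `sequences`, `pop_labels` and `L` (alignment length, bp).
#' @export
sequence_alignment <- function(sample_ids, sequences, pop_labels = "pop1") {
  sample_ids <- as.character(sample_ids)
  sequences <- toupper(as.character(sequences))
  if (length(sample_ids) != length(sequences))
    stop("sample_ids and sequences must have the same length")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  L <- unique(nchar(sequences))
  if (length(L) > 1)
    stop("ragged alignment: sequence lengths ", paste(L, collapse = ", "))
  if (length(L) == 0) L <- 0L
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T,N,-}: sample ",
         sample_ids[which(bad)[1]])
  pop_labels <- rep_len(as.character(pop_labels), length(sample_ids))
  if (any(!nzchar(pop_labels))) stop("empty population label")
  structure(list(sample_ids = sample_ids, sequences = sequences,
                 pop_labels = pop_labels, L = as.integer(L)),
            class = "sequence_alignment")
}

#' @export
print.sequence_alignment <- function(x, ...) {
  cat("sequence_alignment:", length(x$sample_ids), "sequences x", x$L, "bp,",
      length(unique(x$pop_labels)), "population(s)\n")
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln a [sequence_alignment()].
#' @return integer count.
#' @export
n_sequences <- function(aln) length(aln$sample_ids)

# alignment as an n x L character matrix
seq_matrix <- function(aln) {
  if (n_sequences(aln) == 0) return(matrix(character(0), 0, 0))
  do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
}

#' Read an aligned FASTA file
#'
#' Reads a FASTA file through \pkg{ape} and validates it into a
#' [sequence_alignment()]. Record order is preserved and lowercase bases are
#' normalized to uppercase. Ragged records or duplicated ids are errors.
#'
#' @param path path to a FASTA file.
#' @param pop_labels optional population label per record (in file order), or
#'   a single label for all records.
#' @return A [sequence_alignment()].
#' @export
read_fasta <- function(path, pop_labels = "pop1") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  dna <- ape::read.FASTA(path)
  ids <- names(dna)
  seqs <- vapply(as.character(dna), function(x) paste(x, collapse = ""), "")
  sequence_alignment(ids, seqs, pop_labels)
}

#' Write an alignment to FASTA
#' @param aln a [sequence_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  m <- tolower(seq_matrix(aln))
  rownames(m) <- aln$sample_ids
  ape::write.FASTA(ape::as.DNAbin(m), path)
  invisible(path)
}

#' Attach population labels from a population map
#'
#' @param aln a [sequence_alignment()].
#' @param labels named character vector (`sample_id -> population`) or an
#'   unnamed vector in record order.
#' @return The relabelled alignment.
#' @export
set_populations <- function(aln, labels) {
  if (!is.null(names(labels))) {
    miss <- setdiff(aln$sample_ids, names(labels))
    if (length(miss))
      stop("no population label for sample(s): ", paste(head(miss, 5), collapse = ", "))
    labels <- unname(labels[aln$sample_ids])
  }
  sequence_alignment(aln$sample_ids, aln$sequences, labels)
}

#' Subset an alignment
#' @param aln a [sequence_alignment()].
#' @param idx integer or logical index over samples.
#' @return The sub-alignment.
#' @export
subset_alignment <- function(aln, idx) {
  sequence_alignment(aln$sample_ids[idx], aln$sequences[idx], aln$pop_labels[idx])
}
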