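#' Generate synthetic amplicon reads with known truth
#'
#' Each read is drawn from one of the two variant sequences (sibirica with
#' probability `mixture`), then i.i.d. per-base substitution errors are
#' applied at `error_rate` (each error replaces the base with one of the
#' other three, uniformly).
#'
#' @param n_reads number of reads
#' @param mixture fraction of sibirica-variant templates, in \[0, 1\]
#' @param error_rate per-base substitution probability, in \[0, 0.25\]
#' @param ref an [AmpliconReference-class]; defaults to the shipped synthetic
#'   reference
#' @param seed integer seed
#' @return list with `sequences` (character, named read_1..read_n) and
#'   `truth` (data.frame read_id, variant)
#' @export
genAmpliconReads <- function(n_reads, mixture = 0.7, error_rate = 0.01,
                             ref = readAmpliconReference(), seed = 1L) {
  stopifnot(mixture >= 0, mixture <= 1, error_rate >= 0, error_rate <= 0.25,
            n_reads >= 1)
  set.seed(seed)
  L <- nchar(ref@sequences[[1]])
  is_sib <- stats::runif(n_reads) < mixture
  variant <- ifelse(is_sib, "sibirica", "gmelinii")
  tmpl <- matrix(NA_character_, n_reads, L)
  sib <- strsplit(ref@sequences[["sibirica"]], "")[[1]]
  gme <- strsplit(ref@sequences[["gmelinii"]], "")[[1]]
  if (any(is_sib))
    tmpl[is_sib, ] <- matrix(sib, sum(is_sib), L, byrow = TRUE)
  if (any(!is_sib))
    tmpl[!is_sib, ] <- matrix(gme, sum(!is_sib), L, byrow = TRUE)
  if (error_rate > 0) {
    err <- matrix(stats::runif(n_reads * L) < error_rate, n_reads, L)
    if (any(err)) {
      bases <- c("A", "C", "G", "T")
      cur <- tmpl[err]
      # uniform over the three other bases
      sub <- vapply(cur, function(b) sample(setdiff(bases, b), 1), character(1))
      tmpl[err] <- sub
    }
  }
  seqs <- apply(tmpl, 1, paste, collapse = "")
  ids <- paste0("read_", seq_len(n_reads))
  names(seqs) <- ids
  list(sequences = seqs, truth = data.frame(read_id = ids, variant = variant))
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ records carry a constant dummy quality ("I"); the classifier does not
#' use qualities.
#'
#' @param sequences named character vector of read sequences
#' @param path output path; `.fastq`/`.fq` selects FASTQ, anything else FASTA
#' @return `path`, invisibly
#' @export
writeReads <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- paste0("read_", seq_along(sequences))
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) {
    qual <- vapply(nchar(sequences), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", ids, "\n", sequences, "\n+\n", qual), path)
  } else {
    writeLines(paste0(">", ids, "\n", sequences), path)
  }
  invisible(path)
}
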