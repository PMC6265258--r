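#' Read the two-variant amplicon reference
#'
#' Reads a two-record FASTA holding the 61-nt primer-trimmed amplicon in its
#' two allelic states (record names are the variant ids, "sibirica" and
#' "gmelinii"). The diagnostic position is derived by pairwise comparison:
#' the sequences must differ at exactly one site.
#'
#' The FASTA shipped at `inst/extdata/nad4_variants_synthetic.fasta` is a
#' synthetic stand-in with the documented structure (61 nt, one diagnostic
#' site), not the deposited survey sequence.
#'
#' @param path FASTA path; defaults to the shipped synthetic reference
#' @return an [AmpliconReference-class]
#' @export
readAmpliconReference <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "nad4_variants_synthetic.fasta",
                        package = "larch2s", mustWork = TRUE)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L) stop("reference FASTA must contain exactly 2 records")
  s <- toupper(as.character(seqs))
  names(s) <- sub("\\s.*$", "", names(s))
  if (!all(c("sibirica", "gmelinii") %in% names(s)))
    stop("reference records must be named 'sibirica' and 'gmelinii'")
  if (nchar(s[[1]]) != nchar(s[[2]]))
    stop("variant sequences differ in length")
  a <- strsplit(s[["sibirica"]], "")[[1]]
  b <- strsplit(s[["gmelinii"]], "")[[1]]
  diff <- which(a != b)
  if (length(diff) != 1L)
    stop("variant sequences must differ at exactly one site (found ",
         length(diff), ")")
  new("AmpliconReference",
    sequences = s[c("sibirica", "gmelinii")], position = as.integer(diff),
    alleles = stats::setNames(c("sibirica", "gmelinii"), c(a[diff], b[diff]))
  )
}

.as_read_sequences <- function(reads) {
  if (is(reads, "XStringSet")) return(toupper(as.character(reads)))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads, ignore.case = TRUE))
      "fastq" else "fasta"
    return(toupper(as.character(Biostrings::readDNAStringSet(reads, format = fmt))))
  }
  if (is.character(reads)) return(toupper(reads))
  stop("reads must be an XStringSet, a character vector, or a FASTA/FASTQ path")
}

#' Dereplicate and length/count filter reads
#'
#' Merges identical sequences (summing multiplicities), drops records outside
#' the length window and below the count threshold, and returns a
#' deterministic, input-order-independent table sorted by count (descending)
#' then sequence.
#'
#' @param reads an `XStringSet`, a character vector of sequences, or a
#'   FASTA/FASTQ file path (gz accepted)
#' @param min_len,max_len retained sequence length window, nt (defaults 61/61)
#' @param min_count minimum post-dereplication multiplicity (default 2)
#' @param counts optional integer multiplicities accompanying `reads` (e.g.
#'   pre-dereplicated input); defaults to 1 per record
#' @return data.frame with columns `sequence`, `count`
#' @export
dereplicateReads <- function(reads, min_len = 61, max_len = 61, min_count = 2,
                             counts = NULL) {
  s <- .as_read_sequences(reads)
  if (any(grepl("[^ACGTN]", s)))
    stop("unparseable record at index ", which(grepl("[^ACGTN]", s))[1],
         ": alphabet must be ACGTN")
  if (is.null(counts)) counts <- rep(1L, length(s))
  stopifnot(length(counts) == length(s), all(counts >= 1))
  agg <- rowsum(as.numeric(counts), s)
  d <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1]),
                  row.names = NULL)
  len <- nchar(d$sequence)
  d <- d[len >= min_len & len <= max_len & d$count >= min_count, , drop = FALSE]
  d <- d[order(-d$count, d$sequence), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Classify reads into mitochondrial variants
#'
#' A read is assigned to a variant when (1) it is exactly the amplicon length,
#' (2) its Hamming distance to the reference, ignoring the diagnostic
#' position, is at most `max_mismatch`, and (3) its base at the diagnostic
#' position is one of the two alleles. Otherwise (including an N at the
#' diagnostic site) it is "unassigned".
#'
#' @param sequences character vector of read sequences
#' @param ref an [AmpliconReference-class]
#' @param max_mismatch background mismatch tolerance (default 3)
#' @return character vector: "sibirica", "gmelinii" or "unassigned"
#' @export
classifyReads <- function(sequences, ref, max_mismatch = 3) {
  stopifnot(is(ref, "AmpliconReference"))
  sequences <- toupper(sequences)
  out <- rep("unassigned", length(sequences))
  L <- nchar(ref@sequences[[1]])
  ok <- nchar(sequences) == L
  if (!any(ok)) return(out)
  m <- matrix(unlist(strsplit(sequences[ok], ""), use.names = FALSE),
              nrow = sum(ok), byrow = TRUE)
  refchars <- strsplit(ref@sequences[["sibirica"]], "")[[1]]
  bg <- setdiff(seq_len(L), ref@position)
  mism <- rowSums(m[, bg, drop = FALSE] !=
                  matrix(refchars[bg], sum(ok), length(bg), byrow = TRUE))
  allele <- m[, ref@position]
  variant <- ref@alleles[allele]
  assigned <- mism <= max_mismatch & !is.na(variant)
  out[ok][assigned] <- variant[assigned]
  out
}

#' Profile one sediment sample
#'
#' Aggregates [classifyReads()] over a sample's (dereplicated) reads with
#' multiplicities, computes proportions over assigned reads and calls
#' dominance via [callDominance()].
#'
#' @param records data.frame with columns `sequence`, `count` (and optionally
#'   `sample_id`, which must then be constant)
#' @param ref an [AmpliconReference-class]
#' @param sample_id sample identifier (required when `records` lacks one)
#' @param depth_cm,age_calbp optional sample metadata
#' @param max_mismatch background mismatch tolerance
#' @param dom_threshold,min_assigned dominance thresholds, see [callDominance()]
#' @return a [SampleVariantProfile-class]
#' @export
profileSample <- function(records, ref, sample_id = NULL, depth_cm = NA_real_,
                          age_calbp = NA_real_, max_mismatch = 3,
                          dom_threshold = 0.9, min_assigned = 10) {
  if ("sample_id" %in% names(records)) {
    ids <- unique(records$sample_id)
    if (length(ids) > 1L)
      stop("records mix sample ids: ", paste(ids, collapse = ", "))
    if (is.null(sample_id)) sample_id <- ids
  }
  if (is.null(sample_id)) stop("sample_id required")
  cls <- classifyReads(records$sequence, ref, max_mismatch)
  cnt <- c(sibirica = 0L, gmelinii = 0L, unassigned = 0L)
  tab <- rowsum(as.numeric(records$count), cls)
  cnt[rownames(tab)] <- as.integer(tab[, 1])
  assigned <- cnt[["sibirica"]] + cnt[["gmelinii"]]
  props <- if (assigned > 0)
    c(sibirica = cnt[["sibirica"]] / assigned,
      gmelinii = cnt[["gmelinii"]] / assigned)
  else c(sibirica = NA_real_, gmelinii = NA_real_)
  prof <- new("SampleVariantProfile",
    sample_id = as.character(sample_id), depth_cm = depth_cm,
    age_calbp = age_calbp, counts = cnt, proportions = props, call = "none"
  )
  prof@call <- callDominance(prof, dom_threshold, min_assigned)
  prof
}

#' Call variant dominance for a sample
#'
#' "none" when fewer than `min_assigned` reads were assigned; a variant when
#' its proportion of assigned reads is at least `dom_threshold`; otherwise
#' "mixed".
#'
#' @param profile a [SampleVariantProfile-class]
#' @param dom_threshold dominance proportion threshold, must be > 0.5
#'   (default 0.9)
#' @param min_assigned minimum assigned reads for any call (default 10)
#' @return one of "sibirica", "gmelinii", "mixed", "none"
#' @export
callDominance <- function(profile, dom_threshold = 0.9, min_assigned = 10) {
  if (dom_threshold <= 0.5)
    stop("dom_threshold must exceed 0.5; dominance is otherwise ambiguous")
  cnt <- variantCounts(profile)
  assigned <- cnt[["sibirica"]] + cnt[["gmelinii"]]
  if (assigned < min_assigned) return("none")
  p <- variantProportions(profile)
  if (p[["sibirica"]] >= dom_threshold) return("sibirica")
  if (p[["gmelinii"]] >= dom_threshold) return("gmelinii")
  "mixed"
}
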