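#' Genome record constructor
#'
#' A genome record holds one replicon (chromosome or plasmid) of one species:
#' an uppercase nucleotide sequence over `{A,C,G,T,N}` plus identifying labels.
#'
#' @param species_id,replicon_id Text labels. `(species_id, replicon_id)`
#'   pairs must be unique within a dataset.
#' @param sequence Nucleotide string; lowercase and `U` are normalized, any
#'   other character is rejected with its position.
#' @param circular Logical; circular replicons are additionally scanned across
#'   the origin junction by [find_occurrences()].
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(species_id, replicon_id, sequence, circular = TRUE) {
  stopifnot(is.character(species_id), is.character(replicon_id),
            is.character(sequence), length(sequence) == 1L)
  seq <- chartr("U", "T", toupper(sequence))
  if (nchar(seq) < 1L) stop("sequence length must be >= 1")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop(sprintf("illegal character '%s' at position %d in replicon '%s'",
                 substr(seq, bad, bad), bad, replicon_id))
  }
  structure(list(species_id = species_id, replicon_id = replicon_id,
                 sequence = seq, circular = isTRUE(circular)),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s / %s: %s nt%s\n", x$species_id,
              x$replicon_id, format(nchar(x$sequence), big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' Read genome sequences from a FASTA file
#'
#' Each FASTA entry becomes one [genome_record()]. Sequences are uppercased and
#' `U` is mapped to `T`; any character outside `{A,C,G,T,N}` raises an error
#' naming its position within the entry.
#'
#' @param path FASTA file.
#' @param species_id Species label attached to every record (default: file
#'   name without extension).
#' @param circular Logical, recycled over entries.
#' @return List of `genome_record`s, one per FASTA entry.
#' @export
read_genome_fasta <- function(path, species_id = NULL, circular = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (is.null(species_id)) {
    species_id <- sub("\\.[^.]*$", "", basename(path))
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate replicon ids in ", path)
  circular <- rep_len(circular, length(set))
  Map(function(id, s, circ) genome_record(species_id, id, as.character(s), circ),
      ids, as.character(set), circular)
}

#' Write genome records to FASTA
#'
#' @param genomes List of [genome_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genomes, path) {
  seqs <- Biostrings::BStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "replicon_id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Keeps rows whose type equals `feature_kind` (GFF3 column 3). Coordinates
#' stay 1-based inclusive, as in GFF3; no half-open conversion happens
#' anywhere in the package.
#'
#' @param path GFF3 file.
#' @param feature_kind Feature type to keep (default `"CDS"`).
#' @return `data.frame` with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand` (`"+"` or `"-"`).
#' @export
read_gene_features <- function(path, feature_kind = "CDS") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(rows) < 9L)
  if (length(short)) {
    stop("malformed GFF3 row (fewer than 9 columns) at data line ", short[1L])
  }
  keep <- vapply(rows, function(r) r[3L] == feature_kind, logical(1))
  rows <- rows[keep]
  if (!length(rows)) {
    return(data.frame(gene_id = character(), replicon_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- vapply(rows, `[[`, "", 7L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad)) {
    stop("unknown strand symbol '", strand[bad[1L]], "' in ", path)
  }
  start <- as.integer(vapply(rows, `[[`, "", 4L))
  end <- as.integer(vapply(rows, `[[`, "", 5L))
  if (any(is.na(start) | is.na(end))) stop("non-numeric coordinates in ", path)
  if (any(end < start)) {
    stop("feature with end < start at data line ", which(end < start)[1L])
  }
  attr9 <- vapply(rows, `[[`, "", 9L)
  id <- sub("^.*ID=([^;]+).*$", "\\1", attr9)
  no_id <- !grepl("ID=", attr9, fixed = TRUE)
  id[no_id] <- paste0("feature_", which(no_id))
  if (anyDuplicated(id)) stop("duplicate gene ids in ", path)
  data.frame(gene_id = id, replicon_id = vapply(rows, `[[`, "", 1L),
             start = start, end = end, strand = strand,
             stringsAsFactors = FALSE)
}

#' Extract coding-strand gene sequences from genome records
#'
#' Returns the subsequence `start..end` (1-based inclusive) of the feature's
#' replicon; for minus-strand features the reverse complement, so every
#' returned sequence reads 5'->3' on the coding strand.
#'
#' @param genomes List of [genome_record()]s.
#' @param features Feature table as returned by [read_gene_features()].
#' @return Named character vector, `gene_id` -> nucleotide sequence.
#' @export
extract_gene_sequences <- function(genomes, features) {
  seqs <- setNames(vapply(genomes, `[[`, "", "sequence"),
                   vapply(genomes, `[[`, "", "replicon_id"))
  missing <- setdiff(unique(features$replicon_id), names(seqs))
  if (length(missing)) {
    stop("unresolvable replicon id(s): ", paste(missing, collapse = ", "))
  }
  lens <- nchar(seqs)[features$replicon_id]
  oob <- features$start < 1L | features$end > lens
  if (any(oob)) {
    stop("out-of-bounds coordinates for gene(s): ",
         paste(features$gene_id[oob], collapse = ", "))
  }
  out <- substr(seqs[features$replicon_id], features$start, features$end)
  minus <- features$strand == "-"
  if (any(minus)) out[minus] <- reverse_complement(out[minus])
  setNames(out, features$gene_id)
}

#' Write a list of records as a TSV table
#'
#' All records must share one key set. Output is tab-separated with a header
#' row, rows in input order, and numeric values rendered with at least six
#' significant digits.
#'
#' @param records List of named lists/vectors with identical names, or a
#'   `data.frame`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path) {
  if (is.data.frame(records)) {
    df <- records
  } else {
    if (length(records)) {
      keys <- names(records[[1L]])
      same <- vapply(records, function(r) identical(names(r), keys), logical(1))
      if (!all(same)) stop("records do not share a common key set")
      df <- do.call(rbind, lapply(records, function(r) {
        as.data.frame(lapply(r, identity), stringsAsFactors = FALSE)
      }))
    } else {
      df <- data.frame()
    }
  }
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    if (!is.integer(df[[j]])) df[[j]] <- format(df[[j]], digits = 7, trim = TRUE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
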