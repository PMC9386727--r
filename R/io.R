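#' Read / write protein sequences in FASTA
#'
#' Multi-record, wrapped-line FASTA via Biostrings.
#'
#' @param path File path.
#' @return `read_fasta`: named character vector of residue strings.
#' @rdname fasta_io
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @param sequences Named character vector.
#' @rdname fasta_io
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sequences), path)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Tab-separated file with header columns `protein_id` and `annotation_ids`
#' (comma-separated ids; empty for unannotated proteins). Malformed lines
#' are rejected with their line number.
#'
#' @param path File path.
#' @return Data frame with `id` and `annotations` (list column).
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("'", path, "': empty annotation table")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr[1:2], c("protein_id", "annotation_ids")))
    stop("'", path, "' line 1: header must be 'protein_id\tannotation_ids'")
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 1L | lengths(parts) > 2L |
                 vapply(parts, function(p) !nzchar(p[1L]), logical(1)))
  if (length(bad))
    stop("'", path, "' line ", bad[1L] + 1L, ": expected ",
         "'protein_id<TAB>annotation_ids'")
  ids <- vapply(parts, `[[`, character(1), 1L)
  anns <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2L])) character(0)
    else strsplit(p[2L], ",", fixed = TRUE)[[1L]]
  })
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  out$annotations <- anns
  out
}

#' Write an annotation table
#' @param corpus Data frame with `id` and `annotations` list column.
#' @param path Output path.
#' @export
write_annotation_table <- function(corpus, path) {
  lines <- c("protein_id\tannotation_ids",
             paste0(corpus$id, "\t",
                    vapply(corpus$annotations, paste, character(1),
                           collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a corpus from FASTA plus annotation table
#'
#' Proteins absent from the annotation table get an empty annotation set.
#'
#' @param fasta_path FASTA file of sequences.
#' @param annotation_path Optional annotation TSV (see
#'   [read_annotation_table()]).
#' @return Corpus data frame (`id`, `sequence`, `annotations`).
#' @rdname corpus_io
#' @export
read_corpus <- function(fasta_path, annotation_path = NULL) {
  seqs <- read_fasta(fasta_path)
  out <- data.frame(id = names(seqs), sequence = unname(seqs),
                    stringsAsFactors = FALSE)
  out$annotations <- rep(list(character(0)), nrow(out))
  if (!is.null(annotation_path)) {
    ann <- read_annotation_table(annotation_path)
    m <- match(out$id, ann$id)
    out$annotations[!is.na(m)] <- ann$annotations[m[!is.na(m)]]
  }
  out
}

#' @param corpus Corpus data frame.
#' @rdname corpus_io
#' @export
write_corpus <- function(corpus, fasta_path, annotation_path = NULL) {
  write_fasta(stats::setNames(corpus$sequence, corpus$id), fasta_path)
  if (!is.null(annotation_path)) write_annotation_table(corpus, annotation_path)
  invisible(fasta_path)
}

#' Read / write supervised task label tables
#'
#' Global labels: TSV with header `id`, `label`. Local labels: TSV with
#' header `id`, `labels`, where `labels` is a digit string with exactly one
#' character per residue of the corresponding sequence. Records are checked
#' against the sequences and rejected with a line number on mismatch.
#'
#' @param path Label TSV path.
#' @param sequences Named character vector of sequences (for validation of
#'   local label lengths).
#' @param resolution `"global"` or `"local"`.
#' @return Data frame `id`, `label`.
#' @export
read_label_table <- function(path, sequences = NULL,
                             resolution = c("global", "local")) {
  resolution <- match.arg(resolution)
  lines <- readLines(path)
  want <- if (resolution == "global") c("id", "label") else c("id", "labels")
  hdr <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(hdr[1:2], want))
    stop("'", path, "' line 1: header must be '", paste(want, collapse = "\t"), "'")
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("'", path, "' line ", bad[1L] + 1L, ": expected 2 fields")
  ids <- vapply(parts, `[[`, character(1), 1L)
  lab <- vapply(parts, `[[`, character(1), 2L)
  if (resolution == "local" && !is.null(sequences)) {
    ok <- nchar(lab) == nchar(sequences[ids])
    if (any(!ok, na.rm = TRUE))
      stop("'", path, "' line ", which(!ok)[1L] + 1L,
           ": label string length does not match the sequence")
  }
  data.frame(id = ids, label = lab, stringsAsFactors = FALSE)
}

#' Write task splits to a directory
#'
#' Sequences as FASTA, labels as TSV, one pair per split
#' (`<prefix>_<split>.fasta` / `.tsv`).
#'
#' @param task A `pdae_task`.
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix (default the task kind).
#' @export
write_task <- function(task, dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- paste0(task$resolution, "_", task$label_type)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (split in c("train", "valid", "test")) {
    df <- task[[split]]
    write_fasta(stats::setNames(df$sequence, df$id),
                file.path(dir, paste0(prefix, "_", split, ".fasta")))
    hdr <- if (task$resolution == "global") "id\tlabel" else "id\tlabels"
    writeLines(c(hdr, paste0(df$id, "\t", df$label)),
               file.path(dir, paste0(prefix, "_", split, ".tsv")))
  }
  invisible(dir)
}
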