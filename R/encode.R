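#' Encode a protein sequence to fixed-length token ids
#'
#' Sequences that fit within `target_len` (residues plus the two terminal
#' markers) are encoded as `START`, residues, `END`, padded with `PAD`.
#' Longer sequences are encoded as a random contiguous window of exactly
#' `target_len` residues chosen uniformly over all windows that omit at least
#' one terminus; the missing `START`/`END` marker signals to the model that it
#' sees a fragment. Characters other than the 20 standard residues, `U` or
#' `X` map to the `OTHER` token.
#'
#' Window sampling uses the session RNG; call `set.seed()` for
#' reproducibility, or pass `window = "start"` for a deterministic prefix
#' window (used at evaluation time).
#'
#' @param seq Character scalar, the residue string (non-empty).
#' @param target_len Encoded length, at least 3.
#' @param vocab Token vocabulary (defaults to [token_vocabulary()]).
#' @param window `"random"` (default) or `"start"` — deterministic window at
#'   offset 0 for over-long sequences.
#' @return Object of class `encoded_seq`: list with `token_ids` (integer,
#'   0-based, length `target_len`), `has_start`, `has_end`, `window_offset`
#'   (0-based offset of the first encoded residue in the source), and
#'   `n_residues` (number of real residues encoded).
#' @examples
#' e <- encode_sequence("ACD", 8)
#' e$token_ids   # START A C D END PAD PAD PAD
#' @export
encode_sequence <- function(seq, target_len, vocab = token_vocabulary(),
                            window = c("random", "start")) {
  window <- match.arg(window)
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    stop("'seq' must be a non-empty residue string")
  }
  target_len <- as.integer(target_len)
  if (is.na(target_len) || target_len < 3L) {
    stop("'target_len' must be an integer >= 3")
  }
  n <- nchar(seq)
  ids_full <- residues_to_ids(seq, vocab)
  START <- .tok_id(vocab, "START"); END <- .tok_id(vocab, "END")
  PAD <- .tok_id(vocab, "PAD")

  if (n + 2L <= target_len) {
    tok <- c(START, ids_full, END, rep(PAD, target_len - n - 2L))
    return(structure(list(token_ids = as.integer(tok), has_start = TRUE,
                          has_end = TRUE, window_offset = 0L,
                          n_residues = n),
                     class = "encoded_seq"))
  }

  # over-long: window of residues fills the whole encoding; a window starting
  # at the first residue gets START (and then holds target_len - 1 residues),
  # one ending at the last residue gets END, interior windows get neither.
  # Admissible windows are enumerated as (offset, has_start, has_end) with at
  # least one marker absent, sampled uniformly.
  w_plain <- target_len            # residues when no marker present
  w_mark <- target_len - 1L        # residues when one marker present
  choices <- list()
  if (n >= w_mark) {
    choices[[length(choices) + 1L]] <- list(off = 0L, s = TRUE, e = FALSE)
    choices[[length(choices) + 1L]] <- list(off = n - w_mark, s = FALSE, e = TRUE)
  }
  if (n >= w_plain) {
    # interior windows may neither start at the first residue (would carry
    # START) nor end at the last (would carry END)
    for (off in seq_len(max(0L, n - w_plain - 1L))) {
      choices[[length(choices) + 1L]] <- list(off = off, s = FALSE, e = FALSE)
    }
  }
  pick <- if (window == "start" || length(choices) == 1L) 1L
          else sample.int(length(choices), 1L)
  ch <- choices[[pick]]
  w <- if (ch$s || ch$e) w_mark else w_plain
  body <- ids_full[(ch$off + 1L):(ch$off + w)]
  tok <- c(if (ch$s) START, body, if (ch$e) END)
  structure(list(token_ids = as.integer(tok), has_start = ch$s,
                 has_end = ch$e, window_offset = as.integer(ch$off),
                 n_residues = w),
            class = "encoded_seq")
}

#' @export
print.encoded_seq <- function(x, ...) {
  cat("Encoded sequence: length", length(x$token_ids),
      "| residues", x$n_residues,
      "| START", x$has_start, "| END", x$has_end,
      "| offset", x$window_offset, "\n")
  invisible(x)
}

#' Map a residue string to 0-based token ids (no specials)
#'
#' @inheritParams encode_sequence
#' @return Integer vector of 0-based token ids, one per character.
#' @export
residues_to_ids <- function(seq, vocab = token_vocabulary()) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  ids <- vocab$index[chars]
  other <- .tok_id(vocab, "OTHER")
  # anything unknown, or a letter reserved for specials, collapses to OTHER
  ids[is.na(ids)] <- other
  as.integer(unname(ids))
}

#' Decode token ids back to symbols
#'
#' Inverse of the encoding on the residue window: special markers are
#' reported by name, residues by letter.
#'
#' @param token_ids Integer vector of 0-based ids.
#' @param vocab Token vocabulary.
#' @param drop_specials Drop START/END/PAD and return the residue string.
#' @return Character vector of symbols, or a single string when
#'   `drop_specials = TRUE`.
#' @export
decode_tokens <- function(token_ids, vocab = token_vocabulary(),
                          drop_specials = FALSE) {
  if (any(token_ids < 0L | token_ids > 25L)) stop("token ids must be in 0..25")
  syms <- vocab$symbols[token_ids + 1L]
  if (!drop_specials) return(syms)
  paste(syms[!syms %in% c("START", "END", "PAD")], collapse = "")
}

#' Encode an annotation set as a binary vector
#'
#' @param annotation_ids Character vector (or empty) of annotation ids.
#' @param vocab An [annotation_vocabulary()].
#' @param strict Error on ids absent from the vocabulary; default drops them
#'   with a warning.
#' @return Integer 0/1 vector of length `vocab$size`; all zeros encodes "no
#'   information".
#' @export
encode_annotations <- function(annotation_ids, vocab, strict = FALSE) {
  stopifnot(inherits(vocab, "annotation_vocab"))
  bits <- integer(vocab$size)
  if (length(annotation_ids) == 0L) return(bits)
  j <- match(annotation_ids, vocab$ids)
  if (anyNA(j)) {
    bad <- annotation_ids[is.na(j)]
    if (strict) stop("unknown annotation ids: ", paste(bad, collapse = ", "))
    warning("dropping ", length(bad), " unknown annotation id(s)")
    j <- j[!is.na(j)]
  }
  bits[j] <- 1L
  bits
}
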