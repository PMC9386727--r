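#' Canonical amino-acid token vocabulary
#'
#' Builds the fixed 26-symbol vocabulary used throughout the model: the 20
#' standard amino acids in alphabetical one-letter order, selenocysteine
#' (`U`), undetermined residue (`X`), a catch-all `OTHER` for any remaining
#' letter (B, Z, J, ...), and the three structural markers `START`, `END`,
#' `PAD`. Token ids are 0-based (0..25) and the ordering is frozen so that
#' saved model weights remain portable.
#'
#' @return An object of class `token_vocab`: a list with `symbols` (character
#'   vector of length 26, position `i` holds the symbol with id `i - 1`) and
#'   `index` (named integer vector mapping symbol to id).
#' @examples
#' v <- token_vocabulary()
#' length(v$symbols)     # 26
#' v$index[["START"]]
#' @export
token_vocabulary <- function() {
  residues <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  symbols <- c(residues, "U", "X", "OTHER", "START", "END", "PAD")
  index <- stats::setNames(seq_along(symbols) - 1L, symbols)
  structure(list(symbols = symbols, index = index), class = "token_vocab")
}

#' @export
print.token_vocab <- function(x, ...) {
  cat("Token vocabulary:", length(x$symbols), "symbols\n")
  cat(" ", paste(x$symbols, collapse = " "), "\n")
  invisible(x)
}

# id of a named special token
.tok_id <- function(vocab, symbol) unname(vocab$index[[symbol]])

#' Annotation vocabulary
#'
#' A fixed, ordered set of whole-protein annotation identifiers (e.g. GO
#' terms). The annotation input/output of the model is a binary vector whose
#' j-th entry refers to `ids[j]`; the ordering therefore must not change over
#' a model's lifetime. The default size mirrors the 8943-term vocabulary used
#' for the full-scale model, but any size is allowed for reduced corpora.
#'
#' @param ids Character vector of annotation identifiers (unique), or `NULL`
#'   to generate `size` placeholder ids (`GO:0000001`-style).
#' @param size Number of annotations when `ids` is `NULL` (default 8943).
#' @return Object of class `annotation_vocab` with fields `ids` and `size`.
#' @export
annotation_vocabulary <- function(ids = NULL, size = 8943L) {
  if (is.null(ids)) {
    size <- as.integer(size)
    if (size < 1L) stop("annotation vocabulary size must be positive")
    ids <- sprintf("GO:%07d", seq_len(size))
  } else {
    ids <- as.character(ids)
    if (anyDuplicated(ids)) stop("annotation ids must be unique")
    size <- length(ids)
  }
  structure(list(ids = ids, size = size), class = "annotation_vocab")
}

#' @export
print.annotation_vocab <- function(x, ...) {
  cat("Annotation vocabulary:", x$size, "ids\n")
  invisible(x)
}

#' Write / read a token or annotation vocabulary as plain text
#'
#' One symbol per line; the line number minus one is the integer id.
#'
#' @param vocab A `token_vocab` or `annotation_vocab`.
#' @param path File path.
#' @rdname vocab_io
#' @export
write_vocabulary <- function(vocab, path) {
  syms <- if (inherits(vocab, "token_vocab")) vocab$symbols else vocab$ids
  writeLines(syms, path)
  invisible(path)
}

#' @param type `"token"` or `"annotation"`.
#' @rdname vocab_io
#' @export
read_vocabulary <- function(path, type = c("token", "annotation")) {
  type <- match.arg(type)
  syms <- readLines(path)
  if (type == "annotation") return(annotation_vocabulary(ids = syms))
  ref <- token_vocabulary()
  if (!identical(syms, ref$symbols)) {
    stop("file does not contain the canonical 26-symbol token vocabulary")
  }
  ref
}
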