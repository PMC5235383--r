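#' Build an alphabet for n-gram signatures
#'
#' An alphabet is an ordered set of single characters over which n-gram
#' signatures are computed, together with a designated separator character
#' standing in for word boundaries. The ordering is part of the on-disk
#' contract: signature vectors are laid out row-major over it, so two runs
#' with the same alphabet produce comparable columns.
#'
#' @param symbols Character vector of distinct single characters, in the
#'   order that defines the signature layout.
#' @param separator Single character representing word boundaries
#'   (default `"_"`). Appended to `symbols` if not already present.
#'
#' @return An object of class `sls_alphabet`: a list with elements
#'   `symbols` (ordered character vector) and `separator`.
#'
#' @examples
#' build_alphabet(c("a", "b"))           # separator "_" appended, size 3
#' alphabet_size(default_alphabet())     # 65
#' @seealso [default_alphabet()], [signature_of()]
#' @export
build_alphabet <- function(symbols, separator = "_") {
  if (length(symbols) == 0) {
    abort_input("`symbols` must be a nonempty character vector.")
  }
  symbols <- as.character(symbols)
  if (any(is.na(symbols)) || any(nchar(symbols) != 1L)) {
    abort_input("every alphabet symbol must be a single character.")
  }
  if (!is.character(separator) || length(separator) != 1L ||
      nchar(separator) != 1L) {
    abort_input("`separator` must be a single character.")
  }
  dup <- unique(symbols[duplicated(symbols)])
  if (length(dup) > 0) {
    abort_input(sprintf(
      "duplicate alphabet symbol(s): %s",
      paste(sQuote(dup), collapse = ", ")
    ))
  }
  if (!separator %in% symbols) {
    symbols <- c(symbols, separator)
  }
  if (length(symbols) < 2L) {
    abort_input("an alphabet needs at least 2 symbols.")
  }
  structure(
    list(symbols = symbols, separator = separator),
    class = "sls_alphabet"
  )
}

#' The packaged 65-character extended Latin alphabet
#'
#' The default alphabet used for language-signature work: the 26 letters of
#' the basic Latin alphabet, the word separator `"_"`, and 38 accented or
#' special characters occurring across Latin-script Indo-European languages.
#'
#' @return An `sls_alphabet` of size 65.
#' @export
default_alphabet <- function() {
  specials <- c(
    "ä", "à", "á", "â", "å", "ã",
    "æ", "ç", "ê", "ë", "è", "é",
    "ì", "í", "î", "ñ", "ö",
    "ø", "ò", "ó", "õ", "ô", "š",
    "ß", "ü", "ù", "ú", "û",
    "ý", "ž", "ś", "ź", "ð", "ż",
    "ł", "ć", "ą", "ę"
  )
  build_alphabet(c(letters, "_", specials), separator = "_")
}

#' @rdname build_alphabet
#' @param alphabet An `sls_alphabet`.
#' @export
alphabet_size <- function(alphabet) {
  stopifnot(inherits(alphabet, "sls_alphabet"))
  length(alphabet$symbols)
}

#' @export
print.sls_alphabet <- function(x, ...) {
  cat(sprintf(
    "<sls_alphabet> %d symbols, separator %s\n  %s\n",
    length(x$symbols), sQuote(x$separator),
    paste(x$symbols, collapse = " ")
  ))
  invisible(x)
}
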