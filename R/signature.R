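#' Clean raw text into an in-alphabet document
#'
#' Normalises a raw character string so that every remaining character
#' belongs to the alphabet: the text is canonically composed (NFC) and
#' lower-cased, every maximal run of whitespace becomes one separator,
#' characters outside the alphabet are dropped (their count is kept),
#' runs of separators left behind by the drops are collapsed, and leading
#' or trailing separators are removed.
#'
#' @param x A character scalar of raw text.
#' @param alphabet An [`sls_alphabet`][build_alphabet].
#' @param label Item name carried through to the document (default `""`).
#'
#' @return An `sls_document`: a list with `label`, `chars` (the cleaned
#'   string), `n` (character count, separators included) and `dropped`
#'   (number of out-of-alphabet characters removed).
#'
#' @examples
#' ab <- build_alphabet(c("a", "b"))
#' clean_text("Ab  ba", ab)$chars  # "ab_ba"
#' @export
clean_text <- function(x, alphabet = default_alphabet(), label = "") {
  stopifnot(inherits(alphabet, "sls_alphabet"))
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort_input("`x` must be a single character string.")
  }
  sep <- alphabet$separator
  x <- stringi::stri_trans_nfc(x)
  x <- stringi::stri_trans_tolower(x)
  x <- stringi::stri_replace_all_regex(x, "\\s+", sep)
  chars <- stringi::stri_split_boundaries(x, type = "character")[[1]]
  keep <- chars %in% alphabet$symbols
  dropped <- sum(!keep)
  if (dropped > 0) {
    inform(sprintf("clean_text: dropped %d out-of-alphabet character(s).",
                   dropped))
  }
  chars <- chars[keep]
  out <- paste(chars, collapse = "")
  # collapse separator runs created by dropped characters, trim the ends
  sep_re <- stringi::stri_replace_all_regex(sep, "([\\W])", "\\\\$1")
  out <- stringi::stri_replace_all_regex(out, paste0(sep_re, "+"), sep)
  out <- stringi::stri_replace_all_regex(
    out, paste0("^", sep_re, "|", sep_re, "$"), ""
  )
  n <- stringi::stri_length(out)
  if (n < 2L) {
    abort_input("document too short for bi-grams (fewer than 2 characters after cleaning).")
  }
  new_document(label = label, chars = out, n = n, dropped = dropped)
}

new_document <- function(label, chars, n = stringi::stri_length(chars),
                         dropped = 0L) {
  structure(
    list(label = label, chars = chars, n = n, dropped = dropped),
    class = "sls_document"
  )
}

#' @export
print.sls_document <- function(x, ...) {
  preview <- if (x$n > 40) paste0(substr(x$chars, 1, 40), "...") else x$chars
  cat(sprintf("<sls_document> %s (n = %d)\n  %s\n",
              sQuote(x$label), x$n, preview))
  invisible(x)
}

#' Names of the n-gram axes of a signature vector
#'
#' Row-major over the alphabet ordering: the first symbol of the n-gram
#' varies slowest. Symbols within an n-gram are joined by `"|"`.
#'
#' @inheritParams clean_text
#' @param k n-gram order (default 2, bi-grams).
#' @return Character vector of length `alphabet_size(alphabet)^k`.
#' @export
ngram_names <- function(alphabet, k = 2L) {
  stopifnot(inherits(alphabet, "sls_alphabet"))
  k <- check_order_k(k)
  syms <- alphabet$symbols
  out <- syms
  for (i in seq_len(k - 1L)) {
    out <- paste(rep(out, each = length(syms)), syms, sep = "|")
  }
  out
}

check_order_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 2 || k != round(k)) {
    abort_input("`k` must be an integer >= 2.")
  }
  as.integer(k)
}

#' Relative n-gram frequency signature of a document
#'
#' Counts overlapping n-grams (adjacent windows of width `k`) in the cleaned
#' character sequence and divides by their number, `n - k + 1` (for bi-grams,
#' the `n - 1` overlapping adjacent pairs of an `n`-character document). The
#' result is a nonnegative vector of length `alphabet_size^k` that sums to 1,
#' laid out row-major over the alphabet ordering.
#'
#' @param doc An `sls_document` (see [clean_text()]), or a character scalar
#'   already restricted to the alphabet.
#' @inheritParams ngram_names
#'
#' @return A named numeric vector of length `alphabet_size(alphabet)^k`;
#'   names are the [ngram_names()]. Attributes `label` and `k` are set.
#'
#' @examples
#' ab <- build_alphabet(c("a", "b"))
#' sig <- signature_of(new_document("x", "abab"), ab)
#' sig[c("a|b", "b|a")]  # 2/3 and 1/3
#' @export
signature_of <- function(doc, alphabet = default_alphabet(), k = 2L) {
  stopifnot(inherits(alphabet, "sls_alphabet"))
  k <- check_order_k(k)
  if (is.character(doc)) {
    doc <- new_document(label = "", chars = doc)
  }
  stopifnot(inherits(doc, "sls_document"))
  if (doc$n < k) {
    abort_input(sprintf("document too short: need at least %d characters.", k))
  }
  chars <- stringi::stri_split_boundaries(doc$chars,
                                          type = "character")[[1]]
  bad <- setdiff(unique(chars), alphabet$symbols)
  if (length(bad) > 0) {
    abort_input(sprintf("document contains out-of-alphabet character(s): %s",
                        paste(sQuote(bad), collapse = ", ")))
  }
  n_grams <- doc$n - k + 1L
  grams <- chars[seq_len(n_grams)]
  for (i in seq_len(k - 1L)) {
    grams <- paste(grams, chars[seq_len(n_grams) + i], sep = "|")
  }
  lev <- ngram_names(alphabet, k)
  counts <- tabulate(factor(grams, levels = lev), nbins = length(lev))
  values <- counts / n_grams
  names(values) <- lev
  attr(values, "label") <- doc$label
  attr(values, "k") <- k
  values
}

#' Signature table for a corpus
#'
#' The tidy entry point of the signature pipeline: takes a corpus data frame,
#' cleans each text against the alphabet and returns one signature row per
#' document.
#'
#' @param corpus Data frame with columns `label` and `text`
#'   (see [read_corpus()]), or a list of `sls_document`s.
#' @inheritParams ngram_names
#' @param clean Clean the texts with [clean_text()] first (default `TRUE`;
#'   ignored when `corpus` is already a list of documents).
#'
#' @return A tibble with a `label` column followed by
#'   `alphabet_size(alphabet)^k` numeric columns named by [ngram_names()].
#' @export
sls_signatures <- function(corpus, alphabet = default_alphabet(), k = 2L,
                           clean = TRUE) {
  k <- check_order_k(k)
  if (is.data.frame(corpus)) {
    if (!all(c("label", "text") %in% names(corpus))) {
      abort_input("`corpus` must have columns `label` and `text`.")
    }
    docs <- purrr::map2(corpus$text, corpus$label, function(txt, lab) {
      if (clean) clean_text(txt, alphabet, label = lab)
      else new_document(lab, txt)
    })
  } else if (is.list(corpus) &&
             all(purrr::map_lgl(corpus, inherits, "sls_document"))) {
    docs <- corpus
  } else {
    abort_input("`corpus` must be a data frame or a list of sls_documents.")
  }
  if (length(docs) == 0) abort_input("empty corpus.")
  rows <- purrr::map(docs, signature_of, alphabet = alphabet, k = k)
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(
    tibble(label = purrr::map_chr(docs, "label")),
    as_tibble(mat, .name_repair = "minimal")
  )
}

#' Read a corpus of documents
#'
#' Reads one document per plain-text file (label = file name without
#' extension), or all records of FASTA files in sequence mode
#' (label = record id, characters = residues).
#'
#' @param path Directory or vector of file paths.
#' @param format `"text"` (default) or `"fasta"`.
#' @param pattern File-name filter used when `path` is a directory.
#' @return A tibble with columns `label` and `text`.
#' @export
read_corpus <- function(path, format = c("text", "fasta"),
                        pattern = NULL) {
  format <- match.arg(format)
  if (length(path) == 1L && dir.exists(path)) {
    pattern <- pattern %||%
      if (format == "text") "\\.txt$" else "\\.(fa|fasta)$"
    files <- sort(list.files(path, pattern = pattern, full.names = TRUE))
  } else {
    files <- path
  }
  if (length(files) == 0 || !all(file.exists(files))) {
    abort_input("no readable corpus files found.")
  }
  if (format == "text") {
    tibble(
      label = sub("\\.[^.]*$", "", basename(files)),
      text = purrr::map_chr(
        files,
        function(f) paste(readr::read_lines(f), collapse = " ")
      )
    )
  } else {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort_input("reading FASTA requires the Biostrings package.")
    }
    recs <- purrr::map(files, function(f) {
      s <- Biostrings::readBStringSet(f)
      tibble(label = names(s), text = unname(tolower(as.character(s))))
    })
    dplyr::bind_rows(recs)
  }
}

#' Write and read signature tables
#'
#' `write_signatures()` writes the dense table (one row per document, one
#' column per n-gram, names like `"a|b"`); `write_signatures_sparse()`
#' writes only the nonzero entries as `(label, ngram, value)` triplets;
#' `read_signatures()` reads the dense format back.
#'
#' @param signatures Tibble from [sls_signatures()].
#' @param path File path.
#' @return `read_signatures()` returns the signature tibble; the writers
#'   return `path` invisibly.
#' @export
write_signatures <- function(signatures, path) {
  readr::write_tsv(signatures, path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
write_signatures_sparse <- function(signatures, path) {
  long <- tidyr::pivot_longer(signatures, -"label",
                              names_to = "ngram", values_to = "value")
  readr::write_tsv(dplyr::filter(long, .data$value > 0), path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Plot the strongest n-gram frequencies of a signature table
#'
#' @param signatures Tibble from [sls_signatures()].
#' @param top_n Number of highest-frequency n-grams to show (default 20,
#'   ranked by the column maximum across documents).
#' @return A ggplot tile map of documents by n-grams.
#' @export
plot_signature <- function(signatures, top_n = 20) {
  long <- tidyr::pivot_longer(signatures, -"label",
                              names_to = "ngram", values_to = "rf")
  top <- long |>
    dplyr::group_by(.data$ngram) |>
    dplyr::summarise(peak = max(.data$rf)) |>
    dplyr::slice_max(.data$peak, n = top_n, with_ties = FALSE)
  long <- dplyr::semi_join(long, top, by = "ngram")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ngram, y = .data$label,
                                     fill = .data$rf)) +
    ggplot2::geom_tile() +
    ggplot2::labs(x = "n-gram", y = NULL, fill = "rel. freq.") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}
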