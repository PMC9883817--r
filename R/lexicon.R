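#' Stress-condition lexicons
#'
#' A stress lexicon is a named, ordered set of lowercase phrases that mark a
#' review as stress-related when any of them occurs as a whole word (or
#' whole-phrase) match. The bundled default holds the 15 most frequent
#' stress-related conditions observed in company reviews (e.g. "stress",
#' "high stress", "burnout", "pressure to perform"); the file format is
#' plain text, one phrase per line, with `#` comments, so users can extend
#' it with further conditions.
#'
#' @param phrases Character vector of phrases. Stored lowercased; duplicates
#'   (after lowercasing) are an error.
#' @param name Label recording where the lexicon came from.
#'
#' @return A `stress_lexicon`: a character vector of lowercase phrases with
#'   a `name` attribute.
#' @examples
#' lex <- stress_lexicon(c("stress", "burnout"), name = "tiny")
#' default_stress_lexicon()
#' @export
stress_lexicon <- function(phrases, name = "custom") {
  phrases <- stringr::str_squish(tolower(as.character(phrases)))
  phrases <- phrases[nzchar(phrases)]
  if (length(phrases) == 0) {
    abort("A stress lexicon needs at least one phrase.")
  }
  if (anyDuplicated(phrases)) {
    abort(paste0(
      "Duplicate lexicon phrases after lowercasing: ",
      paste(unique(phrases[duplicated(phrases)]), collapse = ", ")
    ))
  }
  structure(phrases, name = name, class = c("stress_lexicon", "character"))
}

#' @rdname stress_lexicon
#' @export
default_stress_lexicon <- function() {
  read_stress_lexicon(
    system.file("extdata", "stress_conditions.txt", package = "stressquad"),
    name = "workplace-stress-15"
  )
}

#' Read a stress lexicon from a plain-text file
#'
#' One phrase per line; blank lines and lines starting with `#` are ignored.
#'
#' @param path Path to the lexicon file.
#' @param name Provenance label; defaults to the file name.
#' @return A [stress_lexicon()].
#' @export
read_stress_lexicon <- function(path, name = basename(path)) {
  if (!file.exists(path)) {
    abort(paste0("Lexicon file not found: ", path))
  }
  lines <- readr::read_lines(path)
  lines <- stringr::str_squish(lines)
  lines <- lines[nzchar(lines) & !stringr::str_starts(lines, "#")]
  stress_lexicon(lines, name = name)
}

#' @export
print.stress_lexicon <- function(x, ...) {
  cat("<stress_lexicon '", attr(x, "name"), "': ", length(x),
      " phrases>\n", sep = "")
  print(as.character(x), ...)
  invisible(x)
}
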