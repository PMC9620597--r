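#' American Soundex phonetic code
#'
#' Encodes a name as it sounds in English rather than as it is spelled, so
#' that common spelling variants (Jon/John) receive the same code. Implements
#' the classic American Soundex: the first letter is retained, subsequent
#' letters are mapped to digit classes (b/f/p/v = 1, c/g/j/k/q/s/x/z = 2,
#' d/t = 3, l = 4, m/n = 5, r = 6), vowels and y are dropped but separate
#' repeated codes, h and w are dropped without separating repeated codes,
#' and the result is padded or truncated to one letter plus three digits.
#'
#' @param name character vector of names. Case and non-alphabetic characters
#'   are ignored.
#' @return character vector of 4-character codes matching
#'   \code{^[A-Z][0-9]{3}$}, or \code{NA} where the input is missing or
#'   contains no letters.
#' @examples
#' soundex(c("Robert", "Rupert", "Jon", "John"))
#' @export
soundex <- function(name) {
  vapply(name, soundex1, character(1), USE.NAMES = FALSE)
}

.sdx_code <- local({
  m <- integer(26)
  names(m) <- LETTERS
  m[c("B", "F", "P", "V")] <- 1L
  m[c("C", "G", "J", "K", "Q", "S", "X", "Z")] <- 2L
  m[c("D", "T")] <- 3L
  m["L"] <- 4L
  m[c("M", "N")] <- 5L
  m["R"] <- 6L
  # vowels + Y get -1 (separator), H/W get 0 (transparent)
  m[c("A", "E", "I", "O", "U", "Y")] <- -1L
  m
})

soundex1 <- function(name) {
  if (is.na(name)) return(NA_character_)
  letters_only <- strsplit(toupper(gsub("[^A-Za-z]", "", name)), "")[[1]]
  if (length(letters_only) == 0) return(NA_character_)
  codes <- .sdx_code[letters_only]
  out <- character(0)
  prev <- codes[1]  # code of the retained first letter participates in dedup
  if (length(codes) > 1) {
    for (i in 2:length(codes)) {
      ci <- codes[i]
      if (ci == 0L) next            # H/W: transparent, prev unchanged
      if (ci == -1L) { prev <- -1L; next }  # vowel: resets the duplicate run
      if (ci != prev) out <- c(out, ci)
      prev <- ci
    }
  }
  digits <- c(as.character(out), "0", "0", "0")[1:3]
  paste0(letters_only[1], paste(digits, collapse = ""))
}
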