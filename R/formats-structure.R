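# Secondary-structure notation handling: extended dot-bracket (DB) and WUSS.
# Both notations encode base pairs with bracket families -- "<>", "()", "[]",
# "{}" -- plus upper/lower-case letter pairs (Aa, Bb, ...) for pseudoknots.
# WUSS additionally distinguishes unpaired contexts (":" external, "_" hairpin
# loop, "-" bulge/interior, "," multibranch, "~" local end, "." insert), all of
# which collapse to "." in dot-bracket.

BRACKET_OPEN  <- c("<", "(", "[", "{")
BRACKET_CLOSE <- c(">", ")", "]", "}")
WUSS_UNPAIRED <- c(".", ":", "_", "-", "~", ",")

#' Pairing map of a secondary-structure string
#'
#' Matches brackets independently per bracket family (`<>`, `()`, `[]`, `{}`)
#' and per pseudoknot letter pair (`A`/`a`, `B`/`b`, ...). Unpaired symbols
#' are the WUSS loop characters and `.`.
#'
#' @param ss Structure string.
#' @return Integer vector of the same length: position of the partner, or 0
#'   for unpaired positions.
#' @export
structure_pairs <- function(ss) {
  stopifnot(is.character(ss), length(ss) == 1L)
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  pairs <- integer(length(chars))
  stacks <- new.env(parent = emptyenv())
  family_of <- function(ch) {
    i <- match(ch, BRACKET_OPEN)
    if (!is.na(i)) return(list(key = BRACKET_OPEN[i], open = TRUE))
    i <- match(ch, BRACKET_CLOSE)
    if (!is.na(i)) return(list(key = BRACKET_OPEN[i], open = FALSE))
    if (grepl("^[A-Z]$", ch)) return(list(key = ch, open = TRUE))
    if (grepl("^[a-z]$", ch)) return(list(key = toupper(ch), open = FALSE))
    NULL
  }
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% WUSS_UNPAIRED) next
    fam <- family_of(ch)
    if (is.null(fam)) {
      stop_rfam("unbalanced_structure",
                sprintf("unrecognized structure symbol '%s' at position %d", ch, i),
                position = i)
    }
    if (fam$open) {
      assign(fam$key, c(get0(fam$key, envir = stacks, ifnotfound = integer()), i),
             envir = stacks)
    } else {
      st <- get0(fam$key, envir = stacks, ifnotfound = integer())
      if (length(st) == 0L) {
        stop_rfam("unbalanced_structure",
                  sprintf("unmatched closing '%s' at position %d", ch, i),
                  family = fam$key, position = i)
      }
      j <- st[length(st)]
      assign(fam$key, st[-length(st)], envir = stacks)
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  for (key in ls(stacks)) {
    st <- get(key, envir = stacks)
    if (length(st) > 0L) {
      stop_rfam("unbalanced_structure",
                sprintf("unmatched opening '%s' at position %d", key, st[length(st)]),
                family = key, position = st[length(st)])
    }
  }
  pairs
}

#' Convert WUSS notation to extended dot-bracket
#'
#' Length and the full base-pair set are preserved: bracket families and
#' pseudoknot letter pairs pass through unchanged, and every unpaired WUSS
#' symbol becomes `.`. Unbalanced input is an error.
#'
#' @param ss WUSS structure string.
#' @return Extended dot-bracket string of the same length.
#' @examples
#' wuss_to_dotbracket("<<<__>>>")  # "<<<..>>>"
#' @export
wuss_to_dotbracket <- function(ss) {
  structure_pairs(ss)  # validates balance
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  chars[chars %in% WUSS_UNPAIRED] <- "."
  paste(chars, collapse = "")
}

#' Write a consensus sequence/structure record
#'
#' Two-line plain-text record -- line 1 the consensus sequence, line 2 the
#' structure string -- readable by helix-plot tools that accept extended
#' dot-bracket files.
#'
#' @param cs A [consensus_structure()] object.
#' @param file Optional path; if `NULL` the text is returned.
#' @return The record text, invisibly when written to a file.
#' @export
write_consensus_file <- function(cs, file = NULL) {
  stopifnot(inherits(cs, "consensus_structure"))
  txt <- paste0(cs$sequence, "\n", cs$structure, "\n")
  if (is.null(file)) return(txt)
  writeChar(txt, file, eos = NULL)
  invisible(txt)
}

#' Read a consensus sequence/structure record written by
#' [write_consensus_file()]
#'
#' @param file Path to a two-line record.
#' @param notation Structure notation of the stored record.
#' @return A [consensus_structure()] object.
#' @export
read_consensus_file <- function(file, notation = c("DB", "WUSS")) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (length(lines) != 2L) {
    stop_rfam("bad_consensus_file", "expected a two-line sequence/structure record")
  }
  consensus_structure(lines[1L], lines[2L], notation = match.arg(notation))
}
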