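# Stockholm 1.0 reader/writer and alignment export formats. Rfam seed
# alignments arrive as Stockholm text with the consensus structure on the
# "#=GC SS_cons" column-annotation line; interleaved (multi-block) records are
# concatenated per row. The writer emits a single block.

#' Parse a Stockholm 1.0 alignment
#'
#' Captures sequence rows, per-column annotations (`#=GC`, including the
#' `SS_cons` consensus structure), per-row annotations (`#=GR`) and file-level
#' annotations (`#=GF`, `#=GS`). Interleaved blocks are concatenated row-wise,
#' so a multi-block record parses identically to its single-block equivalent.
#'
#' @param text Stockholm record as a single string or character vector of lines.
#' @return A [seed_alignment()] object.
#' @export
parse_stockholm <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L || !grepl("^# STOCKHOLM 1\\.0", lines[nonempty[1L]])) {
    stop_rfam("malformed_stockholm", "missing '# STOCKHOLM 1.0' header", line = 1L)
  }
  rows <- character()
  gc <- character()
  gf <- list()
  gr <- list()
  append_str <- function(store, key, value) {
    store[key] <- paste0(if (is.na(store[key])) "" else store[key], value)
    store
  }
  for (i in nonempty[-1L]) {
    line <- lines[i]
    if (grepl("^//\\s*$", line)) break
    if (startsWith(line, "#=GF")) {
      m <- regmatches(line, regexec("^#=GF\\s+(\\S+)\\s+(.*)$", line))[[1L]]
      if (length(m) != 3L) stop_rfam("malformed_stockholm", sprintf("bad #=GF line %d", i), line = i)
      gf[[m[2L]]] <- c(gf[[m[2L]]], m[3L])
    } else if (startsWith(line, "#=GS")) {
      rest <- sub("^#=GS\\s+", "", line)
      gf[["GS"]] <- c(gf[["GS"]], rest)
    } else if (startsWith(line, "#=GC")) {
      m <- regmatches(line, regexec("^#=GC\\s+(\\S+)\\s+(\\S+)\\s*$", line))[[1L]]
      if (length(m) != 3L) stop_rfam("malformed_stockholm", sprintf("bad #=GC line %d", i), line = i)
      gc <- append_str(gc, m[2L], m[3L])
    } else if (startsWith(line, "#=GR")) {
      m <- regmatches(line, regexec("^#=GR\\s+(\\S+)\\s+(\\S+)\\s+(\\S+)\\s*$", line))[[1L]]
      if (length(m) != 4L) stop_rfam("malformed_stockholm", sprintf("bad #=GR line %d", i), line = i)
      name <- m[2L]; tag <- m[3L]
      if (is.null(gr[[name]])) gr[[name]] <- character()
      gr[[name]] <- append_str(gr[[name]], tag, m[4L])
    } else if (startsWith(line, "#")) {
      next  # plain comment
    } else {
      m <- regmatches(line, regexec("^(\\S+)\\s+(\\S+)\\s*$", line))[[1L]]
      if (length(m) != 3L) {
        stop_rfam("malformed_stockholm", sprintf("unparseable line %d: '%s'", i, line),
                  line = i)
      }
      rows <- append_str(rows, m[2L], m[3L])
    }
  }
  seed_alignment(rows, column_annotations = gc, file_annotations = gf,
                 row_annotations = gr)
}

#' Write a seed alignment in one of the supported export formats
#'
#' * `stockholm`: single-block Stockholm 1.0, round-trippable by
#'   [parse_stockholm()].
#' * `pfam`: single-block Stockholm with the consensus-structure annotation
#'   rendered in extended dot-bracket instead of WUSS.
#' * `fasta`: gapped FASTA, rows verbatim.
#' * `fastau`: ungapped FASTA; both `-` and `.` count as gaps.
#'
#' @param aln A [seed_alignment()] object.
#' @param format One of `"stockholm"`, `"pfam"`, `"fasta"`, `"fastau"`.
#' @param file Optional path; if `NULL` the text is returned.
#' @return The formatted text, invisibly when written to a file.
#' @export
write_alignment <- function(aln, format = c("stockholm", "pfam", "fasta", "fastau"),
                            file = NULL) {
  stopifnot(inherits(aln, "seed_alignment"))
  format <- match.arg(format)
  txt <- switch(format,
    stockholm = format_stockholm(aln),
    pfam = {
      a2 <- aln
      if ("SS_cons" %in% names(a2$column_annotations)) {
        a2$column_annotations[["SS_cons"]] <-
          wuss_to_dotbracket(a2$column_annotations[["SS_cons"]])
      }
      format_stockholm(a2)
    },
    fasta = paste0(paste0(">", names(aln$rows), "\n", unname(aln$rows),
                          collapse = "\n"), "\n"),
    fastau = {
      ungapped <- gsub("[-.]", "", unname(aln$rows))
      paste0(paste0(">", names(aln$rows), "\n", ungapped, collapse = "\n"), "\n")
    })
  if (is.null(file)) return(txt)
  writeChar(txt, file, eos = NULL)
  invisible(txt)
}

format_stockholm <- function(aln) {
  out <- c("# STOCKHOLM 1.0", "")
  for (tag in names(aln$file_annotations)) {
    if (tag == "GS") {
      out <- c(out, paste0("#=GS ", aln$file_annotations[[tag]]))
    } else {
      out <- c(out, paste0("#=GF ", tag, " ", aln$file_annotations[[tag]]))
    }
  }
  labels <- names(aln$rows)
  gr_labels <- unlist(lapply(names(aln$row_annotations), function(nm) {
    paste0("#=GR ", nm, " ", names(aln$row_annotations[[nm]]))
  }))
  gc_labels <- if (length(aln$column_annotations)) {
    paste0("#=GC ", names(aln$column_annotations))
  } else character()
  width <- max(nchar(c(labels, gr_labels, gc_labels))) + 2L
  pad <- function(x) formatC(x, width = -width)
  for (nm in labels) {
    out <- c(out, paste0(pad(nm), aln$rows[[nm]]))
    for (tag in names(aln$row_annotations[[nm]])) {
      out <- c(out, paste0(pad(paste0("#=GR ", nm, " ", tag)),
                           aln$row_annotations[[nm]][[tag]]))
    }
  }
  for (tag in names(aln$column_annotations)) {
    out <- c(out, paste0(pad(paste0("#=GC ", tag)), aln$column_annotations[[tag]]))
  }
  paste0(paste(c(out, "//"), collapse = "\n"), "\n")
}
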