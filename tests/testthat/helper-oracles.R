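# Independent oracles used to check the implementation from a second route.

# Pair set of a structure string via one explicit stack per bracket family.
# Returns a sorted "i-j" character vector (or NULL on unbalanced input).
oracle_pair_set <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  open_of <- c(">" = "<", ")" = "(", "]" = "[", "}" = "{",
               stats::setNames(LETTERS, letters))
  openers <- c("<", "(", "[", "{", LETTERS)
  stacks <- list()
  pairs <- character()
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% openers) {
      stacks[[ch]] <- c(stacks[[ch]], i)
    } else if (ch %in% names(open_of)) {
      op <- open_of[[ch]]
      st <- stacks[[op]]
      if (is.null(st) || length(st) == 0L) return(NULL)
      pairs <- c(pairs, paste0(st[length(st)], "-", i))
      stacks[[op]] <- st[-length(st)]
    }
  }
  if (any(vapply(stacks, length, 1L) > 0L)) return(NULL)
  sort(pairs)
}

# Random balanced WUSS string of roughly n symbols.
random_wuss <- function(n) {
  unpaired <- c(".", ":", "_", "-", "~", ",")
  fams <- list(c("<", ">"), c("(", ")"), c("[", "]"), c("{", "}"),
               c("A", "a"), c("B", "b"))
  gen <- function(k) {
    if (k <= 0L) return("")
    if (k == 1L || stats::runif(1) < 0.45) {
      return(paste0(sample(unpaired, 1L), gen(k - 1L)))
    }
    fam <- fams[[sample.int(length(fams), 1L)]]
    inner <- sample.int(k - 1L, 1L) - 1L
    paste0(fam[1L], gen(inner), fam[2L], gen(k - 2L - inner))
  }
  gen(n)
}

# Greedy clan competition, re-derived with the "keep best remaining, discard
# its competitors, repeat" formulation (a different shape from the package's
# rank-walk) for cross-checking.
oracle_clan_filter <- function(hits, clans, threshold) {
  df <- as.data.frame(hits)
  df$.clan <- unname(clans[df$rfam_accession])
  remaining <- df[order(df$e_value, -df$bit_score, df$rfam_accession,
                        df$query_start, df$query_end), , drop = FALSE]
  kept <- remaining[0, , drop = FALSE]
  while (nrow(remaining) > 0L) {
    top <- remaining[1L, , drop = FALSE]
    kept <- rbind(kept, top)
    remaining <- remaining[-1L, , drop = FALSE]
    if (!is.na(top$.clan) && nrow(remaining) > 0L) {
      frac <- vapply(seq_len(nrow(remaining)), function(k) {
        r <- remaining[k, ]
        if (is.na(r$.clan) || r$.clan != top$.clan || r$strand != top$strand) {
          return(0)
        }
        ov <- max(0L, min(r$query_end, top$query_end) -
                      max(r$query_start, top$query_start) + 1L)
        ov / min(r$query_end - r$query_start + 1L,
                 top$query_end - top$query_start + 1L)
      }, 0)
      remaining <- remaining[frac < threshold, , drop = FALSE]
    }
  }
  kept <- kept[order(kept$query_start, kept$query_end, kept$rfam_accession), ]
  kept$.clan <- NULL
  rownames(kept) <- NULL
  kept
}

# Random hit table for clan-filter property tests; e-value/bit-score ties are
# common on purpose so every tie-break level gets exercised.
random_hit_instance <- function(n_max = 8L) {
  n <- sample(2:n_max, 1L)
  accs <- sample(sprintf("RF0%04d", sample(1000:1099, n)))
  starts <- sample.int(400L, n, replace = TRUE)
  lens <- sample(20:150, n, replace = TRUE)
  hits <- rfam_hits(
    rfam_accession = accs,
    rfam_id = paste0("fam_", accs),
    query_start = starts,
    query_end = starts + lens - 1L,
    strand = sample(c("plus", "plus", "plus", "minus"), n, replace = TRUE),
    bit_score = sample(c(25, 50, 75, 100), n, replace = TRUE),
    e_value = 10^sample(-12:-2, n, replace = TRUE))
  clan_pool <- c("CLX", "CLY", NA, NA)
  clans <- stats::setNames(sample(clan_pool, n, replace = TRUE), accs)
  clans <- clans[!is.na(clans)]
  list(hits = hits, clans = clans)
}

# Reconstruct a parent sequence from its fragments, dropping each fragment's
# prefix that was already covered by its predecessor.
reconstruct_from_fragments <- function(fragments) {
  covered <- 0L
  paste(vapply(fragments, function(f) {
    keep_from <- max(f$parent_start, covered + 1L) - f$parent_start + 1L
    covered <<- f$parent_end
    substr(f$residues, keep_from, nchar(f$residues))
  }, ""), collapse = "")
}

# Random seed alignment for Stockholm round-trip tests.
random_alignment <- function(max_rows = 20L, max_width = 200L) {
  n <- sample.int(max_rows, 1L)
  width <- sample.int(max_width, 1L)
  gap_density <- stats::runif(1, 0, 0.5)
  rows <- vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "U"), width, replace = TRUE)
    gaps <- stats::runif(width) < gap_density
    chars[gaps] <- sample(c("-", "."), sum(gaps), replace = TRUE)
    paste(chars, collapse = "")
  }, "")
  names(rows) <- sprintf("seq%03d/%d-%d", seq_len(n), 1L, width)
  gc <- character()
  if (stats::runif(1) < 0.8) {
    gc <- c(SS_cons = paste(sample(c(".", "<", ">", "-", ","), width, TRUE),
                            collapse = ""))
  }
  gf <- list()
  if (stats::runif(1) < 0.5) gf <- list(AC = "RF99001", ID = "random_family")
  gr <- list()
  if (stats::runif(1) < 0.3) {
    gr[[names(rows)[1L]]] <- c(PP = paste(sample(c("*", "9", "8"), width, TRUE),
                                          collapse = ""))
  }
  seed_alignment(rows, column_annotations = gc, file_annotations = gf,
                 row_annotations = gr)
}
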