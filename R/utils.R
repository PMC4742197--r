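#' @importFrom rlang %||% abort warn inform
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dfr map_chr map_int map_dbl map_lgl pmap imap walk
NULL

# reverse complement for plain character vectors (ACGT only)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains characters outside {A,C,G,T}: %s",
                  what, substr(x[bad][1], 1, 40)),
          class = "racescreen_alphabet_error")
  }
  invisible(x)
}

# write a file atomically: write to a temp sibling, then rename
atomic_write <- function(writer, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

# normalise read input: pair tibble (read_id, seq1, seq2[, qual1, qual2]) or
# single-sequence tibble (read_id, seq) -> long tibble (read_id, mate, seq)
reads_long <- function(reads) {
  if (all(c("seq1", "seq2") %in% names(reads))) {
    bind_rows(
      tibble(read_id = reads$read_id, mate = 1L, seq = reads$seq1),
      tibble(read_id = reads$read_id, mate = 2L, seq = reads$seq2)
    )
  } else if ("seq" %in% names(reads)) {
    tibble(read_id = reads$read_id, mate = 1L, seq = reads$seq)
  } else {
    abort("reads must have columns seq1/seq2 or seq")
  }
}

count_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}
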