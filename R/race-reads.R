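#' Trim the 5' RACE adapter from read pairs
#'
#' During RACE cDNA synthesis a template-switch oligo leaves a fixed adapter
#' at the 5' end of every amplicon, so reads that start at (or near) the
#' amplicon 5' end begin with a suffix of the adapter. For each mate, the
#' longest read prefix matching a suffix (or the whole) of the adapter with
#' at least `min_overlap` aligned bases and a mismatch rate at most
#' `max_mismatch_rate` is removed, together with the corresponding quality
#' bases; reads without such a prefix are untouched.
#'
#' @param pairs tibble of read pairs: `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (quality columns optional).
#' @param adapter adapter sequence (non-empty, A/C/G/T).
#' @param min_overlap minimum aligned bases (default 5).
#' @param max_mismatch_rate maximum fraction of mismatching bases in the
#'   alignment (default 0.1).
#' @return the pair tibble with trimmed sequences/qualities, plus columns
#'   `trimmed1`, `trimmed2` giving the number of bases removed per mate.
#' @export
trim_adapter <- function(pairs, adapter, min_overlap = 5L, max_mismatch_rate = 0.1) {
  if (!nzchar(adapter)) abort("adapter must be non-empty", class = "racescreen_parameter_error")
  assert_dna(adapter, "adapter")
  out <- pairs
  for (mate in 1:2) {
    seq_col <- paste0("seq", mate)
    qual_col <- paste0("qual", mate)
    if (!seq_col %in% names(pairs)) next
    ntrim <- adapter_prefix_len(pairs[[seq_col]], adapter, min_overlap, max_mismatch_rate)
    out[[seq_col]] <- substr(pairs[[seq_col]], ntrim + 1L, nchar(pairs[[seq_col]]))
    if (qual_col %in% names(pairs)) {
      out[[qual_col]] <- substr(pairs[[qual_col]], ntrim + 1L, nchar(pairs[[qual_col]]))
    }
    out[[paste0("trimmed", mate)]] <- ntrim
  }
  out
}

# vectorised: for each sequence, the longest L in [min_overlap, len(adapter)]
# such that the last L adapter bases match the first L read bases within the
# mismatch budget; 0 when none qualifies
adapter_prefix_len <- function(seqs, adapter, min_overlap, max_mismatch_rate) {
  na <- nchar(adapter)
  if (length(seqs) == 0L) return(integer(0))
  width <- min(na, max(nchar(seqs)))
  # char matrix of read prefixes, padded with a sentinel
  pref <- substr(seqs, 1L, width)
  mat <- matrix("", nrow = length(seqs), ncol = width)
  spl <- strsplit(pref, "", fixed = TRUE)
  for (i in seq_along(spl)) {
    v <- spl[[i]]
    if (length(v)) mat[i, seq_along(v)] <- v
  }
  achars <- strsplit(adapter, "", fixed = TRUE)[[1]]
  best <- integer(length(seqs))
  for (L in seq(min(width, na), min_overlap)) {
    if (L < min_overlap) break
    suffix <- achars[(na - L + 1L):na]
    cmp <- mat[, seq_len(L), drop = FALSE] != matrix(suffix, nrow = length(seqs),
                                                    ncol = L, byrow = TRUE)
    # a padded (too-short) read cannot align over L bases
    too_short <- nchar(seqs) < L
    mism <- rowSums(cmp)
    ok <- !too_short & (mism / L) <= max_mismatch_rate & best == 0L
    best[ok] <- L
  }
  best
}

#' Retrieve reads carrying part of a nested gene-specific primer
#'
#' Emulates a grep-based rescue of chimeric reads: returns every read that
#' contains an exact occurrence of any substring of the NGSP of length at
#' least `min_match_len`, in either orientation. Reads anchored this way
#' originate from the RACE amplicon of the targeted gene and can be split-
#' mapped to reveal an upstream fusion partner.
#'
#' @param reads pair tibble (`read_id`, `seq1`, `seq2`) or single-sequence
#'   tibble (`read_id`, `seq`).
#' @param ngsp nested gene-specific primer sequence.
#' @param min_match_len minimum exact match length (default 15); must not
#'   exceed the primer length.
#' @return tibble of matching reads: `read_id`, `mate`, `position` (1-based
#'   start of the best match in the read), `match_len`, `orientation`
#'   (`"forward"` = primer strand, `"reverse"` = reverse complement).
#' @export
find_primer_reads <- function(reads, ngsp, min_match_len = 15L) {
  assert_dna(ngsp, "NGSP")
  if (min_match_len > nchar(ngsp)) {
    abort("min_match_len exceeds primer length", class = "racescreen_parameter_error")
  }
  long <- reads_long(reads)
  hits <- list()
  for (ori in c("forward", "reverse")) {
    pat <- if (ori == "forward") ngsp else revcomp(ngsp)
    h <- best_common_match(long$seq, pat, min_match_len)
    keep <- which(h$len > 0L)
    if (length(keep)) {
      hits[[ori]] <- tibble(read_id = long$read_id[keep], mate = long$mate[keep],
                            position = h$pos[keep], match_len = h$len[keep],
                            orientation = ori)
    }
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(read_id = character(), mate = integer(), position = integer(),
                  match_len = integer(), orientation = character()))
  }
  # one row per read/mate: longest match wins, forward preferred on ties
  out |>
    mutate(ori_rank = ifelse(.data$orientation == "forward", 0L, 1L)) |>
    arrange(desc(.data$match_len), .data$ori_rank, .data$position) |>
    distinct(.data$read_id, .data$mate, .keep_all = TRUE) |>
    select(-"ori_rank") |>
    arrange(.data$read_id, .data$mate)
}

# for each sequence, the longest exact shared substring with `pat` of length
# >= m, located by scanning all length-m windows of pat and extending
best_common_match <- function(seqs, pat, m) {
  np <- nchar(pat)
  pos <- integer(length(seqs)); len <- integer(length(seqs))
  windows <- vapply(seq_len(np - m + 1L), function(i) substr(pat, i, i + m - 1L), "")
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    where <- stringr::str_locate(seqs, stringr::fixed(w))[, "start"]
    found <- which(!is.na(where))
    for (idx in found) {
      # extend the seed match maximally in both directions
      rs <- where[idx]; re <- rs + m - 1L
      ps <- wi; pe <- wi + m - 1L
      s <- seqs[idx]
      while (rs > 1L && ps > 1L &&
             substr(s, rs - 1L, rs - 1L) == substr(pat, ps - 1L, ps - 1L)) {
        rs <- rs - 1L; ps <- ps - 1L
      }
      while (re < nchar(s) && pe < np &&
             substr(s, re + 1L, re + 1L) == substr(pat, pe + 1L, pe + 1L)) {
        re <- re + 1L; pe <- pe + 1L
      }
      if (re - rs + 1L > len[idx]) {
        len[idx] <- re - rs + 1L; pos[idx] <- rs
      }
    }
  }
  list(pos = pos, len = len)
}

#' Reference set of transcripts and gene models
#'
#' A desk-scale stand-in for a transcriptome reference: named transcript
#' sequences plus a GTF-lite exon table.
#'
#' @param transcripts named character vector of transcript sequences
#'   (names = transcript ids).
#' @param gene_models tibble with columns `gene_id`, `transcript_id`,
#'   `exon_number` (1..n in transcriptional order), `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (+1/-1).
#' @return a `reference_set`.
#' @export
reference_set <- function(transcripts, gene_models) {
  gene_models <- as_tibble(gene_models)
  stopifnot(all(c("gene_id", "transcript_id", "exon_number", "chrom",
                  "start", "end", "strand") %in% names(gene_models)))
  # exons must be non-overlapping and ordered 5'->3' within each transcript
  chk <- gene_models |>
    group_by(.data$transcript_id) |>
    arrange(.data$exon_number, .by_group = TRUE) |>
    summarise(ok = {
      s <- if (first(.data$strand) == 1L) .data$start else -.data$start
      all(diff(s) > 0)
    }, .groups = "drop")
  if (!all(chk$ok)) {
    abort(sprintf("transcript %s: exons out of 5'->3' order or overlapping",
                  chk$transcript_id[!chk$ok][1]),
          class = "racescreen_validation_error")
  }
  structure(list(transcripts = transcripts, gene_models = gene_models),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d transcripts, %d genes, %d exons\n",
              length(x$transcripts),
              length(unique(x$gene_models$gene_id)),
              nrow(x$gene_models)))
  invisible(x)
}

tx_gene_map <- function(ref) {
  ref$gene_models |> distinct(.data$transcript_id, .data$gene_id)
}

#' Exact split mapping of one read against a transcript reference
#'
#' Greedy seed-and-extend with exact matches: all maximal exact matches of
#' length >= `seed_len` between the read (both orientations) and the
#' transcripts are located, then a minimal set of non-overlapping read
#' segments covering as much of the read as possible is chosen greedily
#' (leftmost uncovered base, furthest-reaching match). A read is chimeric
#' when its cover uses transcripts of two or more different genes.
#'
#' @param read read sequence (A/C/G/T).
#' @param ref a [reference_set()].
#' @param seed_len exact seed length (default 20, minimum 11).
#' @return a `split_map` result: list with `segments` (tibble `read_start`,
#'   `read_end`, `transcript_id`, `gene_id`, `t_start`, `t_end`, `strand`),
#'   `chimeric` (logical) and `genes` (gene ids used by the cover).
#' @export
split_map <- function(read, ref, seed_len = 20L) {
  if (seed_len < 11L) abort("seed_len must be >= 11", class = "racescreen_parameter_error")
  assert_dna(read, "read")
  matches <- maximal_exact_matches(read, ref, seed_len)
  segments <- greedy_cover(matches, nchar(read))
  if (nrow(segments)) {
    segments <- left_join(segments, tx_gene_map(ref), by = "transcript_id") |>
      select("read_start", "read_end", "transcript_id", "gene_id",
             "t_start", "t_end", "strand")
  } else {
    segments <- tibble(read_start = integer(), read_end = integer(),
                       transcript_id = character(), gene_id = character(),
                       t_start = integer(), t_end = integer(), strand = character())
  }
  genes <- unique(segments$gene_id)
  structure(list(segments = segments, chimeric = length(genes) >= 2L, genes = genes),
            class = "split_map")
}

# all maximal exact matches >= seed_len between read (both orientations) and
# the reference transcripts, in read coordinates of the original read
maximal_exact_matches <- function(read, ref, seed_len) {
  n <- nchar(read)
  if (n < seed_len) {
    return(tibble(read_start = integer(), read_end = integer(),
                  transcript_id = character(), t_start = integer(),
                  t_end = integer(), strand = character()))
  }
  res <- list()
  for (ori in c("+", "-")) {
    q <- if (ori == "+") read else revcomp(read)
    starts <- seq_len(n - seed_len + 1L)
    seeds <- substring(q, starts, starts + seed_len - 1L)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
    for (tx in names(ref$transcripts)) {
      subject <- Biostrings::DNAString(ref$transcripts[[tx]])
      hits <- Biostrings::matchPDict(pd, subject)
      idx <- rep(seq_along(hits), lengths(hits))
      if (!length(idx)) next
      starts_t <- unlist(lapply(hits, BiocGenerics::start), use.names = FALSE)
      # diagonal grouping: runs of consecutive seed indices on one diagonal
      # correspond to one maximal exact match
      d <- starts_t - idx
      o <- order(d, idx)
      idx <- idx[o]; d <- d[o]; starts_t <- starts_t[o]
      run_break <- c(TRUE, diff(d) != 0 | diff(idx) != 1L)
      run_id <- cumsum(run_break)
      first_i <- tapply(idx, run_id, min)
      last_i <- tapply(idx, run_id, max)
      first_t <- tapply(starts_t, run_id, min)
      q_start <- as.integer(first_i)
      q_end <- as.integer(last_i) + seed_len - 1L
      t_start <- as.integer(first_t)
      t_end <- t_start + (q_end - q_start)
      # map back to original read coordinates for the reverse orientation
      if (ori == "+") {
        rs <- q_start; re <- q_end
      } else {
        rs <- n - q_end + 1L; re <- n - q_start + 1L
      }
      res[[length(res) + 1L]] <- tibble(
        read_start = rs, read_end = re, transcript_id = tx,
        t_start = t_start, t_end = t_end, strand = ori
      )
    }
  }
  bind_rows(res)
}

# minimal-cardinality greedy cover of [1, n] by (possibly trimmed) matches
greedy_cover <- function(matches, n) {
  if (nrow(matches) == 0L) return(matches)
  matches <- arrange(matches, .data$read_start, desc(.data$read_end))
  chosen <- list()
  pos <- 1L
  while (pos <= n) {
    cand <- filter(matches, .data$read_start <= pos, .data$read_end >= pos)
    if (nrow(cand) == 0L) {
      nxt <- filter(matches, .data$read_start > pos)
      if (nrow(nxt) == 0L) break
      pos <- min(nxt$read_start)
      next
    }
    best <- cand[which.max(cand$read_end), ]
    # trim to start at the first uncovered base, shifting transcript coords
    shift <- pos - best$read_start
    if (shift > 0L) {
      if (best$strand == "+") best$t_start <- best$t_start + shift
      else best$t_end <- best$t_end - shift
      best$read_start <- pos
    }
    chosen[[length(chosen) + 1L]] <- best
    pos <- best$read_end + 1L
  }
  bind_rows(chosen)
}

#' Split-map a whole table of read pairs
#'
#' Convenience wrapper applying [split_map()] to every mate of every pair;
#' used to build coverage tables and to identify chimeric reads in bulk.
#'
#' @inheritParams find_primer_reads
#' @param ref a [reference_set()].
#' @param seed_len exact seed length.
#' @return tibble of segments with `read_id` and `mate` columns prepended.
#' @export
split_map_reads <- function(reads, ref, seed_len = 20L) {
  long <- reads_long(reads)
  res <- pmap(long, function(read_id, mate, seq) {
    sm <- split_map(seq, ref, seed_len)
    if (nrow(sm$segments) == 0L) return(NULL)
    sm$segments |> mutate(read_id = read_id, mate = mate, .before = 1L)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) {
    out <- tibble(read_id = character(), mate = integer(), read_start = integer(),
                  read_end = integer(), transcript_id = character(),
                  gene_id = character(), t_start = integer(), t_end = integer(),
                  strand = character())
  }
  out
}

#' Build a fusion scaffold
#'
#' Concatenates the upstream partner's transcript up to its breakpoint with
#' the downstream partner's transcript from its breakpoint, producing an
#' artificial reference against which raw reads are realigned to count
#' junction-supporting evidence. Breakpoints must coincide with annotated
#' exon boundaries (fusions formed through intact splice sites).
#'
#' @param ref a [reference_set()].
#' @param gene_a,gene_b upstream / downstream partner gene ids.
#' @param break_a 1-based genomic coordinate of the last base gene A donates
#'   (the 3' end of one of its exons in transcript direction).
#' @param break_b 1-based genomic coordinate of the first base gene B
#'   contributes (the 5' end of one of its exons).
#' @param flank bases of each transcript kept around the junction (default
#'   150); clipped when a transcript is shorter.
#' @return a `fusion_scaffold`: list with `name_a`, `name_b`, `break_a`,
#'   `break_b`, `seq` and `junction_offset` (1-based position in `seq` of
#'   the last upstream base).
#' @export
build_scaffold <- function(ref, gene_a, break_a, gene_b, break_b, flank = 150L) {
  a <- transcript_break(ref, gene_a, break_a, side = "donor")
  b <- transcript_break(ref, gene_b, break_b, side = "acceptor")
  seq_a <- ref$transcripts[[a$transcript_id]]
  seq_b <- ref$transcripts[[b$transcript_id]]
  up <- substr(seq_a, max(1L, a$t_pos - flank + 1L), a$t_pos)
  down <- substr(seq_b, b$t_pos, min(nchar(seq_b), b$t_pos + flank - 1L))
  structure(
    list(name_a = gene_a, name_b = gene_b,
         break_a = break_a, break_b = break_b,
         seq = paste0(up, down),
         junction_offset = nchar(up)),
    class = "fusion_scaffold"
  )
}

#' @export
print.fusion_scaffold <- function(x, ...) {
  cat(sprintf("<fusion_scaffold> %s|%s, %d bp, junction after base %d\n",
              x$name_a, x$name_b, nchar(x$seq), x$junction_offset))
  invisible(x)
}

# locate a genomic breakpoint at an exon boundary of a gene; returns the
# transcript and the 1-based transcript coordinate of the boundary base
transcript_break <- function(ref, gene, gpos, side) {
  gm <- ref$gene_models |> filter(.data$gene_id == gene)
  if (nrow(gm) == 0L) abort(sprintf("unknown gene: %s", gene), class = "racescreen_lookup_error")
  tx <- gm$transcript_id[1]
  gm <- gm |> filter(.data$transcript_id == tx) |> arrange(.data$exon_number)
  len <- gm$end - gm$start + 1L
  cum <- cumsum(len)
  # transcript-direction boundary coordinates of each exon
  if (side == "donor") {
    bound <- ifelse(gm$strand == 1L, gm$end, gm$start)    # exon 3' end
    hit <- which(bound == gpos)
    if (!length(hit)) {
      abort(sprintf("breakpoint %d of %s is not at an exon 3' boundary (fusions use intact splice sites)",
                    gpos, gene),
            class = "racescreen_breakpoint_error")
    }
    list(transcript_id = tx, t_pos = cum[hit[1]])
  } else {
    bound <- ifelse(gm$strand == 1L, gm$start, gm$end)    # exon 5' end
    hit <- which(bound == gpos)
    if (!length(hit)) {
      abort(sprintf("breakpoint %d of %s is not at an exon 5' boundary (fusions use intact splice sites)",
                    gpos, gene),
            class = "racescreen_breakpoint_error")
    }
    list(transcript_id = tx, t_pos = cum[hit[1]] - len[hit[1]] + 1L)
  }
}

#' Count split and spanning reads on a fusion scaffold
#'
#' Realigns read pairs to the scaffold (exact matching with at most
#' `max_mismatches` substitutions, both orientations, full containment) and
#' counts distinct read ids: a split read crosses the junction with at
#' least `min_overhang` aligned bases on each side; a spanning pair has one
#' mate entirely on each side of the junction with neither mate touching
#' it.
#'
#' @param pairs pair tibble (`read_id`, `seq1`, `seq2`).
#' @param scaffold a [build_scaffold()] result.
#' @param min_overhang minimum bases on each side of the junction for a
#'   split read (default 10).
#' @param max_mismatches substitution budget per aligned mate (default 0).
#' @return one-row tibble `split_reads`, `spanning_pairs`; attribute
#'   `detail` holds the per-mate alignment classification.
#' @export
count_junction_reads <- function(pairs, scaffold, min_overhang = 10L,
                                 max_mismatches = 0L) {
  stopifnot(min_overhang >= 1L)
  jo <- scaffold$junction_offset
  subject <- Biostrings::DNAString(scaffold$seq)
  long <- reads_long(pairs)
  if (nrow(long) == 0L) {
    out <- tibble(split_reads = 0L, spanning_pairs = 0L)
    attr(out, "detail") <- tibble()
    return(out)
  }
  cls <- pmap(long, function(read_id, mate, seq) {
    al <- align_contained(seq, subject, max_mismatches)
    if (is.null(al)) {
      return(tibble(read_id = read_id, mate = mate, aligned = FALSE,
                    crossing_any = FALSE, crossing_split = FALSE,
                    side = NA_character_))
    }
    a <- al$start; b <- al$end
    crossing_any <- a <= jo && b > jo
    crossing_split <- (jo - a + 1L) >= min_overhang && (b - jo) >= min_overhang
    side <- if (b <= jo) "upstream" else if (a > jo) "downstream" else "crossing"
    tibble(read_id = read_id, mate = mate, aligned = TRUE,
           crossing_any = crossing_any, crossing_split = crossing_split,
           side = side)
  }) |> bind_rows()

  split_ids <- unique(cls$read_id[cls$crossing_split])
  span <- cls |>
    filter(.data$aligned) |>
    group_by(.data$read_id) |>
    summarise(
      one_each = n() == 2L && setequal(.data$side, c("upstream", "downstream")),
      any_cross = any(.data$crossing_any),
      .groups = "drop"
    )
  spanning_ids <- span$read_id[span$one_each & !span$any_cross]
  out <- tibble(split_reads = length(split_ids),
                spanning_pairs = length(spanning_ids))
  attr(out, "detail") <- cls
  out
}

# best full-containment alignment of `seq` (either orientation) in subject
# with at most max_mismatches substitutions; NULL when none
align_contained <- function(seq, subject, max_mismatches) {
  for (ori in c("+", "-")) {
    q <- if (ori == "+") seq else revcomp(seq)
    if (nchar(q) > length(subject)) next
    m <- Biostrings::matchPattern(q, subject, max.mismatch = max_mismatches,
                                  with.indels = FALSE)
    if (length(m) > 0L) {
      return(list(start = BiocGenerics::start(m)[1], end = BiocGenerics::end(m)[1],
                  strand = ori))
    }
  }
  NULL
}

#' Junction k-mer search at multiple half-lengths
#'
#' For each half-length `h`, counts reads containing the exact `2h`-mer
#' centered on the scaffold junction (either orientation) -- a grep-style
#' in-silico validation of a fusion junction. Longer spanning k-mers are
#' nested in shorter ones, so counts are non-increasing in `h`.
#'
#' @param reads pair or single-sequence read tibble.
#' @param scaffold a [build_scaffold()] result.
#' @param half_lengths bases taken on each side of the junction (default
#'   `c(8, 10, 15, 20, 24)`); each must fit within the scaffold flanks.
#' @return tibble `half_length`, `kmer`, `n_reads` (distinct read ids).
#' @export
scaffold_kmer_search <- function(reads, scaffold, half_lengths = c(8L, 10L, 15L, 20L, 24L)) {
  jo <- scaffold$junction_offset
  avail_left <- jo
  avail_right <- nchar(scaffold$seq) - jo
  if (any(half_lengths > avail_left | half_lengths > avail_right)) {
    abort(sprintf("half-length exceeds available flank (%d left / %d right)",
                  avail_left, avail_right),
          class = "racescreen_parameter_error")
  }
  long <- reads_long(reads)
  map_dfr(sort(half_lengths), function(h) {
    kmer <- substr(scaffold$seq, jo - h + 1L, jo + h)
    hit <- stringr::str_detect(long$seq, stringr::fixed(kmer)) |
      stringr::str_detect(long$seq, stringr::fixed(revcomp(kmer)))
    tibble(half_length = h, kmer = kmer,
           n_reads = length(unique(long$read_id[hit])))
  })
}

#' Exon coverage and normalized gene counts
#'
#' Summarises split-map segments into per-exon read counts and RPK (reads
#' per kilobase of exon sequence), plus per-gene raw and size-factor
#' normalized counts. Each read is attributed through its leftmost segment
#' and counts once per exon it overlaps by at least one base, and once per
#' gene. When segments carry a `sample_id` column, gene counts are computed
#' per sample and normalized with median-of-ratios size factors (see
#' [size_factors()]).
#'
#' @param segments segment tibble from [split_map_reads()] (optionally with
#'   a `sample_id` column).
#' @param gene_models exon table as in [reference_set()].
#' @return a `coverage_table`: list with `exons` (per-exon `count`, `rpk`),
#'   `genes` (per-gene, per-sample `count`, `norm_count`) and
#'   `size_factors`.
#' @export
exon_coverage <- function(segments, gene_models) {
  gm <- as_tibble(gene_models) |> arrange(.data$transcript_id, .data$exon_number)
  segs <- as_tibble(segments)
  if (!"sample_id" %in% names(segs)) segs$sample_id <- "sample1"
  # leftmost segment per read (smallest read_start; mate 1 preferred)
  left <- segs |>
    arrange(.data$read_id, .data$mate, .data$read_start) |>
    group_by(.data$read_id) |>
    slice_head(n = 1L) |>
    ungroup()

  # transcript coordinate span of each exon
  exon_spans <- gm |>
    group_by(.data$transcript_id) |>
    arrange(.data$exon_number, .by_group = TRUE) |>
    mutate(exon_len = .data$end - .data$start + 1L,
           t_end = cumsum(.data$exon_len),
           t_start = .data$t_end - .data$exon_len + 1L) |>
    ungroup()

  ov <- left |>
    inner_join(exon_spans, by = "transcript_id", suffix = c("", ".ex"),
               relationship = "many-to-many") |>
    filter(.data$t_start <= .data$t_end.ex, .data$t_end >= .data$t_start.ex)

  exons <- ov |>
    group_by(.data$gene_id, .data$transcript_id, .data$exon_number,
             .data$exon_len, .data$sample_id) |>
    summarise(count = n_distinct(.data$read_id), .groups = "drop") |>
    mutate(rpk = .data$count / (.data$exon_len / 1000))
  # include uncovered exons at zero
  all_ex <- exon_spans |>
    select("gene_id", "transcript_id", "exon_number", "exon_len") |>
    tidyr::crossing(sample_id = unique(segs$sample_id))
  exons <- all_ex |>
    left_join(exons, by = c("gene_id", "transcript_id", "exon_number",
                            "exon_len", "sample_id")) |>
    mutate(count = coalesce(.data$count, 0L),
           rpk = coalesce(.data$rpk, 0)) |>
    arrange(.data$gene_id, .data$exon_number, .data$sample_id)

  genes <- ov |>
    distinct(.data$gene_id, .data$sample_id, .data$read_id) |>
    count(.data$gene_id, .data$sample_id, name = "count") |>
    tidyr::complete(gene_id = unique(gm$gene_id),
                    sample_id = unique(segs$sample_id),
                    fill = list(count = 0L))

  cnt <- genes |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count") |>
    tibble::column_to_rownames("gene_id") |>
    as.matrix()
  sf <- size_factors(cnt)
  genes <- genes |>
    left_join(tibble(sample_id = names(sf), size_factor = unname(sf)),
              by = "sample_id") |>
    mutate(norm_count = .data$count / .data$size_factor)

  structure(list(exons = exons, genes = genes,
                 size_factors = tibble(sample_id = names(sf), size_factor = unname(sf))),
            class = "coverage_table")
}

#' @export
print.coverage_table <- function(x, ...) {
  cat(sprintf("<coverage_table> %d exons x %d samples, %d genes\n",
              length(unique(paste(x$exons$transcript_id, x$exons$exon_number))),
              length(unique(x$exons$sample_id)),
              length(unique(x$genes$gene_id))))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For a genes x samples count matrix, each sample's size factor is the
#' median across genes of its counts divided by the gene's geometric mean
#' over samples; genes with a zero count in any sample are excluded from
#' the median. Samples with proportional counts get proportional factors,
#' making normalized counts comparable across libraries of different depth.
#'
#' @param counts numeric matrix, genes in rows, samples in columns.
#' @return named numeric vector of size factors (NA when no gene usable).
#' @export
size_factors <- function(counts) {
  usable <- apply(counts, 1L, function(r) all(r > 0))
  if (!any(usable)) {
    return(stats::setNames(rep(NA_real_, ncol(counts)), colnames(counts)))
  }
  sub <- counts[usable, , drop = FALSE]
  log_gm <- rowMeans(log(sub))
  apply(sub, 2L, function(cs) exp(stats::median(log(cs) - log_gm)))
}
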