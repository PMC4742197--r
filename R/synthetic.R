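#' Default 5' template-switch adapter used by the read simulator
#'
#' The real template-switch oligo of RACE cDNA synthesis kits is
#' proprietary; the simulator ships a fixed, documented 30-mer stand-in
#' with no internal repeats. Any analysis of simulated reads must be given
#' the same adapter.
#'
#' @export
default_adapter <- function() "AAGCAGTGGTATCAACGCAGAGTACGCGGG"

#' Cohort simulation configuration
#'
#' Study conditions for the expression-cohort simulator: a cohort of tumor
#' and normal samples measured on per-gene probe-set ladders, with Gaussian
#' probe-set baselines and log2-scale Gaussian noise, and a list of planted
#' sample-specific expression steps ("breaks"). Defaults mirror the
#' screening conditions the package's recovery tests use: 100 tumors + 10
#' normals, 200 genes of 8 probe sets, noise SD 1.
#'
#' @param n_tumor,n_normal cohort sizes.
#' @param genes tibble `gene_id`, `n_probesets`, `strand`; default 200
#'   genes x 8 probe sets, alternating strand.
#' @param noise_sd per-measurement Gaussian noise SD (log2 units).
#' @param baseline_sd SD of per-probe-set baseline levels around 8.
#' @param breaks tibble `gene_id`, `sample_id`, `breakpoint_index`,
#'   `delta`: in the named sample, `delta` log2 units are added to every
#'   probe set 3' of the breakpoint. Negative `delta` plants a 5'-up
#'   profile.
#' @param seed RNG seed.
#' @export
cohort_config <- function(n_tumor = 100L, n_normal = 10L,
                          genes = NULL, noise_sd = 1, baseline_sd = 1,
                          breaks = NULL, seed = 1L) {
  if (is.null(genes)) {
    genes <- tibble(gene_id = sprintf("G%03d", 1:200),
                    n_probesets = 8L,
                    strand = rep(c(1L, -1L), length.out = 200))
  }
  if (is.null(breaks)) breaks <- tibble(gene_id = character(), sample_id = character(),
                                        breakpoint_index = integer(), delta = numeric())
  bad <- anti_join(breaks, genes, by = "gene_id")
  if (nrow(bad)) {
    abort(sprintf("break references unknown gene: %s", bad$gene_id[1]),
          class = "racescreen_config_error")
  }
  k <- genes$n_probesets[match(breaks$gene_id, genes$gene_id)]
  if (any(breaks$breakpoint_index >= k | breaks$breakpoint_index < 1L)) {
    abort("break index must lie strictly inside the gene's probe-set ladder",
          class = "racescreen_config_error")
  }
  structure(list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                 genes = as_tibble(genes), noise_sd = noise_sd,
                 baseline_sd = baseline_sd, breaks = as_tibble(breaks),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Standard planted-break set for the default cohort
#'
#' Ten 3'-up steps of `delta` log2 units, one per gene G001..G010, each in
#' a different tumor sample, with the break after probe set 4 of 8.
#'
#' @param delta step height (default 3).
#' @export
default_breaks <- function(delta = 3) {
  tibble(gene_id = sprintf("G%03d", 1:10),
         sample_id = sprintf("Sample%d_T", 1:10),
         breakpoint_index = 4L,
         delta = delta)
}

#' Simulate an exon-level expression cohort
#'
#' Generates `p[i,j] = baseline[j] + noise`, with baselines ~ N(8,
#' `baseline_sd`) and noise ~ N(0, `noise_sd`), then adds each planted
#' break's `delta` to the probe sets 3' of its breakpoint in its sample.
#' Probe sets are laid out on toy chromosomes with strand-consistent
#' coordinates. Deterministic given `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth` (the
#'   planted break table).
#' @export
simulate_expression_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  withr::with_seed(cfg$seed, {
    samples <- tibble(
      sample_id = c(sprintf("Sample%d_T", seq_len(cfg$n_tumor)),
                    sprintf("Normal%d_N", seq_len(cfg$n_normal))),
      class = c(rep("tumor", cfg$n_tumor), rep("normal", cfg$n_normal))
    )
    bad_s <- setdiff(cfg$breaks$sample_id, samples$sample_id)
    if (length(bad_s)) {
      abort(sprintf("break references unknown sample: %s", bad_s[1]),
            class = "racescreen_config_error")
    }
    probesets <- cfg$genes |>
      mutate(chrom = paste0("chr", (row_number() - 1L) %% 22L + 1L),
             gstart = 1e6 + (row_number() - 1L) * 1e5) |>
      pmap(function(gene_id, n_probesets, strand, chrom, gstart) {
        idx <- seq_len(n_probesets)
        # genomic order ascending; order_index follows strand
        starts <- gstart + (idx - 1L) * 1000L
        oi <- if (strand == 1L) idx else rev(idx)
        tibble(probeset_id = sprintf("%s_ps%02d", gene_id, idx),
               gene_id = gene_id, chrom = chrom, strand = strand,
               start = starts, end = starts + 99L,
               order_index = oi)
      }) |> bind_rows()
    n_s <- nrow(samples); n_p <- nrow(probesets)
    baseline <- stats::rnorm(n_p, mean = 8, sd = cfg$baseline_sd)
    values <- matrix(stats::rnorm(n_s * n_p, sd = cfg$noise_sd), n_s, n_p) +
      matrix(baseline, n_s, n_p, byrow = TRUE)
    rownames(values) <- samples$sample_id
    colnames(values) <- probesets$probeset_id
    for (r in seq_len(nrow(cfg$breaks))) {
      br <- cfg$breaks[r, ]
      ps <- probesets |>
        filter(.data$gene_id == br$gene_id, .data$order_index > br$breakpoint_index)
      values[br$sample_id, ps$probeset_id] <-
        values[br$sample_id, ps$probeset_id] + br$delta
    }
    list(matrix = expression_matrix(values, samples, probesets),
         truth = cfg$breaks)
  })
}

#' Simulate a toy transcriptome reference
#'
#' Random multi-exon genes on a single toy chromosome, alternating strand,
#' with globally unique 20-mers across transcripts (both orientations) so
#' exact seed matching is unambiguous. Rejection-samples duplicated k-mers
#' with a bounded number of retries.
#'
#' @param n_genes,exons_per_gene,exon_len,intergenic_len,intron_len layout
#'   parameters (defaults 10 genes x 6 exons x 120 bp).
#' @param seed RNG seed.
#' @param max_retries regenerations allowed before giving up.
#' @return a [reference_set()].
#' @export
simulate_reference <- function(n_genes = 10L, exons_per_gene = 6L, exon_len = 120L,
                               intergenic_len = 500L, intron_len = 100L,
                               seed = 1L, max_retries = 20L) {
  withr::with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      genes <- sprintf("GENE%02d", seq_len(n_genes))
      strands <- rep(c(1L, -1L), length.out = n_genes)
      tx_seqs <- list(); gm <- list()
      gpos <- 1L
      for (gi in seq_len(n_genes)) {
        exons <- replicate(exons_per_gene,
                           paste(sample(c("A", "C", "G", "T"), exon_len, replace = TRUE),
                                 collapse = ""))
        tx_seqs[[paste0("TX_", genes[gi])]] <- paste(exons, collapse = "")
        # genomic layout: exons left to right; exon_number follows strand
        ex_starts <- gpos + (seq_len(exons_per_gene) - 1L) * (exon_len + intron_len)
        exon_number <- if (strands[gi] == 1L) seq_len(exons_per_gene) else rev(seq_len(exons_per_gene))
        gm[[gi]] <- tibble(gene_id = genes[gi], transcript_id = paste0("TX_", genes[gi]),
                           exon_number = exon_number, chrom = "chrT",
                           start = ex_starts, end = ex_starts + exon_len - 1L,
                           strand = strands[gi])
        gpos <- max(gm[[gi]]$end) + intergenic_len
      }
      gm <- bind_rows(gm) |> arrange(.data$gene_id, .data$exon_number)
      seqs <- unlist(tx_seqs)
      kmers <- unlist(lapply(c(seqs, revcomp(seqs)), function(s) {
        n <- nchar(s)
        substring(s, 1:(n - 19L), 20:n)
      }))
      if (!anyDuplicated(kmers)) {
        # exon sequence lookup follows transcript order, not genomic order
        return(reference_set(seqs, gm))
      }
    }
    abort("could not generate a reference with unique 20-mers",
          class = "racescreen_generation_error")
  })
}

# sequence of one exon, extracted from the transcript by cumulative length
exon_seq <- function(ref, gene, exon_number) {
  gm <- ref$gene_models |> filter(.data$gene_id == gene) |> arrange(.data$exon_number)
  if (nrow(gm) == 0L) abort(sprintf("unknown gene: %s", gene), class = "racescreen_lookup_error")
  if (!exon_number %in% gm$exon_number) {
    abort(sprintf("gene %s has no exon %d", gene, exon_number),
          class = "racescreen_lookup_error")
  }
  len <- gm$end - gm$start + 1L
  cum <- cumsum(len)
  e <- which(gm$exon_number == exon_number)
  substr(ref$transcripts[[gm$transcript_id[1]]], cum[e] - len[e] + 1L, cum[e])
}

#' Plant a fusion transcript in a toy reference
#'
#' Joins exons 1..`last_exon_a` of the upstream gene to exons
#' `first_exon_b`..end of the downstream gene through intact exon
#' boundaries, and records the ground truth needed to build and check the
#' matching fusion scaffold.
#'
#' @param ref a [reference_set()].
#' @param gene_a,last_exon_a upstream partner and its last donated exon.
#' @param gene_b,first_exon_b downstream partner and its first contributed
#'   exon.
#' @return a `planted_fusion`: list with `fusion_id`, `seq`,
#'   `junction_pos` (last upstream base, 1-based in `seq`), genomic
#'   breakpoints `break_a`, `break_b`, and the partner gene ids.
#' @export
plant_fusion <- function(ref, gene_a, last_exon_a, gene_b, first_exon_b) {
  gma <- ref$gene_models |> filter(.data$gene_id == gene_a) |> arrange(.data$exon_number)
  gmb <- ref$gene_models |> filter(.data$gene_id == gene_b) |> arrange(.data$exon_number)
  if (last_exon_a < 1L || last_exon_a > nrow(gma)) {
    abort(sprintf("invalid exon index %d for gene %s", last_exon_a, gene_a),
          class = "racescreen_config_error")
  }
  if (first_exon_b < 1L || first_exon_b > nrow(gmb)) {
    abort(sprintf("invalid exon index %d for gene %s", first_exon_b, gene_b),
          class = "racescreen_config_error")
  }
  up <- paste(vapply(seq_len(last_exon_a), function(e) exon_seq(ref, gene_a, e), ""),
              collapse = "")
  down <- paste(vapply(seq(first_exon_b, nrow(gmb)),
                       function(e) exon_seq(ref, gene_b, e), ""),
                collapse = "")
  ex_a <- gma[gma$exon_number == last_exon_a, ]
  ex_b <- gmb[gmb$exon_number == first_exon_b, ]
  structure(
    list(fusion_id = paste0("FUS_", gene_a, "_", gene_b),
         gene_a = gene_a, gene_b = gene_b,
         last_exon_a = last_exon_a, first_exon_b = first_exon_b,
         seq = paste0(up, down),
         junction_pos = nchar(up),
         break_a = if (ex_a$strand == 1L) ex_a$end else ex_a$start,
         break_b = if (ex_b$strand == 1L) ex_b$start else ex_b$end),
    class = "planted_fusion"
  )
}

#' Simulate RACE-seq read pairs from amplicons
#'
#' Models the RACE-seq library: each source transcript yields an amplicon
#' consisting of the 5' template-switch adapter followed by the transcript
#' prefix ending at the nested primer (NGSP) site; tagmentation-style
#' fragmentation draws fragments uniformly along the amplicon with
#' Gaussian lengths; paired `read_len` reads are taken from the fragment
#' ends (mate 2 reverse-complemented) with per-base substitution errors.
#' Truth labels record, per mate, junction-crossing status and overhang,
#' adapter content and NGSP-site overlap.
#'
#' @param transcripts tibble `name`, `seq`, `abundance`, and optional
#'   `junction_pos` (1-based transcript coordinate of the last upstream
#'   base for fusion transcripts, NA otherwise).
#' @param ngsp nested gene-specific primer (reverse primer; its reverse
#'   complement must occur in at least one transcript).
#' @param n_pairs number of read pairs.
#' @param read_len,insert_mean,insert_sd read and fragment-length model.
#' @param adapter 5' adapter sequence (default [default_adapter()]).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return list with `pairs` (tibble `read_id`, `seq1`, `qual1`, `seq2`,
#'   `qual2`) and `truth` (per-pair labels).
#' @export
simulate_race_reads <- function(transcripts, ngsp, n_pairs, read_len = 150L,
                                insert_mean = 300L, insert_sd = 60L,
                                adapter = default_adapter(), error_rate = 0,
                                seed = 1L) {
  transcripts <- as_tibble(transcripts)
  if (!"junction_pos" %in% names(transcripts)) transcripts$junction_pos <- NA_integer_
  site <- revcomp(ngsp)
  amp <- transcripts |>
    mutate(site_end = stringr::str_locate(.data$seq, stringr::fixed(site))[, "end"]) |>
    filter(!is.na(.data$site_end)) |>
    mutate(amplicon = paste0(adapter, substr(.data$seq, 1L, .data$site_end)),
           amp_len = nchar(.data$amplicon),
           amp_junction = ifelse(is.na(.data$junction_pos), NA_integer_,
                                 nchar(adapter) + .data$junction_pos))
  if (nrow(amp) == 0L) {
    abort("NGSP site absent from every transcript", class = "racescreen_assay_error")
  }
  empty <- list(
    pairs = tibble(read_id = character(), seq1 = character(), qual1 = character(),
                   seq2 = character(), qual2 = character()),
    truth = tibble(read_id = character(), source = character(),
                   frag_start = integer(), frag_end = integer(),
                   crossing1 = logical(), overhang1 = integer(),
                   crossing2 = logical(), overhang2 = integer(),
                   adapter_bases1 = integer(), primer_overlap2 = integer())
  )
  if (n_pairs == 0L) return(empty)
  withr::with_seed(seed, {
    src <- sample(nrow(amp), n_pairs, replace = TRUE, prob = amp$abundance)
    frag_len <- pmax(25L, pmin(amp$amp_len[src],
                               as.integer(round(stats::rnorm(n_pairs, insert_mean, insert_sd)))))
    frag_start <- map_int(seq_len(n_pairs), function(i) {
      sample.int(amp$amp_len[src[i]] - frag_len[i] + 1L, 1L)
    })
    frag_end <- frag_start + frag_len - 1L
    l1 <- pmin(read_len, frag_len)
    l2 <- pmin(read_len, frag_len)
    frag <- substring(amp$amplicon[src], frag_start, frag_end)
    seq1 <- substr(frag, 1L, l1)
    seq2 <- revcomp(substring(frag, frag_len - l2 + 1L, frag_len))
    if (error_rate > 0) {
      seq1 <- add_errors(seq1, error_rate)
      seq2 <- add_errors(seq2, error_rate)
    }
    jo <- amp$amp_junction[src]
    m1_start <- frag_start; m1_end <- frag_start + l1 - 1L
    m2_start <- frag_end - l2 + 1L; m2_end <- frag_end
    overhang <- function(a, b) {
      oh <- pmin(jo - a + 1L, b - jo)
      ifelse(is.na(jo) | oh < 1L, 0L, as.integer(oh))
    }
    adapter_len <- nchar(adapter)
    site_start <- amp$amp_len[src] - nchar(ngsp) + 1L
    read_id <- sprintf("read%06d", seq_len(n_pairs))
    pairs <- tibble(read_id = read_id,
                    seq1 = seq1, qual1 = strrep("I", nchar(seq1)),
                    seq2 = seq2, qual2 = strrep("I", nchar(seq2)))
    truth <- tibble(
      read_id = read_id,
      source = amp$name[src],
      frag_start = frag_start, frag_end = frag_end,
      crossing1 = overhang(m1_start, m1_end) >= 1L,
      overhang1 = overhang(m1_start, m1_end),
      crossing2 = overhang(m2_start, m2_end) >= 1L,
      overhang2 = overhang(m2_start, m2_end),
      adapter_bases1 = pmax(0L, pmin(m1_end, adapter_len) - m1_start + 1L),
      primer_overlap2 = pmax(0L, pmin(m2_end, amp$amp_len[src]) - pmax(m2_start, site_start) + 1L)
    )
    list(pairs = pairs, truth = truth)
  })
}

add_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Simulate junction cohorts with planted truth classes
#'
#' Generates per-sample junction tables for tumor, cell-line, normal and
#' body-map cohorts with three planted junction classes: annotated
#' (broadly present and listed in the known set), normal-shared (present
#' in at least one normal/body-map sample) and novel-cancer (tumor/cell
#' line only, with split-read support >= `high_support` in at least one
#' carrier). Default cohort sizes mirror a RACE-seq study design: 19
#' tumors + 3 cell lines versus 1 matched normal + 16 body-map tissues.
#'
#' @param n_tumor,n_cell_line,n_normal,n_bodymap cohort sizes.
#' @param n_annotated,n_normal_shared,n_novel_cancer junctions per class.
#' @param prevalence fraction of tumor/cell-line samples carrying each
#'   novel-cancer junction (at least one carrier is always drawn).
#' @param high_support minimum support of each novel-cancer junction's
#'   top carrier (default 120; drawn as `high_support + Poisson(50)`).
#' @param background_lambda Poisson mean of ordinary junction counts.
#' @param seed RNG seed.
#' @return list: `tumor_tables` (tumor + cell-line [junction_table()]s),
#'   `normal_tables` (normal + body map), `known` (annotated junction
#'   keys), `truth` (tibble of all planted junctions with `class_label`).
#' @export
simulate_junction_cohorts <- function(n_tumor = 19L, n_cell_line = 3L,
                                      n_normal = 1L, n_bodymap = 16L,
                                      n_annotated = 100L, n_normal_shared = 40L,
                                      n_novel_cancer = 15L,
                                      prevalence = 0.4, high_support = 120L,
                                      background_lambda = 20, seed = 1L) {
  withr::with_seed(seed, {
    n_j <- n_annotated + n_normal_shared + n_novel_cancer
    pos1 <- sort(sample.int(5e7, n_j)) * 10L   # distinct, well-separated
    spans <- sample(60:20000, n_j, replace = TRUE)
    juncs <- tibble(
      chrom = paste0("chr", sample(1:22, n_j, replace = TRUE)),
      pos1 = pos1,
      pos2 = pos1 + spans,
      strand = sample(c("+", "-"), n_j, replace = TRUE),
      class_label = c(rep("annotated", n_annotated),
                      rep("normal_shared", n_normal_shared),
                      rep("novel_cancer", n_novel_cancer))
    )
    tumor_ids <- c(sprintf("Tumor%02d_T", seq_len(n_tumor)),
                   sprintf("CellLine%d", seq_len(n_cell_line)))
    tumor_classes <- c(rep("tumor", n_tumor), rep("cell_line", n_cell_line))
    normal_ids <- c(sprintf("Normal%d_N", seq_len(n_normal)),
                    sprintf("BodyMap%02d", seq_len(n_bodymap)))
    normal_classes <- c(rep("normal", n_normal), rep("body_map", n_bodymap))

    draw_counts <- function(n) stats::rpois(n, background_lambda) + 1L

    rows_tumor <- vector("list", length(tumor_ids))
    rows_normal <- vector("list", length(normal_ids))
    add <- function(store, si, idx, counts) {
      store[[si]] <- bind_rows(store[[si]], tibble(j = idx, count = counts))
      store
    }
    for (r in seq_len(n_j)) {
      cl <- juncs$class_label[r]
      if (cl == "annotated") {
        # broadly present in both compartments
        ts <- which(stats::runif(length(tumor_ids)) < 0.8)
        ns <- which(stats::runif(length(normal_ids)) < 0.8)
        for (si in ts) rows_tumor <- add(rows_tumor, si, r, draw_counts(1L))
        for (si in ns) rows_normal <- add(rows_normal, si, r, draw_counts(1L))
      } else if (cl == "normal_shared") {
        ts <- which(stats::runif(length(tumor_ids)) < 0.5)
        ns <- which(stats::runif(length(normal_ids)) < 0.5)
        if (!length(ns)) ns <- sample(seq_along(normal_ids), 1L)
        for (si in ts) rows_tumor <- add(rows_tumor, si, r, draw_counts(1L))
        for (si in ns) rows_normal <- add(rows_normal, si, r, draw_counts(1L))
      } else {
        carriers <- which(stats::runif(length(tumor_ids)) < prevalence)
        if (!length(carriers)) carriers <- sample(seq_along(tumor_ids), 1L)
        top <- carriers[1]
        for (si in carriers) {
          cnt <- if (si == top) high_support + stats::rpois(1L, 50) else draw_counts(1L)
          rows_tumor <- add(rows_tumor, si, r, cnt)
        }
      }
    }
    mk_tables <- function(rows, ids, classes) {
      out <- list()
      for (si in seq_along(ids)) {
        if (is.null(rows[[si]]) || nrow(rows[[si]]) == 0L) next
        jt <- juncs[rows[[si]]$j, c("chrom", "pos1", "pos2", "strand")]
        jt$count <- rows[[si]]$count
        out[[ids[si]]] <- junction_table(ids[si], classes[si], jt)
      }
      out
    }
    list(
      tumor_tables = mk_tables(rows_tumor, tumor_ids, tumor_classes),
      normal_tables = mk_tables(rows_normal, normal_ids, normal_classes),
      known = juncs |> filter(.data$class_label == "annotated") |>
        select("chrom", "pos1", "pos2", "strand"),
      truth = juncs
    )
  })
}

#' Write paired reads to FASTQ files
#'
#' @param pairs pair tibble from [simulate_race_reads()].
#' @param fq1,fq2 output FASTQ paths (mate 1 / mate 2).
#' @export
write_read_pairs <- function(pairs, fq1, fq2) {
  for (mate in 1:2) {
    ss <- Biostrings::DNAStringSet(pairs[[paste0("seq", mate)]])
    names(ss) <- pairs$read_id
    qs <- Biostrings::BStringSet(pairs[[paste0("qual", mate)]])
    path <- if (mate == 1L) fq1 else fq2
    atomic_write(function(p) {
      Biostrings::writeXStringSet(ss, p, format = "fastq", qualities = qs)
    }, path)
  }
  invisible(pairs)
}

#' Read paired FASTQ files into a pair tibble
#'
#' @param fq1,fq2 FASTQ paths; records must be in matching order.
#' @return tibble `read_id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
read_read_pairs <- function(fq1, fq2) {
  r1 <- Biostrings::readDNAStringSet(fq1, format = "fastq", with.qualities = TRUE)
  r2 <- Biostrings::readDNAStringSet(fq2, format = "fastq", with.qualities = TRUE)
  stopifnot(length(r1) == length(r2))
  tibble(read_id = sub("\\s.*$", "", names(r1)),
         seq1 = unname(as.character(r1)),
         qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)),
         seq2 = unname(as.character(r2)),
         qual2 = unname(as.character(S4Vectors::mcols(r2)$qualities)))
}

#' Write / read a toy reference (FASTA + GTF-lite TSV)
#'
#' @param ref a [reference_set()].
#' @param fasta_path,gtf_path file paths.
#' @export
write_reference <- function(ref, fasta_path, gtf_path) {
  ss <- Biostrings::DNAStringSet(unlist(ref$transcripts))
  atomic_write(function(p) Biostrings::writeXStringSet(ss, p), fasta_path)
  atomic_write(function(p) readr::write_tsv(ref$gene_models, p), gtf_path)
  invisible(ref)
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta_path, gtf_path) {
  ss <- Biostrings::readDNAStringSet(fasta_path)
  gm <- readr::read_tsv(gtf_path, progress = FALSE, col_types = readr::cols())
  gm$strand <- as.integer(gm$strand)
  reference_set(stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss))), gm)
}
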