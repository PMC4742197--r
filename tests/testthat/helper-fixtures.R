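# shared in-code fixtures; everything is generated, nothing is stored

toy_samples <- function() {
  tibble::tibble(sample_id = c("T1", "T2", "T3", "N1"),
                 class = c("tumor", "tumor", "tumor", "normal"))
}

toy_probesets <- function() {
  tibble::tibble(
    probeset_id = c("GA_1", "GA_2", "GA_3", "GB_1", "GB_2"),
    gene_id = c("GA", "GA", "GA", "GB", "GB"),
    chrom = "chr1",
    strand = c(1L, 1L, 1L, -1L, -1L),
    start = c(100L, 200L, 300L, 1000L, 1100L),
    end = c(150L, 250L, 350L, 1050L, 1150L)
  )
}

toy_matrix <- function(values = NULL) {
  ps <- toy_probesets()
  sm <- toy_samples()
  if (is.null(values)) {
    set.seed(7)
    values <- matrix(rnorm(nrow(sm) * nrow(ps), 8), nrow(sm), nrow(ps))
  }
  rownames(values) <- sm$sample_id
  colnames(values) <- ps$probeset_id
  expression_matrix(values, sm, ps)
}

# write a small expression dataset to TSVs, returning the three paths
toy_expression_files <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  m <- toy_matrix()
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                annotation = file.path(dir, "annotation.tsv"),
                samples = file.path(dir, "samples.tsv"))
  write_expression_matrix(m, paths$matrix, paths$annotation, paths$samples)
  paths$object <- m
  paths
}

toy_gene_model <- function(n_exons = 6L, strand = 1L, exon_len = 100L,
                           intron_len = 50L, chrom = "chr2", gene_id = "GX") {
  starts <- 1000L + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  exon_number <- if (strand == 1L) seq_len(n_exons) else rev(seq_len(n_exons))
  tibble::tibble(gene_id = gene_id, exon_number = exon_number, chrom = chrom,
                 start = starts, end = starts + exon_len - 1L, strand = strand)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_pairs <- function(seqs1, seqs2 = NULL) {
  if (is.null(seqs2)) seqs2 <- vapply(nchar(seqs1), random_dna, "")
  tibble::tibble(read_id = sprintf("r%03d", seq_along(seqs1)),
                 seq1 = seqs1, qual1 = strrep("I", nchar(seqs1)),
                 seq2 = seqs2, qual2 = strrep("I", nchar(seqs2)))
}

# a small fused-reference fixture shared by the read-analysis tests:
# GENE01 exons 1-3 fused to GENE02 exons 4-6, NGSP in GENE02 exon 4
fusion_fixture <- function(seed = 3L, n_pairs = 300L, read_len = 100L,
                           error_rate = 0, abundances = NULL) {
  ref <- simulate_reference(seed = seed)
  fus <- plant_fusion(ref, "GENE01", 3L, "GENE02", 4L)
  ngsp <- racescreen:::revcomp(substr(racescreen:::exon_seq(ref, "GENE02", 4L), 40L, 63L))
  wt_b <- ref$transcripts[["TX_GENE02"]]
  transcripts <- tibble::tibble(
    name = c(fus$fusion_id, "TX_GENE02"),
    seq = c(fus$seq, wt_b),
    abundance = abundances %||% c(1, 0),
    junction_pos = c(fus$junction_pos, NA_integer_)
  )
  sim <- simulate_race_reads(transcripts, ngsp, n_pairs = n_pairs,
                             read_len = read_len, insert_mean = 220L,
                             insert_sd = 40L, error_rate = error_rate,
                             seed = seed + 1L)
  list(ref = ref, fus = fus, ngsp = ngsp, pairs = sim$pairs, truth = sim$truth)
}

`%||%` <- rlang::`%||%`
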