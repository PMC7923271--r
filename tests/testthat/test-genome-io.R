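cfg <- sim_config(seed = 101)
toy <- generate_toy_mitogenome(cfg)
g <- toy$genome

test_that("toy genome satisfies the mitogenome invariants", {
  expect_s3_class(g, "mitogenome")
  expect_true(g$complete)
  expect_equal(sum(g$features$kind == "CR"), 2)
  expect_equal(nrow(g$features), 39)
  expect_setequal(g$features$token[g$features$kind != "CR"], gene_tokens())
})

test_that("GenBank write-then-read round trip preserves the mitogenome", {
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(g, path)
  g2 <- read_genbank(path)[[1]]
  expect_equal(g2, g)
})

test_that("FASTA + feature table round trip matches the GenBank path", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tb <- withr::local_tempfile(fileext = ".tsv")
  write_fasta_features(g, fa, tb)
  g2 <- read_fasta_features(fa, tb)
  expect_equal(g2$sequence, g$sequence)
  expect_equal(g2$features, g$features)
  expect_equal(extract_gene_order(g2), extract_gene_order(g))
})

test_that("feature-table coordinates are 1-based inclusive on disk", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  tb <- withr::local_tempfile(fileext = ".tsv")
  seqinr::write.fasta("ACGT", names = "x", file.out = fa)
  seq1536 <- paste(rep("ACGT", 400), collapse = "")
  seqinr::write.fasta(seq1536, names = "x", file.out = fa)
  writeLines(c("token\tstart\tend\tstrand\tkind",
               "cox1\t1\t1536\t+\tPCG",
               "CR1\t1500\t40\t+\tCR"), tb)
  g3 <- read_fasta_features(fa, tb)
  expect_equal(g3$features$start[1], 0L)
  expect_equal(g3$features$end[1], 1536L)
  expect_true(g3$features$wrap[2])  # start > end on input forces the wrap flag
  # out-of-bounds coordinates are a data error
  writeLines(c("token\tstart\tend\tstrand\tkind", "cox1\t1\t99999\t+\tPCG"), tb)
  expect_error(read_fasta_features(fa, tb), class = "mito_data_error")
})

test_that("synonym table maps annotation vocabulary onto standard tokens", {
  expect_equal(map_gene_name("COI"), "cox1")
  expect_equal(map_gene_name("cytochrome c oxidase subunit I"), "cox1")
  expect_equal(map_gene_name("16S ribosomal RNA"), "rrnL")
  expect_equal(map_gene_name("tRNA-Leu (UUR)"), "trnL2")
  expect_true(is.na(map_gene_name("mystery ORF")))
})

test_that("GenBank records with synonyms and complement strands parse", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST1 60 bp    DNA     circular   INV",
    "FEATURES             Location/Qualifiers",
    "     source          1..60",
    "     CDS             complement(1..30)",
    '                     /gene="COX1"',
    "     tRNA            31..55",
    '                     /product="tRNA-Phe"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtaacgta", 6), collapse = " ")),
    "//"), path)
  gg <- read_genbank(path)[[1]]
  expect_equal(gg$features$token, c("cox1", "trnF"))
  expect_equal(gg$features$strand, c("-", "+"))
  expect_equal(nchar(gg$sequence), 60)
  expect_error(read_genbank(withr::local_tempfile(lines = "no genbank here")),
               class = "mito_format_error")
})

test_that("gene orders extract in plus-strand start order with canonical rotation", {
  ord <- extract_gene_order(g)
  expect_equal(nrow(ord), 37)
  expect_equal(ord$token[1], "cox1")
  expect_equal(ord$sign[1], 1L)
  expect_equal(format(ord), format(pancrustacean_gene_order()))
  with_cr <- extract_gene_order(g, include_cr = TRUE)
  expect_equal(nrow(with_cr), 39)
})

test_that("gene order is invariant to rotation and reverse complement", {
  # rotate the genome sequence, cutting at a feature boundary
  rot <- g$features$start[10]
  L <- nchar(g$sequence)
  seq_rot <- paste0(substr(g$sequence, rot + 1, L), substr(g$sequence, 1, rot))
  f <- g$features[g$features$kind != "CR", ]
  f$start <- (f$start - rot) %% L
  f$end2 <- (f$end - rot) %% L
  f$end2[f$end2 == 0] <- L
  keep <- f$start < f$end2  # drop any feature that would now wrap
  f2 <- tibble::tibble(token = f$token[keep], start = f$start[keep],
                       end = f$end2[keep], strand = f$strand[keep],
                       kind = f$kind[keep], wrap = FALSE)
  g_rot <- mitogenome("rot", seq_rot, f2)
  expect_equal(format(extract_gene_order(g_rot)),
               format(extract_gene_order(g)))
  # reverse complement flips every strand and reverses coordinates
  seq_rc <- revcomp(g$sequence)
  f <- g$features
  f_rc <- tibble::tibble(
    token = f$token, start = L - f$end, end = L - f$start,
    strand = ifelse(f$strand == "+", "-", "+"), kind = f$kind, wrap = FALSE)
  g_rc <- mitogenome("rc", seq_rc, f_rc[f_rc$kind != "CR", ])
  expect_equal(format(extract_gene_order(g_rc)), format(extract_gene_order(g)))
  # and the extracted coding sequences are unchanged
  cds_rc <- extract_cds(g_rc)
  cds <- extract_cds(g)
  expect_equal(cds_rc$seq[match(cds$gene, cds_rc$gene)], cds$seq)
})

test_that("duplicate non-CR tokens are rejected", {
  f <- tibble::tibble(token = c("cox1", "cox1"), start = c(0L, 10L),
                      end = c(9L, 19L), strand = "+", kind = "PCG",
                      wrap = FALSE)
  expect_error(mitogenome("dup", paste(rep("A", 20), collapse = ""), f),
               class = "mito_data_error")
})

test_that("a single-feature genome yields an order of length one", {
  f <- tibble::tibble(token = "cox1", start = 0L, end = 9L, strand = "+",
                      kind = "PCG", wrap = FALSE)
  g1 <- mitogenome("one", "ATGAAATTTA", f)
  expect_equal(nrow(extract_gene_order(g1)), 1)
})

test_that("extract_cds frames genes, reverse-complements minus strands, flags problems", {
  cds <- extract_cds(g)
  expect_equal(nrow(cds), 13)
  expect_true(all(cds$seq == vapply(cds$gene, function(gn) toy$truth$gene_seqs[[gn]], "")))
  expect_false(any(cds$truncated))
  # a 9-bp plus-strand gene gives 3 codons and no truncation
  f <- tibble::tibble(token = "atp8", start = 0L, end = 9L, strand = "+",
                      kind = "PCG", wrap = FALSE)
  g9 <- mitogenome("x", "ATGAAATTTA", f)
  expect_equal(extract_cds(g9)$n_codons, 3)
  expect_false(extract_cds(g9)$truncated)
  # internal stop is a warning record, not an error
  f <- tibble::tibble(token = "atp8", start = 0L, end = 9L, strand = "+",
                      kind = "PCG", wrap = FALSE)
  gs <- mitogenome("y", "ATGTAATTTA", f)
  expect_warning(out <- extract_cds(gs), "internal stop")
  expect_true(out$internal_stop)
})

test_that("start/stop audit recognizes canonical, alternative and truncated codons", {
  audit <- audit_start_stop_codons(tibble::tibble(
    gene = c("a", "b", "c"), taxon = "t",
    seq = c("ATGAAATAA",      # canonical complete
            "GTGAAATA",       # alternative start, truncated TA stop
            "TTGAAAT")))      # TTG start, truncated T stop
  expect_equal(audit$start_codon, c("ATG", "GTG", "TTG"))
  expect_equal(audit$canonical_start, c(TRUE, FALSE, FALSE))
  expect_equal(audit$stop_codon, c("TAA", "TA", "T"))
  expect_equal(audit$truncated, c(FALSE, TRUE, TRUE))
  expect_equal(audit$canonical_stop, c(TRUE, FALSE, FALSE))
})

test_that("gene-order text files round trip", {
  path <- withr::local_tempfile(fileext = ".txt")
  orders <- list(toy = extract_gene_order(g), ref = pancrustacean_gene_order())
  write_gene_orders(orders, path)
  back <- read_gene_orders(path)
  expect_equal(names(back), c("toy", "ref"))
  expect_equal(format(back$ref), format(orders$ref))
})
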