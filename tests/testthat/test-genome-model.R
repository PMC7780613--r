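test_that("segment_lus tiles a region and catches boundary-crossing genes", {
  # minimal 2-LU arm: three sites at 0, 1034, 2068 over [0, 2102)
  sites <- c(0L, 1034L, 2068L)
  lus <- segment_lus(sites, c(0L, 2102L))
  expect_equal(nrow(lus), 2L)
  expect_equal(lus$length_bp, c(1000L, 1000L))

  # single LU between the two boundary sites
  one <- segment_lus(c(0L, 534L), c(0L, 568L))
  expect_equal(nrow(one), 1L)
  expect_equal(one$length_bp, 500L)

  expect_error(segment_lus(c(100L, 0L, 2068L), c(0L, 2102L)),
               "strictly increasing")

  # a gene spanning the interior site is rejected by name
  g <- data.frame(id = "BAD1", start = 1000L, end = 1100L, strand = "+",
                  essentiality = "nonessential")
  expect_error(segment_lus(sites, c(0L, 2102L), genes = g), "BAD1")
})

test_that("lu_stats counts genes per class and LU extremes", {
  chrom <- make_toy_chromosome(4, lengths = c(500L, 1500L, 800L, 2500L),
                               essential_lus = 2, empty_lus = 3)
  s <- lu_stats(chrom)
  expect_equal(s$n_lus, 4L)
  expect_equal(s$n_essential_lus, 1L)
  expect_equal(s$n_genes, 3L)
  expect_equal(s$n_essential, 1L)
  expect_equal(s$n_nonessential, 2L)
  expect_equal(s$min_lu_bp, 500L)
  expect_equal(s$max_lu_bp, 2500L)
  expect_equal(s$total_synthetic_bp, 5300L)
  # the empty LU is represented with zero genes
  expect_equal(lu_table(chrom)$n_genes[3L], 0L)
})

test_that("URA3 integration modes behave and are guarded", {
  chrom <- make_synxiil_fixture(1)

  # replace_gene keeps the LU count, records the marker, flags the gene
  c8 <- integrate_ura3(chrom, "LU-8", "replace_gene", gene_id = "YLL054C")
  expect_equal(nrow(c8$lus), 46L)
  expect_equal(c8$markers$URA3, "LU-8")
  expect_true(c8$genes$replaced[c8$genes$id == "YLL054C"])
  # replaced gene still counted in the reference totals
  expect_equal(lu_stats(c8)$n_genes, 81L)

  # insert_between requires adjacency inside the target LU
  c20 <- integrate_ura3(chrom, "LU-20", "insert_between",
                        between = c("GPI13", "YLL032C"))
  expect_equal(c20$markers$URA3, "LU-20")
  expect_true(lu_table(c20)$has_essential[lu_table(c20)$lu_id == "LU-20"])
  expect_error(integrate_ura3(chrom, "LU-20", "insert_between",
                              between = c("GPI13", "FRA1")), "adjacent")

  # chunk_split grows the LU table 46 -> 48 with -a/-b/-c sub-units
  c24 <- integrate_ura3(chrom, "LU-24", "chunk_split",
                        offsets = synxiil_chunk_offsets())
  expect_equal(nrow(c24$lus), 48L)
  expect_true(all(paste0("LU-24-", c("a", "b", "c")) %in% c24$lus$lu_id))
  expect_equal(c24$markers$URA3, "LU-24-b")
  expect_equal(sum(c24$lus$length_bp), sum(chrom$lus$length_bp))

  expect_error(integrate_ura3(chrom, "LU-20", "replace_gene",
                              gene_id = "GPI13"), "non-dispensable")
  expect_error(integrate_ura3(chrom, "LU-24", "chunk_split",
                              offsets = c(100L, 99999L)), "offsets")
})

test_that("chunk_split then merge restores the original boundaries", {
  chrom <- make_synxiil_fixture(1, with_sequence = TRUE)
  c24 <- integrate_ura3(chrom, "LU-24", "chunk_split",
                        offsets = synxiil_chunk_offsets())
  back <- merge_split_lu(c24, "LU-24")
  expect_equal(lu_table(back), lu_table(chrom))
  expect_equal(back$lu_seqs[["LU-24"]], chrom$lu_seqs[["LU-24"]])
  g0 <- chrom$genes[order(chrom$genes$id), ]
  g1 <- back$genes[order(back$genes$id), ]
  rownames(g0) <- rownames(g1) <- NULL
  expect_equal(g0, g1)
})

test_that("eArray builder groups essential genes into flanked loci", {
  chrom <- make_synxiil_fixture(1)
  ea <- build_earray(chrom, 140000L)
  expect_s3_class(ea, "earray")
  expect_length(ea$gene_ids, 10L)
  expect_equal(nrow(ea$loci), 7L)
  runs <- strsplit(ea$loci$genes, ";")
  expect_true(any(vapply(runs, function(r)
    setequal(r, c("PRP19", "GRC3", "RIX7")), FALSE)))
  expect_true(any(vapply(runs, function(r)
    setequal(r, c("SFI1", "ORC3")), FALSE)))
  expect_false(ea$contains_loxpsym)

  # no locus interval contains a loxPsym site
  st <- site_table(chrom)
  for (k in seq_len(nrow(ea$loci))) {
    inside <- st$position >= ea$loci$start[k] & st$position < ea$loci$end[k]
    expect_false(any(inside))
  }
  # every essential gene sits in at most one locus
  expect_false(anyDuplicated(ea$gene_ids) > 0)

  # cutoff 0 is an empty array, not an error
  expect_length(build_earray(chrom, 0L)$gene_ids, 0L)
})

test_that("annotation round-trips through canonical TSV and GFF3", {
  chrom <- make_synxiil_fixture(1)
  tsv <- tempfile(fileext = ".tsv")
  write_annotation(chrom, tsv, "tsv")
  back <- load_annotation(tsv, "tsv", name = chrom$name)
  expect_equal(lu_table(back), lu_table(chrom))
  expect_equal(gene_table(back), gene_table(chrom))
  expect_equal(back$centromere, chrom$centromere)
  # canonical TSV re-emission is content-identical
  tsv2 <- tempfile(fileext = ".tsv")
  write_annotation(back, tsv2, "tsv")
  expect_identical(readLines(tsv), readLines(tsv2))

  gff <- tempfile(fileext = ".gff3")
  write_annotation(chrom, gff, "gff3")
  back2 <- load_annotation(gff, "gff3", name = chrom$name)
  expect_equal(lu_table(back2), lu_table(chrom))
  expect_equal(gene_table(back2)$essentiality, gene_table(chrom)$essentiality)

  # a URA3-integrated arm keeps its marker through TSV I/O
  c8 <- integrate_ura3(chrom, "LU-8", "replace_gene", gene_id = "YLL054C")
  tsv3 <- tempfile(fileext = ".tsv")
  write_annotation(c8, tsv3, "tsv")
  back3 <- load_annotation(tsv3, "tsv")
  expect_equal(back3$markers$URA3, "LU-8")
  expect_true(back3$genes$replaced[back3$genes$id == "YLL054C"])

  expect_error(load_annotation(tempfile()), "no such file")
})

test_that("LU tiling invariant holds on every constructed chromosome", {
  for (chrom in list(make_synxiil_fixture(1),
                     make_toy_chromosome(1),
                     make_toy_chromosome(5, centromere_lu = 3),
                     integrate_ura3(make_synxiil_fixture(2), "LU-24",
                                    "chunk_split",
                                    offsets = synxiil_chunk_offsets()))) {
    lt <- lu_table(chrom)
    expect_equal(sum(lt$length_bp) + (nrow(lt) + 1L) * chrom$loxpsym_bp,
                 region_length(chrom))
    expect_true(all(lt$start[-1L] - lt$end[-nrow(lt)] == chrom$loxpsym_bp))
    expect_s3_class(validate_chromosome(chrom), "synthetic_chromosome")
  }
})
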