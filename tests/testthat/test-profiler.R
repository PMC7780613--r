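test_that("profiles report deletions as maximal reference segments", {
  chrom <- make_synxiil_fixture(1)
  st <- new_state(chrom)

  # single-LU deletion
  p1 <- profile_from_events(chrom,
                            list(recombination_event("deletion", 8, 9)))
  expect_equal(sum(p1$status$deleted), 1L)
  expect_equal(p1$status$lu_id[p1$status$deleted], "LU-8")

  # one event deleting LU-18..LU-28 -> a single contiguous segment
  p2 <- profile_from_events(chrom,
                            list(recombination_event("deletion", 18, 29)))
  expect_equal(nrow(p2$deleted_segments), 1L)
  expect_equal(p2$deleted_segments$first_lu, "LU-18")
  expect_equal(p2$deleted_segments$last_lu, "LU-28")
  expect_equal(p2$deleted_segments$n_lus, 11L)

  # two disjoint deletions -> two segments ("not concatenated")
  st3 <- apply_event(st, recombination_event("deletion", 5, 7))
  st3 <- apply_event(st3, recombination_event("deletion", 20, 22))
  p3 <- profile_from_state(st3)
  expect_equal(nrow(p3$deleted_segments), 2L)

  expect_error(profile_from_events(chrom, list(list(type = "deletion",
                                                    i = 90, j = 95))),
               "replayable")
})

test_that("event-replay and sequence-tiling profiles agree on random strains", {
  chrom <- make_toy_chromosome(7, lengths = c(400L, 800L, 1200L, 300L, 900L,
                                              600L, 1500L),
                               with_sequence = TRUE, seed = 2)
  pop <- simulate_population(chrom, 100L, lambda_events = 2,
                             model = "power_law",
                             params = list(alpha = 0.5, d0 = 100), seed = 17)
  for (s in pop) {
    pe <- profile_from_state(s$state)
    ps <- profile_from_sequence(chrom, state_contig(s$state))
    expect_equal(pe$status, ps$status)
    expect_equal(pe$deleted_segments, ps$deleted_segments)
  }
})

test_that("sequence tiling reports copy number and rejects foreign contigs", {
  chrom <- make_toy_chromosome(4, with_sequence = TRUE)
  st <- new_state(chrom)
  ref <- profile_from_sequence(chrom, state_contig(st))
  expect_true(all(ref$status$copies == 1L))
  expect_true(all(!ref$status$inverted))

  dup <- apply_event(st, recombination_event("duplication", 2, 4))
  pd <- profile_from_sequence(chrom, state_contig(dup))
  expect_equal(pd$status$copies[2:3], c(2L, 2L))

  expect_error(profile_from_sequence(chrom, paste(rep("ACGT", 300),
                                                  collapse = "")),
               "loxPsym")
})

test_that("PCRtag screening is equivalent to LU presence", {
  chrom <- make_synxiil_fixture(1, with_sequence = TRUE)
  tags <- make_pcrtags(chrom)
  # the 50-bp LU-2 is untagged, like real tag tables with tagless units
  expect_false("LU-2" %in% tags$lu_id)

  st <- new_state(chrom)
  res0 <- insilico_pcrtag(st, tags)
  expect_true(all(res0$positive))

  k20 <- match("LU-20", chrom$lus$lu_id)
  st20 <- apply_event(st, recombination_event("deletion", k20, k20 + 1L))
  res1 <- insilico_pcrtag(st20, tags)
  expect_false(res1$positive[res1$lu_id == "LU-20"])
  expect_true(all(res1$positive[res1$lu_id != "LU-20"]))

  # an inverted LU keeps its internal amplicon (checked on real sequence)
  k5 <- match("LU-5", chrom$lus$lu_id)
  inv <- apply_event(st, recombination_event("inversion", k5, k5 + 1L))
  res2 <- insilico_pcrtag(state_contig(inv), tags)
  expect_true(res2$positive[res2$lu_id == "LU-5"])
  # sequence mode agrees with profile mode after a deletion
  res3 <- insilico_pcrtag(state_contig(st20), tags)
  expect_equal(res3, res1)

  bad <- tags[1, ]; bad$lu_id <- "LU-99"
  expect_error(insilico_pcrtag(st, bad), "unknown LU")
})

test_that("PCRtag positivity matches copy number across simulated strains", {
  chrom <- make_toy_chromosome(6, lengths = 700L, with_sequence = TRUE)
  tags <- make_pcrtags(chrom)
  pop <- simulate_population(chrom, 60L, lambda_events = 2,
                             model = "power_law",
                             params = list(alpha = 0.5, d0 = 100), seed = 23)
  for (s in pop) {
    prof <- profile_from_state(s$state)
    res <- insilico_pcrtag(prof, tags)
    copies <- setNames(prof$status$copies, prof$status$lu_id)
    expect_equal(res$positive, unname(copies[res$lu_id] >= 1L))
  }
})

test_that("compaction statistics follow the reference LU content", {
  chrom <- make_synxiil_fixture(1)
  # delete 12 LUs in two events and check the bookkeeping sums
  st <- new_state(chrom)
  st <- apply_event(st, recombination_event("deletion", 3, 10))   # LU-3..9
  st <- apply_event(st, recombination_event("deletion", 10, 15))  # 5 more
  prof <- profile_from_state(st)
  cs <- compaction_stats(prof, chrom)
  expect_equal(cs$n_lus_deleted, 12L)
  lt <- lu_table(chrom)
  expect_equal(cs$bp_deleted,
               sum(lt$length_bp[lt$lu_id %in% cs$deleted_lus]))
  expect_equal(cs$n_genes_deleted,
               sum(chrom$genes$lu_id %in% cs$deleted_lus))

  # empty profile and whole-arm deletion bracket the range
  p0 <- profile_from_state(new_state(chrom))
  expect_equal(compaction_stats(p0, chrom)$bp_deleted, 0L)
  toy <- make_toy_chromosome(3)
  all_gone <- apply_event(new_state(toy), recombination_event("deletion", 1, 4))
  expect_equal(compaction_stats(profile_from_state(all_gone), toy)$bp_deleted,
               sum(toy$lus$length_bp))

  # a reporter-replaced gene still counts among deleted genes
  c8 <- integrate_ura3(chrom, "LU-8", "replace_gene", gene_id = "YLL054C")
  k8 <- match("LU-8", c8$lus$lu_id)
  st8 <- apply_event(new_state(c8), recombination_event("deletion", k8, k8 + 1L))
  cs8 <- compaction_stats(profile_from_state(st8), c8)
  expect_equal(cs8$n_genes_deleted, 2L)
})

test_that("ledger arithmetic reproduces the three-round worked example", {
  chrom <- make_synxiil_fixture(1)
  lt <- lu_table(chrom)
  cand <- lt$lu_id[!lt$has_essential & !lt$has_centromere]
  r1 <- cand[1:12]; r2 <- cand[13:21]; r3 <- cand[22:28]

  led <- new_ledger(chrom)
  led <- update_ledger(led, list(round_id = "R1", strain = "ZLY298",
                                 deleted_lus = r1, chrom = chrom))
  led <- update_ledger(led, list(round_id = "R2", strain = "ZLY348",
                                 deleted_lus = r2, chrom = chrom))
  cum2 <- ledger_cumulative(led)
  expect_equal(cum2$retained_lus, 25L)

  led <- update_ledger(led, list(round_id = "R3", strain = "ZLY349",
                                 deleted_lus = r3, chrom = chrom))
  cum3 <- ledger_cumulative(led)
  expect_equal(cum3$retained_lus, 18L)
  # conservation every round
  expect_equal(cum3$retained_bp + cum3$deleted_bp, 170000L)
  expect_equal(cum3$retained_genes + cum3$deleted_genes, 81L)

  # 71 kbp removed from 170 kbp leaves 99 kbp retained
  led_bp <- new_ledger(chrom)
  led_bp$rounds <- data.frame(round_id = "R", strain = "S",
                              n_lus_deleted = 21L, bp_deleted = 71000L,
                              n_genes_deleted = 27L, deleted_lus = "",
                              stringsAsFactors = FALSE)
  expect_equal(ledger_cumulative(led_bp)$retained_bp, 99000L)

  # overlapping rounds are rejected
  expect_error(update_ledger(led, list(round_id = "R4", strain = "X",
                                       deleted_lus = r1[1], chrom = chrom)),
               "overlap")
})

test_that("sub-LU deletions only retire the parent once all parts are gone", {
  chrom <- make_synxiil_fixture(1)
  c24 <- integrate_ura3(chrom, "LU-24", "chunk_split",
                        offsets = synxiil_chunk_offsets())
  led <- new_ledger(chrom)
  led <- update_ledger(led, list(round_id = "R1", strain = "A",
                                 deleted_lus = c("LU-24-a", "LU-24-b"),
                                 chrom = c24))
  expect_equal(led$rounds$n_lus_deleted, 0L)
  expect_equal(led$rounds$bp_deleted, 9300L)
  led <- update_ledger(led, list(round_id = "R2", strain = "B",
                                 deleted_lus = "LU-24-c", chrom = c24))
  expect_equal(sum(led$rounds$n_lus_deleted), 1L)
  expect_equal(ledger_cumulative(led)$deleted_bp, 16404L)
})
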