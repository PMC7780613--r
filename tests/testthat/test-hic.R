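test_that("triplet I/O round-trips and validates", {
  f <- tempfile()
  writeLines(c("1\t2\t5", "2\t3\t1.5"), f)
  cm <- read_triplet(f, 2000L, n_bins = 3L)
  expect_equal(cm$counts[1, 2], 5)
  expect_equal(cm$counts[2, 1], 5)
  expect_equal(cm$counts[3, 2], 1.5)

  f2 <- tempfile()
  write_triplet(cm, f2)
  cm2 <- read_triplet(f2, 2000L, n_bins = 3L)
  expect_equal(cm2$counts, cm$counts)

  # empty file is a zero matrix
  f3 <- tempfile(); file.create(f3)
  expect_equal(sum(read_triplet(f3, 2000L, n_bins = 4L)$counts), 0)

  f4 <- tempfile(); writeLines("1\t2\t-3", f4)
  expect_error(read_triplet(f4, 2000L), "negative")
  f5 <- tempfile(); writeLines("1\t9\t3", f5)
  expect_error(read_triplet(f5, 2000L, n_bins = 3L), "out of range")
})

test_that("ICE balancing equalizes bin sums and masks dead bins", {
  # uniform matrix is already balanced: only global scale changes
  u <- contact_matrix(matrix(4, 6, 6), 2000L)
  bu <- ice_balance(u, filter_low_pct = 0)
  expect_equal(max(abs(rowSums(bu$counts) - 1)), 0, tolerance = 1e-6)
  expect_equal(bu$counts / bu$counts[1, 1], u$counts / u$counts[1, 1])

  # 2-bin closed form: [[2,1],[1,4]] balances to equal bin sums
  m2 <- contact_matrix(matrix(c(2, 1, 1, 4), 2, 2), 2000L)
  b2 <- ice_balance(m2, filter_low_pct = 0, tol = 1e-8)
  s <- rowSums(b2$counts)
  expect_equal(s[1], s[2], tolerance = 1e-6)

  # zero-coverage bin is masked, the rest balanced
  m <- matrix(runif(25, 1, 3), 5, 5); m <- m + t(m); m[3, ] <- 0; m[, 3] <- 0
  b <- ice_balance(contact_matrix(m, 2000L), filter_low_pct = 0)
  expect_true(3L %in% b$masked)
  keep <- setdiff(1:5, b$masked)
  s <- rowSums(b$counts)[keep]
  expect_lt(max(abs(s / mean(s) - 1)), 1e-4)

  # idempotence: balancing a balanced matrix moves bin sums < tol
  bb <- ice_balance(b, filter_low_pct = 0)
  expect_lt(max(abs(bb$counts - b$counts)), 1e-4)

  expect_error(ice_balance(contact_matrix(matrix(0, 3, 3), 2000L)), "masked")
})

test_that("insulation segmentation recovers planted domains", {
  # constant matrix: no boundaries
  flat <- contact_matrix(matrix(2, 30, 30), 2000L)
  expect_length(insulation_cids(flat, window_bins = 4L)$boundaries, 0L)

  # noise-free planted boundaries: precision = recall = 1 within 1 bin
  planted <- c(16L, 31L, 46L)
  cm <- make_synthetic_hic(60, 2000, boundaries = planted, alpha = 1,
                           block_boost = 5, noise = 0)
  cids <- insulation_cids(ice_balance(cm), window_bins = 5L)
  hits <- vapply(planted, function(b) any(abs(cids$boundaries - b) <= 1L), FALSE)
  expect_true(all(hits))                      # recall 1
  spurious <- vapply(cids$boundaries, function(b)
    all(abs(planted - b) > 1L), FALSE)
  expect_false(any(spurious))                 # precision 1

  # moderate noise: still perfect at +/- 1 bin with a fixed seed
  cmn <- make_synthetic_hic(60, 2000, boundaries = planted, alpha = 1,
                            block_boost = 5, noise = 0.05, seed = 4)
  cidsn <- insulation_cids(ice_balance(cmn), window_bins = 5L)
  expect_true(all(vapply(planted, function(b)
    any(abs(cidsn$boundaries - b) <= 1L), FALSE)))
  expect_false(any(vapply(cidsn$boundaries, function(b)
    all(abs(planted - b) > 1L), FALSE)))

  # insulation is invariant to global scaling
  cm10 <- contact_matrix(cm$counts * 10, cm$bin_bp)
  expect_equal(insulation_cids(cm10, 5L)$boundaries,
               insulation_cids(cm, 5L)$boundaries)

  expect_error(insulation_cids(flat, window_bins = 20L), "window")
})

test_that("proximity weight models compute what they claim", {
  toy <- make_toy_chromosome(3, lengths = c(1000L, 9000L, 1000L))
  st <- new_state(toy)
  w <- weights_for_sites(st, "power_law", params = list(alpha = 1, d0 = 0))
  # separations: site1-site2 = 1034 bp, site2-site3 = 9034
  expect_equal(w[1, 2] / w[2, 3], 9034 / 1034)

  # cid_boost multiplies same-domain pairs by beta
  # domain split at 2 kbp: sites 1 (pos 0) and 2 (pos 1034) share the first
  # domain; sites 3 and 4 (pos ~10-11 kbp) share the second
  cids <- structure(list(
    boundaries = 1L,
    domains = data.frame(start_bin = c(1L, 2L), end_bin = c(1L, 10L),
                         start_bp = c(0L, 2000L), end_bp = c(2000L, 20000L)),
    insulation = NULL, bin_bp = 2000L), class = "cid_segmentation")
  wb <- weights_for_sites(st, "cid_boost",
                          params = list(alpha = 1, d0 = 0, beta = 5),
                          cids = cids)
  expect_equal(wb[1, 2] / w[1, 2], 5)
  expect_equal(wb[3, 4] / w[3, 4], 5)
  expect_equal(wb[2, 3] / w[2, 3], 1)

  # hic_contact reads the balanced reference contacts
  cm <- make_synthetic_hic(12, 1000L, alpha = 1, block_boost = 1, noise = 0)
  wh <- weights_for_sites(st, "hic_contact", matrix = cm)
  expect_equal(wh[1, 2], cm$counts[1, 2 + 0])
  expect_error(weights_for_sites(st, "hic_contact"), "matrix")
  expect_error(weights_for_sites(st, "cid_boost"), "CID")
})

test_that("deletion/CID concordance counts segments inside one domain", {
  cids <- structure(list(
    boundaries = 5L,
    domains = data.frame(start_bin = c(1L, 6L), end_bin = c(5L, 20L),
                         start_bp = c(0L, 10000L), end_bp = c(10000L, 40000L)),
    insulation = NULL, bin_bp = 2000L), class = "cid_segmentation")
  seg_in <- list(deleted_segments = data.frame(start_bp = 1000L,
                                               end_bp = 8000L))
  seg_out <- list(deleted_segments = data.frame(start_bp = 8000L,
                                                end_bp = 14000L))
  class(seg_in) <- class(seg_out) <- "lu_profile"
  expect_equal(deletion_cid_concordance(seg_in, cids), 1.0)
  expect_equal(deletion_cid_concordance(seg_out, cids), 0.0)
  expect_equal(deletion_cid_concordance(list(seg_in, seg_out), cids), 0.5)
})

test_that("stronger CID boost raises concordance; larger decay shortens deletions", {
  chrom <- make_synxiil_fixture(1)
  c24 <- integrate_ura3(chrom, "LU-24", "chunk_split",
                        offsets = synxiil_chunk_offsets())
  b <- lu_cid_boundaries(c24)
  hic <- make_synthetic_hic(ceiling(region_length(c24) / 2000), 2000,
                            boundaries = b, noise = 0)
  cids <- insulation_cids(ice_balance(hic))
  ea <- build_earray(c24, 140000L)

  conc <- vapply(c(1, 10), function(beta) {
    pop <- simulate_population(c24, 1500L, lambda_events = 2,
                               model = "cid_boost",
                               params = list(alpha = 1.0, d0 = 1000,
                                             beta = beta),
                               cids = cids, episomes = "eArray", seed = 31)
    surv <- select_population(pop, earray = ea, medium = "5FOA")
    deletion_cid_concordance(lapply(surv, profile_from_state), cids)
  }, 0)
  expect_gt(conc[2], conc[1])

  med <- vapply(c(0.6, 1.8), function(alpha) {
    pop <- simulate_population(c24, 1500L, lambda_events = 2,
                               model = "power_law",
                               params = list(alpha = alpha, d0 = 1000),
                               episomes = "eArray", seed = 32)
    surv <- select_population(pop, earray = ea, medium = "5FOA")
    median(pooled_spans(surv))
  }, 0)
  expect_gt(med[1], med[2])
})
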