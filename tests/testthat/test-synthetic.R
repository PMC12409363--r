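test_that("nicking partitions the molecule at the site or leaves it intact", {
  rec <- host_trnas()[["Eco-Lys-UUU"]]
  set.seed(1)
  for (i in 1:20) {
    cl <- simulate_cleavage(rec, c("40", "41"), p = 0)
    expect_false(cl$nicked)
  }
  cl <- simulate_cleavage(rec, c("40", "41"), p = 1)
  expect_true(cl$nicked)
  len5 <- cl$frag5$end - cl$frag5$start + 1L
  len3 <- cl$frag3$end - cl$frag3$start + 1L
  expect_equal(len5, 40L)
  expect_equal(len3, 36L)
  expect_equal(len5 + len3, nchar(rec$sequence))

  expect_error(simulate_cleavage(rec, c("40", "42"), p = 1), "not adjacent")
})

test_that("fragment length conservation holds across sites and records", {
  set.seed(42)
  for (rec in host_trnas()) {
    for (lab in as.character(c(30, 35, 40, 55))) {
      nxt <- as.character(as.integer(lab) + 1L)
      cl <- simulate_cleavage(rec, c(lab, nxt), p = 1)
      expect_equal((cl$frag5$end - cl$frag5$start + 1L) +
                     (cl$frag3$end - cl$frag3$start + 1L),
                   nchar(rec$sequence))
    }
  }
})

test_that("protocol B reads start at the true RNA 5' end", {
  rec <- host_trnas()[["Eco-Lys-UUU"]]
  spec <- pool_spec(c(`Eco-Lys-UUU` = 1), protocol = "B", error_rate = 0,
                    n_reads = 1)
  rd <- simulate_read(rec, list(start = 1L, end = 76L), spec)
  expect_equal(rd$start, 1L)
  expect_equal(rd$seq, substr(rec$sequence, 1, 50))

  # read_length >= fragment, no errors: read equals the fragment
  spec2 <- pool_spec(c(`Eco-Lys-UUU` = 1), protocol = "B", error_rate = 0,
                     read_length = 100, n_reads = 1)
  rd2 <- simulate_read(rec, list(start = 41L, end = 76L), spec2)
  expect_equal(rd2$seq, substr(rec$sequence, 41, 76))
})

test_that("protocol A reads stall immediately 3' of a firing modified position", {
  rec <- host_trnas()[["Eco-Lys-UUU"]]
  mods <- data.frame(trna_id = "Eco-Lys-UUU", position_label = "37",
                     mod_name = "ct6A", mass_delta_avg_da = 127.1,
                     stringsAsFactors = FALSE)
  spec <- pool_spec(c(`Eco-Lys-UUU` = 1), protocol = "A", stall_prob = 1,
                    error_rate = 0, n_reads = 1)
  set.seed(3)
  for (i in 1:10) {
    rd <- simulate_read(rec, list(start = 1L, end = 76L), spec, mods)
    expect_equal(index_to_canonical(rec, rd$start), "38")
  }
  # stall_prob 0 behaves like protocol B
  spec0 <- pool_spec(c(`Eco-Lys-UUU` = 1), protocol = "A", stall_prob = 0,
                     error_rate = 0, n_reads = 1)
  rd0 <- simulate_read(rec, list(start = 1L, end = 76L), spec0, mods)
  expect_equal(rd0$start, 1L)
})

test_that("pool simulation is seed-deterministic and byte-identical on disk", {
  pool <- host_trnas()
  w <- stats::setNames(rep(1, length(pool)), names(pool))
  spec <- pool_spec(w, nick_sites = data.frame(
    trna_id = "Eco-Lys-UUU", site5 = "40", site3 = "41", prob = 0.5),
    protocol = "B", n_reads = 500, seed = 11)
  p1 <- tempfile(); p2 <- tempfile()
  out1 <- simulate_pool(spec, pool, out_prefix = p1)
  out2 <- simulate_pool(spec, pool, out_prefix = p2)
  expect_identical(out1$reads, out2$reads)
  expect_identical(out1$truth, out2$truth)
  expect_identical(readLines(paste0(p1, "_R1.fastq")),
                   readLines(paste0(p2, "_R1.fastq")))
  expect_identical(readLines(paste0(p1, "_truth.tsv")),
                   readLines(paste0(p2, "_truth.tsv")))
  expect_equal(length(out1$reads), 500L)
  expect_equal(nrow(out1$truth), 500L)
})

test_that("an empty pool yields empty FASTQ and truth", {
  pool <- host_trnas()
  spec <- pool_spec(stats::setNames(rep(1, length(pool)), names(pool)),
                    n_reads = 0)
  out <- simulate_pool(spec, pool)
  expect_length(out$reads, 0)
  expect_equal(nrow(out$truth), 0L)
})

test_that("unknown tRNA ids in the spec are rejected", {
  pool <- host_trnas()
  expect_error(simulate_pool(pool_spec(c(Nope = 1)), pool), "unknown")
  spec <- pool_spec(stats::setNames(rep(1, length(pool)), names(pool)),
                    nick_sites = data.frame(trna_id = "Nope", site5 = "40",
                                            site3 = "41", prob = 1))
  expect_error(simulate_pool(spec, pool), "unknown")
})

test_that("nicked-read fraction matches the nick probability at n = 10000", {
  pool <- host_trnas()
  w <- stats::setNames(rep(1, length(pool)), names(pool))
  spec <- pool_spec(w, nick_sites = data.frame(
    trna_id = "Eco-Lys-UUU", site5 = "40", site3 = "41", prob = 0.8),
    protocol = "B", n_reads = 10000, seed = 5)
  out <- simulate_pool(spec, pool)
  lys <- out$truth[out$truth$trna_id == "Eco-Lys-UUU", ]
  frac <- mean(lys$nick != "none")
  expect_gt(nrow(lys), 1000)
  expect_lt(abs(frac - 0.8), 0.02)
})

test_that("read 5' ends obey the protocol end-point invariants", {
  pool <- host_trnas()
  w <- stats::setNames(rep(1, length(pool)), names(pool))
  nk <- data.frame(trna_id = "Eco-Lys-UUU", site5 = "40", site3 = "41",
                   prob = 0.6)
  # protocol B: 5' ends are true RNA 5' ends (position 1 or the nick 3' side)
  specB <- pool_spec(w, nick_sites = nk, protocol = "B", n_reads = 2000,
                     seed = 8)
  outB <- simulate_pool(specB, pool)
  expect_true(all(outB$truth$frag_start %in% c("1", "41")))
  expect_true(all(outB$truth$stall == "none"))

  # protocol A: 5' ends are fragment starts or positions 3' of a modification
  mods <- trna_modifications()
  specA <- pool_spec(w, nick_sites = nk, protocol = "A", stall_prob = 0.3,
                     n_reads = 2000, seed = 9)
  outA <- simulate_pool(specA, pool, mods)
  allowed <- function(id) {
    rec <- pool[[id]]
    mpos <- mods$position_label[mods$trna_id == id]
    starts <- c("1", "41")
    if (length(mpos)) {
      idx <- match(mpos, rec$numbering)
      starts <- c(starts, rec$numbering[idx + 1L])
    }
    starts
  }
  for (id in unique(outA$truth$trna_id)) {
    got <- unique(outA$truth$frag_start[outA$truth$trna_id == id])
    expect_true(all(got %in% allowed(id)), label = id)
  }
})

test_that("paired mode emits mate 2 as the reverse complement of the 3' portion", {
  rec <- host_trnas()[["Eco-Lys-UUU"]]
  pool <- host_trnas()
  spec <- pool_spec(c(`Eco-Lys-UUU` = 1), protocol = "A", stall_prob = 0,
                    error_rate = 0, read_length = 50, paired = TRUE,
                    n_reads = 5, seed = 2)
  out <- simulate_pool(spec, pool)
  expect_length(out$reads2, 5)
  rc <- chartr("ACGU", "UGCA", paste(rev(strsplit(
    substr(rec$sequence, 27, 76), "")[[1]]), collapse = ""))
  expect_true(all(out$reads2 == rc))
})
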