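test_that("mapper places unique reads and drops cross-tRNA ties", {
  h <- host_trnas()
  lys <- h[["Eco-Lys-UUU"]]$sequence
  # a 30-mer unique to Lys
  reads <- c(r1 = substr(lys, 31, 60))
  aln <- map_reads(reads, h)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$trna_id, "Eco-Lys-UUU")
  expect_equal(aln$start, 30L)
  expect_equal(aln$end, 60L)
  expect_true(aln$unique)

  # identical isodecoders: a shared read must be dropped under unique_only
  dup <- c(A1 = lys, A2 = lys)
  aln2 <- map_reads(c(r1 = substr(lys, 1, 40)), dup)
  expect_equal(nrow(aln2), 0L)
  aln2b <- map_reads(c(r1 = substr(lys, 1, 40)), dup, unique_only = FALSE)
  expect_false(aln2b$unique)

  # more substitutions than allowed: unmapped
  bad <- substr(lys, 31, 60)
  substr(bad, 1, 3) <- "GGG"
  n_changed <- sum(strsplit(bad, "")[[1]] != strsplit(substr(lys, 31, 60), "")[[1]])
  expect_gte(n_changed, 3)
  expect_equal(nrow(map_reads(c(r1 = bad), h, max_mismatch = 2)), 0L)

  expect_error(map_reads(c(r1 = "ACGU"), character(0)), "empty reference")
})

test_that("mapper agrees with the brute-force all-placements oracle", {
  set.seed(21)
  h <- host_trnas()
  refs <- c(h[c("Eco-Lys-UUU", "Eco-Thr-UGU", "Eco-Asn-GUU")])
  refs <- reference_sequences(refs)
  refs <- c(refs, Iso1 = refs[["Eco-Lys-UUU"]])   # exact isodecoder twin
  refs <- c(refs, Rand = random_rna(76))
  reads <- character(0)
  for (i in 1:200) {
    id <- sample(names(refs), 1)
    L <- sample(20:60, 1)
    pos <- sample(nchar(refs[[id]]) - L + 1, 1)
    s <- substr(refs[[id]], pos, pos + L - 1)
    k <- sample(0:3, 1)   # up to one more error than the mapper allows
    if (k > 0) {
      ch <- strsplit(s, "")[[1]]
      for (p in sample(L, k))
        ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
      s <- paste(ch, collapse = "")
    }
    reads[paste0("r", i)] <- s
  }
  got <- map_reads(reads, refs, unique_only = FALSE)
  want <- bf_map(reads, refs, unique_only = FALSE)
  expect_equal(got[order(got$read_id), ], want[order(want$read_id), ],
               ignore_attr = TRUE)
  # and identically after the uniqueness filter
  expect_equal(map_reads(reads, refs)$read_id, bf_map(reads, refs)$read_id)
})

test_that("SAM import keeps primary mapped lines and infers uniqueness", {
  h <- host_trnas()
  sam <- tempfile(fileext = ".sam")
  seq30 <- chartr("U", "T", substr(h[["Eco-Lys-UUU"]]$sequence, 41, 70))
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:Eco-Lys-UUU\tLN:76",
    paste("r1", 0, "Eco-Lys-UUU", 41, 42, "30M", "*", 0, 0, seq30, "*",
          "NM:i:0", "AS:i:60", sep = "\t"),
    paste("r2", 4, "*", 0, 0, "*", "*", 0, 0, seq30, "*", sep = "\t"),
    paste("r3", 0, "Eco-Lys-UUU", 1, 1, "30M", "*", 0, 0, seq30, "*",
          "NM:i:1", "AS:i:55", sep = "\t"),
    paste("r3", 256, "Eco-Lys-UUU", 10, 0, "30M", "*", 0, 0, "*", "*",
          "NM:i:1", "AS:i:55", sep = "\t")), sam)
  aln <- import_alignments(sam, h)
  expect_equal(nrow(aln), 2L)          # unmapped r2 skipped
  r1 <- aln[aln$read_id == "r1", ]
  expect_equal(r1$start, 40L)
  expect_equal(r1$end, 70L)
  expect_true(r1$unique)
  expect_false(aln[aln$read_id == "r3", ]$unique)  # equal-scoring secondary

  writeLines(c("@SQ\tSN:NotATRNA\tLN:76",
               paste("r1", 0, "NotATRNA", 1, 42, "30M", "*", 0, 0, seq30,
                     "*", sep = "\t")), sam)
  expect_error(import_alignments(sam, h), "absent")
})

test_that("classification thresholds split full-length, fragment and other", {
  h <- host_trnas()
  aln <- data.frame(read_id = c("a", "b", "c"),
                    trna_id = "Eco-Lys-UUU",
                    start = c(0L, 40L, 10L),
                    end = c(70L, 76L, 60L),
                    n_mismatches = 0L, unique = TRUE,
                    stringsAsFactors = FALSE)
  cl <- classify_reads(aln, h)
  expect_equal(cl$class, c("full_length", "anticodon_fragment", "other"))
  expect_equal(cl$span, c(70L, 36L, 50L))
  expect_equal(cl$label5[2], "41")

  # a short read starting outside the window is not a fragment
  aln2 <- data.frame(read_id = "d", trna_id = "Eco-Lys-UUU", start = 0L,
                     end = 40L, n_mismatches = 0L, unique = TRUE,
                     stringsAsFactors = FALSE)
  expect_equal(classify_reads(aln2, h)$class, "other")
})

test_that("abundance gives CPM summing to 1e6 and is order-invariant", {
  h <- host_trnas()
  aln <- data.frame(read_id = sprintf("r%d", 1:4),
                    trna_id = c(rep("Eco-Lys-UUU", 3), "Eco-Asn-GUU"),
                    start = 0L, end = 70L, n_mismatches = 0L, unique = TRUE,
                    class = "full_length", stringsAsFactors = FALSE)
  ab <- abundance(aln, h)
  expect_equal(sum(ab$cpm), 1e6)
  expect_equal(ab$cpm[ab$trna_id == "Eco-Lys-UUU"], 750000)
  expect_equal(ab$cpm[ab$trna_id == "Eco-Asn-GUU"], 250000)
  ab_perm <- abundance(aln[sample(4), ], h)
  expect_equal(ab, ab_perm)

  expect_warning(ab0 <- abundance(aln[0, ], h), "no reads")
  expect_true(all(ab0$cpm == 0))
})

test_that("depletion regression is exact on identical samples", {
  h <- host_trnas()
  ab <- data.frame(trna_id = names(h), count = 100L,
                   cpm = 1e6 / length(h), sample = "x",
                   class = "full_length", stringsAsFactors = FALSE)
  ab$cpm <- c(5, 4, 3, 2, 1) / 15 * 1e6
  res <- depletion_analysis(ab, ab)
  expect_equal(res$slope, 1, tolerance = 1e-10)
  expect_equal(res$intercept, 0, tolerance = 1e-10)
  expect_true(all(abs(res$table$residual) < 1e-12))
  expect_false(any(res$table$depleted))
})

test_that("ten-fold reduction of three tRNAs among forty is flagged exactly", {
  set.seed(33)
  ids <- sprintf("t%02d", 1:40)
  lam <- stats::runif(40, 500, 5000)
  ctrl_counts <- stats::rpois(40, lam)
  trt_counts <- stats::rpois(40, lam)
  down <- c("t05", "t17", "t29")
  trt_counts[ids %in% down] <- stats::rpois(3, lam[ids %in% down] / 10)
  mk <- function(cnt) data.frame(trna_id = ids, count = cnt,
                                 cpm = cnt / sum(cnt) * 1e6,
                                 sample = "s", class = "full_length",
                                 stringsAsFactors = FALSE)
  res <- depletion_analysis(mk(ctrl_counts), mk(trt_counts))
  expect_setequal(res$table$trna_id[res$table$depleted], down)
  expect_true(all(res$table$residual[res$table$trna_id %in% down] < 0))

  # flags are invariant under relabelling/permutation of rows
  perm <- sample(40)
  res2 <- depletion_analysis(mk(ctrl_counts)[perm, ], mk(trt_counts)[perm, ])
  expect_setequal(res2$table$trna_id[res2$table$depleted], down)

  few <- mk(ctrl_counts)[1:2, ]
  expect_error(depletion_analysis(few, few), "fewer than 3")
})
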