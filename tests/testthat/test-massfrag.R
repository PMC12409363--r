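test_that("T1 digestion cleaves 3' of every G with the right chemistries", {
  rec <- trna_record("toy", paste0(strrep("A", 30), "GGA",
                                   strrep("C", 30), strrep("U", 13)))
  # toy 76-mer with Gs only at 31-32: products end at each G
  d <- digest_t1(rec)
  expect_equal(d$sequence,
               c(paste0(strrep("A", 30), "G"), "G",
                 paste0("A", strrep("C", 30), strrep("U", 13))))
  expect_equal(d$five_prime, c("PPP", "OH", "OH"))
  expect_equal(d$three_prime, c("P", "P", "OH"))

  # no G: a single whole-molecule product
  rec2 <- trna_record("noG", paste(rep(c("A", "C", "U"), length.out = 76),
                                   collapse = ""))
  d2 <- digest_t1(rec2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$sequence, rec2$sequence)
})

test_that("digest products tile the parent exactly, with and without nicks", {
  set.seed(12)
  recs <- c(host_trnas(), phage_trnas())
  for (i in 1:40) {
    n <- sample(74:78, 1)
    recs[[paste0("rnd", i)]] <- trna_record(paste0("rnd", i), random_rna(n))
  }
  for (rec in recs) {
    d <- digest_t1(rec)
    expect_equal(paste(d$sequence, collapse = ""), rec$sequence,
                 label = rec$id)
    if (all(c("40", "41") %in% rec$numbering) &&
        rec$residues[["40"]] != "G") {
      dn <- digest_t1(rec, nicks = c("40", "41"))
      expect_equal(paste(dn$sequence, collapse = ""), rec$sequence)
    }
  }
})

test_that("the Lys transcript yields a 14-nt product spanning the nick site", {
  lys <- host_trnas()[["Eco-Lys-UUU"]]
  d <- digest_t1(lys)
  starts <- match(d$start_label, lys$numbering)
  ends <- match(d$end_label, lys$numbering)
  span <- d[starts <= 40 & ends >= 41, ]
  expect_equal(nrow(span), 1L)
  expect_equal(span$length, 14L)

  sig <- nick_signature(lys, c("40", "41"))
  expect_equal(sig$spanning$length, 14L)
  expect_equal(sort(sig$nicked$length), c(4L, 10L))
  expect_equal(sum(sig$nicked$length), sig$spanning$length)
  # nick chemistry: upstream 3'-OH, downstream 5'-P
  up <- sig$nicked[sig$nicked$end_label == "40", ]
  down <- sig$nicked[sig$nicked$start_label == "41", ]
  expect_equal(up$three_prime, "OH")
  expect_equal(down$five_prime, "P")

  # a nick probability of zero is just the intact digest
  expect_true(span$sequence == sig$spanning$sequence)
  # nick at a T1 junction is rejected
  expect_error(nick_signature(lys, c("30", "31")), "coincides")
})

test_that("average masses match the atomic-composition oracle", {
  # adenosine: C10 H13 N5 O4
  expect_equal(average_mass(oligo("A", five_prime = "OH",
                                  three_prime = "OH")),
               10 * 12.011 + 13 * 1.008 + 5 * 14.007 + 4 * 15.999,
               tolerance = 1e-6)
  expect_equal(mh_plus(oligo("A", five_prime = "OH", three_prime = "OH")) -
                 average_mass(oligo("A", five_prime = "OH",
                                    three_prime = "OH")),
               1.008, tolerance = 1e-6)

  set.seed(4)
  for (i in 1:100) {
    s <- random_rna(sample(1:30, 1))
    fp <- sample(c("OH", "P", "PPP"), 1)
    tp <- sample(c("OH", "P", "cP"), 1)
    expect_equal(average_mass(oligo(s, five_prime = fp, three_prime = tp)),
                 oracle_mass(s, fp, tp), tolerance = 0.01, label = s)
  }
})

test_that("mass bookkeeping obeys hydrolysis and ring-opening identities", {
  h2o <- 2 * 1.008 + 15.999
  set.seed(9)
  for (i in 1:20) {
    s <- random_rna(sample(5:30, 1))
    cut <- sample(nchar(s) - 1, 1)
    parent <- average_mass(oligo(s, five_prime = "PPP", three_prime = "OH"))
    up <- average_mass(oligo(substr(s, 1, cut), five_prime = "PPP",
                             three_prime = "OH"))
    down <- average_mass(oligo(substr(s, cut + 1, nchar(s)),
                               five_prime = "P", three_prime = "OH"))
    expect_equal(up + down, parent + h2o, tolerance = 1e-9)
  }
  # ring opening of a 2',3'-cyclic phosphate adds one water
  s <- "ACGUA"
  expect_equal(average_mass(oligo(s, three_prime = "P")) -
                 average_mass(oligo(s, three_prime = "cP")),
               h2o, tolerance = 1e-9)
  # extension is monotone in MH+
  expect_gt(mh_plus(oligo("ACGUA")), mh_plus(oligo("ACGU")))
})

test_that("digest mass totals track cut counts in linear and cyclic modes", {
  h2o <- 2 * 1.008 + 15.999
  for (rec in host_trnas()) {
    parent <- average_mass(oligo(rec$sequence, five_prime = "PPP",
                                 three_prime = "OH"))
    for (nicks in list(NULL, c("40", "41"))) {
      if (!is.null(nicks) && rec$residues[["40"]] == "G") next
      lin <- digest_t1(rec, nicks = nicks)
      n_t1 <- sum(lin$right_src == "T1")
      n_nick <- sum(lin$right_src == "nick")
      expect_equal(sum(lin$neutral_mass) - parent,
                   (n_t1 + n_nick) * h2o, tolerance = 1e-6, label = rec$id)
      cyc <- digest_t1(rec, nicks = nicks, cyclic = TRUE)
      expect_equal(sum(cyc$neutral_mass) - parent, n_nick * h2o,
                   tolerance = 1e-6, label = rec$id)
    }
  }
})

test_that("modification deltas shift product masses only in modified mode", {
  lys <- host_trnas()[["Eco-Lys-UUU"]]
  mods <- trna_modifications()
  plain <- digest_t1(lys)
  modded <- digest_t1(lys, mods = mods)
  expect_equal(sum(modded$neutral_mass) - sum(plain$neutral_mass),
               sum(mods$mass_delta_avg_da[mods$trna_id == "Eco-Lys-UUU"]),
               tolerance = 1e-9)
})

test_that("peak matching respects tolerance and flags ambiguity", {
  lys <- host_trnas()[["Eco-Lys-UUU"]]
  pred <- digest_t1(lys)
  target <- pred$mh_plus[pred$length == 14]
  m <- match_peaks(pred, c(target + 0.8, target + 2.2))
  expect_true(m$matched[1])
  expect_equal(m$delta[1], 0.8, tolerance = 1e-9)
  expect_false(m$matched[2])

  two <- pred[c(1, 1), ]
  two$mh_plus <- c(1000.0, 1000.5)
  amb <- match_peaks(two, 1000.2)
  expect_true(amb$ambiguous)
  expect_equal(amb$predicted_mh, 1000.0)

  expect_error(match_peaks(pred, 1000, tol = 0), "tol")
})

test_that("peak lists load from CSV", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("mz", "4675.8", "3155.9"), f)
  expect_equal(read_peak_list(f)$mz, c(4675.8, 3155.9))
  writeLines(c("mass", "1"), f)
  expect_error(read_peak_list(f), "mz")
})
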