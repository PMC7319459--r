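be3_only <- function() {
  editor_registry(list(lookup_editor(builtin_registry(), "BE3")))
}

test_that("a single planted NGG yields placements exactly at the window distances", {
  # 60 A's except a GG making the only NGG PAM at 40-42; protospacer 20-39
  s <- paste(rep("A", 60), collapse = "")
  substr(s, 41, 42) <- "GG"
  reg <- be3_only()
  for (p in 20:39) {
    var <- substr(s, p, p)
    snv <- snv_record("t", s, p, if (var == "A") "G" else "A", var, 0)
    pls <- enumerate_placements(snv, reg)
    expect_equal(placement_key(pls[, c("editor", "strand", "proto_start",
                                       "window", "dist", "pam_site")]),
                 placement_key(oracle_placements(snv, reg)))
    d <- 40 - p
    if (d >= 13 && d <= 17) {
      expect_equal(nrow(pls), 1)
      expect_equal(pls$window, "major")
      expect_equal(pls$dist, d)
      expect_equal(pls$proto_start, 20L)
    } else if ((d >= 10 && d <= 12) || (d >= 18 && d <= 19)) {
      expect_equal(nrow(pls), 1)
      expect_equal(pls$window, "minor")
    } else {
      expect_equal(nrow(pls), 0)
    }
  }
})

test_that("placement criteria are positional: wrong-base SNVs still match, edits are no-ops", {
  # all-A protospacer with AGG PAM: BE3 places, but there is no C to edit
  s <- paste0(paste(rep("A", 20), collapse = ""), "AGGAAA")
  snv <- snv_record("noop", s, 6, "G", "A", 0)  # distance 15, major
  reg <- be3_only()
  pls <- enumerate_placements(snv, reg)
  expect_equal(nrow(pls), 1)
  expect_equal(pls$window, "major")
  out <- simulate_edit(pls[1, ], snv, reg)
  expect_equal(out$edited_sequence, s)
  expect_length(out$changed_positions, 0)
})

test_that("a sequence without any candidate PAM yields no placements", {
  s <- paste(rep("T", 60), collapse = "")
  snv <- snv_record("none", s, 30, "C", "T", 0)
  pls <- enumerate_placements(snv, builtin_registry())
  # brute-force agreement on the full registry for this degenerate case
  expect_equal(nrow(pls), nrow(oracle_placements(snv, builtin_registry())))
  expect_equal(nrow(pls), 0)
})

test_that("every major-window cytosine is converted deterministically", {
  s <- paste0("AAACCCCCAAAAAAAAAAAA", "AGGTTT")
  snv <- snv_record("block", s, 6, "T", "C", 0)  # distance 15
  reg <- be3_only()
  pls <- enumerate_placements(snv, reg)
  expect_true(any(pls$window == "major"))
  out <- simulate_edit(pls[pls$window == "major", ][1, ], snv, reg)
  expect_equal(substr(out$edited_sequence, 1, 20), "AAATTTTTAAAAAAAAAAAA")
  expect_equal(out$changed_positions, 4:8)
})

test_that("the TC context rule converts only T-preceded cytosines", {
  reg <- editor_registry(list(lookup_editor(builtin_registry(),
                                            "eA3A-BE3")))
  # C run preceded by T at window position 4 only
  s1 <- paste0("AATCCCCCAAAAAAAAAAAA", "AGGTTT")
  snv1 <- snv_record("tc", s1, 6, "T", "C", 0)
  pls1 <- enumerate_placements(snv1, reg)
  out1 <- simulate_edit(pls1[pls1$window == "major", ][1, ], snv1, reg)
  expect_equal(out1$changed_positions, 4L)
  expect_equal(substr(out1$edited_sequence, 4, 8), "TCCCC")
  # same run preceded by A: nothing converts
  s2 <- paste0("AAACCCCCAAAAAAAAAAAA", "AGGTTT")
  snv2 <- snv_record("ac", s2, 6, "T", "C", 0)
  pls2 <- enumerate_placements(snv2, reg)
  out2 <- simulate_edit(pls2[pls2$window == "major", ][1, ], snv2, reg)
  expect_length(out2$changed_positions, 0)
})

test_that("minus-strand adenine editing appears as T-to-C on the sense strand", {
  reg <- editor_registry(list(lookup_editor(builtin_registry(),
                                            "ABE 7.10")))
  s <- paste0("CCA", "G", paste(rep("A", 12), collapse = ""), "TTTT",
              "AAA", "AA")
  snv <- snv_record("ms", s, 18, "C", "T", 0)
  pls <- enumerate_placements(snv, reg)
  minus <- pls[pls$strand == "-" & pls$window == "major", ]
  expect_true(nrow(minus) >= 1)
  out <- simulate_edit(minus[1, ], snv, reg)
  expect_equal(substr(out$edited_sequence, 17, 20), "CCCC")
  expect_equal(out$changed_positions, 17:20)
})

test_that("placement search agrees with the sliding brute-force oracle", {
  reg <- oracle_registry()
  set.seed(401)
  for (i in 1:120) {
    snv <- random_snv(sprintf("r%03d", i))
    pls <- enumerate_placements(snv, reg)
    expect_equal(placement_key(pls[, c("editor", "strand", "proto_start",
                                       "window", "dist", "pam_site")]),
                 placement_key(oracle_placements(snv, reg)),
                 info = snv$id)
  }
})

test_that("the pipeline is strand symmetric", {
  reg <- oracle_registry()
  set.seed(402)
  for (i in 1:60) {
    snv <- random_snv(sprintf("s%03d", i))
    expect_equal(sort(outcome_keys(snv, reg)),
                 sort(mirrored_outcome_keys(snv, reg)), info = snv$id)
  }
})

test_that("each outcome applies exactly one chemistry on one strand", {
  reg <- builtin_registry()
  set.seed(403)
  pure <- c("C>T", "G>A", "A>G", "T>C")
  for (i in 1:40) {
    snv <- random_snv(sprintf("p%03d", i))
    pls <- enumerate_placements(snv, reg)
    for (j in seq_len(nrow(pls))) {
      out <- simulate_edit(pls[j, ], snv, reg)
      ch <- out$changed_positions
      if (length(ch) == 0) {
        expect_equal(out$edited_sequence, snv$sequence)
        next
      }
      subs <- unique(paste0(substring(snv$sequence, ch, ch), ">",
                            substring(out$edited_sequence, ch, ch)))
      expect_length(subs, 1)
      expect_true(subs %in% pure)
      # nothing changed outside the recorded positions
      rest <- setdiff(seq_len(nchar(snv$sequence)), ch)
      expect_equal(substring(out$edited_sequence, rest, rest),
                   substring(snv$sequence, rest, rest))
    }
  }
})
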