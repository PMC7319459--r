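# hand-built outcome, for unit-testing the classification rules in isolation
mk_outcome <- function(edited, changed, window = "major") {
  structure(list(placement = list(editor = "BE3", strand = "+",
                                  proto_start = 1L,
                                  proto_end = nchar(edited), pam_start = NA,
                                  pam_end = NA, pam_site = "NGG",
                                  window = window, dist = 15L),
                 edited_sequence = edited,
                 changed_positions = as.integer(changed),
                 minor_bystander_flag = FALSE,
                 minor_window_match = window == "minor"),
            class = "edit_outcome")
}

test_that("the four scenarios and rejection follow the decision order", {
  # precise: edited DNA equals the reference allele
  snv <- snv_record("p", "ACTAAA", 2, "T", "C", 0)
  expect_equal(classify_outcome(mk_outcome("ATTAAA", 2), snv)$scenario,
               "precise")
  # multiple bases synonymous: SNV restored, bystander changed, protein kept
  snv <- snv_record("m", "ACTCTA", 2, "T", "C", 0)
  res <- classify_outcome(mk_outcome("ATTTTA", c(2, 4)), snv)
  expect_equal(res$scenario, "multiple_bases_synonymous")
  expect_equal(res$reference_protein, "IL")
  expect_equal(res$variant_protein, "TL")
  expect_equal(res$edited_protein, "IL")
  # on-target synonymous: Ile ATG variant reverted to ATA, not ATT
  snv <- snv_record("o", "ATGAAA", 3, "T", "G", 0)
  res <- classify_outcome(mk_outcome("ATAAAA", 3), snv)
  expect_equal(res$scenario, "on_target_synonymous")
  expect_equal(res$snv_base_after_edit, "A")
  # bystander synonymous: Phe TTT variant turned into Leu CTT, SNV untouched
  snv <- snv_record("b", "TTTAAA", 3, "A", "T", 0)
  res <- classify_outcome(mk_outcome("CTTAAA", 1), snv)
  expect_equal(res$scenario, "bystander_synonymous")
  expect_equal(res$snv_base_after_edit, "T")
  # rejection: SNV codon fixed but the edit breaks the neighboring codon
  snv <- snv_record("n", "ACTCAA", 2, "T", "C", 0)
  expect_equal(classify_outcome(mk_outcome("ATTTAA", c(2, 4)), snv)$scenario,
               "none")
})

test_that("classification is a pure function of its inputs", {
  snv <- snv_record("x", "ACTCTA", 2, "T", "C", 0)
  out <- mk_outcome("ATTTTA", c(2, 4))
  expect_identical(classify_outcome(out, snv)$scenario,
                   classify_outcome(out, snv)$scenario)
})

test_that("an R>W transversion is rescued on-target by an adenine editor", {
  # reference codon AGG (Arg), variant TGG (Trp): T-to-C on the sense strand
  # (an ABE acting on the minus strand) restores an Arg codon, CGG
  cassette <- "GTCCAGGAAGACGAAGACGGCTGGAAA"
  s <- paste0(cassette, strrep("GAA", 18))  # 81 nt
  snv <- snv_record("rw", s, 22, "A", "T", 0)
  cs <- find_corrections(snv, builtin_registry())
  df <- as.data.frame(cs)
  expect_true(nrow(df) >= 1)
  expect_false(any(df$scenario == "precise"))
  hit <- df[df$scenario == "on_target_synonymous" & df$window == "major", ]
  expect_true("ABE 7.10" %in% hit$editor)
  expect_true(all(df$scenario %in% c("on_target_synonymous",
                                     "bystander_synonymous",
                                     "multiple_bases_synonymous")))
  # the rescue restores an Arg codon, CGG
  abe <- which(df$editor == "ABE 7.10")[1]
  expect_equal(substr(cs$results[[abe]]$outcome$edited_sequence, 22, 24),
               "CGG")
})

test_that("transversions never yield precise corrections", {
  reg <- builtin_registry()
  set.seed(404)
  n_checked <- 0
  for (i in 1:60) {
    snv <- random_snv(sprintf("tv%03d", i))
    if (is_transition(snv$ref_base, snv$var_base)) next
    n_checked <- n_checked + 1
    df <- as.data.frame(find_corrections(snv, reg))
    expect_false(any(df$scenario == "precise"), info = snv$id)
  }
  expect_gt(n_checked, 10)
})

test_that("a transition with no PAM in the flanks finds nothing", {
  s <- paste(rep("T", 60), collapse = "")
  snv <- snv_record("bare", s, 30, "C", "T", 0)
  expect_length(find_corrections(snv, builtin_registry()), 0)
})

test_that("results are serialized precise-first with the output columns", {
  fx <- generate_fixture(1, c(precise = 1), seed = 3)
  cs <- find_corrections(fx$records[[1]], builtin_registry())
  df <- as.data.frame(cs)
  expect_named(df, c("id", "editor", "strand", "protospacer", "pam",
                     "snv_distance_from_pam", "window", "scenario",
                     "edited_window_sequence", "bystander_count",
                     "minor_bystander_flag"))
  expect_true(any(df$scenario == "precise"))
  prec_rows <- which(df$scenario == "precise")
  expect_equal(prec_rows, seq_along(prec_rows))
})
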