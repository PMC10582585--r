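test_that("find_hinge locates exact and mismatched anchors", {
  cfg0 <- hinge_config("FOXP2", max_mismatch = 0)
  hm <- find_hinge("QQQQHPGKQAKEQQ", cfg0)
  expect_equal(hm$start, 4L)
  expect_equal(hm$end, 12L)
  expect_equal(hm$mismatches, 0L)

  hm1 <- find_hinge("QQQQHPGKQAKDQQ", hinge_config("FOXP2"))
  expect_equal(hm1$start, 4L)
  expect_equal(hm1$mismatches, 1L)

  hmf1 <- find_hinge("MKKQQALQVARQLLLQQQQ", hinge_config("FOXP1"))
  expect_equal(hmf1$mismatches, 0L)
  expect_equal(hmf1$matched_text, "ALQVARQLLL")

  err <- tryCatch(find_hinge("QQQQQQQQ", hinge_config("FOXP2")),
                  polyqvoc_no_hinge = function(e) e)
  expect_s3_class(err, "polyqvoc_no_hinge")
  expect_false(is.na(err$best_distance))
})

test_that("find_hinge agrees with an exhaustive Hamming scan", {
  set.seed(101)
  cfg <- hinge_config("FOXP2")
  for (i in 1:1000) {
    seq <- random_protein(sample(20:80, 1))
    oracle <- brute_force_hinge(seq, cfg$anchor)
    got <- tryCatch(find_hinge(seq, cfg),
                    polyqvoc_no_hinge = function(e) e)
    if (oracle$dist <= cfg$max_mismatch) {
      expect_equal(got$start, oracle$start)
      expect_equal(got$mismatches, oracle$dist)
    } else {
      expect_s3_class(got, "polyqvoc_no_hinge")
      expect_equal(got$best_distance, oracle$dist)
    }
  }
})

test_that("call_repeats applies the proline and histidine rules", {
  c1 <- call_repeats(paste0("M", strrep("Q", 12), "HPGKQAKE",
                            strrep("Q", 5), "AAA"))
  expect_equal(c1$q1_len, 12L)
  expect_equal(c1$q2_len, 5L)
  expect_equal(c1$sum_s, 17L)
  expect_equal(c1$ratio_r, 2.4)
  expect_equal(c1$extension_len, 0L)

  # Q1 is the run upstream of the first proline; fragments ignored
  c2 <- call_repeats(paste0("M", "QQQQQQ", "P", "QQ", "P", "QQ",
                            "HPGKQAKE", "QQQ"))
  expect_equal(c2$q1_len, 6L)
  expect_true(c2$q1_truncated_by_proline)
  expect_equal(c2$q2_len, 3L)

  # a single embedded histidine counts toward the run
  c3 <- call_repeats(paste0("M", "QQQHQQQQ", "AA", "HPGKQAKE", "QQ"))
  expect_equal(c3$q1_len, 8L)
  expect_true(c3$q1_contains_histidine)
  expect_false(c3$q1_truncated_by_proline)

  # the cetacean-style 22-residue hinge extension
  c4 <- call_repeats(paste0(strrep("Q", 20), "HPGKQAKE",
                            "VGSGRLTHAEEGEAGRGPRRPG", strrep("Q", 10)))
  expect_equal(c4$extension_len, 22L)
  expect_equal(c4$q2_len, 10L)
  expect_equal(c4$q1_len, 20L)
  expect_true("hinge_extension" %in% c4$flags)

  # no downstream run -> flagged, ratio undefined
  c5 <- call_repeats(paste0(strrep("Q", 10), "HPGKQAKE", "AAAAAA"))
  expect_false(is_called(c5))
  expect_true("no_q2" %in% c5$flags)
  expect_true(is.na(c5$ratio_r))
})

test_that("histidine may not open or close a Q1 run", {
  # HQQQ upstream: the H is not interior, so the run has length 3
  cl <- call_repeats(paste0("MA", "HQQQ", "AA", "HPGKQAKE", "QQ"))
  expect_equal(cl$q1_len, 3L)
  expect_false(cl$q1_contains_histidine)
})

test_that("repeat intervals sit on the correct side of the hinge", {
  cl <- call_repeats(paste0("M", strrep("Q", 8), "HPGKQAKE", strrep("Q", 4)))
  expect_lt(cl$q1_interval[2], cl$hinge$start + 1)
  expect_gte(cl$q2_interval[1], cl$hinge$end + cl$extension_len)
  expect_equal(cl$sum_s, cl$q1_len + cl$q2_len)
})

test_that("generated orthologs round-trip exactly across the parameter grid", {
  set.seed(7)
  cases <- expand.grid(q1 = c(2, 3, 7, 20, 41, 60), q2 = c(2, 5, 11, 20),
                       n_p = 0:3, hist = c(FALSE, TRUE), ext = c(0, 22))
  cases <- cases[!(cases$hist & cases$q1 < 3), ]
  for (r in seq_len(nrow(cases))) {
    cs <- cases[r, ]
    g <- gen_ortholog(cs$q1, cs$q2,
                      proline_fragments = rep(2L, cs$n_p),
                      histidine_in_q1 = cs$hist,
                      extension_peptide = if (cs$ext > 0)
                        "VGSGRLTHAEEGEAGRGPRRPG" else NULL)
    cl <- call_repeats(g$record)
    expect_equal(cl$q1_len, g$truth$q1)
    expect_equal(cl$q2_len, g$truth$q2)
    expect_equal(cl$extension_len, g$truth$extension_len)
    expect_equal(cl$q1_truncated_by_proline, cs$n_p > 0)
    expect_equal(cl$q1_contains_histidine, cs$hist)
    expect_identical(cl$ratio_r, cl$q1_len / cl$q2_len)
  }
})

test_that("appending residues after the Q2 run never changes the call", {
  set.seed(11)
  for (i in 1:25) {
    g <- gen_ortholog(sample(2:40, 1), sample(2:15, 1),
                      flank_lengths = c(20L, 0L))
    base <- call_repeats(g$record)
    extended <- paste0(g$record$sequence, random_protein(50,
      letters = setdiff(LETTERS, c("B", "J", "O", "U", "Z", "X", "Q"))))
    again <- call_repeats(extended)
    expect_equal(again$q1_len, base$q1_len)
    expect_equal(again$q2_len, base$q2_len)
    expect_equal(again$extension_len, base$extension_len)
  }
})

test_that("select_longest_isoform maximizes the polyQ sum", {
  mk <- function(q1, q2, id) {
    gen_ortholog(q1, q2, species_label = "sp", sequence_id = id,
                 seed = 3)$record
  }
  sel <- select_longest_isoform(list(mk(10, 5, "a"), mk(12, 5, "b")))
  expect_equal(sel$sequence_id, "b")
  expect_equal(attr(sel, "repeat_call")$q1_len, 12L)

  # tie on the sum keeps input order and flags it
  tie <- select_longest_isoform(list(mk(10, 5, "a"), mk(12, 3, "b")))
  expect_equal(tie$sequence_id, "a")
  expect_true("isoform_tie" %in% attr(tie, "repeat_call")$flags)

  # a flagged record ranks below any called record
  broken <- ortholog_record("sp", "FOXP2", "c", strrep("A", 50))
  sel2 <- select_longest_isoform(list(broken, mk(4, 2, "d")))
  expect_equal(sel2$sequence_id, "d")

  # all flagged -> flagged result propagates
  sel3 <- select_longest_isoform(list(broken))
  expect_false(is_called(attr(sel3, "repeat_call")))
})

test_that("repeat_call_table conserves every input species exactly once", {
  set.seed(21)
  recs <- c(
    lapply(1:5, function(i) gen_ortholog(5 + i, 4,
      species_label = sprintf("sp%d", i),
      sequence_id = sprintf("id%d", i))$record),
    list(ortholog_record("hingeless", "FOXP2", "x", strrep("A", 40))))
  tab <- repeat_call_table(recs)
  expect_equal(sort(tab$species),
               sort(c(sprintf("sp%d", 1:5), "hingeless")))
  expect_equal(tab$flags[tab$species == "hingeless"], "no_hinge")
  expect_equal(anyDuplicated(tab$species), 0L)
})
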