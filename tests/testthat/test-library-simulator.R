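test_that("shearing is deterministic and matches its length model", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 9000L, cds_start = 3000L)
  sm <- shear_model(mean_len = 350, sd_len = 35, n_fragments = 60000, seed = 5)
  lib1 <- shear_plasmid(p, sm)
  lib2 <- shear_plasmid(p, sm)
  expect_identical(lib1, lib2)
  expect_lt(abs(mean(lib1$length) - 350) / 350, 0.01)
  # start distribution uniform: a single fixed-seed chi-square has a 1%
  # false-alarm rate by construction, so check GOF over three seeds (at
  # most one may dip below 0.01) plus a coarse max-deviation bound
  pvals <- vapply(c(5, 6, 7), function(s) {
    lib <- shear_plasmid(p, shear_model(350, 35, 30, 60000, seed = s))
    counts <- tabulate(lib$start %/% 90L + 1L, 100L)
    expect_lt(max(abs(counts - 600)) / 600, 0.2)
    chisq.test(counts)$p.value
  }, numeric(1))
  expect_gte(sum(pvals > 0.01), 2L)
  # strands balanced
  expect_lt(abs(mean(lib1$strand == "+") - 0.5), 0.01)
})

test_that("an empty shear model warns and returns an empty library", {
  p <- toy_plasmid()
  expect_warning(lib <- shear_plasmid(p, shear_model(n_fragments = 0)), "empty")
  expect_identical(nrow(lib), 0L)
})

test_that("exactly six frame classes exist and follow the label map", {
  p <- toy_plasmid()
  s0 <- codon_nt(p, 10L)
  labels <- as.vector(outer(0:2, c("+", "-"), function(o, st)
    assign_frame_label(s0 + o, st, p)))
  expect_setequal(labels, c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_length(unique(labels), 6L)
  # offset 0 on the sense strand is the coding class "+2"
  expect_identical(assign_frame_label(s0, "+", p), "+2")
  # +3 nt preserves the label; +1 nt moves to the next label cyclically
  expect_identical(assign_frame_label(s0 + 3L, "+", p), "+2")
  expect_identical(assign_frame_label(s0 + 1L, "+", p), "+3")
  expect_identical(assign_frame_label(s0 + 2L, "+", p), "+1")
  # reverse strand is always a negative class
  expect_true(all(assign_frame_label(s0 + 0:5, "-", p) %in% c("-1", "-2", "-3")))
  # configurable coding label
  lm <- frame_label_map("+1")
  expect_identical(assign_frame_label(s0, "+", p, lm), "+1")
})

test_that("pre-selection frame fractions are uniform at 1/6", {
  p <- toy_plasmid(orf_aa = 400L, total_len = 9000L, cds_start = 3000L)
  lib <- shear_plasmid(p, shear_model(n_fragments = 50000, seed = 9))
  fd <- frame_distribution(lib$frame)
  expect_equal(fd$mean_pct, 100 / 6, tolerance = 1e-12)
  expect_true(all(abs(fd$fractions - 1 / 6) < 0.02))
  cs <- suppressWarnings(chisq.test(as.vector(fd$counts)))
  expect_gt(cs$p.value, 0.01)
})

test_that("binding selection requires coding frame, full coverage and no stop", {
  p <- toy_plasmid(orf_aa = 200L, total_len = 2000L, cds_start = 600L)
  bm <- binding_model(true_interval = aa_interval(58, 128))
  # coding-frame fragment spanning aa 50..140 -> selected for binding
  lib <- lib_df(codon_nt(p, 50L), 3L * 91L, "+", p)
  sel <- select_fragments(lib, p, bm, seed = 1)
  expect_identical(sel$cause, "binding")
  # same interval but frame-shifted by 1 nt -> not selected
  lib2 <- lib_df(codon_nt(p, 50L) + 1L, 3L * 91L, "+", p)
  expect_identical(select_fragments(lib2, p, bm, seed = 1)$cause, "none")
  # reverse strand -> not selected
  lib3 <- lib_df(codon_nt(p, 50L), 3L * 91L, "-", p)
  expect_identical(select_fragments(lib3, p, bm, seed = 1)$cause, "none")
  # partial coverage (aa 58..100) at stringency 0 -> not selected
  lib4 <- lib_df(codon_nt(p, 58L), 3L * 43L, "+", p)
  expect_identical(select_fragments(lib4, p, bm, seed = 1)$cause, "none")
})

test_that("a stop codon before the end of the binding interval kills selection", {
  # build a plasmid whose backbone immediately upstream of the ORF is all TAA
  set.seed(2)
  orf <- paste0(c("ATG", sample(fragmap:::SENSE_CODONS, 149, TRUE), "TAA"),
                collapse = "")
  backbone <- strrep("TAA", 400)
  seqn <- paste0(backbone, orf, strrep("AC", 300))
  p <- plasmid_map("stopper", seqn, cds_start = nchar(backbone),
                   cds_aa_length = 150L)
  bm <- binding_model(true_interval = aa_interval(10, 60))
  # junction inside the CDS: stop-free, selected
  lib_in <- lib_df(codon_nt(p, 2L), 3L * 80L, "+", p)
  expect_identical(select_fragments(lib_in, p, bm, seed = 1)$cause, "binding")
  # junction 9 nt upstream in the stop-ridden backbone: read-through blocked
  lib_up <- lib_df(codon_nt(p, 2L) - 9L, 3L * 83L, "+", p)
  expect_identical(select_fragments(lib_up, p, bm, seed = 1)$cause, "none")
})

test_that("forbidden-interval inclusion abolishes binding selection", {
  p <- toy_plasmid(orf_aa = 200L, total_len = 2000L, cds_start = 600L)
  bm <- binding_model(true_interval = aa_interval(58, 128),
                      forbidden_interval = aa_interval(129, 135))
  # ends exactly at codon 128: selected
  ok <- lib_df(codon_nt(p, 50L), 3L * 79L, "+", p)
  expect_identical(select_fragments(ok, p, bm, seed = 1)$cause, "binding")
  # extends one codon further: covers residue 129 -> vetoed
  veto <- lib_df(codon_nt(p, 50L), 3L * 80L, "+", p)
  expect_identical(select_fragments(veto, p, bm, seed = 1)$cause, "none")
})

test_that("fragments shorter than the binding interval are never selected for binding", {
  p <- toy_plasmid(orf_aa = 200L, total_len = 2000L, cds_start = 600L)
  bm <- binding_model(true_interval = aa_interval(58, 128),
                      background_rate = 0.1)
  set.seed(4)
  lib <- lib_df(sample(0:1999, 3000, TRUE),
                sample(30:(3L * 70L), 3000, TRUE),  # all < 71 codons
                sample(c("+", "-"), 3000, TRUE), p)
  sel <- select_fragments(lib, p, bm, seed = 2)
  expect_false(any(sel$cause == "binding"))
  expect_gt(sum(sel$cause == "background"), 0L)
})

test_that("TAD intervals cause self-activation in coding frame only", {
  p <- toy_plasmid(orf_aa = 200L, total_len = 2000L, cds_start = 600L)
  bm <- binding_model(true_interval = aa_interval(150, 190),
                      tad_intervals = list(aa_interval(20, 28)))
  # covers the TAD but not the (unreachable) bait interval
  lib <- lib_df(codon_nt(p, 10L), 3L * 30L, "+", p)
  expect_identical(select_fragments(lib, p, bm, seed = 1)$cause, "self_activation")
  s <- simulate_selection(lib, p, bm, seed = 1)
  expect_identical(unname(s$by_cause[["self_activation"]]), 1L)
})

test_that("with no background and no TADs every selected fragment is coding", {
  p <- toy_plasmid(orf_aa = 300L, total_len = 3000L, cds_start = 900L)
  lib <- shear_plasmid(p, shear_model(250, 25, n_fragments = 30000, seed = 8))
  bm <- binding_model(true_interval = aa_interval(100, 140))
  s <- simulate_selection(lib, p, bm, seed = 3)
  expect_true(all(s$selected$frame == "+2"))
  expect_true(all(s$selected$cause == "binding"))
  # the intersection of selected spans contains the true interval
  spans <- lapply(seq_len(nrow(s$selected)), function(i)
    residue_span(s$selected$start[i], s$selected$length[i], p))
  inter <- oracle_intersection(spans)
  expect_lte(inter$start_res, 100L)
  expect_gte(inter$end_res, 140L)
})

test_that("increasing coverage stringency never removes selected fragments", {
  p <- toy_plasmid(orf_aa = 300L, total_len = 3000L, cds_start = 900L)
  lib <- shear_plasmid(p, shear_model(250, 25, n_fragments = 20000, seed = 8))
  bm0 <- binding_model(true_interval = aa_interval(100, 160))
  sel_prev <- select_fragments(lib, p, bm0, seed = 7)$selected
  for (cs in c(0.2, 0.5, 1)) {
    bm <- binding_model(true_interval = aa_interval(100, 160),
                        coverage_stringency = cs)
    sel <- select_fragments(lib, p, bm, seed = 7)$selected
    expect_true(all(which(sel_prev) %in% which(sel)))
    sel_prev <- sel
  }
})

test_that("selection is deterministic for a fixed seed and errors when empty", {
  p <- toy_plasmid(orf_aa = 300L, total_len = 3000L, cds_start = 900L)
  lib <- shear_plasmid(p, shear_model(250, 25, n_fragments = 5000, seed = 8))
  bm <- binding_model(true_interval = aa_interval(100, 140),
                      background_rate = 0.01)
  s1 <- simulate_selection(lib, p, bm, seed = 3)
  s2 <- simulate_selection(lib, p, bm, seed = 3)
  expect_identical(s1$fragments, s2$fragments)
  # unreachable interval, no background -> explicit empty-selection error
  bm_dead <- binding_model(true_interval = aa_interval(1, 299))
  expect_error(simulate_selection(lib, p, bm_dead, seed = 3), "empty selection")
})
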